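# shared fixtures: small geometries and parameter sets built in code

# circular cell with concentric circular nucleus, pixel radii given
disc_geometry <- function(n = 64, pixel_size = 1.24, r_cell_px = 24,
                          r_nuc_px = 9, center = NULL) {
  if (is.null(center)) center <- c((n + 1) / 2, (n + 1) / 2)
  X <- matrix(seq_len(n), n, n)
  Y <- matrix(seq_len(n), n, n, byrow = TRUE)
  d2 <- (X - center[1])^2 + (Y - center[2])^2
  lab <- matrix(0L, n, n)
  lab[d2 <= r_cell_px^2] <- 1L
  lab[d2 <= r_nuc_px^2] <- 2L
  compartment_geometry(lab, pixel_size)
}

# total amount (concentration x pixel area) per effector
total_amount <- function(fields, geometry) {
  cell <- geometry$labels != 0L
  sum(fields$U[cell] + fields$P[cell]) * geometry$pixel_size^2
}

default_volumes <- function(geometry) {
  list(V_cyt = geometry$areas[["cytoplasm"]],
       V_nuc = geometry$areas[["nucleus"]])
}
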