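#' Kinetic parameters of the shuttling model
#'
#' All reactions are first order; membrane transports are expressed as
#' permeabilities (flux density = permeability x source-side
#' concentration). Units: rate constants 1/s, permeabilities um/s,
#' diffusion coefficients um^2/s, synthesis conc/s.
#'
#' Defaults describe a cell in which the nuclear
#' phosphorylation/dephosphorylation ratio `r = k_phos / k_dephos_nuc`
#' controls localization: at the low end of the scanned range the
#' effector is nuclear-enriched, at the high end it is excluded (the
#' well-mixed NCR crosses 1 between the two regimes).
#'
#' @param k_phos Phosphorylation rate (nuclear under the alternative
#'   topology, cytoplasmic under the canonical), 1/s.
#' @param k_dephos_nuc Nuclear dephosphorylation rate, 1/s (alternative
#'   topology only).
#' @param k_dephos_cyt Cytoplasmic dephosphorylation rate, 1/s.
#' @param k_import Nuclear-membrane permeability for import of U, um/s.
#' @param k_export Nuclear-membrane permeability for export (of P under
#'   the alternative topology, return flux of U under the canonical),
#'   um/s.
#' @param k_syn Zeroth-order cytoplasmic synthesis of U, conc/s.
#' @param k_deg First-order cytoplasmic degradation of U and P, 1/s.
#' @param D_U_cyt,D_U_nuc,D_P_cyt,D_P_nuc Diffusion coefficients per
#'   species and compartment, um^2/s.
#' @param bounds Optional bounds table as returned by
#'   [default_param_bounds()]; when supplied, values outside it are
#'   rejected.
#' @return An object of class `shuttle_params` (a named list).
#' @examples
#' p <- shuttle_params(k_phos = 0.17 * 0.2)
#' phospho_ratio(p)
#' @export
shuttle_params <- function(k_phos = 0.1, k_dephos_nuc = 0.2,
                           k_dephos_cyt = 0.05, k_import = 0.2,
                           k_export = 1.0, k_syn = 0.01, k_deg = 0.01,
                           D_U_cyt = 3, D_U_nuc = 3, D_P_cyt = 3,
                           D_P_nuc = 3, bounds = NULL) {
  p <- list(k_phos = k_phos, k_dephos_nuc = k_dephos_nuc,
            k_dephos_cyt = k_dephos_cyt, k_import = k_import,
            k_export = k_export, k_syn = k_syn, k_deg = k_deg,
            D_U_cyt = D_U_cyt, D_U_nuc = D_U_nuc, D_P_cyt = D_P_cyt,
            D_P_nuc = D_P_nuc)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all kinetic parameters must be finite and >= 0", call. = FALSE)
  if (any(vals[grep("^D_", names(vals))] <= 0))
    stop("diffusion coefficients must be strictly positive", call. = FALSE)
  if (!is.null(bounds)) {
    for (nm in intersect(names(p), rownames(bounds))) {
      if (p[[nm]] < bounds[nm, "lower"] || p[[nm]] > bounds[nm, "upper"])
        stop("parameter ", nm, " = ", p[[nm]], " outside bounds [",
             bounds[nm, "lower"], ", ", bounds[nm, "upper"], "]",
             call. = FALSE)
    }
  }
  structure(p, class = "shuttle_params")
}

#' @export
print.shuttle_params <- function(x, ...) {
  cat("Shuttling model parameters:\n")
  print(unlist(x))
  if (x$k_dephos_nuc > 0)
    cat("phospho/dephospho ratio r =",
        format(x$k_phos / x$k_dephos_nuc, digits = 4), "\n")
  invisible(x)
}

#' Default parameter bounds for fitting
#'
#' Spans covering published estimates of YAP/TAZ transport and mobility:
#' first-order rate constants 1e-4 to 1 1/s, membrane permeabilities
#' 1e-3 to 10 um/s, diffusion coefficients 0.1 to 30 um^2/s. Synthesis
#' shares the rate-constant span (its scale only sets the arbitrary
#' concentration unit). All bounds are overridable.
#'
#' @return A matrix with rownames = parameter names and columns
#'   `lower`, `upper`.
#' @export
default_param_bounds <- function() {
  nm <- c("k_phos", "k_dephos_nuc", "k_dephos_cyt", "k_syn", "k_deg",
          "k_import", "k_export",
          "D_U_cyt", "D_U_nuc", "D_P_cyt", "D_P_nuc")
  lower <- c(rep(1e-4, 5), rep(1e-3, 2), rep(0.1, 4))
  upper <- c(rep(1, 5), rep(10, 2), rep(30, 4))
  m <- cbind(lower = lower, upper = upper)
  rownames(m) <- nm
  m
}

#' Read / write kinetic parameters as YAML
#'
#' @param params A `shuttle_params` object.
#' @param path YAML file path.
#' @return `params_from_yaml` returns a validated `shuttle_params`.
#' @export
params_to_yaml <- function(params, path) {
  stopifnot(inherits(params, "shuttle_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname params_to_yaml
#' @export
params_from_yaml <- function(path) {
  do.call(shuttle_params, yaml::read_yaml(path))
}

#' Modify parameters, setting the nuclear phospho/dephospho ratio
#'
#' Returns a copy of `params` with `k_phos = r * k_dephos_nuc`.
#'
#' @param params A `shuttle_params` object.
#' @param r Target ratio (> 0).
#' @export
set_phospho_ratio <- function(params, r) {
  stopifnot(inherits(params, "shuttle_params"), r >= 0,
            params$k_dephos_nuc > 0)
  params$k_phos <- r * params$k_dephos_nuc
  params
}
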