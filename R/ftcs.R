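#' Stable explicit time step for the FTCS scheme
#'
#' The forward-time centred-space update is stable (and preserves
#' non-negativity for first-order kinetics) when
#' `dt <= safety * h^2 / (4 * D_max)` and when no pixel can lose more
#' than a `safety` fraction of its content per step through first-order
#' reactions or membrane fluxes, i.e. `dt * k_max <= safety` with
#' `k_max` the largest total first-order loss rate (rate constants plus
#' permeabilities divided by the pixel size).
#'
#' @param params A [shuttle_params()] object.
#' @param pixel_size Pixel edge length, um (> 0).
#' @param safety Fraction of the stability limit to use, in (0, 1].
#' @return Time step in seconds.
#' @examples
#' stable_timestep(shuttle_params(D_U_cyt = 1, D_U_nuc = 1, D_P_cyt = 1,
#'                                D_P_nuc = 1), pixel_size = 1, safety = 1)
#' @export
stable_timestep <- function(params, pixel_size, safety = 0.9) {
  stopifnot(inherits(params, "shuttle_params"))
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be positive", call. = FALSE)
  if (safety <= 0 || safety > 1)
    stop("safety must lie in (0, 1]", call. = FALSE)
  D_max <- max(params$D_U_cyt, params$D_U_nuc, params$D_P_cyt,
               params$D_P_nuc)
  dt <- safety * pixel_size^2 / (4 * D_max)
  # worst-case total first-order loss rate on any pixel; a pixel can
  # carry up to 3 membrane faces, so permeability losses count 3x
  k_max <- max(
    params$k_phos + params$k_deg + 3 * params$k_import / pixel_size,
    params$k_dephos_cyt + params$k_deg,
    params$k_phos,
    params$k_dephos_nuc + 3 * params$k_export / pixel_size,
    3 * params$k_export / pixel_size
  )
  if (k_max > 0) dt <- min(dt, safety / k_max)
  dt
}

#' Initial concentration fields
#'
#' Default initial condition: all protein unphosphorylated, uniform in
#' the cytoplasm at concentration `u0`. Because the reaction network is
#' linear and simulations are run to steady state, the fitted observable
#' does not depend on this choice.
#'
#' @param geometry A [compartment_geometry()].
#' @param u0 Initial cytoplasmic U concentration.
#' @return List with matrices `U` and `P` (zero outside allowed regions)
#'   and `t = 0`.
#' @export
initial_fields <- function(geometry, u0 = 1) {
  lab <- geometry$labels
  U <- matrix(0, nrow(lab), ncol(lab))
  U[lab == 1L] <- u0
  list(U = U, P = matrix(0, nrow(lab), ncol(lab)), t = 0)
}

#' Advance the concentration fields by one FTCS step
#'
#' Single explicit update `c <- c + dt * (D lap(c) + reactions + membrane
#' fluxes)`; exposed mainly for testing and for custom stepping loops.
#' Refuses a `dt` above the stability bound.
#'
#' @param fields List with matrices `U`, `P` and time `t`.
#' @param geometry A [compartment_geometry()].
#' @param network A [shuttle_topology()] network.
#' @param params A [shuttle_params()] object.
#' @param dt Time step, s.
#' @return Updated fields list.
#' @export
ftcs_step <- function(fields, geometry, network, params, dt) {
  dt_max <- stable_timestep(params, geometry$pixel_size, safety = 1)
  if (dt > dt_max * (1 + 1e-12))
    stop("dt = ", dt, " exceeds the FTCS stability bound ", dt_max,
         call. = FALSE)
  out <- ftcs_run_cpp(fields$U, fields$P, geometry$labels,
                      topology_code(network), param_vector(params),
                      geometry$pixel_size, dt, 1L, 0, 1L)
  list(U = out$U, P = out$P, t = fields$t + dt)
}

topology_code <- function(network) {
  if (network$topology == "alternative") 1L else 0L
}

param_vector <- function(params) {
  unlist(params[c("k_phos", "k_dephos_nuc", "k_dephos_cyt", "k_import",
                  "k_export", "k_syn", "k_deg", "D_U_cyt", "D_U_nuc",
                  "D_P_cyt", "D_P_nuc")])
}

#' Simulate the spatial model to steady state
#'
#' Runs the FTCS scheme until the concentration distribution no longer
#' changes: the maximum pixelwise rate of change across species must
#' fall below `tol` times the mean concentration over the cell (units of
#' concentration per second), or until `t_max` is reached.
#'
#' @inheritParams ftcs_step
#' @param init Initial fields as from [initial_fields()]; `NULL` uses the
#'   default (all protein as U, uniform in cytoplasm).
#' @param tol Relative steady-state tolerance (per second); the absolute
#'   threshold is `tol * mean(U + P over cell pixels)` evaluated at the
#'   initial condition.
#' @param t_max Maximum simulated time, s.
#' @param dt Time step, s; default [stable_timestep()].
#' @param safety Safety fraction passed to [stable_timestep()] when `dt`
#'   is not given.
#' @return An object of class `simulation_result`: list with `fields`
#'   (final `U`, `P`), `steady_state_reached`, `final_rate_norm`
#'   (conc/s), `elapsed_time`, `dt_used`, `n_steps`, and the inputs
#'   `geometry`, `network`, `params`.
#' @examples
#' g <- synth_geometry(scene_spec(grid = 48, n_cells = 1, seed = 1))
#' sim <- simulate_steady_state(g, shuttle_topology("alternative"),
#'                              shuttle_params(), t_max = 500)
#' sim$steady_state_reached
#' @export
simulate_steady_state <- function(geometry, network, params, init = NULL,
                                  tol = 1e-6, t_max = 5000, dt = NULL,
                                  safety = 0.9) {
  stopifnot(inherits(geometry, "compartment_geometry"))
  validate_network(network)
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  if (is.null(init)) init <- initial_fields(geometry)
  if (is.null(dt)) dt <- stable_timestep(params, geometry$pixel_size, safety)
  dt_max <- stable_timestep(params, geometry$pixel_size, safety = 1)
  if (dt > dt_max * (1 + 1e-12))
    stop("dt exceeds the FTCS stability bound", call. = FALSE)

  cell <- geometry$labels != 0L
  mean_conc <- mean(init$U[cell] + init$P[cell])
  if (mean_conc <= 0) mean_conc <- 1
  tol_abs <- tol * mean_conc

  n_steps <- max(1L, as.integer(ceiling(t_max / dt)))
  out <- ftcs_run_cpp(init$U, init$P, geometry$labels,
                      topology_code(network), param_vector(params),
                      geometry$pixel_size, dt, n_steps, tol_abs, 25L)

  structure(list(
    fields = list(U = out$U, P = out$P),
    steady_state_reached = out$converged,
    final_rate_norm = out$max_rate,
    rate_ss = out$rate_ss,
    elapsed_time = out$n_steps * dt,
    dt_used = dt,
    n_steps = out$n_steps,
    geometry = geometry,
    network = network,
    params = params
  ), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("FTCS simulation (", x$network$topology, " topology): ",
      x$n_steps, " steps of dt = ", format(x$dt_used, digits = 4),
      " s (t = ", format(x$elapsed_time, digits = 5), " s)\n", sep = "")
  cat("  steady state reached: ", x$steady_state_reached,
      " (max |dc/dt| = ", format(x$final_rate_norm, digits = 3),
      " conc/s)\n", sep = "")
  cat("  simulated NCR: ", format(simulated_ncr(x), digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Total-fluorescence observable of a simulation
#'
#' The fluorescent tag labels both phospho-forms, so the imaged quantity
#' is `U + P` per pixel (zero on exterior pixels).
#'
#' @param sim A `simulation_result`, or a fields list with `U` and `P`.
#' @return A matrix of per-pixel intensities.
#' @export
total_fluorescence <- function(sim) {
  f <- if (inherits(sim, "simulation_result")) sim$fields else sim
  f$U + f$P
}

#' Compartment-mean NCR of a simulation
#'
#' Mean of U+P over nucleus pixels divided by the mean over cytoplasm
#' pixels.
#'
#' @param sim A `simulation_result`.
#' @return The simulated nuclear/cytoplasmic ratio.
#' @export
simulated_ncr <- function(sim) {
  stopifnot(inherits(sim, "simulation_result"))
  tot <- total_fluorescence(sim)
  lab <- sim$geometry$labels
  mean(tot[lab == 2L]) / mean(tot[lab == 1L])
}

#' Compartment means of a simulation
#' @param sim A `simulation_result`.
#' @return Named vector of mean concentrations per species and
#'   compartment.
#' @export
compartment_means <- function(sim) {
  stopifnot(inherits(sim, "simulation_result"))
  lab <- sim$geometry$labels
  c(U_cyt = mean(sim$fields$U[lab == 1L]),
    P_cyt = mean(sim$fields$P[lab == 1L]),
    U_nuc = mean(sim$fields$U[lab == 2L]),
    P_nuc = mean(sim$fields$P[lab == 2L]))
}

#' Write simulated fields as a multi-page TIFF
#'
#' Pages: U then P, stored as 32-bit floats scaled by the caller.
#'
#' @param sim A `simulation_result` or fields list.
#' @param path Output `.tif` path.
#' @export
write_fields <- function(sim, path) {
  f <- if (inherits(sim, "simulation_result")) sim$fields else sim
  mx <- max(f$U, f$P, 1e-12)
  tiff::writeTIFF(list(f$U / mx, f$P / mx), path, bits.per.sample = 32L)
  invisible(path)
}
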