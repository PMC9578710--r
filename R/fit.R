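#' Normalize an intensity image to its maximum
#'
#' Each target and simulated image is divided by its own maximum before
#' comparison, which removes the arbitrary intensity scale of
#' fluorescence data. An all-zero image is returned unchanged and
#' flagged via the `"all_zero"` attribute; negative pixels are rejected
#' (background subtraction must happen upstream).
#'
#' @param image Numeric matrix, finite and non-negative.
#' @return The normalized matrix (max pixel = 1 unless all-zero), with
#'   attribute `all_zero`.
#' @examples
#' normalize_to_max(matrix(c(0, 50, 100, 200), 2))
#' @export
normalize_to_max <- function(image) {
  if (!is.matrix(image) || !all(is.finite(image)))
    stop("image must be a finite numeric matrix", call. = FALSE)
  if (any(image < 0))
    stop("image has negative pixels; subtract background first",
         call. = FALSE)
  mx <- max(image)
  if (mx == 0) {
    warning("all-zero image: normalization skipped")
    attr(image, "all_zero") <- TRUE
    return(image)
  }
  out <- image / mx
  attr(out, "all_zero") <- FALSE
  out
}

#' Residual image: data minus model
#'
#' Per-pixel `target - simulated`, restricted to cell pixels (exterior
#' set to 0). Positive residuals mean the model under-predicts the data.
#'
#' @param target,simulated Max-normalized intensity matrices of equal
#'   dimensions.
#' @param geometry A [compartment_geometry()] matching both images.
#' @return Residual matrix.
#' @export
residual_image <- function(target, simulated, geometry) {
  if (!all(dim(target) == dim(simulated)) ||
      !all(dim(target) == dim(geometry$labels)))
    stop("target, simulation and geometry dimensions differ", call. = FALSE)
  res <- target - simulated
  res[geometry$labels == 0L] <- 0
  res
}

#' Summarized residual between target and simulation
#'
#' Scalar aggregate of the residual image: the mean of squared residuals
#' over cell pixels, so values are comparable across geometries of
#' different size.
#'
#' @inheritParams residual_image
#' @return Mean squared residual (dimensionless).
#' @export
summarized_residual <- function(target, simulated, geometry) {
  res <- residual_image(target, simulated, geometry)
  cell <- geometry$labels != 0L
  mean(res[cell]^2)
}

#' Two-term fitting cost at a parameter point
#'
#' Simulates the model to steady state at `params`, max-normalizes the
#' total-fluorescence observable and returns
#' `w_img * <squared pixel differences> + w_ss * <squared concentration
#' rates of change>`. The image term is the mean squared difference over
#' cell pixels; the steady-state term is the mean squared rate of change
#' relative to the mean concentration, so a residual drift of 1\% of the
#' mean concentration per second costs as much as a 1\% image mismatch.
#' A failed simulation yields `+Inf` so that optimizers discard the
#' point.
#'
#' @param params A [shuttle_params()] object.
#' @param target Max-normalized target matrix.
#' @param geometry A [compartment_geometry()].
#' @param network A [shuttle_topology()] network.
#' @param weights Named vector `c(w_img, w_ss)`, both >= 0, not both 0.
#' @param sim_tol,sim_t_max,dt_safety Steady-state solver controls, see
#'   [simulate_steady_state()].
#' @return The scalar cost; the simulation is attached as attribute
#'   `"sim"` when `keep_sim = TRUE`.
#' @param keep_sim Attach the simulation result to the returned cost?
#' @export
fit_cost <- function(params, target, geometry, network,
                     weights = c(w_img = 1, w_ss = 1),
                     sim_tol = 1e-5, sim_t_max = 3000, dt_safety = 0.9,
                     keep_sim = FALSE) {
  if (any(weights < 0) || sum(weights) == 0)
    stop("weights must be >= 0 and not both zero", call. = FALSE)
  sim <- tryCatch(
    simulate_steady_state(geometry, network, params, tol = sim_tol,
                          t_max = sim_t_max, safety = dt_safety),
    error = function(e) NULL)
  if (is.null(sim) || !all(is.finite(sim$fields$U)) ||
      !all(is.finite(sim$fields$P)))
    return(Inf)
  obs <- normalize_to_max(total_fluorescence(sim))
  cell <- geometry$labels != 0L
  img_term <- mean((target[cell] - obs[cell])^2)
  mean_conc <- mean(sim$fields$U[cell] + sim$fields$P[cell])
  ss_term <- if (mean_conc > 0)
    (sim$rate_ss / (2 * sum(cell))) / mean_conc^2 else Inf
  cost <- weights[["w_img"]] * img_term + weights[["w_ss"]] * ss_term
  if (keep_sim) attr(cost, "sim") <- sim
  cost
}

#' Global-best particle swarm minimizer
#'
#' Standard global-best PSO with constriction-style coefficients
#' (inertia 0.729, cognitive and social acceleration 1.49445) and
#' reflecting bound handling. Deterministic given `seed`.
#'
#' @param fn Objective `function(x)` returning a scalar (may be `Inf`).
#' @param lower,upper Numeric bounds, `lower < upper` elementwise.
#' @param n_particles,n_iterations Swarm size (>= 2) and iteration count.
#' @param seed Integer RNG seed.
#' @param inertia,c_cog,c_soc Velocity-update coefficients.
#' @return List with `par` (best position), `value`, `trace`
#'   (best-so-far cost per iteration, non-increasing), `n_evaluations`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' pso_optim(sphere, rep(-5, 3), rep(5, 3), seed = 1)$value
#' @export
pso_optim <- function(fn, lower, upper, n_particles = 20,
                      n_iterations = 200, seed = 1, inertia = 0.729,
                      c_cog = 1.49445, c_soc = 1.49445) {
  d <- length(lower)
  if (d == 0 || length(upper) != d || any(!is.finite(lower)) ||
      any(!is.finite(upper)) || any(lower >= upper))
    stop("bounds must be finite with lower < upper", call. = FALSE)
  if (n_particles < 2) stop("n_particles must be >= 2", call. = FALSE)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  span <- upper - lower
  X <- matrix(runif(n_particles * d, lower, upper), n_particles, d,
              byrow = TRUE)
  V <- matrix(runif(n_particles * d, -span, span), n_particles, d,
              byrow = TRUE) * 0.1
  pbest <- X
  pcost <- apply(X, 1, fn)
  g <- which.min(pcost)
  gbest <- X[g, ]
  gcost <- pcost[g]
  trace <- numeric(n_iterations)
  n_eval <- n_particles

  for (it in seq_len(n_iterations)) {
    r1 <- matrix(runif(n_particles * d), n_particles, d)
    r2 <- matrix(runif(n_particles * d), n_particles, d)
    V <- inertia * V + c_cog * r1 * (pbest - X) +
      c_soc * r2 * sweep(-X, 2, gbest, "+")
    X <- X + V
    # reflect at bounds
    for (k in seq_len(d)) {
      lo <- X[, k] < lower[k]
      X[lo, k] <- pmin(2 * lower[k] - X[lo, k], upper[k])
      V[lo, k] <- -V[lo, k]
      hi <- X[, k] > upper[k]
      X[hi, k] <- pmax(2 * upper[k] - X[hi, k], lower[k])
      V[hi, k] <- -V[hi, k]
    }
    cost <- apply(X, 1, fn)
    n_eval <- n_eval + n_particles
    better <- cost < pcost
    pbest[better, ] <- X[better, , drop = FALSE]
    pcost[better] <- cost[better]
    g <- which.min(pcost)
    if (pcost[g] < gcost) {
      gcost <- pcost[g]
      gbest <- pbest[g, ]
    }
    trace[it] <- gcost
  }
  list(par = gbest, value = gcost, trace = trace, n_evaluations = n_eval)
}

#' Fit the spatial shuttling model to a target image
#'
#' Estimates kinetic parameters of a shuttling topology from a
#' max-normalized fluorescence image by global-best particle swarm
#' minimization of the two-term cost ([fit_cost()]). The search runs in
#' log10 parameter space because rate constants span orders of
#' magnitude. Parameters named in `bounds` are fitted; all others are
#' held at `base_params`. Repeated calls with different seeds build a
#' fitted-parametrization ensemble.
#'
#' @param target Intensity matrix (will be max-normalized).
#' @param geometry A [compartment_geometry()].
#' @param network A [shuttle_topology()] network (or topology name).
#' @param bounds Matrix with rownames = fitted parameter names and
#'   columns `lower`, `upper` (see [default_param_bounds()]), or a named
#'   list of `c(lower, upper)`.
#' @param base_params `shuttle_params` supplying fixed parameters.
#' @param n_particles,n_iterations Swarm size and iterations (defaults
#'   20 and 200).
#' @param seed Integer seed; the fit is deterministic given it.
#' @param weights,sim_tol,sim_t_max Passed to [fit_cost()].
#' @return An object of class `shuttle_fit` with components
#'   `best_params`, `best_cost`, `cost_trace`, `residual`, `target`
#'   (normalized), `geometry`, `network`, `seed`, `n_particles`,
#'   `n_iterations`, `fitted_names`, and `sim` (steady-state simulation
#'   at the optimum). Supports `print`, `summary`, `coef`, `residuals`,
#'   `fitted`, `predict` and `plot`.
#' @export
fit_shuttling_model <- function(target, geometry, network,
                                bounds = NULL,
                                base_params = shuttle_params(),
                                n_particles = 20, n_iterations = 200,
                                seed = 1,
                                weights = c(w_img = 1, w_ss = 1),
                                sim_tol = 1e-5, sim_t_max = 3000) {
  if (is.character(network)) network <- shuttle_topology(network)
  validate_network(network)
  target <- normalize_to_max(target)
  if (is.null(bounds)) {
    bounds <- default_param_bounds()[c("k_phos", "k_dephos_nuc"), ,
                                     drop = FALSE]
  }
  if (is.list(bounds)) {
    bounds <- do.call(rbind, bounds)
    colnames(bounds) <- c("lower", "upper")
  }
  nm <- rownames(bounds)
  if (is.null(nm) || !all(nm %in% names(base_params)))
    stop("bounds rownames must name kinetic parameters", call. = FALSE)
  if (any(bounds[, "lower"] <= 0))
    stop("log10 search requires strictly positive lower bounds",
         call. = FALSE)

  objective <- function(x) {
    p <- base_params
    p[nm] <- as.list(10^x)
    fit_cost(p, target, geometry, network, weights = weights,
             sim_tol = sim_tol, sim_t_max = sim_t_max)
  }
  opt <- pso_optim(objective, log10(bounds[, "lower"]),
                   log10(bounds[, "upper"]), n_particles = n_particles,
                   n_iterations = n_iterations, seed = seed)

  best <- base_params
  best[nm] <- as.list(10^opt$par)
  class(best) <- "shuttle_params"
  cost <- fit_cost(best, target, geometry, network, weights = weights,
                   sim_tol = sim_tol, sim_t_max = sim_t_max,
                   keep_sim = TRUE)
  sim <- attr(cost, "sim")
  obs <- normalize_to_max(total_fluorescence(sim))

  structure(list(
    best_params = best,
    best_cost = opt$value,
    cost_trace = opt$trace,
    n_particles = n_particles,
    n_iterations = n_iterations,
    seed = seed,
    fitted_names = nm,
    residual = residual_image(target, obs, geometry),
    target = target,
    geometry = geometry,
    network = network,
    weights = weights,
    sim = sim
  ), class = "shuttle_fit")
}

#' @export
print.shuttle_fit <- function(x, ...) {
  cat("Spatial shuttling-model fit (", x$network$topology,
      " topology)\n", sep = "")
  cat("  particle swarm: ", x$n_particles, " particles x ",
      x$n_iterations, " iterations, seed ", x$seed, "\n", sep = "")
  cat("  fitted parameters:\n")
  print(unlist(x$best_params[x$fitted_names]))
  cat("  best cost: ", format(x$best_cost, digits = 5), "\n", sep = "")
  invisible(x)
}

#' @export
summary.shuttle_fit <- function(object, ...) {
  cell <- object$geometry$labels != 0L
  out <- list(
    topology = object$network$topology,
    fitted = unlist(object$best_params[object$fitted_names]),
    best_cost = object$best_cost,
    summarized_residual = mean(object$residual[cell]^2),
    ncr_sim = simulated_ncr(object$sim),
    ratio = if (object$best_params$k_dephos_nuc > 0)
      phospho_ratio(object$best_params) else NA_real_,
    converged = object$sim$steady_state_reached,
    trace_range = range(object$cost_trace)
  )
  class(out) <- "summary.shuttle_fit"
  out
}

#' @export
print.summary.shuttle_fit <- function(x, ...) {
  cat("Shuttling-model fit summary (", x$topology, " topology)\n",
      sep = "")
  print(x$fitted)
  cat("  phospho/dephospho ratio r:", format(x$ratio, digits = 4), "\n")
  cat("  best cost:", format(x$best_cost, digits = 5),
      " | mean squared residual:",
      format(x$summarized_residual, digits = 5), "\n")
  cat("  simulated NCR at optimum:", format(x$ncr_sim, digits = 4), "\n")
  cat("  steady state reached:", x$converged, "\n")
  invisible(x)
}

#' @export
coef.shuttle_fit <- function(object, all = FALSE, ...) {
  if (all) unlist(object$best_params)
  else unlist(object$best_params[object$fitted_names])
}

#' @export
residuals.shuttle_fit <- function(object, ...) object$residual

#' @export
fitted.shuttle_fit <- function(object, ...)
  normalize_to_max(total_fluorescence(object$sim))

#' Predict the normalized steady-state image at given parameters
#'
#' @param object A `shuttle_fit`.
#' @param params Optional `shuttle_params` (default: fitted optimum).
#' @param ... Unused.
#' @return Max-normalized simulated intensity matrix.
#' @export
predict.shuttle_fit <- function(object, params = NULL, ...) {
  if (is.null(params)) return(fitted(object))
  sim <- simulate_steady_state(object$geometry, object$network, params)
  normalize_to_max(total_fluorescence(sim))
}

#' @export
plot.shuttle_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(2, 2, 2, 1))
  on.exit(graphics::par(op))
  show <- function(m, main, col = grDevices::gray.colors(64, 0, 1)) {
    graphics::image(t(m[nrow(m):1, ]), axes = FALSE, main = main,
                    col = col, useRaster = TRUE)
  }
  show(x$target, "target")
  show(fitted(x), "model")
  rmax <- max(abs(x$residual), 1e-12)
  show(x$residual / rmax / 2 + 0.5, "residual (data - model)",
       col = grDevices::hcl.colors(64, "Blue-Red 3"))
  graphics::plot(x$cost_trace, type = "l", log = "y",
                 xlab = "iteration", ylab = "best cost",
                 main = "cost trace")
  invisible(x)
}

#' Scan the nuclear phosphorylation/dephosphorylation ratio
#'
#' For each ratio `r`, sets `k_phos = r * k_dephos_nuc` with all other
#' parameters fixed at `base_params`, simulates the alternative model to
#' steady state and reports the summarized residual against the target
#' and the simulated NCR. Non-convergent rows are flagged, never
#' dropped.
#'
#' @param target Intensity matrix (max-normalized internally).
#' @param geometry A [compartment_geometry()].
#' @param base_params `shuttle_params` fixing all non-ratio parameters.
#' @param ratios Numeric vector of ratios (> 0).
#' @param network Network or topology name (default alternative).
#' @param sim_tol,sim_t_max Solver controls.
#' @return Data frame with columns `r`, `summarized_residual`,
#'   `ncr_sim`, `converged`, ordered by `r`.
#' @export
ratio_scan <- function(target, geometry, base_params, ratios,
                       network = shuttle_topology("alternative"),
                       sim_tol = 1e-5, sim_t_max = 3000) {
  if (is.character(network)) network <- shuttle_topology(network)
  if (any(ratios <= 0)) stop("ratios must be > 0", call. = FALSE)
  target <- normalize_to_max(target)
  ratios <- sort(ratios)
  rows <- lapply(ratios, function(r) {
    p <- set_phospho_ratio(base_params, r)
    sim <- simulate_steady_state(geometry, network, p, tol = sim_tol,
                                 t_max = sim_t_max)
    obs <- normalize_to_max(total_fluorescence(sim))
    data.frame(r = r,
               summarized_residual = summarized_residual(target, obs,
                                                         geometry),
               ncr_sim = simulated_ncr(sim),
               converged = sim$steady_state_reached)
  })
  do.call(rbind, rows)
}
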