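#' Well-mixed (compartment ODE) counterpart of the spatial model
#'
#' Removing diffusion and assuming perfect mixing inside each compartment
#' turns the spatial model into a small linear ODE system, whose steady
#' state is available by a direct linear solve. This serves as the
#' reference for the spatial solver in its high-diffusion limit.
#'
#' Membrane fluxes scale as `area / volume` on each side: a permeability
#' `k` (um/s) acting on source concentration `c` moves `k * area * c`
#' amount per second. In 2D image geometries "volumes" are compartment
#' areas (um^2) and the membrane "area" is the nuclear perimeter (um).
#'
#' @param network A [shuttle_topology()] network.
#' @param params A [shuttle_params()] object.
#' @param volumes Named list/vector with `V_cyt`, `V_nuc` (> 0).
#' @param membrane_area Nuclear membrane area (> 0).
#' @param total Total amount used to scale the conservative case
#'   (`k_syn = k_deg = 0`), where the steady state is defined only up to
#'   the conserved total; default 1 amount unit.
#' @return A list with `concentrations` (named: `U_cyt`, `P_cyt`,
#'   `U_nuc`, and `P_nuc` for the alternative topology), `ncr`
#'   (nuclear/cytoplasmic ratio of U+P), and `diverged` (TRUE with
#'   `ncr = Inf` when all protein drains into the nucleus and no finite
#'   steady state exists).
#' @examples
#' net <- shuttle_topology("alternative")
#' p <- shuttle_params()
#' wellmixed_steady_state(net, p, list(V_cyt = 1000, V_nuc = 200),
#'                        membrane_area = 50)
#' @export
wellmixed_steady_state <- function(network, params, volumes, membrane_area,
                                   total = 1) {
  validate_network(network)
  stopifnot(inherits(params, "shuttle_params"))
  V_cyt <- volumes[["V_cyt"]]
  V_nuc <- volumes[["V_nuc"]]
  if (!is.numeric(V_cyt) || !is.numeric(V_nuc) || V_cyt <= 0 || V_nuc <= 0 ||
      !is.numeric(membrane_area) || membrane_area <= 0)
    stop("volumes and membrane_area must be positive", call. = FALSE)

  sys <- wellmixed_system(network, params, V_cyt, V_nuc, membrane_area)
  A <- sys$A
  b <- sys$b

  conservative <- params$k_syn == 0 && params$k_deg == 0
  if (conservative) {
    # steady state = nullspace direction, scaled to the conserved total
    ns <- svd(A)
    v <- ns$v[, ncol(A)]
    if (ns$d[ncol(A)] > 1e-10 * max(ns$d))
      stop("no steady state: conservative system has no nullspace",
           call. = FALSE)
    if (all(v <= 1e-12)) v <- -v
    if (any(v < -1e-9)) {
      return(list(concentrations = NULL, ncr = Inf, diverged = TRUE))
    }
    vols <- c(V_cyt, V_cyt, V_nuc, V_nuc)[seq_along(v)]
    y <- v * total / sum(v * vols)
  } else {
    y <- tryCatch(solve(A, -b), error = function(e) NULL)
    if (is.null(y)) {
      if (params$k_deg > 0) {
        # singular despite degradation: a compartment without an exit
        # path (e.g. k_phos = 0 in the alternative network) accumulates
        # without bound
        return(list(concentrations = NULL, ncr = Inf, diverged = TRUE))
      }
      stop("no steady state: singular system (e.g. k_deg = 0 with ",
           "nonzero k_syn)", call. = FALSE)
    }
    if (any(y < -1e-9 * max(abs(y), 1))) {
      # infeasible fixed point: material accumulates without bound
      return(list(concentrations = NULL, ncr = Inf, diverged = TRUE))
    }
    y[y < 0] <- 0
  }

  names(y) <- sys$state
  nuc <- sum(y[grep("_nuc$", names(y))])
  cyt <- sum(y[grep("_cyt$", names(y))])
  ncr <- if (cyt > 0) nuc / cyt else Inf
  list(concentrations = y, ncr = ncr, diverged = !is.finite(ncr))
}

#' Right-hand side of the well-mixed compartment ODEs
#'
#' Exposes the linear system `dy/dt = A y + b` in a form directly usable
#' by ODE integrators (e.g. `deSolve::ode`), which provides an
#' independent route to the steady state.
#'
#' @inheritParams wellmixed_steady_state
#' @return A list with `A`, `b`, `state` (state names) and `rhs`, a
#'   `function(t, y, ...)` returning `list(A %*% y + b)`.
#' @export
wellmixed_rhs <- function(network, params, volumes, membrane_area) {
  sys <- wellmixed_system(network, params, volumes[["V_cyt"]],
                          volumes[["V_nuc"]], membrane_area)
  sys$rhs <- function(t, y, parms = NULL) list(as.numeric(sys$A %*% y + sys$b))
  sys
}

wellmixed_system <- function(network, params, V_cyt, V_nuc, area) {
  p <- params
  a_n <- area / V_nuc
  a_c <- area / V_cyt
  if (network$topology == "alternative") {
    state <- c("U_cyt", "P_cyt", "U_nuc", "P_nuc")
    A <- matrix(0, 4, 4, dimnames = list(state, state))
    A["U_cyt", "U_cyt"] <- -(p$k_deg + a_c * p$k_import)
    A["U_cyt", "P_cyt"] <- p$k_dephos_cyt
    A["P_cyt", "P_cyt"] <- -(p$k_dephos_cyt + p$k_deg)
    A["P_cyt", "P_nuc"] <- a_c * p$k_export
    A["U_nuc", "U_cyt"] <- a_n * p$k_import
    A["U_nuc", "U_nuc"] <- -p$k_phos
    A["U_nuc", "P_nuc"] <- p$k_dephos_nuc
    A["P_nuc", "U_nuc"] <- p$k_phos
    A["P_nuc", "P_nuc"] <- -(p$k_dephos_nuc + a_n * p$k_export)
    b <- c(p$k_syn, 0, 0, 0)
  } else {
    state <- c("U_cyt", "P_cyt", "U_nuc")
    A <- matrix(0, 3, 3, dimnames = list(state, state))
    A["U_cyt", "U_cyt"] <- -(p$k_deg + p$k_phos + a_c * p$k_import)
    A["U_cyt", "P_cyt"] <- p$k_dephos_cyt
    A["U_cyt", "U_nuc"] <- a_c * p$k_export
    A["P_cyt", "U_cyt"] <- p$k_phos
    A["P_cyt", "P_cyt"] <- -(p$k_dephos_cyt + p$k_deg)
    A["U_nuc", "U_cyt"] <- a_n * p$k_import
    A["U_nuc", "U_nuc"] <- -a_n * p$k_export
    b <- c(p$k_syn, 0, 0)
  }
  list(A = A, b = b, state = state)
}
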