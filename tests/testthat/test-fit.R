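test_that("max-normalization scales, idempotent, flags zero, rejects negatives", {
  expect_equal(normalize_to_max(matrix(7, 3, 3)),
               matrix(1, 3, 3), ignore_attr = TRUE)
  img <- matrix(c(50, 100, 200, 0), 2)
  out <- normalize_to_max(img)
  expect_equal(out[1, 1], 0.25)
  expect_equal(max(out), 1)
  expect_equal(normalize_to_max(out), out, ignore_attr = TRUE)
  expect_warning(z <- normalize_to_max(matrix(0, 2, 2)), "all-zero")
  expect_true(attr(z, "all_zero"))
  expect_error(normalize_to_max(matrix(-1, 2, 2)), "negative")
})

test_that("residual image is data minus model on cell pixels", {
  g <- disc_geometry(n = 24, pixel_size = 1, r_cell_px = 9, r_nuc_px = 4)
  t1 <- matrix(0.5, 24, 24)
  expect_equal(residual_image(t1, t1, g), matrix(0, 24, 24))
  res <- residual_image(t1, matrix(0, 24, 24), g)
  expect_true(all(res[g$labels != 0L] == 0.5))
  expect_true(all(res[g$labels == 0L] == 0))
  expect_error(residual_image(t1, matrix(0, 12, 12), g), "dimensions")
  # summarized residual: mean of squares over cell pixels
  expect_equal(summarized_residual(t1, t1, g), 0)
  sim <- t1; sim[g$labels != 0L] <- 0.4
  expect_equal(summarized_residual(t1, sim, g), 0.01)
})

test_that("a nuclear-halo target against a flat model leaves a positive ring", {
  g <- disc_geometry(n = 48, pixel_size = 1.24, r_cell_px = 18, r_nuc_px = 7)
  sim <- simulate_steady_state(g, shuttle_topology("alternative"),
                               set_phospho_ratio(shuttle_params(), 0.15),
                               tol = 1e-6, t_max = 3000)
  target <- normalize_to_max(total_fluorescence(sim))
  flat <- matrix(0, 48, 48)
  flat[g$labels != 0L] <- 1
  res <- residual_image(target, flat, g)
  # ring of cytoplasm pixels adjacent to the nucleus
  ring_idx <- unique(g$nuclear_faces[, c("row_a", "col_a")])
  far_cyt <- g$labels == 1L
  far_cyt[ring_idx] <- FALSE
  expect_gt(mean(res[ring_idx]), mean(res[far_cyt]))
})

test_that("self-fit cost is near zero and grows under perturbation", {
  g <- disc_geometry(n = 48, pixel_size = 1.24, r_cell_px = 18, r_nuc_px = 7)
  net <- shuttle_topology("alternative")
  p <- shuttle_params()
  sim <- simulate_steady_state(g, net, p, tol = 1e-6, t_max = 3000)
  target <- normalize_to_max(total_fluorescence(sim))
  c_true <- fit_cost(p, target, g, net, sim_tol = 1e-6, sim_t_max = 3000)
  expect_lt(c_true, 1e-6)
  p2 <- p; p2$k_phos <- 2 * p$k_phos
  c_pert <- fit_cost(p2, target, g, net, sim_tol = 1e-6, sim_t_max = 3000)
  expect_gt(c_pert, c_true)
  expect_error(fit_cost(p, target, g, net, weights = c(w_img = 0, w_ss = 0)),
               "weights")
})

test_that("a deliberately non-steady snapshot pays the rate penalty", {
  g <- disc_geometry(n = 32, pixel_size = 1.24, r_cell_px = 12, r_nuc_px = 5)
  net <- shuttle_topology("alternative")
  p <- shuttle_params()
  # huge tolerance: the "converged" state is far from steady
  early <- simulate_steady_state(g, net, p, tol = 0.5, t_max = 2)
  obs <- normalize_to_max(total_fluorescence(early))
  cost <- fit_cost(p, obs, g, net, sim_tol = 0.5, sim_t_max = 2)
  # image term is ~0 against itself, so any cost is the rate term
  expect_gt(cost, 1e-4)
})

test_that("particle swarm solves a sphere function and is seed-deterministic", {
  sphere <- function(x) sum((x - c(0.5, -1, 2))^2)
  out <- pso_optim(sphere, rep(-5, 3), rep(5, 3), n_particles = 20,
                   n_iterations = 200, seed = 11)
  expect_lt(out$value, 1e-3)
  expect_equal(out$par, c(0.5, -1, 2), tolerance = 0.05)
  expect_true(all(diff(out$trace) <= 0))
  out2 <- pso_optim(sphere, rep(-5, 3), rep(5, 3), n_particles = 20,
                    n_iterations = 200, seed = 11)
  expect_identical(out, out2)
  out3 <- pso_optim(sphere, rep(-5, 3), rep(5, 3), seed = 12)
  expect_false(identical(out$par, out3$par))
  expect_error(pso_optim(sphere, rep(-5, 3), rep(5, 3), n_particles = 1),
               "n_particles")
  expect_error(pso_optim(sphere, c(1, 1), c(0, 2)), "bounds")
})

test_that("pso does not disturb the caller's RNG stream", {
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  invisible(pso_optim(function(x) sum(x^2), -1, 1, n_particles = 3,
                      n_iterations = 3, seed = 5))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("ratio_scan is minimized at the generating ratio and orders NCR", {
  g <- disc_geometry(n = 48, pixel_size = 1.24, r_cell_px = 18, r_nuc_px = 7)
  base <- shuttle_params()
  r_true <- 0.3
  sim <- simulate_steady_state(g, shuttle_topology("alternative"),
                               set_phospho_ratio(base, r_true),
                               tol = 1e-6, t_max = 3000)
  target <- normalize_to_max(total_fluorescence(sim))
  tab <- ratio_scan(target, g, base, ratios = c(0.1, 0.2, 0.3, 0.5, 0.8),
                    sim_tol = 1e-6, sim_t_max = 3000)
  expect_equal(tab$r[which.min(tab$summarized_residual)], r_true)
  expect_true(all(diff(tab$ncr_sim) <= 0))     # NCR non-increasing in r
  expect_true(all(tab$converged))
  expect_error(ratio_scan(target, g, base, ratios = c(-1, 0.5)), "ratios")
  # non-convergent rows are flagged, not dropped
  tab2 <- ratio_scan(target, g, base, ratios = c(0.2, 0.6),
                     sim_tol = 1e-9, sim_t_max = 1)
  expect_equal(nrow(tab2), 2)
  expect_true(all(!tab2$converged))
})

test_that("shuttle_fit methods expose coefficients, residuals and predictions", {
  g <- disc_geometry(n = 32, pixel_size = 1.24, r_cell_px = 12, r_nuc_px = 5)
  net <- shuttle_topology("alternative")
  truth <- set_phospho_ratio(shuttle_params(), 0.25)
  sim <- simulate_steady_state(g, net, truth, tol = 1e-5, t_max = 2000)
  target <- normalize_to_max(total_fluorescence(sim))
  fit <- fit_shuttling_model(target, g, net,
                             n_particles = 6, n_iterations = 8, seed = 3,
                             sim_tol = 1e-4, sim_t_max = 1500)
  expect_s3_class(fit, "shuttle_fit")
  expect_named(coef(fit), c("k_phos", "k_dephos_nuc"))
  expect_length(coef(fit, all = TRUE), 11)
  expect_equal(dim(residuals(fit)), dim(target))
  expect_equal(fit$best_cost, min(fit$cost_trace))
  expect_true(all(diff(fit$cost_trace) <= 0))
  expect_equal(max(fitted(fit)), 1)
  pred <- predict(fit, params = truth)
  expect_equal(dim(pred), dim(target))
  s <- summary(fit)
  expect_s3_class(s, "summary.shuttle_fit")
  expect_true(is.finite(s$ratio))
  expect_output(print(fit), "particle swarm")
  # bit-identical refit under the same seed
  fit2 <- fit_shuttling_model(target, g, net,
                              n_particles = 6, n_iterations = 8, seed = 3,
                              sim_tol = 1e-4, sim_t_max = 1500)
  expect_identical(coef(fit), coef(fit2))
  expect_identical(fit$cost_trace, fit2$cost_trace)
})
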