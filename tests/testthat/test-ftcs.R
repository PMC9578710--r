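test_that("stable_timestep follows the CFL and rate bounds", {
  p1 <- shuttle_params(D_U_cyt = 1, D_U_nuc = 1, D_P_cyt = 1, D_P_nuc = 1,
                       k_phos = 0, k_dephos_nuc = 0, k_dephos_cyt = 0,
                       k_import = 0, k_export = 0, k_syn = 0, k_deg = 0)
  expect_equal(stable_timestep(p1, pixel_size = 1, safety = 1), 0.25)
  # quadratic scaling with pixel size (diffusion-limited regime)
  expect_equal(stable_timestep(p1, pixel_size = 2, safety = 1), 1)
  # rate-limited regime: k_max = 10/s wins over the diffusion bound
  p2 <- shuttle_params(D_U_cyt = 1, D_U_nuc = 1, D_P_cyt = 1, D_P_nuc = 1,
                       k_phos = 10, k_dephos_nuc = 0, k_dephos_cyt = 0,
                       k_import = 0, k_export = 0, k_syn = 0, k_deg = 0)
  expect_equal(stable_timestep(p2, pixel_size = 1, safety = 0.5), 0.05)
  expect_error(stable_timestep(p1, pixel_size = -1), "positive")
  expect_error(stable_timestep(p1, 1, safety = 0), "safety")
})

test_that("a uniform field with no reactions is a fixed point", {
  g <- disc_geometry(n = 32, pixel_size = 1, r_cell_px = 12, r_nuc_px = 5)
  p <- shuttle_params(k_phos = 0, k_dephos_nuc = 0, k_dephos_cyt = 0,
                      k_import = 0, k_export = 0, k_syn = 0, k_deg = 0)
  net <- shuttle_topology("alternative")
  f <- initial_fields(g, u0 = 0)
  f$U[g$labels == 1L] <- 0.7
  f$U[g$labels == 2L] <- 0.3   # uniform per compartment, no coupling
  f$P[g$labels != 0L] <- 0.2
  dt <- stable_timestep(p, 1)
  f2 <- f
  for (i in 1:20) f2 <- ftcs_step(f2, g, net, p, dt)
  expect_equal(f2$U, f$U, tolerance = 1e-14)
  expect_equal(f2$P, f$P, tolerance = 1e-14)
  expect_error(ftcs_step(f, g, net, p, dt * 4), "stability")
})

test_that("the diffusion stencil conserves mass exactly", {
  g <- disc_geometry(n = 32, pixel_size = 1, r_cell_px = 12, r_nuc_px = 5)
  p <- shuttle_params(k_phos = 0, k_dephos_nuc = 0, k_dephos_cyt = 0,
                      k_import = 0, k_export = 0, k_syn = 0, k_deg = 0,
                      D_U_cyt = 2, D_U_nuc = 2, D_P_cyt = 2, D_P_nuc = 2)
  net <- shuttle_topology("alternative")
  f <- initial_fields(g)
  f$U[20, 20] <- 5  # non-uniform start
  a0 <- total_amount(f, g)
  dt <- stable_timestep(p, 1)
  for (i in 1:50) {
    f <- ftcs_step(f, g, net, p, dt)
    expect_equal(total_amount(f, g) / a0, 1, tolerance = 1e-12)
  }
})

test_that("point-source diffusion matches the 2D heat kernel", {
  n <- 101
  lab <- matrix(1L, n, n)        # one big cytoplasm, reflecting far walls
  lab[5:6, 5:6] <- 2L            # token nucleus far from the source
  g <- compartment_geometry(lab, pixel_size = 1)
  p <- shuttle_params(k_phos = 0, k_dephos_nuc = 0, k_dephos_cyt = 0,
                      k_import = 0, k_export = 0, k_syn = 0, k_deg = 0,
                      D_U_cyt = 1, D_U_nuc = 1, D_P_cyt = 1, D_P_nuc = 1)
  net <- shuttle_topology("alternative")
  f <- initial_fields(g, u0 = 0)
  ctr <- 51
  f$U[ctr, ctr] <- 1  # unit amount in one pixel
  dt <- stable_timestep(p, 1, safety = 0.8)
  Tend <- 40
  steps <- ceiling(Tend / dt)
  sim <- simulate_steady_state(g, net, p, init = f, tol = 1e-300,
                               t_max = steps * dt, dt = dt)
  Tnum <- sim$elapsed_time
  X <- matrix(seq_len(n), n, n)
  Y <- matrix(seq_len(n), n, n, byrow = TRUE)
  r2 <- (X - ctr)^2 + (Y - ctr)^2
  kernel <- exp(-r2 / (4 * p$D_U_cyt * Tnum)) / (4 * pi * p$D_U_cyt * Tnum)
  # compare away from boundaries and the token nucleus
  sel <- r2 <= (2.2 * sqrt(2 * p$D_U_cyt * Tnum))^2
  rel <- abs(sim$fields$U[sel] - kernel[sel]) / max(kernel)
  expect_lt(max(rel), 0.02)
})

test_that("canonical P never leaks into the nucleus", {
  g <- disc_geometry(n = 48, pixel_size = 1.24, r_cell_px = 18, r_nuc_px = 7)
  sim <- simulate_steady_state(g, shuttle_topology("canonical"),
                               shuttle_params(), tol = 1e-5, t_max = 2000)
  expect_true(all(sim$fields$P[g$labels == 2L] == 0))
  expect_true(all(sim$fields$U >= 0) && all(sim$fields$P >= 0))
})

test_that("zero kinetics from a uniform start is steady immediately", {
  g <- disc_geometry(n = 32, pixel_size = 1, r_cell_px = 12, r_nuc_px = 5)
  p <- shuttle_params(k_phos = 0, k_dephos_nuc = 0, k_dephos_cyt = 0,
                      k_import = 0, k_export = 0, k_syn = 0, k_deg = 0)
  sim <- simulate_steady_state(g, shuttle_topology("alternative"), p,
                               tol = 1e-9, t_max = 10)
  expect_true(sim$steady_state_reached)
  expect_equal(sim$final_rate_norm, 0)
})

test_that("spatial steady state approaches the well-mixed oracle as D grows", {
  g <- disc_geometry(n = 48, pixel_size = 1.24, r_cell_px = 18, r_nuc_px = 7)
  net <- shuttle_topology("alternative")
  errs <- vapply(c(3, 10, 30), function(D) {
    p <- shuttle_params(D_U_cyt = D, D_U_nuc = D, D_P_cyt = D, D_P_nuc = D)
    sim <- simulate_steady_state(g, net, p, tol = 1e-6, t_max = 4000)
    wm <- wellmixed_steady_state(net, p, default_volumes(g),
                                 g$membrane_length)
    abs(simulated_ncr(sim) / wm$ncr - 1)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))   # error shrinks monotonically
  expect_lt(errs[3], 0.02)           # within 2% at the largest D
})

test_that("result is insensitive to the admissible dt and to the init", {
  g <- disc_geometry(n = 40, pixel_size = 1.24, r_cell_px = 15, r_nuc_px = 6)
  net <- shuttle_topology("alternative")
  p <- shuttle_params()
  s1 <- simulate_steady_state(g, net, p, tol = 1e-6, t_max = 4000,
                              safety = 0.9)
  s2 <- simulate_steady_state(g, net, p, tol = 1e-6, t_max = 4000,
                              safety = 0.45)
  expect_equal(simulated_ncr(s1), simulated_ncr(s2), tolerance = 0.01)
  expect_equal(compartment_means(s1), compartment_means(s2),
               tolerance = 0.01)
  # different initial condition, same steady state (linear system)
  init2 <- initial_fields(g, u0 = 0)
  init2$U[g$labels != 0L] <- 0.4
  init2$P[g$labels != 0L] <- 0.4
  s3 <- simulate_steady_state(g, net, p, init = init2, tol = 1e-6,
                              t_max = 4000)
  expect_equal(compartment_means(s1), compartment_means(s3),
               tolerance = 0.005)
})

test_that("halving the pixel size moves compartment means by under 2%", {
  net <- shuttle_topology("alternative")
  # smooth regime: the membrane boundary layer (~ D / k_export) must be
  # resolved at both resolutions for grid-halving comparisons
  p <- shuttle_params(k_export = 0.3)
  g_coarse <- disc_geometry(n = 40, pixel_size = 2, r_cell_px = 15,
                            r_nuc_px = 6)
  g_fine <- disc_geometry(n = 80, pixel_size = 1, r_cell_px = 30,
                          r_nuc_px = 12)
  s_c <- simulate_steady_state(g_coarse, net, p, tol = 1e-6, t_max = 4000)
  s_f <- simulate_steady_state(g_fine, net, p, tol = 1e-6, t_max = 4000)
  m_c <- compartment_means(s_c)
  m_f <- compartment_means(s_f)
  expect_equal(unname(m_c / m_f), rep(1, 4), tolerance = 0.02)
})

test_that("total fluorescence sums the two phospho-forms", {
  g <- disc_geometry(n = 24, pixel_size = 1, r_cell_px = 9, r_nuc_px = 4)
  f <- initial_fields(g, u0 = 0)
  f$U[g$labels == 1L] <- 1
  tot <- total_fluorescence(f)
  expect_equal(tot, f$U)           # P == 0 everywhere
  f$P[g$labels == 1L] <- 1
  tot <- total_fluorescence(f)
  expect_true(all(tot[g$labels == 1L] == 2))
  expect_true(all(tot[g$labels == 0L] == 0))
})
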