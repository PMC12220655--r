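test_that("the Gaussian bolus matches its printed closed form", {
  g <- structured_grid(320, 8, dx = 8 / 320, dy = 1.172 / 8, x0 = 1.6,
                       periodic_x = FALSE, wall_y = TRUE)
  b <- gaussian_bolus(g, center = 5.6, width_param = 0.5)
  x <- cell_centers(g)$x
  i56 <- which.min(abs(x - 5.6))
  expect_equal(b$c[i56, 1, 1], exp(-(x[i56] - 5.6)^2 / 0.5))
  expect_gt(b$c[i56, 1, 1], 0.999)
  # rostral-boundary value of the printed exponential
  expect_equal(exp(-(1.6 - 5.6)^2 / 0.5), 1.27e-14, tolerance = 1e-2)
  # bolus volume with A(x) = 1.172 cm^2 over [1.6, 9.6] is about 1.5 mL
  vol <- sum(exp(-(x - 5.6)^2 / 0.5)) * g$dx * 1.172
  expect_equal(vol, 1.172 * sqrt(0.5 * pi), tolerance = 1e-3)
  expect_equal(vol, 1.5, tolerance = 0.03)
  expect_error(gaussian_bolus(g, center = 0.5), "inside")
})

test_that("degenerate transport limits are exact", {
  g <- structured_grid(40, 8, 0.1, 0.1, periodic_x = TRUE, wall_y = TRUE,
                       n_segments = 2L)
  zero <- uniform_pvf(g, U = 0)
  gt <- tile_grid(g)
  b <- gaussian_bolus(gt, center = 4, width_param = 0.5)
  # zero velocity, zero diffusivity: identity evolution
  h <- integrate_full_transport(zero, b, transport_params(
    kappa = 0, dt = 0.5, t_end = 5, snapshot_every = 1))
  expect_equal(h$c[, , 6], h$c[, , 1], tolerance = 1e-14)
  expect_lt(h$ledger_error, 1e-12)
})

test_that("pure diffusion follows heat-kernel variance growth and recovers kappa", {
  g <- structured_grid(160, 6, 0.05, 0.1, periodic_x = TRUE, wall_y = TRUE,
                       n_segments = 1L)
  zero <- uniform_pvf(g, U = 0)
  gt <- tile_grid(g)
  b <- gaussian_bolus(gt, center = 4, width_param = 0.5)
  kap <- 1e-7   # m^2/s = 1e-3 cm^2/s
  h <- integrate_full_transport(zero, b, transport_params(
    kappa = kap, dt = 0.5, t_end = 20, snapshot_every = 5))
  ds <- dispersion_stats(longitudinal_profile(h))
  # sigma^2(t) = sigma^2(0) + 2 kappa t
  expect_equal(ds$sigma2, ds$sigma2[1] + 2 * 1e-3 * ds$t, tolerance = 1e-3)
  kH <- hydrodynamic_diffusivity(ds)
  expect_equal(kH$kappa_H[-1], rep(1e-3, 4), tolerance = 1e-2)
})

test_that("a steady uniform flow translates the bolus at speed U", {
  g <- structured_grid(200, 6, 0.05, 0.1, periodic_x = TRUE, wall_y = TRUE)
  U <- 0.2
  f <- uniform_pvf(g, U = U)
  gt <- tile_grid(g, 1L)
  b <- gaussian_bolus(gt, center = 3, width_param = 0.25)
  h <- integrate_full_transport(f, b, transport_params(
    kappa = 0, dt = 0.05, t_end = 10, snapshot_every = 10), n_segments = 1L)
  ds <- dispersion_stats(longitudinal_profile(h))
  expect_equal(utils::tail(ds$xbar, 1) - ds$xbar[1], U * 10, tolerance = 5e-3)
  # translation leaves sigma nearly unchanged (scheme dispersion error only)
  expect_equal(utils::tail(ds$sigma2, 1), ds$sigma2[1], tolerance = 2e-2)
})

test_that("reduced and full solvers agree exactly for the same steady field", {
  g <- structured_grid(32, 16, 0.05, 0.05, periodic_x = TRUE, wall_y = TRUE,
                       n_segments = 2L)
  # a steady sheared axial field via the eulerian_mean pathway
  y <- cell_centers(g)$y
  u <- array(0, c(g$nx + 1L, g$ny, 2L))
  for (p in 1:2) u[, , p] <- matrix(0.3 * sin(pi * y / g$Ly), g$nx + 1L, g$ny,
                                    byrow = TRUE)
  v <- array(0, c(g$nx, g$ny + 1L, 2L))
  f <- periodic_velocity_field(g, u, v, period = 1)
  em <- cycle_average(f)
  gt <- tile_grid(g)
  b <- gaussian_bolus(gt, center = 0.8, width_param = 0.05)
  pars <- transport_params(kappa = 1e-8, dt = 0.02, t_end = 2,
                           snapshot_every = 1, scheme = "upwind_2nd")
  h_full <- integrate_full_transport(f, b, pars)
  h_red <- integrate_reduced_transport(em, b, pars)
  expect_lt(max(abs(h_full$c - h_red$c)), 1e-8)
})

test_that("the mass ledger closes and undershoots stay bounded in an outflow run", {
  g <- structured_grid(32, 16, 0.05, 0.05, periodic_x = TRUE, wall_y = TRUE,
                       n_segments = 2L)
  f <- uniform_pvf(g, U = 0.4)
  gt <- tile_grid(g)
  b <- gaussian_bolus(gt, center = 1.6, width_param = 0.1)
  h <- integrate_full_transport(f, b, transport_params(
    kappa = 1e-9, dt = 0.05, t_end = 6, snapshot_every = 1))
  expect_gt(utils::tail(h$outflow, 1), 0.1 * h$mass[1])  # mass did leave
  expect_lt(h$ledger_error, 1e-6)
  expect_gt(h$params$min_c, -1e-10 * max(b$c))
})

test_that("unprojected drift fields are rejected by the reduced solver", {
  g <- structured_grid(16, 8, 0.1, 0.1, periodic_x = TRUE, wall_y = TRUE)
  raw <- steady_velocity_field(g, matrix(0.1, 16, 8), matrix(0, 16, 8),
                               "lagrangian_raw")
  expect_error(integrate_reduced_transport(raw, NULL), "sinks")
  sd <- steady_velocity_field(g, matrix(0.1, 16, 8), matrix(0, 16, 8),
                              "stokes_drift")
  expect_error(integrate_reduced_transport(sd, NULL), "unsupported")
})

test_that("longitudinal profiles integrate concentration over the open section", {
  m <- matrix(FALSE, 20, 10); m[8:10, 4:6] <- TRUE
  g <- structured_grid(20, 10, 0.1, 0.1, mask = m, periodic_x = FALSE,
                       wall_y = TRUE)
  h <- gaussian_bolus(g, center = 1, width_param = 0.3)
  pr <- longitudinal_profile(h)
  # cross-sectionally uniform c integrates to c * A(x)
  x <- cell_centers(g)$x
  expect_equal(pr$C[, 1], exp(-(x - 1)^2 / 0.3) * open_area(g),
               tolerance = 1e-12)
  # zero field gives a zero profile
  h0 <- h; h0$c[] <- 0
  expect_equal(max(abs(longitudinal_profile(h0)$C)), 0)
})

test_that("dispersion statistics have exact Gaussian moments and symmetries", {
  x <- seq(0, 11.2, by = 0.002)
  Cg <- exp(-(x - 5.6)^2 / 0.5)
  prof <- structure(list(x = x, C = cbind(Cg), times = 0, dx = 0.002),
                    class = "longitudinal_profile")
  ds <- dispersion_stats(prof)
  expect_equal(ds$xbar, 5.6, tolerance = 1e-8)
  expect_equal(sqrt(ds$sigma2), 0.5, tolerance = 1e-6)  # 2 sigma^2 = 0.5
  # symmetric two-bump profile about 5.6
  C2 <- exp(-(x - 4.6)^2 / 0.2) + exp(-(x - 6.6)^2 / 0.2)
  ds2 <- dispersion_stats(structure(list(x = x, C = cbind(C2), times = 0),
                                    class = "longitudinal_profile"))
  expect_equal(ds2$xbar, 5.6, tolerance = 1e-8)
  # translation shifts xbar, not sigma
  C3 <- exp(-(x - 6.6)^2 / 0.5)
  ds3 <- dispersion_stats(structure(list(x = x, C = cbind(C3), times = 0),
                                    class = "longitudinal_profile"))
  expect_equal(ds3$xbar, 6.6, tolerance = 1e-6)
  expect_equal(ds3$sigma2, ds$sigma2, tolerance = 1e-5)
  # zero mass is an error
  expect_error(dispersion_stats(structure(
    list(x = x, C = cbind(0 * x), times = 0),
    class = "longitudinal_profile")), "mass")
})

test_that("the secant hydrodynamic diffusivity follows its defining formula", {
  m <- data.frame(t = c(0, 10, 20), xbar = 5.6,
                  sigma2 = c(0.25, 0.25, 0.25))
  class(m) <- c("dispersion_metrics", "data.frame")
  kH <- hydrodynamic_diffusivity(m)
  expect_true(is.na(kH$kappa_H[1]))
  expect_equal(kH$kappa_H[-1], c(0, 0))
  m$sigma2 <- 0.25 + 2 * 0.03 * m$t
  expect_equal(hydrodynamic_diffusivity(m)$kappa_H[-1], c(0.03, 0.03))
})
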