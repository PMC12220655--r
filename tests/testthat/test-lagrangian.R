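test_that("cycle averaging is exact for steady, zero-mean, and mixed fields", {
  g <- wave_grid(nx = 32)
  # single-harmonic zero-mean field averages to zero
  f <- make_manufactured_wave_flow(g, 0.01, 2 * pi, 1, "standing")
  eu <- cycle_average(f)
  expect_lt(max(abs(eu$u), abs(eu$v)), 1e-14)
  # steady + harmonic returns the steady part exactly
  U0 <- 0.37
  fmix <- f
  fmix$u <- f$u + U0
  eu2 <- cycle_average(fmix)
  expect_equal(max(abs(eu2$u - U0)), 0, tolerance = 1e-13)
  # constant-in-time field is its own average
  fc <- uniform_pvf(g, U = 1.2, n_phases = 4L)
  eu3 <- cycle_average(fc)
  expect_equal(unname(eu3$u[1, 1]), 1.2)
})

test_that("the asymptotic Stokes drift matches closed forms", {
  g <- wave_grid()
  # spatially uniform oscillation: zero drift
  fu <- oscillating_uniform_pvf(g)
  sdu <- stokes_drift_asymptotic(fu)
  expect_lt(max(abs(sdu$u), abs(sdu$v)), 1e-14)
  # steady field: zero fluctuation, zero drift
  fs <- uniform_pvf(g, U = 0.5, n_phases = 4L)
  sds <- stokes_drift_asymptotic(fs)
  expect_lt(max(abs(sds$u), abs(sds$v)), 1e-14)
  # traveling wave u = U cos(kx - wt): drift U^2 k / (2 w), uniform
  f <- traveling_wave(U = 0.01)
  sd <- stokes_drift_asymptotic(f)
  oracle <- f$metadata$drift_u
  expect_lt(max(abs(sd$u - oracle)) / oracle, 5e-3)
  expect_lt(max(abs(sd$v)), 1e-3 * oracle)
  # the Eulerian mean vanishes while the drift does not: the central contrast
  expect_lt(max(abs(cycle_average(f)$u)), 1e-14)
  expect_gt(min(sd$u), 0)
})

test_that("particle advection reproduces exact displacements", {
  g <- wave_grid(nx = 32)
  # uniform steady field over one period: dx = U T
  fU <- uniform_pvf(g, U = 0.31)
  r1 <- advect_particles(fU, x = 0.5, y = 0, t0 = 0, n_cycles = 1)
  expect_equal(r1$dx, 0.31, tolerance = 1e-12)
  expect_equal(r1$dy, 0, tolerance = 1e-14)
  # solid-body zero-mean oscillation: no net displacement after a full cycle
  fo <- oscillating_uniform_pvf(g, V0 = 0.05)
  r2 <- advect_particles(fo, x = 0.5, y = 0, t0 = 0, n_cycles = 1)
  expect_lt(abs(r2$dx), 1e-8 * 0.05)
  # traveling wave, small amplitude: axial drift approaches U^2 k / (2 w)
  f <- traveling_wave(U = 0.003)
  r3 <- advect_particles(f, x = 0.4, y = 0, t0 = 0, n_cycles = 1)
  expect_equal(r3$dx / 1, f$metadata$drift_u, tolerance = 2e-2)
})

test_that("advection is time-reversible: the reversed field returns the particle", {
  f <- traveling_wave(U = 0.05, n_phases = 50L)
  fwd <- advect_particles(f, x = 0.43, y = 0.02, t0 = 0, n_cycles = 1)
  # reversed-time field: w(x, t) = -v(x, T - t); snapshot k of the reverse
  # field (time k*dtp) is -snapshot(np - k) of the forward field
  np <- f$n_phases
  rev <- f
  idx <- c(np - seq_len(np - 1), np)   # maps k -> np - k, with k = np -> np
  rev$u <- -f$u[, , idx]
  rev$v <- -f$v[, , idx]
  back <- advect_particles(rev, x = fwd$x, y = fwd$y, t0 = 0, n_cycles = 1)
  expect_equal(back$x, 0.43, tolerance = 1e-9)
  expect_equal(back$dx, -fwd$dx, tolerance = 1e-6)
})

test_that("trajectory-based drift agrees with the field for degenerate cases", {
  g <- wave_grid(nx = 32)
  fU <- uniform_pvf(g, U = 0.2)
  tr <- lagrangian_mean_from_trajectories(fU, phases = c(0, 0.25, 0.5))
  expect_true(all(tr$particles$status == "ok"))
  expect_equal(max(abs(tr$samples$u - 0.2)), 0, tolerance = 1e-12)
  fo <- oscillating_uniform_pvf(g, V0 = 0.05)
  tr2 <- lagrangian_mean_from_trajectories(fo, phases = c(0, 0.35))
  expect_lt(max(abs(tr2$samples$u)), 1e-8 * 0.05)
})

test_that("drift samples are phase-independent at small stroke length", {
  f <- traveling_wave(U = 0.003)
  tr <- lagrangian_mean_from_trajectories(f)
  p <- tr$particles
  byseed <- split(p$dx, paste(p$x_i, p$y_i))
  relsd <- vapply(byseed, function(d) stats::sd(d) / abs(mean(d)), 0)
  expect_lt(max(relsd), 0.05)
})

test_that("scattered-data deposition is exact on linear data and on centered hits", {
  g <- structured_grid(12, 10, 0.1, 0.1, periodic_x = FALSE, wall_y = TRUE)
  cc <- cell_centers(g)
  xs <- rep(cc$x, length(cc$y)); ys <- rep(cc$y, each = length(cc$x))
  # samples exactly at every cell center: identity deposition
  uval <- sin(3 * xs) * ys^2
  dep <- scatter_to_grid(list(x = xs, y = ys, u = uval, v = -uval), g)
  expect_equal(as.numeric(dep$u), uval, tolerance = 1e-12)
  # constant samples at scattered positions
  set.seed(7)
  xr <- runif(400, 0, 1.2); yr <- runif(400, 0, 1)
  depc <- scatter_to_grid(list(x = xr, y = yr, u = rep(2.5, 400),
                               v = rep(-1, 400)), g)
  expect_equal(max(abs(depc$u - 2.5)), 0, tolerance = 1e-9)
  # linear-in-x samples reproduce the linear field to round-off
  depl <- scatter_to_grid(list(x = xr, y = yr, u = 3 * xr - 1, v = yr), g)
  expect_equal(as.numeric(depl$u), as.numeric(3 * outer(cc$x, rep(1, 10)) - 1),
               tolerance = 1e-8)
  expect_error(scatter_to_grid(list(x = numeric(0), y = numeric(0),
                                    u = numeric(0), v = numeric(0)), g),
               "empty")
})

test_that("small-stroke equivalence: trajectory drift converges to the asymptotic formula", {
  gap_at <- function(U) {
    f <- traveling_wave(U = U)
    tr <- lagrangian_mean_from_trajectories(f)
    raw <- scatter_to_grid(tr$samples, f$grid)
    vl <- project_solenoidal(raw)$field
    la <- lagrangian_mean_asymptotic(f)
    c(gap = max(abs(vl$u - la$u)), ref = max(abs(la$u)))
  }
  g1 <- gap_at(0.003)
  expect_lt(g1["gap"] / g1["ref"], 0.02)
  g2 <- gap_at(0.0015)
  # halving the stroke at least halves the absolute discrepancy
  expect_lt(g2[["gap"]], 0.55 * g1[["gap"]])
})
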