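# oscillatory Navier-Stokes solver with the flow-rate controller

test_that("the solver matches the analytic pulsatile profile and refines at second order", {
  fl <- fluid_params(nu = 5e-6)
  wf <- harmonic_waveform(1, 1)
  err_at <- function(ny) {
    g <- channel_grid(ny = ny, h = 1)
    wo <- womersley_channel_flow(g, wf, fl)
    res <- solve_oscillatory_channel(g, wf, fl)
    ref <- max(sapply(seq_len(100), function(p) sqrt(mean(wo$u[, , p]^2))))
    max(sapply(seq_len(100), function(p)
      sqrt(mean((res$field$u[, , p] - wo$u[, , p])^2)) / ref))
  }
  e16 <- err_at(16)
  e32 <- err_at(32)
  expect_lt(e32, 1e-2)
  # halving the spacing reduces the oracle error by at least a factor 3
  expect_gt(e16 / e32, 3)
})

test_that("flow-rate tracking and controller convergence hold at the periodic state", {
  g <- channel_grid(ny = 32, h = 1)
  fl <- fluid_params(nu = 5e-6)
  wf <- harmonic_waveform(1, 1)
  res <- solve_oscillatory_channel(g, wf, fl)
  Q <- flow_rate(res$field)
  Qt <- waveform_at(wf, (1:100) / 100)
  expect_lt(max(abs(Q - Qt)) / max(abs(Qt)), 1e-2)
  # per-cycle flow-rate error norm does not grow toward convergence
  en <- res$controller$cycle_error_norms
  expect_lte(utils::tail(en, 1), max(en) * 1.01)
  last <- utils::tail(en, min(5, length(en)))
  expect_true(all(diff(last) <= 0.01 * max(en)))  # non-increasing up to jitter
  # converged field is periodic and divergence-free
  expect_lt(res$field$metadata$periodicity_residual, 1e-4)
  expect_lt(max(abs(mac_divergence(res$field))),
            csfdrift:::div_tolerance(res$field))
})

test_that("obstacles raise the forcing amplitude needed for the same flow rate", {
  fl <- fluid_params(nu = 2e-6)
  wf <- harmonic_waveform(pi * 0.823, 1)
  nx <- 32L; ny <- 32L
  dx <- 1.6 / nx; dy <- 1.172 / ny
  xl <- ((seq_len(nx) - 0.5) * dx) %% 0.8
  yc <- (seq_len(ny) - 0.5) * dy
  mask <- outer(xl, yc, function(a, b)
    (a >= 0.1 & a < 0.6) & (b < 0.66 * (a - 0.1) / 0.5))
  gp <- structured_grid(nx, ny, dx, dy, periodic_x = TRUE, wall_y = TRUE)
  go <- structured_grid(nx, ny, dx, dy, mask = mask, periodic_x = TRUE,
                        wall_y = TRUE)
  rp <- solve_oscillatory_channel(gp, wf, fl, n_phases = 50L)
  ro <- solve_oscillatory_channel(go, wf, fl, n_phases = 50L)
  expect_gt(max(abs(ro$controller$force_per_phase)),
            max(abs(rp$controller$force_per_phase)))
})

test_that("a zero target waveform yields zero velocity and zero forcing", {
  g <- channel_grid(ny = 16)
  res <- solve_oscillatory_channel(
    g, flow_waveform(c(0, 0.5), c(0, 0), 1), fluid_params(nu = 5e-6),
    n_phases = 10L)
  expect_equal(max(abs(res$field$u), abs(res$field$v)), 0)
  expect_equal(max(abs(res$controller$force_per_phase)), 0)
})
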