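test_that("manufactured wave fields are divergence-free with the advertised drift", {
  g <- wave_grid()
  f <- traveling_wave(U = 0.01)
  expect_lt(max(abs(mac_divergence(f))), csfdrift:::div_tolerance(f))
  expect_equal(f$metadata$drift_u, 0.01^2 * 2 * pi / (2 * 2 * pi))
  # standing wave: zero cycle-averaged Eulerian velocity
  fs <- make_manufactured_wave_flow(g, 0.01, 2 * pi, 1, "standing")
  eu <- cycle_average(fs)
  expect_lt(max(abs(eu$u), abs(eu$v)), 1e-14)
  expect_equal(fs$metadata$drift_u, 0)
  # zero amplitude: identically zero snapshots
  f0 <- make_manufactured_wave_flow(g, 0, 2 * pi, 1, "traveling")
  expect_equal(max(abs(f0$u), abs(f0$v)), 0)
})

test_that("an under-resolved wavelength is rejected", {
  g <- structured_grid(16, 8, dx = 0.25, dy = 0.025, x0 = 0, y0 = -0.1,
                       periodic_x = TRUE, wall_y = FALSE)
  expect_error(make_manufactured_wave_flow(g, 0.01, 2 * pi, 1, "traveling"),
               "resolved")
})

test_that("pulsatile channel flow reproduces the target flow rate at every phase", {
  g <- channel_grid(ny = 64, h = 1)
  fl <- fluid_params(nu = 5e-6)
  wf <- harmonic_waveform(1, 1)
  wo <- womersley_channel_flow(g, wf, fl)
  Q <- flow_rate(wo)
  Qt <- waveform_at(wf, (1:100) / 100)
  expect_lt(max(abs(Q - Qt)) / max(abs(Qt)), 5e-3)
  expect_lt(max(abs(mac_divergence(wo))), csfdrift:::div_tolerance(wo))
  # stroke volume of the configured waveform: Q0 T / pi
  expect_equal(stroke_volume_and_epsilon(wf, 1)$V_s, 1 / pi, tolerance = 1e-4)
})

test_that("the quasi-steady limit is the Poiseuille profile", {
  g <- channel_grid(ny = 64, h = 1)
  # high viscosity at fixed frequency: Womersley number << 1
  fl <- fluid_params(nu = 5e-2)
  wf <- harmonic_waveform(1, 1)
  wo <- womersley_channel_flow(g, wf, fl)
  y <- cell_centers(g)$y - 0.5
  p <- 25L  # Q(0.25 s) = 1, the peak
  upar <- 1.5 * (1 - (y / 0.5)^2) / 1     # parabolic profile with unit flow rate
  expect_equal(wo$u[1, , p], upar * flow_rate(wo)[p], tolerance = 2e-3)
})

test_that("a zero waveform produces a zero field", {
  g <- channel_grid()
  wo <- womersley_channel_flow(g, flow_waveform(c(0, 0.5), c(0, 0), 1),
                               fluid_params(nu = 5e-6))
  expect_equal(max(abs(wo$u)), 0)
})

test_that("no-slip and divergence contracts are enforced at construction", {
  g <- channel_grid()
  u <- array(1, c(g$nx + 1L, g$ny, 2L))
  v <- array(0, c(g$nx, g$ny + 1L, 2L))
  v[, 1L, ] <- 0.5  # nonzero on the wall face
  expect_error(periodic_velocity_field(g, u, v, 1), "no-slip")
  v[, 1L, ] <- 0
  v[3, 4, ] <- 0.7  # interior divergence
  expect_error(periodic_velocity_field(g, u, v, 1), "divergence")
})
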