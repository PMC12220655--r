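# masked grid with an interior obstacle used across the projection tests
helm_grid <- function(nx = 48, ny = 32) {
  m <- matrix(FALSE, nx, ny)
  m[20:26, 12:18] <- TRUE
  structured_grid(nx, ny, dx = 1 / nx, dy = 1 / ny, mask = m,
                  periodic_x = TRUE, wall_y = TRUE)
}

test_that("divergence of a constant field vanishes and analytic fields are recovered", {
  g <- structured_grid(64, 16, 1 / 64, 1 / 16, periodic_x = TRUE,
                       periodic_y = TRUE, wall_y = FALSE)
  sf <- steady_velocity_field(g, matrix(1.3, 64, 16), matrix(-0.4, 64, 16),
                              "lagrangian_raw")
  expect_lt(max(abs(divergence(sf))), 1e-13)
  # field = grad(phi), phi = sin(kx): divergence = -k^2 sin(kx) + O(dx^2)
  k <- 2 * pi
  x <- cell_centers(g)$x
  u <- matrix(k * cos(k * x), 64, 16)
  sf2 <- steady_velocity_field(g, u, matrix(0, 64, 16), "lagrangian_raw")
  d <- divergence(sf2)
  expect_equal(d[, 1], -k^2 * sin(k * x), tolerance = 5e-3)
})

test_that("generated periodic fields satisfy the divergence contract", {
  f <- traveling_wave(U = 0.01)
  expect_lt(max(abs(mac_divergence(f))), csfdrift:::div_tolerance(f))
})

test_that("the Poisson solve recovers manufactured potentials with a zero-mean gauge", {
  g <- structured_grid(64, 16, 1 / 64, 1 / 16, periodic_x = TRUE,
                       periodic_y = TRUE, wall_y = FALSE)
  # zero source: gauge-fixed zero potential
  p0 <- solve_poisson(matrix(0, 64, 16), g)
  expect_equal(max(abs(p0$phi)), 0)
  # manufactured: Lap(sin(kx)) = -k^2 sin(kx)
  k <- 2 * pi
  x <- cell_centers(g)$x
  src <- matrix(-k^2 * sin(k * x), 64, 16)
  p <- solve_poisson(src, g)
  expect_equal(p$phi[, 1], sin(k * x), tolerance = 5e-3)
  expect_lt(abs(mean(p$phi)), 1e-12)
  # antisymmetric source pair gives an antisymmetric potential
  p2 <- solve_poisson(-src, g)
  expect_equal(p2$phi, -p$phi, tolerance = 1e-8)
})

test_that("an incompatible source raises a conservation error", {
  g <- helm_grid()
  src <- matrix(1, g$nx, g$ny)   # pure mean: no Neumann solution
  expect_error(solve_poisson(src, g), "incompatible")
})

test_that("the projection recovers manufactured solenoidal + gradient decompositions", {
  g <- structured_grid(48, 32, 1 / 48, 1 / 32, periodic_x = TRUE,
                       periodic_y = TRUE, wall_y = FALSE)
  ops <- csfdrift:::grad_operator(g)
  n <- ops$n
  # solenoidal part from a discrete stream function (s = curl psi in the
  # operator's own algebra), gradient part from a discrete potential
  cc <- cell_centers(g)
  psi <- outer(sin(2 * pi * cc$x), cos(2 * pi * cc$y))
  phi <- outer(cos(4 * pi * cc$x), rep(1, 32)) +
    outer(rep(1, 48), sin(2 * pi * cc$y))
  Gpsi <- as.numeric(ops$G %*% psi[ops$fluid])
  s_u <- matrix(Gpsi[n + seq_len(n)], 48, 32)    # ( dpsi/dy, -dpsi/dx )
  s_v <- matrix(-Gpsi[seq_len(n)], 48, 32)
  Gphi <- as.numeric(ops$G %*% phi[ops$fluid])
  g_u <- matrix(Gphi[seq_len(n)], 48, 32)
  g_v <- matrix(Gphi[n + seq_len(n)], 48, 32)
  raw <- steady_velocity_field(g, s_u + g_u, s_v + g_v, "lagrangian_raw")
  pr <- project_solenoidal(raw)
  # on the fully periodic grid the discrete curl is exactly solenoidal, so
  # the decomposition is recovered to solver tolerance, not just O(dx^2)
  expect_lt(max(abs(pr$field$u - s_u), abs(pr$field$v - s_v)), 1e-7)
  # pure gradient input projects to (nearly) zero
  prg <- project_solenoidal(
    steady_velocity_field(g, g_u, g_v, "lagrangian_raw"))
  expect_lt(max(abs(prg$field$u), abs(prg$field$v)), 1e-7)
  # already-solenoidal input is (nearly) unchanged with a flat potential
  prs <- project_solenoidal(
    steady_velocity_field(g, s_u, s_v, "lagrangian_raw"))
  expect_lt(max(abs(prs$field$u - s_u)), 1e-7)
  expect_lt(max(abs(prs$potential$phi)), 1e-7)
})

test_that("projection invariants: divergence kill, idempotence, energy ordering", {
  g <- helm_grid()
  set.seed(11)
  u <- matrix(rnorm(g$nx * g$ny), g$nx, g$ny)
  v <- matrix(rnorm(g$nx * g$ny), g$nx, g$ny)
  u[g$mask] <- 0; v[g$mask] <- 0
  raw <- steady_velocity_field(g, u, v, "lagrangian_raw")
  pr <- project_solenoidal(raw)
  # divergence kill ratio
  expect_lt(pr$diagnostics$max_div_after,
            1e-3 * pr$diagnostics$max_div_before)
  # idempotence: projecting twice equals projecting once
  pr2 <- project_solenoidal(pr$field)
  expect_lt(max(abs(pr2$field$u - pr$field$u), abs(pr2$field$v - pr$field$v)),
            1e-7 * max(abs(pr$field$u)))
  # energy ordering on the discrete inner product
  e_raw <- sum(u^2 + v^2)
  e_sol <- sum(pr$field$u^2 + pr$field$v^2)
  expect_lte(e_sol, e_raw)
  # the removed part is a pure gradient: orthogonal to the solenoidal part
  dot <- sum(pr$field$u * pr$grad_potential$u +
               pr$field$v * pr$grad_potential$v)
  expect_lt(abs(dot), 1e-8 * e_raw)
})
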