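# shared fixture builders and a lazy cache for the heavy study runs

.cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .cache)) assign(key, builder(), envir = .cache)
  get(key, envir = .cache)
}

# obstacle-free strip for manufactured-wave fixtures
wave_grid <- function(nx = 96, ny = 8) {
  structured_grid(nx, ny, dx = 1 / nx, dy = 0.025, x0 = 0, y0 = -0.1,
                  periodic_x = TRUE, wall_y = FALSE)
}

traveling_wave <- function(U = 0.003, nx = 96, n_phases = 100L) {
  make_manufactured_wave_flow(wave_grid(nx), U, 2 * pi, 1, "traveling",
                              n_phases = n_phases)
}

# small plane channel for solver tests
channel_grid <- function(nx = 8, ny = 32, h = 1) {
  structured_grid(nx, ny, dx = 1.6 / nx, dy = h / ny,
                  periodic_x = TRUE, wall_y = TRUE)
}

# uniform steady axial field as a periodic field with 2 identical phases
uniform_pvf <- function(grid, U = 1, n_phases = 2L) {
  u <- array(U, c(grid$nx + 1L, grid$ny, n_phases))
  v <- array(0, c(grid$nx, grid$ny + 1L, n_phases))
  v[, c(1L, grid$ny + 1L), ] <- if (grid$wall_y) 0 else 0
  periodic_velocity_field(grid, u, v, period = 1, check = FALSE)
}

# spatially uniform zero-mean oscillation (no walls)
oscillating_uniform_pvf <- function(grid, V0 = 1, n_phases = 100L) {
  ph <- (seq_len(n_phases)) / n_phases
  u <- array(0, c(grid$nx + 1L, grid$ny, n_phases))
  v <- array(0, c(grid$nx, grid$ny + 1L, n_phases))
  for (p in seq_len(n_phases)) u[, , p] <- V0 * sin(2 * pi * ph[p])
  periodic_velocity_field(grid, u, v, period = 1, check = FALSE)
}

# the heavy study conditions, computed once per test run
obstructed_study <- function() {
  cache_get("obstructed_study", function() {
    sc <- channel_scenario(obstructed = TRUE)
    dispersion_study(sc, variants = c("full_dns", "reduced_lagrangian",
                                      "comparison_eulerian",
                                      "diffusionless_dns"))
  })
}

patent_study <- function() {
  cache_get("patent_study", function() {
    sc <- channel_scenario(obstructed = FALSE)
    dispersion_study(sc, variants = "full_dns")
  })
}

sigma_at <- function(stats, t) sqrt(stats$sigma2[which.min(abs(stats$t - t))])
kappaH_at <- function(stats, t) {
  tt <- stats$t[which.min(abs(stats$t - t))]
  (stats$sigma2[which.min(abs(stats$t - t))] - stats$sigma2[1]) / (2 * tt)
}
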