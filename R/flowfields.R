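#' Manufactured divergence-free wave flow with closed-form drift
#'
#' Builds a time-periodic velocity field from a discrete stream function
#' evaluated at grid nodes, so every snapshot is divergence-free to machine
#' precision. Two kinds are available:
#'
#' * `traveling`: stream function `psi = U y cos(k x - omega t)`, whose axial
#'   velocity is the classic traveling wave `u = U cos(k x - omega t)` with a
#'   small compensating transverse component `v = U k y sin(k x - omega t)`.
#'   The cycle-averaged Eulerian velocity vanishes identically, yet particles
#'   drift axially at the Stokes-drift rate `U^2 k / (2 omega)` — the central
#'   Eulerian/Lagrangian contrast that motivates the reduced transport model.
#' * `standing`: `psi = U y cos(k x) cos(omega t)`; the flow is a zero-mean
#'   oscillation with zero drift.
#'
#' The closed-form cycle mean and Stokes drift are attached as metadata so
#' the field can serve as an oracle for the drift operators.
#'
#' @param grid an obstacle-free [structured_grid()], periodic in `x`.
#' @param amplitude wave amplitude `U` (cm/s).
#' @param wavenumber axial wavenumber `k` (1/cm); the wavelength `2 pi / k`
#'   must be resolved by at least 16 axial cells.
#' @param period temporal period `T` (s).
#' @param kind `"traveling"` or `"standing"`.
#' @param n_phases snapshots per cycle.
#' @return a [periodic_velocity_field()] with metadata fields `kind`, `U`,
#'   `k`, `omega`, `epsilon` (`U k / omega`, the dimensionless stroke length),
#'   `drift_u` and `drift_v` (closed-form mean Lagrangian drift, cm/s).
#' @export
make_manufactured_wave_flow <- function(grid, amplitude, wavenumber, period,
                                        kind = c("traveling", "standing"),
                                        n_phases = 100L) {
  kind <- match.arg(kind)
  if (any(grid$mask)) stop("manufactured wave flow requires an obstacle-free grid")
  if (!grid$periodic_x) stop("manufactured wave flow requires an axially periodic grid")
  if (!(wavenumber > 0)) stop("wavenumber must be positive")
  lambda <- 2 * pi / wavenumber
  if (lambda / grid$dx < 16) {
    stop(sprintf("under-resolved wavelength: %.3g cells per wavelength (need >= 16)",
                 lambda / grid$dx))
  }
  omega <- 2 * pi / period
  fc <- face_coords(grid)
  nx <- grid$nx; ny <- grid$ny
  u <- array(0, c(nx + 1L, ny, n_phases))
  v <- array(0, c(nx, ny + 1L, n_phases))
  # stream function at nodes (xf_i, yf_j); faces by discrete differences
  psi_nodes <- function(t) {
    if (kind == "traveling") {
      outer(cos(wavenumber * fc$xf - omega * t), fc$yf, function(cx, y) cx * y) * amplitude
    } else {
      outer(cos(wavenumber * fc$xf), fc$yf, function(cx, y) cx * y) *
        amplitude * cos(omega * t)
    }
  }
  for (p in seq_len(n_phases)) {
    t <- p * period / n_phases
    psi <- psi_nodes(t)
    u[, , p] <- (psi[, -1L, drop = FALSE] - psi[, -(ny + 1L), drop = FALSE]) / grid$dy
    v[, , p] <- -(psi[-1L, , drop = FALSE] - psi[-(nx + 1L), , drop = FALSE]) / grid$dx
  }
  drift_u <- if (kind == "traveling") amplitude^2 * wavenumber / (2 * omega) else 0
  periodic_velocity_field(
    grid, u, v, period,
    metadata = list(kind = kind, U = amplitude, k = wavenumber, omega = omega,
                    epsilon = amplitude * wavenumber / omega,
                    drift_u = drift_u, drift_v = 0))
}

# complex amplitude profile of one pulsatile-channel harmonic:
#   u_hat(y) = A [1 - cosh(beta yt) / cosh(beta H)],  beta = sqrt(i n omega / nu)
# with yt measured from the centerline, H the half-height, and A fixed so the
# cross-sectional integral matches the harmonic's complex flow rate.
womersley_mode <- function(Qhat, n, omega, nu, H, yt) {
  beta <- sqrt(1i * n * omega / nu)
  S <- 2 * H - (2 / beta) * tanh(beta * H)
  A <- Qhat / S
  A * (1 - cosh(beta * yt) / cosh(beta * H))
}

#' Analytic oscillatory channel flow matched to a flow-rate waveform
#'
#' Closed-form laminar pulsatile flow in a plane channel whose cross-sectional
#' flow rate reproduces `Q(t)`: each temporal harmonic of the waveform drives
#' the corresponding oscillatory channel profile (the plane-channel analogue
#' of pulsatile pipe flow), and a steady Poiseuille component carries the
#' cycle-mean flow. Serves as the exact oracle for the oscillatory
#' Navier-Stokes solver.
#'
#' @param grid an obstacle-free plane-channel [structured_grid()] (periodic in
#'   `x`, walls in `y`).
#' @param waveform a [flow_waveform()]. With `multi_harmonic = "error"` it
#'   must be a single harmonic (plus optionally a mean); with `"decompose"`
#'   arbitrary periodic waveforms are decomposed harmonic by harmonic.
#' @param fluid a [fluid_params()].
#' @param n_phases snapshots per cycle.
#' @param multi_harmonic `"decompose"` (default) or `"error"`.
#' @param harmonic_tol relative amplitude below which a harmonic is dropped.
#' @return a [periodic_velocity_field()]; metadata `profile_fun(y, t)` is the
#'   closed-form evaluator and `waveform` the target.
#' @export
womersley_channel_flow <- function(grid, waveform, fluid, n_phases = 100L,
                                   multi_harmonic = c("decompose", "error"),
                                   harmonic_tol = 1e-9) {
  multi_harmonic <- match.arg(multi_harmonic)
  if (any(grid$mask)) stop("womersley_channel_flow requires an obstacle-free channel")
  if (!grid$periodic_x || !grid$wall_y)
    stop("womersley_channel_flow requires an axially periodic channel with walls in y")
  period <- waveform$period
  if (abs(period - fluid$period) > 1e-12 * period)
    warning("waveform and fluid periods differ; using the waveform period")
  omega <- 2 * pi / period
  nu <- fluid$nu_cm2s
  h <- grid$Ly
  H <- h / 2
  # harmonic decomposition of Q(t) on a uniform phase grid
  nfft <- 512L
  tg <- (seq_len(nfft) - 1) * period / nfft
  Qg <- waveform_at(waveform, tg)
  co <- stats::fft(Qg) / nfft
  Qmax <- max(abs(Qg), 1e-300)
  nmax <- nfft %/% 2 - 1L
  amps <- 2 * co[2:(nmax + 1L)]            # Q(t) = Re{ sum amps_n e^{i n w t} } + mean
  keep <- which(Mod(amps) > harmonic_tol * Qmax)
  if (multi_harmonic == "error" && length(keep) > 1L)
    stop("waveform has multiple harmonics; set multi_harmonic = 'decompose'")
  Qmean <- Re(co[1])
  yc <- cell_centers(grid)$y
  yt <- yc - (grid$y0 + H)
  modes <- lapply(keep, function(n) womersley_mode(amps[n], n, omega, nu, H, yt))
  profile <- function(ytq, t) {
    u <- (3 * Qmean / (4 * H^3)) * (H^2 - ytq^2)
    for (ii in seq_along(keep)) {
      n <- keep[ii]
      md <- womersley_mode(amps[n], n, omega, nu, H, ytq)
      u <- u + Re(md * exp(1i * n * omega * t))
    }
    u
  }
  nx <- grid$nx; ny <- grid$ny
  u <- array(0, c(nx + 1L, ny, n_phases))
  v <- array(0, c(nx, ny + 1L, n_phases))
  for (p in seq_len(n_phases)) {
    t <- p * period / n_phases
    up <- (3 * Qmean / (4 * H^3)) * (H^2 - yt^2)
    for (ii in seq_along(keep)) {
      n <- keep[ii]
      up <- up + Re(modes[[ii]] * exp(1i * n * omega * t))
    }
    u[, , p] <- matrix(up, nx + 1L, ny, byrow = TRUE)
  }
  f <- periodic_velocity_field(
    grid, u, v, period,
    metadata = list(profile_fun = profile, waveform = waveform,
                    womersley_alpha = H * sqrt(omega / nu)))
  # contract: cross-sectional integral reproduces Q at every phase
  Qnum <- flow_rate(f)
  Qtgt <- waveform_at(waveform, (seq_len(n_phases)) * period / n_phases)
  err <- max(abs(Qnum - Qtgt)) / max(abs(Qtgt), 1e-300)
  if (max(abs(Qtgt)) > 0 && err > 5e-3) {
    stop(sprintf("flow-rate reproduction error %.3g exceeds 0.5%% (refine the transverse grid)",
                 err))
  }
  f$metadata$flow_rate_rel_err <- err
  f
}

#' Fluid properties
#'
#' @param rho density in kg/m^3.
#' @param nu kinematic viscosity in m^2/s.
#' @param period oscillation period in s.
#' @return an object of class `fluid_params`; `nu_cm2s` carries the viscosity
#'   in the package's working units (cm^2/s).
#' @export
fluid_params <- function(rho = 1000, nu = 0.7e-6, period = 1) {
  if (!(rho > 0 && nu > 0 && period > 0))
    stop("fluid parameters must be positive")
  structure(list(rho = rho, nu = nu, nu_cm2s = nu * 1e4, period = period),
            class = "fluid_params")
}

#' @method print fluid_params
#' @export
print.fluid_params <- function(x, ...) {
  cat(sprintf("<fluid_params> rho = %g kg/m^3, nu = %g m^2/s (%.4g cm^2/s), T = %g s\n",
              x$rho, x$nu, x$nu_cm2s, x$period))
  invisible(x)
}
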