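#' Solute transport parameters
#'
#' @param kappa molecular diffusivity in m^2/s (0 allowed: diffusionless
#'   variant).
#' @param dt requested time step in s (an upper bound; the solver sub-steps
#'   further whenever the CFL or diffusive stability limits demand it, and
#'   both values are recorded).
#' @param scheme `"limited_upwind_3rd"` (Koren flux limiter, default) or
#'   `"upwind_2nd"` (minmod) or `"upwind_1st"`.
#' @param t_end end time in s.
#' @param snapshot_every snapshot cadence in s.
#' @param cfl Courant number used for sub-stepping.
#' @return an object of class `transport_params`.
#' @export
transport_params <- function(kappa = 7e-10, dt = 0.01,
                             scheme = c("limited_upwind_3rd", "upwind_2nd", "upwind_1st"),
                             t_end = 60, snapshot_every = 1, cfl = 0.35) {
  scheme <- match.arg(scheme)
  if (kappa < 0) stop("kappa must be non-negative")
  if (!(dt > 0 && t_end > 0 && snapshot_every > 0)) stop("times must be positive")
  structure(list(kappa = kappa, kappa_cm2s = kappa * 1e4, dt = dt,
                 scheme = scheme, t_end = t_end,
                 snapshot_every = snapshot_every, cfl = cfl),
            class = "transport_params")
}

scheme_code <- function(scheme) {
  switch(scheme, limited_upwind_3rd = 1L, upwind_2nd = 2L, upwind_1st = 0L)
}

#' Gaussian solute bolus
#'
#' Initial condition `c(x) = exp(-(x - center)^2 / width_param)`, uniform in
#' the cross-sectional (transverse) direction and zero inside solids —
#' the canonical bolus released in the middle of the canal.
#'
#' @param grid the transport-domain [structured_grid()].
#' @param center bolus center (cm); must lie strictly inside the axial
#'   extent.
#' @param width_param Gaussian width parameter (cm^2); the axial variance of
#'   the profile is `width_param / 2`.
#' @return a `concentration_history` holding the single `t = 0` snapshot.
#' @export
gaussian_bolus <- function(grid, center = 5.6, width_param = 0.5) {
  if (center <= grid$x0 || center >= grid$x0 + grid$Lx)
    stop("bolus center must lie inside the domain")
  x <- cell_centers(grid)$x
  c0 <- matrix(exp(-(x - center)^2 / width_param), grid$nx, grid$ny)
  c0[grid$mask] <- 0
  concentration_history(grid, array(c0, c(grid$nx, grid$ny, 1L)), times = 0,
                        mass = sum(c0) * grid$dx * grid$dy, outflow = 0,
                        params = list(center = center, width_param = width_param))
}

concentration_history <- function(grid, snaps, times, mass, outflow,
                                  params = list(), variant = NULL) {
  h <- structure(list(grid = grid, c = snaps, times = times, mass = mass,
                      outflow = outflow, params = params, variant = variant),
                 class = "concentration_history")
  h$ledger_error <- if (mass[1] > 0)
    max(abs(mass + outflow - mass[1])) / mass[1] else 0
  h
}

#' @method print concentration_history
#' @export
print.concentration_history <- function(x, ...) {
  cat(sprintf("<concentration_history>%s %d snapshots, t in [%g, %g] s\n",
              if (is.null(x$variant)) "" else paste0(" [", x$variant, "]"),
              length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  initial mass %.6g, final mass %.6g, cumulative outflow %.6g (ledger error %.2e)\n",
              x$mass[1], utils::tail(x$mass, 1), utils::tail(x$outflow, 1),
              x$ledger_error))
  invisible(x)
}

initial_snapshot <- function(c0, grid) {
  if (inherits(c0, "concentration_history")) {
    m <- c0$c[, , dim(c0$c)[3]]
  } else m <- as.matrix(c0)
  if (!all(dim(m) == c(grid$nx, grid$ny)))
    stop("initial condition does not match the transport grid")
  m
}

# tile single-segment periodic face snapshots n_segments times along x
tile_faces <- function(field, n_segments) {
  g <- field$grid
  nx <- g$nx; ny <- g$ny; np <- field$n_phases
  nxt <- nx * n_segments
  u <- array(0, c(nxt + 1L, ny, np))
  v <- array(0, c(nxt, ny + 1L, np))
  for (s in seq_len(n_segments)) {
    u[(s - 1L) * nx + seq_len(nx), , ] <- field$u[seq_len(nx), , , drop = FALSE]
    v[(s - 1L) * nx + seq_len(nx), , ] <- field$v
  }
  u[nxt + 1L, , ] <- field$u[1L, , ]
  list(u = u, v = v)
}

#' Integrate the full oscillatory transport equation
#'
#' Solves `dc/dt + v . grad(c) = kappa Lap(c)` with the time-periodic
#' velocity field, on the axially replicated transport domain: conservative
#' finite-volume advection (flux-limited third-order upwind by default),
#' explicit centered diffusion, zero-flux on all solid surfaces, and open
#' rostral/caudal ends where exiting mass is lost to the ledger. This is the
#' desk-scale benchmark ("DNS") against which the reduced model is compared.
#'
#' @param field a [periodic_velocity_field()] on the single-segment grid.
#' @param c0 initial condition: matrix on the tiled grid, or the
#'   `concentration_history` from [gaussian_bolus()].
#' @param params a [transport_params()]; the default time step 0.01 s matches
#'   the stored 100 phases per 1 s cycle.
#' @param n_segments number of axial replicas (default from the grid).
#' @return a `concentration_history` (variant `"full_dns"`).
#' @export
integrate_full_transport <- function(field, c0 = NULL, params = transport_params(),
                                     n_segments = field$grid$n_segments) {
  g <- field$grid
  gt <- tile_grid(g, n_segments)
  if (is.null(c0)) c0 <- gaussian_bolus(gt)
  c0m <- initial_snapshot(c0, gt)
  tf <- tile_faces(field, n_segments)
  res <- transport_kernel(
    as.numeric(tf$u), dim(tf$u), as.numeric(tf$v), dim(tf$v),
    as.logical(gt$mask), gt$nx, gt$ny, gt$dx, gt$dy, field$period,
    as.numeric(c0m), params$kappa_cm2s, scheme_code(params$scheme),
    params$cfl, params$dt, params$t_end, params$snapshot_every,
    FALSE)
  finish_history(res, gt, params, "full_dns")
}

#' Integrate the reduced steady-advection transport equation
#'
#' Solves `dc/dt + v_L . grad(c) = kappa Lap(c)` with a time-independent
#' drift field: the solenoidal mean Lagrangian velocity for the reduced
#' model, or the cycle-averaged Eulerian velocity for the comparison model
#' (labeled `comparison_eulerian`). A raw, unprojected trajectory-based
#' drift is rejected: its nonzero divergence acts as a non-physical
#' distribution of solute sinks and sources that violates conservation.
#'
#' The requested time step (default 1 s) is reduced automatically whenever
#' the CFL limit on fast drift cells demands it; both values are recorded.
#'
#' @param mean_field a [steady_velocity_field()] with role
#'   `"lagrangian_solenoidal"` or `"eulerian_mean"`, on the single-segment
#'   grid.
#' @param c0 initial condition on the tiled grid (matrix or
#'   `concentration_history`); defaults to the standard bolus.
#' @param params a [transport_params()]; consider `dt = 1`.
#' @param n_segments number of axial replicas.
#' @return a `concentration_history` (variant `"reduced_lagrangian"` or
#'   `"comparison_eulerian"`).
#' @export
integrate_reduced_transport <- function(mean_field, c0 = NULL,
                                        params = transport_params(dt = 1),
                                        n_segments = mean_field$grid$n_segments) {
  role <- mean_field$role
  if (role == "lagrangian_raw") {
    stop(paste("unprojected trajectory-based drift rejected: its divergence acts",
               "as solute sinks/sources; apply project_solenoidal() first"))
  }
  if (!role %in% c("lagrangian_solenoidal", "eulerian_mean")) {
    stop(sprintf("unsupported drift role '%s' for reduced transport", role))
  }
  g <- mean_field$grid
  # face representation on the periodic segment; the cycle-averaged faces of
  # the flow solve are already divergence-free, center fields are averaged to
  # faces and cleaned by one projection
  if (!is.null(mean_field$metadata$face_u)) {
    uf <- mean_field$metadata$face_u[seq_len(g$nx), , drop = FALSE]
    vf <- mean_field$metadata$face_v
  } else {
    fc <- center_to_face(g, mean_field$u, mean_field$v)
    ops <- ns_poisson_setup(g)
    ufl <- !u_face_solid(g)[seq_len(g$nx), , drop = FALSE]
    vfl <- !v_face_solid(g)
    pr <- ns_project(fc$u[seq_len(g$nx), , drop = FALSE], fc$v, g, ops, ufl, vfl)
    uf <- pr$u; vf <- pr$v
  }
  ufull <- rbind(uf, uf[1L, ])
  gt <- tile_grid(g, n_segments)
  if (is.null(c0)) c0 <- gaussian_bolus(gt)
  c0m <- initial_snapshot(c0, gt)
  seg <- periodic_velocity_field(g, array(ufull, c(g$nx + 1L, g$ny, 1L)),
                                 array(vf, c(g$nx, g$ny + 1L, 1L)),
                                 period = 1, check = FALSE)
  tf <- tile_faces(seg, n_segments)
  res <- transport_kernel(
    as.numeric(tf$u), dim(tf$u), as.numeric(tf$v), dim(tf$v),
    as.logical(gt$mask), gt$nx, gt$ny, gt$dx, gt$dy, 1,
    as.numeric(c0m), params$kappa_cm2s, scheme_code(params$scheme),
    params$cfl, params$dt, params$t_end, params$snapshot_every,
    FALSE)
  variant <- if (role == "eulerian_mean") "comparison_eulerian" else "reduced_lagrangian"
  finish_history(res, gt, params, variant)
}

finish_history <- function(res, gt, params, variant) {
  snaps <- array(res$snaps, c(gt$nx, gt$ny, length(res$times)))
  h <- concentration_history(
    gt, snaps, times = res$times, mass = res$mass, outflow = res$outflow,
    params = list(scheme = params$scheme, kappa_cm2s = params$kappa_cm2s,
                  dt_requested = params$dt, dt_used = res$dt,
                  substeps_per_snapshot = res$substeps_per_snap,
                  min_c = res$min_c),
    variant = variant)
  utol <- if (params$scheme == "upwind_1st") 1e-12 else 1e-10
  if (res$min_c < -utol * max(res$mass[1], 1e-300))
    warning(sprintf("undershoot %.3e below the bounded-undershoot tolerance", res$min_c))
  h
}

#' Longitudinal solute distribution
#'
#' Integrates the concentration across the open cross section at each axial
#' station, `C(x, t) = integral of c ds` (cm^2 at unit depth): the quantity
#' whose spreading measures drug dispersion.
#'
#' @param history a `concentration_history`.
#' @return an object of class `longitudinal_profile` with stations `x`,
#'   matrix `C` (`nx` by `n_times`), and `times`.
#' @export
longitudinal_profile <- function(history) {
  g <- history$grid
  nt <- length(history$times)
  C <- matrix(0, g$nx, nt)
  for (k in seq_len(nt)) {
    ck <- history$c[, , k]
    ck[g$mask] <- 0
    C[, k] <- rowSums(ck) * g$dy
  }
  structure(list(x = cell_centers(g)$x, C = C, times = history$times,
                 dx = g$dx),
            class = "longitudinal_profile")
}

trapz <- function(x, y) sum(0.5 * (y[-1] + y[-length(y)]) * diff(x))

#' Bolus dispersion statistics
#'
#' Center of mass `xbar(t)` and axial variance
#' `sigma^2(t) = integral (x - xbar)^2 C dx / integral C dx` of the
#' longitudinal distribution, by trapezoidal quadrature over the stations.
#'
#' @param profile a [longitudinal_profile()].
#' @return a `dispersion_metrics` data frame with columns `t`, `xbar` (cm),
#'   `sigma2` (cm^2).
#' @export
dispersion_stats <- function(profile) {
  nt <- length(profile$times)
  xbar <- numeric(nt); s2 <- numeric(nt)
  for (k in seq_len(nt)) {
    Ck <- profile$C[, k]
    M <- trapz(profile$x, Ck)
    if (!(M > 0) || M < 1e-300) stop("zero total mass: dispersion statistics undefined")
    xbar[k] <- trapz(profile$x, profile$x * Ck) / M
    s2[k] <- trapz(profile$x, (profile$x - xbar[k])^2 * Ck) / M
  }
  out <- data.frame(t = profile$times, xbar = xbar, sigma2 = s2)
  class(out) <- c("dispersion_metrics", "data.frame")
  out
}

#' Effective hydrodynamic diffusivity
#'
#' Taylor-type dispersion coefficient `kappa_H(t) = 0.5 d(sigma^2)/dt`,
#' evaluated with the secant formula
#' `kappa_H(t) = (sigma^2(t) - sigma^2(0)) / (2 t)` and reported in cm^2/s.
#'
#' @param metrics a `dispersion_metrics` data frame (from
#'   [dispersion_stats()]).
#' @return data frame with columns `t` and `kappa_H` (cm^2/s); `kappa_H` is
#'   `NA` at `t = 0`.
#' @export
hydrodynamic_diffusivity <- function(metrics) {
  s20 <- metrics$sigma2[metrics$t == min(metrics$t)][1]
  kH <- ifelse(metrics$t > 0, (metrics$sigma2 - s20) / (2 * metrics$t), NA_real_)
  data.frame(t = metrics$t, kappa_H = kH)
}
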