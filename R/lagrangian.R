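#' Mean Lagrangian velocity: asymptotic streaming + Stokes drift
#'
#' In the small-stroke limit the mean Lagrangian velocity of fluid particles
#' in a time-periodic flow splits into the cycle-averaged Eulerian (streaming)
#' velocity plus the Stokes drift — a kinematic contribution from the spatial
#' non-uniformity of the purely oscillatory component,
#' `< (integral of (v - <v>) dt) . grad(v - <v>) >`, where `< >` is the cycle
#' average. The antiderivative is the zero-mean cumulative phase integral of
#' the fluctuation; gradients are centered differences, falling back to
#' one-sided stencils where the stencil would cross into a solid.
#'
#' @param field a [periodic_velocity_field()] (divergence-free).
#' @return a [steady_velocity_field()] with role `"stokes_drift"`; metadata
#'   flags the cells where one-sided gradients were used.
#' @export
stokes_drift_asymptotic <- function(field) {
  g <- field$grid
  np <- field$n_phases
  if (np < 2L) stop("Stokes drift needs at least 2 phase snapshots")
  dt <- field$period / np
  nx <- g$nx; ny <- g$ny
  uc <- array(0, c(nx, ny, np)); vc <- array(0, c(nx, ny, np))
  for (p in seq_len(np)) {
    cc <- cell_center_velocity(field, p)
    uc[, , p] <- cc$u; vc[, , p] <- cc$v
  }
  um <- apply(uc, c(1, 2), mean); vm <- apply(vc, c(1, 2), mean)
  up <- sweep(uc, c(1, 2), um); vp <- sweep(vc, c(1, 2), vm)
  # zero-mean antiderivative of the fluctuation (cumulative trapezoid in phase)
  anti <- function(a) {
    w <- array(0, dim(a))
    for (p in 2:np) w[, , p] <- w[, , p - 1] + 0.5 * dt * (a[, , p - 1] + a[, , p])
    sweep(w, c(1, 2), apply(w, c(1, 2), mean))
  }
  Wx <- anti(up); Wy <- anti(vp)
  du <- array(0, c(nx, ny, np, 2L)); dv <- array(0, c(nx, ny, np, 2L))
  onesided <- matrix(FALSE, nx, ny)
  for (p in seq_len(np)) {
    gu <- grad_center(up[, , p], g); gv <- grad_center(vp[, , p], g)
    du[, , p, 1] <- gu$gx; du[, , p, 2] <- gu$gy
    dv[, , p, 1] <- gv$gx; dv[, , p, 2] <- gv$gy
    onesided <- onesided | gu$onesided
  }
  drift_u <- apply(Wx * du[, , , 1] + Wy * du[, , , 2], c(1, 2), mean)
  drift_v <- apply(Wx * dv[, , , 1] + Wy * dv[, , , 2], c(1, 2), mean)
  drift_u[g$mask] <- 0; drift_v[g$mask] <- 0
  steady_velocity_field(g, drift_u, drift_v, "stokes_drift",
                        metadata = list(onesided_cells = onesided))
}

# centered-difference gradient of a cell-centered scalar with mask awareness:
# centered where both neighbours are fluid, one-sided otherwise
grad_center <- function(f, g) {
  nx <- g$nx; ny <- g$ny
  fluid <- !g$mask
  fE <- if (g$periodic_x) f[c(2:nx, 1L), , drop = FALSE] else
    rbind(f[-1L, , drop = FALSE], f[nx, ])
  fW <- if (g$periodic_x) f[c(nx, 1:(nx - 1)), , drop = FALSE] else
    rbind(f[1L, ], f[-nx, , drop = FALSE])
  okE <- if (g$periodic_x) fluid[c(2:nx, 1L), , drop = FALSE] else
    rbind(fluid[-1L, , drop = FALSE], rep(FALSE, ny))
  okW <- if (g$periodic_x) fluid[c(nx, 1:(nx - 1)), , drop = FALSE] else
    rbind(rep(FALSE, ny), fluid[-nx, , drop = FALSE])
  gx <- matrix(0, nx, ny)
  both <- okE & okW; pe <- okE & !okW; pw <- okW & !okE
  gx[both] <- (fE[both] - fW[both]) / (2 * g$dx)
  gx[pe] <- (fE[pe] - f[pe]) / g$dx
  gx[pw] <- (f[pw] - fW[pw]) / g$dx
  fN <- if (g$periodic_y) f[, c(2:ny, 1L), drop = FALSE] else
    cbind(f[, -1L, drop = FALSE], f[, ny])
  fS <- if (g$periodic_y) f[, c(ny, 1:(ny - 1)), drop = FALSE] else
    cbind(f[, 1L], f[, -ny, drop = FALSE])
  okN <- if (g$periodic_y) fluid[, c(2:ny, 1L), drop = FALSE] else
    cbind(fluid[, -1L, drop = FALSE], rep(FALSE, nx))
  okS <- if (g$periodic_y) fluid[, c(ny, 1:(ny - 1)), drop = FALSE] else
    cbind(rep(FALSE, nx), fluid[, -ny, drop = FALSE])
  gy <- matrix(0, nx, ny)
  both2 <- okN & okS; pn <- okN & !okS; ps <- okS & !okN
  gy[both2] <- (fN[both2] - fS[both2]) / (2 * g$dy)
  gy[pn] <- (fN[pn] - f[pn]) / g$dy
  gy[ps] <- (f[ps] - fS[ps]) / g$dy
  gx[!fluid] <- 0; gy[!fluid] <- 0
  list(gx = gx, gy = gy, onesided = fluid & !(both & both2))
}

#' @rdname stokes_drift_asymptotic
#' @details `lagrangian_mean_asymptotic()` returns the small-stroke mean
#'   Lagrangian velocity, the sum of the cycle average and the Stokes drift.
#'   The formula is an asymptotic approximation, strictly valid only for
#'   dimensionless stroke lengths `epsilon << 1`.
#' @export
lagrangian_mean_asymptotic <- function(field) {
  eu <- cycle_average(field)
  sd <- stokes_drift_asymptotic(field)
  steady_velocity_field(field$grid, eu$u + sd$u, eu$v + sd$v,
                        "lagrangian_asymptotic",
                        metadata = list(onesided_cells = sd$metadata$onesided_cells))
}

# ghost-padded per-phase face arrays for interpolation: honors no-slip
# (mirror across walls so the interpolant vanishes there), periodic wrap in x,
# flat extrapolation across open boundaries
pad_for_interp <- function(field) {
  g <- field$grid
  nx <- g$nx; ny <- g$ny; np <- field$n_phases
  U <- array(0, c(nx + 3L, ny + 2L, np))
  V <- array(0, c(nx + 2L, ny + 3L, np))
  for (p in seq_len(np)) {
    u <- field$u[, , p]                 # (nx+1) x ny
    ug <- matrix(0, nx + 3L, ny + 2L)
    ug[2:(nx + 2L), 2:(ny + 1L)] <- u
    ug[1L, ] <- if (g$periodic_x) ug[nx + 1L, ] else ug[2L, ]
    ug[nx + 3L, ] <- if (g$periodic_x) ug[3L, ] else ug[nx + 2L, ]
    if (g$periodic_y) {
      ug[, 1L] <- ug[, ny + 1L]; ug[, ny + 2L] <- ug[, 2L]
    } else if (g$wall_y) {
      ug[, 1L] <- -ug[, 2L]; ug[, ny + 2L] <- -ug[, ny + 1L]
    } else {
      ug[, 1L] <- ug[, 2L]; ug[, ny + 2L] <- ug[, ny + 1L]
    }
    U[, , p] <- ug
    v <- field$v[, , p]                 # nx x (ny+1)
    vg <- matrix(0, nx + 2L, ny + 3L)
    vg[2:(nx + 1L), 2:(ny + 2L)] <- v
    vg[1L, ] <- if (g$periodic_x) vg[nx + 1L, ] else vg[2L, ]
    vg[nx + 2L, ] <- if (g$periodic_x) vg[3L, ] else vg[nx + 1L, ]
    if (g$periodic_y) {
      vg[, 1L] <- vg[, ny + 1L]; vg[, ny + 3L] <- vg[, 3L]
    } else {
      vg[, 1L] <- vg[, 2L]; vg[, ny + 3L] <- vg[, ny + 2L]
    }
    V[, , p] <- vg
  }
  list(U = U, V = V)
}

# vectorized staggered bilinear sample of one padded snapshot pair
# u lattice: positions x0 + (i-2)*dx (i = 1..nx+3), y0 + (j-1.5)*dy
# v lattice: positions x0 + (i-1.5)*dx, y0 + (j-2)*dy
interp_face <- function(A, x, y, x0, y0, dx, dy, xoff, yoff, p) {
  gx <- (x - x0) / dx + xoff
  gy <- (y - y0) / dy + yoff
  i0 <- floor(gx); j0 <- floor(gy)
  fx <- gx - i0; fy <- gy - j0
  ni <- dim(A)[1]; nj <- dim(A)[2]
  i0 <- pmin(pmax(i0, 1L), ni - 1L)
  j0 <- pmin(pmax(j0, 1L), nj - 1L)
  base <- (p - 1L) * ni * nj
  idx <- function(ii, jj) base + (jj - 1L) * ni + ii
  a00 <- A[idx(i0, j0)]; a10 <- A[idx(i0 + 1L, j0)]
  a01 <- A[idx(i0, j0 + 1L)]; a11 <- A[idx(i0 + 1L, j0 + 1L)]
  (1 - fx) * (1 - fy) * a00 + fx * (1 - fy) * a10 +
    (1 - fx) * fy * a01 + fx * fy * a11
}

# velocity at arbitrary points and times: spatial staggered bilinear,
# temporal periodic-linear between snapshots (snapshot p is at p*T/np)
velocity_at <- function(pads, field, x, y, t) {
  g <- field$grid
  np <- field$n_phases
  dtp <- field$period / np
  xs <- if (g$periodic_x) g$x0 + ((x - g$x0) %% g$Lx) else x
  if (np == 1L) {
    u <- interp_face(pads$U, xs, y, g$x0, g$y0, g$dx, g$dy, 2, 1.5, 1L)
    v <- interp_face(pads$V, xs, y, g$x0, g$y0, g$dx, g$dy, 1.5, 2, 1L)
    return(list(u = u, v = v))
  }
  ph <- (t / dtp) %% np                     # snapshot p at phase-index p
  p0 <- floor(ph)
  w1 <- ph - p0
  pa <- as.integer((p0 - 1L) %% np + 1L)    # snapshot at index p0 (time p0*dtp)
  pb <- as.integer(p0 %% np + 1L)
  ua <- interp_face(pads$U, xs, y, g$x0, g$y0, g$dx, g$dy, 2, 1.5, pa)
  ub <- interp_face(pads$U, xs, y, g$x0, g$y0, g$dx, g$dy, 2, 1.5, pb)
  va <- interp_face(pads$V, xs, y, g$x0, g$y0, g$dx, g$dy, 1.5, 2, pa)
  vb <- interp_face(pads$V, xs, y, g$x0, g$y0, g$dx, g$dy, 1.5, 2, pb)
  list(u = (1 - w1) * ua + w1 * ub, v = (1 - w1) * va + w1 * vb)
}

#' Advect fluid particles through a periodic velocity field
#'
#' Integrates the particle trajectory equation `dx/dt = v(x, t)` with the
#' classical four-stage Runge-Kutta scheme; velocity at arbitrary points is
#' obtained by staggered bilinear interpolation in space and periodic linear
#' interpolation in time between the stored phase snapshots. The axial
#' coordinate is unwrapped across the periodic seam so cycle displacements
#' are exact. Particles whose position enters a solid cell are truncated with
#' status `"entered_solid"`; particles leaving a non-periodic boundary get
#' `"left_domain"`.
#'
#' @param field a [periodic_velocity_field()].
#' @param x,y seed coordinates (cm), equal-length vectors.
#' @param t0 seed phase(s) in s (scalar or per-particle).
#' @param n_cycles number of periods to integrate.
#' @param substep integration step (s), at most the snapshot interval.
#' @param trajectory if `TRUE`, also return the full unwrapped trajectories
#'   (arrays `n_steps+1 x n_particles`).
#' @return a list with unwrapped final positions `x`, `y`, cycle displacement
#'   `dx`, `dy`, trapezoidal cycle-mean positions `xo`, `yo` (unwrapped),
#'   `status` (factor: ok / entered_solid / left_domain), and optionally
#'   `traj_x`, `traj_y`, `times`.
#' @export
advect_particles <- function(field, x, y, t0 = 0, n_cycles = 1,
                             substep = NULL, trajectory = FALSE) {
  g <- field$grid
  np <- field$n_phases
  dt_snap <- field$period / np
  if (is.null(substep)) substep <- dt_snap
  if (substep > dt_snap + 1e-12) stop("substep must not exceed the snapshot interval")
  n <- length(x)
  stopifnot(length(y) == n)
  t <- rep_len(t0, n)
  pads <- pad_for_interp(field)
  nsteps <- ceiling(n_cycles * field$period / substep)
  dt <- n_cycles * field$period / nsteps
  xi <- x; yi <- y
  alive <- rep(TRUE, n)
  status <- rep("ok", n)
  # trapezoidal running mean of the unwrapped trajectory
  xacc <- numeric(n); yacc <- numeric(n)
  if (trajectory) {
    tx <- matrix(NA_real_, nsteps + 1L, n); ty <- matrix(NA_real_, nsteps + 1L, n)
    tx[1L, ] <- x; ty[1L, ] <- y
  }
  in_solid <- function(xq, yq) {
    xs <- if (g$periodic_x) g$x0 + ((xq - g$x0) %% g$Lx) else xq
    i <- pmin(pmax(floor((xs - g$x0) / g$dx) + 1L, 1L), g$nx)
    j <- pmin(pmax(floor((yq - g$y0) / g$dy) + 1L, 1L), g$ny)
    g$mask[cbind(i, j)]
  }
  out_of_domain <- function(xq, yq) {
    bad <- rep(FALSE, length(xq))
    if (!g$periodic_x) bad <- bad | xq < g$x0 | xq > g$x0 + g$Lx
    if (!g$periodic_y) bad <- bad | yq < g$y0 | yq > g$y0 + g$Ly
    bad
  }
  for (s in seq_len(nsteps)) {
    ia <- which(alive)
    if (!length(ia)) break
    xa <- x[ia]; ya <- y[ia]; ta <- t[ia]
    k1 <- velocity_at(pads, field, xa, ya, ta)
    k2 <- velocity_at(pads, field, xa + 0.5 * dt * k1$u, ya + 0.5 * dt * k1$v, ta + 0.5 * dt)
    k3 <- velocity_at(pads, field, xa + 0.5 * dt * k2$u, ya + 0.5 * dt * k2$v, ta + 0.5 * dt)
    k4 <- velocity_at(pads, field, xa + dt * k3$u, ya + dt * k3$v, ta + dt)
    xn <- xa + dt / 6 * (k1$u + 2 * k2$u + 2 * k3$u + k4$u)
    yn <- ya + dt / 6 * (k1$v + 2 * k2$v + 2 * k3$v + k4$v)
    xacc[ia] <- xacc[ia] + 0.5 * dt * (xa + xn)
    yacc[ia] <- yacc[ia] + 0.5 * dt * (ya + yn)
    bad_dom <- out_of_domain(xn, yn)
    bad_sol <- !bad_dom & in_solid(xn, yn)
    status[ia[bad_dom]] <- "left_domain"
    status[ia[bad_sol]] <- "entered_solid"
    alive[ia[bad_dom | bad_sol]] <- FALSE
    keep <- !(bad_dom | bad_sol)
    x[ia[keep]] <- xn[keep]; y[ia[keep]] <- yn[keep]
    t[ia] <- ta + dt
    if (trajectory) { tx[s + 1L, ia[keep]] <- xn[keep]; ty[s + 1L, ia[keep]] <- yn[keep] }
  }
  Ttot <- n_cycles * field$period
  out <- list(x = x, y = y, dx = x - xi, dy = y - yi,
              xo = xacc / Ttot, yo = yacc / Ttot,
              status = factor(status, levels = c("ok", "entered_solid", "left_domain")))
  if (trajectory) {
    out$traj_x <- tx; out$traj_y <- ty
    out$times <- rep_len(t0, n)[1] + (0:nsteps) * dt
  }
  out
}

#' Trajectory-based mean Lagrangian velocity
#'
#' Seeds massless particles at every fluid-cell center, integrates each over
#' one full cycle from several initial phases, and evaluates the mean
#' Lagrangian velocity as the cycle displacement divided by the period,
#' `v*_L(x_o) = delta_x / T`, attached at the cycle-mean particle position
#' `x_o`. Samples from all initial phases are deposited independently and
#' averaged on the grid (see [scatter_to_grid()]), which removes the
#' dependence on the seeding phase.
#'
#' @param field a [periodic_velocity_field()].
#' @param seeding `"cell_centers"` or a list with numeric vectors `x`, `y`.
#' @param phases initial phases `t_i` (s); default 20 equispaced values over
#'   one period.
#' @param substep trajectory integration step, at most the snapshot interval.
#' @param max_bad_frac fraction of non-ok particles above which a warning is
#'   emitted.
#' @return a list with `particles` (a `particle_set` data frame: id, phase,
#'   seed, displacement, mean position, status) and `samples` (the scattered
#'   drift samples at the ok mean positions).
#' @export
lagrangian_mean_from_trajectories <- function(field, seeding = "cell_centers",
                                              phases = NULL, substep = NULL,
                                              max_bad_frac = 0.05) {
  g <- field$grid
  if (is.null(phases)) phases <- (0:19) / 20 * field$period
  if (identical(seeding, "cell_centers")) {
    cc <- cell_centers(g)
    fl <- which(!g$mask, arr.ind = TRUE)
    sx <- cc$x[fl[, 1]]; sy <- cc$y[fl[, 2]]
  } else {
    sx <- seeding$x; sy <- seeding$y
  }
  ns <- length(sx); nph <- length(phases)
  X <- rep(sx, nph); Y <- rep(sy, nph)
  PH <- rep(phases, each = ns)
  res <- advect_particles(field, X, Y, t0 = PH, n_cycles = 1, substep = substep)
  Tper <- field$period
  # wrap mean positions back into the domain
  xo <- if (g$periodic_x) g$x0 + ((res$xo - g$x0) %% g$Lx) else res$xo
  yo <- if (g$periodic_y) g$y0 + ((res$yo - g$y0) %% g$Ly) else res$yo
  ok <- res$status == "ok"
  bad_frac <- 1 - mean(ok)
  if (bad_frac > max_bad_frac) {
    warning(sprintf("%.1f%% of particles lost (entered_solid: %d, left_domain: %d); excluded",
                    100 * bad_frac, sum(res$status == "entered_solid"),
                    sum(res$status == "left_domain")))
  }
  particles <- data.frame(
    id = seq_along(X), phase = PH, x_i = X, y_i = Y,
    dx = res$dx, dy = res$dy, x_o = xo, y_o = yo, status = res$status)
  class(particles) <- c("particle_set", "data.frame")
  samples <- list(x = xo[ok], y = yo[ok],
                  u = res$dx[ok] / Tper, v = res$dy[ok] / Tper)
  list(particles = particles, samples = samples)
}

#' Deposit scattered drift samples onto cell centers
#'
#' Interpolating moving-least-squares deposition with a linear basis: for
#' each fluid-cell center the nearby samples (inverse-squared-distance
#' weights, singular at zero distance so a sample sitting on the center is
#' reproduced exactly) are fit with a local linear model and evaluated at the
#' center. Linear scattered data are therefore reproduced to round-off. Cells
#' whose neighbourhood holds fewer than three usable samples fall back to the
#' nearest sample and are flagged.
#'
#' @param samples list with vectors `x`, `y`, `u`, `v` (scattered drift
#'   samples, cm and cm/s).
#' @param grid the target [structured_grid()].
#' @param role role tag of the returned field, default `"lagrangian_raw"`.
#' @return a [steady_velocity_field()]; metadata `nn_filled` flags cells
#'   filled by the nearest-neighbour fallback.
#' @export
scatter_to_grid <- function(samples, grid, role = "lagrangian_raw") {
  if (!length(samples$x)) stop("empty scattered sample set")
  nx <- grid$nx; ny <- grid$ny
  cc <- cell_centers(grid)
  # bin samples into cells (periodic wrap applied by caller already)
  bi <- pmin(pmax(floor((samples$x - grid$x0) / grid$dx) + 1L, 1L), nx)
  bj <- pmin(pmax(floor((samples$y - grid$y0) / grid$dy) + 1L, 1L), ny)
  bins <- split(seq_along(samples$x), (bj - 1L) * nx + bi)
  U <- matrix(0, nx, ny); V <- matrix(0, nx, ny)
  nnfill <- matrix(FALSE, nx, ny)
  gather <- function(i, j, ring) {
    ir <- (i - ring):(i + ring); jr <- (j - ring):(j + ring)
    if (grid$periodic_x) ir <- ((ir - 1L) %% nx) + 1L else ir <- ir[ir >= 1 & ir <= nx]
    if (grid$periodic_y) jr <- ((jr - 1L) %% ny) + 1L else jr <- jr[jr >= 1 & jr <= ny]
    keys <- as.character(outer((jr - 1L) * nx, ir, `+`))
    unlist(bins[keys], use.names = FALSE)
  }
  Lx <- grid$Lx; Ly <- grid$Ly
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    if (grid$mask[i, j]) next
    ring <- 1L
    id <- gather(i, j, ring)
    while (length(id) < 4L && ring < max(nx, ny)) {
      ring <- ring + 1L
      id <- gather(i, j, ring)
    }
    if (!length(id)) stop("scattered samples do not cover the fluid region")
    ddx <- samples$x[id] - cc$x[i]
    ddy <- samples$y[id] - cc$y[j]
    if (grid$periodic_x) ddx <- ddx - round(ddx / Lx) * Lx
    if (grid$periodic_y) ddy <- ddy - round(ddy / Ly) * Ly
    d2 <- ddx^2 + ddy^2
    hit <- d2 < (1e-9 * min(grid$dx, grid$dy))^2
    if (any(hit)) {
      U[i, j] <- mean(samples$u[id[hit]]); V[i, j] <- mean(samples$v[id[hit]])
      next
    }
    if (length(id) < 3L) {
      k <- id[which.min(d2)]
      U[i, j] <- samples$u[k]; V[i, j] <- samples$v[k]
      nnfill[i, j] <- TRUE
      next
    }
    # smooth inverse-distance weights: a half-cell floor averages the local
    # sample cloud (many seeding phases land near one center) instead of
    # chasing individual samples; linear-basis exactness is unaffected
    w <- 1 / (d2 + (0.45 * min(grid$dx, grid$dy))^2)
    sw <- sum(w); swx <- sum(w * ddx); swy <- sum(w * ddy)
    sxx <- sum(w * ddx^2); sxy <- sum(w * ddx * ddy); syy <- sum(w * ddy^2)
    A <- matrix(c(sw, swx, swy, swx, sxx, sxy, swy, sxy, syy), 3, 3)
    fit <- function(val) {
      b <- c(sum(w * val), sum(w * ddx * val), sum(w * ddy * val))
      co <- tryCatch(solve(A, b), error = function(e) NULL)
      if (is.null(co)) stats::weighted.mean(val, w) else co[1]
    }
    U[i, j] <- fit(samples$u[id])
    V[i, j] <- fit(samples$v[id])
  }
  steady_velocity_field(grid, U, V, role, metadata = list(nn_filled = nnfill))
}
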