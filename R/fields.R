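#' One cycle of a time-periodic incompressible velocity field
#'
#' Stores `n_phases` equally spaced snapshots of a divergence-free velocity
#' field over one oscillation period on a staggered (marker-and-cell) face
#' lattice: the axial component `u` lives on x-faces (`(nx + 1) x ny` per
#' phase, with the seam face duplicated on axially periodic grids) and the
#' transverse component `v` on y-faces (`nx x (ny + 1)`). Face storage is what
#' makes the discrete divergence of every snapshot vanish to machine
#' precision; use [cell_center_velocity()] to obtain collocated values for
#' export or plotting. Snapshot `k` holds the state at time `k * T / n_phases`
#' (so the set wraps periodically, snapshot `n_phases` being the cycle end
#' which equals the cycle start of a converged field).
#'
#' @param grid a [structured_grid()].
#' @param u numeric array `(nx + 1) x ny x n_phases`, axial velocity at
#'   x-faces (cm/s).
#' @param v numeric array `nx x (ny + 1) x n_phases`, transverse velocity at
#'   y-faces (cm/s).
#' @param period oscillation period `T` in s.
#' @param metadata optional list (closed-form drift for manufactured fields,
#'   oracle coefficients, solver diagnostics, ...).
#' @param check validate the no-slip and divergence invariants (default TRUE).
#' @return an object of class `periodic_velocity_field`.
#' @export
periodic_velocity_field <- function(grid, u, v, period, metadata = list(),
                                    check = TRUE) {
  nx <- grid$nx; ny <- grid$ny
  stopifnot(length(dim(u)) == 3L, length(dim(v)) == 3L)
  if (!all(dim(u)[1:2] == c(nx + 1L, ny)) || !all(dim(v)[1:2] == c(nx, ny + 1L)))
    stop("face array dimensions do not match the grid")
  np <- dim(u)[3]
  if (dim(v)[3] != np) stop("u and v must have the same number of phases")
  if (np < 1L) stop("at least one phase snapshot required")
  if (!(period > 0)) stop("period must be positive")
  f <- structure(list(grid = grid, u = u, v = v, period = period,
                      n_phases = np, metadata = metadata),
                 class = "periodic_velocity_field")
  if (check) validate_pvf(f)
  f
}

# divergence tolerance of the generated-field contract: 1e-10 * U_ref / dx
div_tolerance <- function(field) {
  uref <- max(abs(field$u), abs(field$v), 1e-12)
  1e-10 * uref / min(field$grid$dx, field$grid$dy)
}

validate_pvf <- function(f) {
  g <- f$grid
  usol <- u_face_solid(g)
  vsol <- v_face_solid(g)
  for (p in seq_len(f$n_phases)) {
    if (any(abs(f$u[, , p][usol]) > 0) || any(abs(f$v[, , p][vsol]) > 0))
      stop("no-slip violation: nonzero velocity on a solid face")
  }
  dv <- max_divergence(f)
  tol <- div_tolerance(f)
  if (dv > tol) {
    stop(sprintf("field is not discretely divergence-free: max |div| = %.3e > tol %.3e",
                 dv, tol))
  }
  invisible(TRUE)
}

#' @method print periodic_velocity_field
#' @export
print.periodic_velocity_field <- function(x, ...) {
  cat(sprintf("<periodic_velocity_field> %d phases, T = %.4g s, grid %d x %d\n",
              x$n_phases, x$period, x$grid$nx, x$grid$ny))
  cat(sprintf("  max |u| = %.4g cm/s, max |v| = %.4g cm/s, max |div| = %.3e 1/s\n",
              max(abs(x$u)), max(abs(x$v)), max_divergence(x)))
  invisible(x)
}

#' Compact (staggered) divergence of a face-stored field
#'
#' @param field a [periodic_velocity_field()].
#' @param phase snapshot index, or `NULL` for all phases.
#' @return matrix `nx x ny` (or array with phases) of the discrete divergence
#'   in 1/s; identically zero in solid cells.
#' @export
mac_divergence <- function(field, phase = NULL) {
  g <- field$grid
  one <- function(p) {
    u <- field$u[, , p]; v <- field$v[, , p]
    d <- (u[-1L, , drop = FALSE] - u[-(g$nx + 1L), , drop = FALSE]) / g$dx +
      (v[, -1L, drop = FALSE] - v[, -(g$ny + 1L), drop = FALSE]) / g$dy
    d[g$mask] <- 0
    d
  }
  if (!is.null(phase)) return(one(phase))
  out <- array(0, c(g$nx, g$ny, field$n_phases))
  for (p in seq_len(field$n_phases)) out[, , p] <- one(p)
  out
}

max_divergence <- function(field) max(abs(mac_divergence(field)))

#' Collocated (cell-center) velocity of a face-stored snapshot
#'
#' @param field a [periodic_velocity_field()].
#' @param phase snapshot index.
#' @return list of `nx x ny` matrices `u`, `v` (cm/s) at cell centers.
#' @export
cell_center_velocity <- function(field, phase = 1L) {
  g <- field$grid
  u <- field$u[, , phase]; v <- field$v[, , phase]
  uc <- 0.5 * (u[-1L, , drop = FALSE] + u[-(g$nx + 1L), , drop = FALSE])
  vc <- 0.5 * (v[, -1L, drop = FALSE] + v[, -(g$ny + 1L), drop = FALSE])
  uc[g$mask] <- 0; vc[g$mask] <- 0
  list(u = uc, v = vc)
}

#' Instantaneous flow rate of a periodic field
#'
#' Integrates the axial velocity over the cross section at a given axial face
#' station. For a divergence-free field bounded by walls the result is
#' independent of the station.
#'
#' @param field a [periodic_velocity_field()].
#' @param station axial face index (1-based).
#' @return numeric vector, one flow rate (mL/s, unit depth) per phase.
#' @export
flow_rate <- function(field, station = 1L) {
  g <- field$grid
  colSums(matrix(field$u[station, , ], g$ny, field$n_phases)) * g$dy
}

#' Time-independent (cycle-mean or drift) velocity field
#'
#' Cell-center collocated steady vector field with a role tag identifying its
#' provenance: the cycle-averaged Eulerian (streaming) velocity, the asymptotic
#' Stokes drift, their sum (the small-stroke mean Lagrangian velocity), the
#' raw trajectory-based mean Lagrangian velocity, its solenoidal projection,
#' or the potential gradient removed by the projection.
#'
#' @param grid a [structured_grid()].
#' @param u,v `nx x ny` matrices (cm/s) at cell centers; zero in solid cells.
#' @param role one of `"eulerian_mean"`, `"stokes_drift"`,
#'   `"lagrangian_asymptotic"`, `"lagrangian_raw"`, `"lagrangian_solenoidal"`,
#'   `"potential_gradient"`.
#' @param metadata optional list.
#' @return an object of class `steady_velocity_field`.
#' @export
steady_velocity_field <- function(grid, u, v, role, metadata = list()) {
  roles <- c("eulerian_mean", "stokes_drift", "lagrangian_asymptotic",
             "lagrangian_raw", "lagrangian_solenoidal", "potential_gradient")
  role <- match.arg(role, roles)
  u <- as.matrix(u); v <- as.matrix(v)
  if (!all(dim(u) == c(grid$nx, grid$ny)) || !all(dim(v) == c(grid$nx, grid$ny)))
    stop("u and v must be nx x ny matrices")
  if (any(abs(u[grid$mask]) > 0) || any(abs(v[grid$mask]) > 0))
    stop("steady field must vanish in solid cells")
  structure(list(grid = grid, u = u, v = v, role = role, metadata = metadata),
            class = "steady_velocity_field")
}

#' @method print steady_velocity_field
#' @export
print.steady_velocity_field <- function(x, ...) {
  cat(sprintf("<steady_velocity_field> role %s, grid %d x %d, max speed %.4g cm/s\n",
              x$role, x$grid$nx, x$grid$ny, max(sqrt(x$u^2 + x$v^2))))
  invisible(x)
}

#' Cycle average of a periodic velocity field
#'
#' Per-cell time mean over one period. With equally spaced snapshots of a
#' periodic signal the trapezoidal rule with periodic closure reduces to the
#' arithmetic mean of the snapshots. The result is the mean Eulerian
#' (streaming) velocity.
#'
#' @param field a [periodic_velocity_field()] with at least 2 snapshots.
#' @return a [steady_velocity_field()] with role `"eulerian_mean"`.
#' @export
cycle_average <- function(field) {
  if (field$n_phases < 2L) stop("cycle average needs at least 2 phase snapshots")
  g <- field$grid
  um <- apply(field$u, c(1, 2), mean)
  vm <- apply(field$v, c(1, 2), mean)
  uc <- 0.5 * (um[-1L, , drop = FALSE] + um[-(g$nx + 1L), , drop = FALSE])
  vc <- 0.5 * (vm[, -1L, drop = FALSE] + vm[, -(g$ny + 1L), drop = FALSE])
  uc[g$mask] <- 0; vc[g$mask] <- 0
  steady_velocity_field(g, uc, vc, "eulerian_mean",
                        metadata = list(face_u = um, face_v = vm))
}

# center -> face averaging (used to feed steady drift fields to the
# finite-volume transport kernel); periodic wrap in x where applicable,
# zero on solid faces and walls, one-sided copy at open boundaries.
center_to_face <- function(grid, u, v) {
  nx <- grid$nx; ny <- grid$ny
  uf <- matrix(0, nx + 1L, ny)
  if (grid$periodic_x) {
    uf[2:nx, ] <- 0.5 * (u[1:(nx - 1), ] + u[2:nx, ])
    uf[1L, ] <- 0.5 * (u[nx, ] + u[1L, ])
    uf[nx + 1L, ] <- uf[1L, ]
  } else {
    uf[2:nx, ] <- 0.5 * (u[1:(nx - 1), ] + u[2:nx, ])
    uf[1L, ] <- u[1L, ]
    uf[nx + 1L, ] <- u[nx, ]
  }
  vf <- matrix(0, nx, ny + 1L)
  vf[, 2:ny] <- 0.5 * (v[, 1:(ny - 1)] + v[, 2:ny])
  if (grid$periodic_y) {
    vf[, 1L] <- 0.5 * (v[, ny] + v[, 1L])
    vf[, ny + 1L] <- vf[, 1L]
  } else if (!grid$wall_y) {
    vf[, 1L] <- v[, 1L]
    vf[, ny + 1L] <- v[, ny]
  }
  uf[u_face_solid(grid)] <- 0
  vf[v_face_solid(grid)] <- 0
  list(u = uf, v = vf)
}
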