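#' Helmholtz decomposition of cell-centered drift fields
#'
#' The trajectory-based mean Lagrangian velocity is in general not
#' divergence-free at finite stroke length; its non-solenoidal part acts as a
#' non-physical distribution of solute sinks and sources. These routines
#' remove it: the scalar potential solves the Poisson problem
#' `div(v*) = Lap(Phi)` and the solenoidal drift is `v_L = v* - grad(Phi)`.
#'
#' Discretely, the gradient `G` is an explicit sparse operator (centered in
#' the interior, one-sided against walls and obstacles, periodic across the
#' axial seam), the divergence is its negative adjoint `D = -t(G)`, and the
#' Laplacian is their composition. Because the projection then solves the
#' normal equations `t(G) G Phi = t(G) v*`, the decomposition is exactly
#' orthogonal in the discrete inner product: the projected field satisfies
#' `D v_L = 0` to solver tolerance, projecting twice equals projecting once,
#' and `||v_L||_2 <= ||v*||_2`.
#'
#' @name helmholtz
NULL

# sparse gradient operator over fluid cells: rows 1..n are d/dx, n+1..2n d/dy
# centered where both neighbours are fluid, one-sided against solids/walls,
# periodic wrap where the grid is periodic
grad_operator <- function(grid) {
  nx <- grid$nx; ny <- grid$ny
  fluid <- !grid$mask
  idx <- matrix(NA_integer_, nx, ny)
  idx[fluid] <- seq_len(sum(fluid))
  n <- sum(fluid)
  is <- rep(seq_len(nx), ny)[fluid]
  js <- rep(seq_len(ny), each = nx)[fluid]
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  axis_entries <- function(ip, jp, im, jm, self_i, self_j, d, roff) {
    # neighbour fluid indices (NA when blocked)
    np_ <- ifelse(!is.na(ip) & fluid[cbind(pmax(ip, 1L), pmax(jp, 1L))] &
                    !is.na(ip), idx[cbind(pmax(ip, 1L), pmax(jp, 1L))], NA_integer_)
    nm_ <- ifelse(!is.na(im) & fluid[cbind(pmax(im, 1L), pmax(jm, 1L))] &
                    !is.na(im), idx[cbind(pmax(im, 1L), pmax(jm, 1L))], NA_integer_)
    ns_ <- idx[cbind(self_i, self_j)]
    r <- roff + ns_
    both <- !is.na(np_) & !is.na(nm_)
    onlyp <- !is.na(np_) & is.na(nm_)
    onlym <- is.na(np_) & !is.na(nm_)
    rows <<- c(rows, r[both], r[both], r[onlyp], r[onlyp], r[onlym], r[onlym])
    cols <<- c(cols, np_[both], nm_[both], np_[onlyp], ns_[onlyp],
               ns_[onlym], nm_[onlym])
    vals <<- c(vals, rep(1 / (2 * d), sum(both)), rep(-1 / (2 * d), sum(both)),
               rep(1 / d, sum(onlyp)), rep(-1 / d, sum(onlyp)),
               rep(1 / d, sum(onlym)), rep(-1 / d, sum(onlym)))
  }
  wrap <- function(i, nmax, periodic) {
    out <- i
    out[out > nmax] <- if (periodic) 1L else NA_integer_
    out[out < 1L] <- if (periodic) nmax else NA_integer_
    out
  }
  ip <- wrap(is + 1L, nx, grid$periodic_x); im <- wrap(is - 1L, nx, grid$periodic_x)
  axis_entries(ip, js, im, js, is, js, grid$dx, 0L)
  jp <- wrap(js + 1L, ny, grid$periodic_y); jm <- wrap(js - 1L, ny, grid$periodic_y)
  axis_entries(is, jp, is, jm, is, js, grid$dy, n)
  G <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(2L * n, n))
  # known nullspace of G: the constant mode, plus the parity (checkerboard)
  # modes that the wide centered stencil cannot see on fully periodic grids
  cand <- list(rep(1, n),
               (-1)^is, (-1)^js, (-1)^(is + js))
  gmax <- max(abs(vals))
  N <- NULL
  for (v in cand) {
    if (max(abs(G %*% v)) <= 1e-12 * gmax * sqrt(n)) {
      v <- v / sqrt(sum(v^2))
      if (!is.null(N)) v <- v - N %*% crossprod(N, v)
      nv <- sqrt(sum(v^2))
      if (nv > 0.5) N <- cbind(N, as.numeric(v) / nv)
    }
  }
  list(G = G, idx = idx, fluid = fluid, n = n, nullsp = N)
}

field_vec <- function(sf, ops) c(sf$u[ops$fluid], sf$v[ops$fluid])

vec_field <- function(w, grid, ops, role, metadata = list()) {
  n <- ops$n
  u <- matrix(0, grid$nx, grid$ny); v <- matrix(0, grid$nx, grid$ny)
  u[ops$fluid] <- w[seq_len(n)]
  v[ops$fluid] <- w[n + seq_len(n)]
  steady_velocity_field(grid, u, v, role, metadata)
}

#' Discrete divergence of a steady cell-centered field
#'
#' Applies the adjoint divergence `D = -t(G)` of the [helmholtz] operator
#' pair, which reduces to centered differences in the interior.
#'
#' @param field a [steady_velocity_field()].
#' @param ops optional precomputed operator set from `grad_operator()`.
#' @return `nx x ny` matrix of the divergence (1/s), zero in solid cells.
#' @export
divergence <- function(field, ops = NULL) {
  grid <- field$grid
  if (is.null(ops)) ops <- grad_operator(grid)
  w <- field_vec(field, ops)
  d <- -as.numeric(Matrix::crossprod(ops$G, w))
  out <- matrix(0, grid$nx, grid$ny)
  out[ops$fluid] <- d
  out
}

# preconditioned conjugate gradients for the consistent singular SPD system
# A x = b with A = crossprod(G); Jacobi preconditioner, deflation of the
# known nullspace, and a stagnation guard so roundoff-level right-hand
# sides cannot drive unbounded growth along null directions
cg_normal <- function(G, b, tol = 1e-10, maxit = 20000L, nullsp = NULL,
                      bscale = NULL) {
  n <- length(b)
  deflate <- function(v) {
    if (is.null(nullsp)) v else v - as.numeric(nullsp %*% crossprod(nullsp, v))
  }
  b <- deflate(b)
  b0 <- sqrt(sum(b^2))
  if (b0 == 0 || (!is.null(bscale) && b0 <= 1e-12 * bscale)) {
    return(list(x = numeric(n), resid = 0, iters = 0L))
  }
  dA <- as.numeric(Matrix::colSums(G^2))
  dA[dA <= 0] <- 1
  x <- numeric(n)
  r <- b
  z <- r / dA
  p <- z
  rz <- sum(r * z)
  best_x <- x; best_rn <- b0; last_best_it <- 0L
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(Matrix::crossprod(G, G %*% p))
    pAp <- sum(p * Ap)
    if (!(pAp > 0)) break
    alpha <- rz / pAp
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (it %% 50L == 0L) r <- deflate(r)
    rn <- sqrt(sum(r^2))
    if (rn < best_rn) { best_rn <- rn; best_x <- x; last_best_it <- it }
    if (rn <= tol * b0) return(list(x = deflate(x), resid = rn / b0, iters = it))
    if (it - last_best_it > 100L) break   # stagnation: roundoff floor reached
    z <- r / dA
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  list(x = deflate(best_x), resid = best_rn / b0, iters = maxit)
}

#' Scalar potential field
#'
#' @param grid a [structured_grid()].
#' @param phi `nx x ny` matrix of the potential (cm^2/s), zero-mean over fluid
#'   cells (the pure-Neumann gauge).
#' @param metadata optional list (solver residual, removed source mean, ...).
#' @return an object of class `potential_field`.
#' @export
potential_field <- function(grid, phi, metadata = list()) {
  phi <- as.matrix(phi)
  if (!all(dim(phi) == c(grid$nx, grid$ny))) stop("phi must be nx x ny")
  structure(list(grid = grid, phi = phi, metadata = metadata),
            class = "potential_field")
}

#' @method print potential_field
#' @export
print.potential_field <- function(x, ...) {
  cat(sprintf("<potential_field> grid %d x %d, range [%.4g, %.4g] cm^2/s\n",
              x$grid$nx, x$grid$ny, min(x$phi), max(x$phi)))
  invisible(x)
}

#' Solve the potential Poisson problem
#'
#' Integrates `Lap(Phi) = source` on the fluid cells with the operator pair of
#' [helmholtz] (Neumann against solids/walls, periodic across the axial seam),
#' removing the source mean to enforce pure-Neumann compatibility and fixing
#' the gauge by a zero fluid-cell mean.
#'
#' @param source `nx x ny` matrix (1/s).
#' @param grid a [structured_grid()].
#' @param tol relative residual tolerance.
#' @param compat_tol maximum tolerated relative source imbalance; a mean
#'   component larger than this fraction of the source magnitude raises a
#'   conservation error.
#' @return a [potential_field()]; metadata records the solver residual and
#'   the removed source mean.
#' @export
solve_poisson <- function(source, grid, tol = 1e-10, compat_tol = 0.5) {
  ops <- grad_operator(grid)
  s <- as.matrix(source)[ops$fluid]
  smax <- max(abs(s))
  smean <- mean(s)
  if (smax > 0 && abs(smean) > compat_tol * smax) {
    stop(sprintf("incompatible Poisson source: mean %.3e exceeds %.0f%% of max %.3e",
                 smean, 100 * compat_tol, smax))
  }
  s <- s - smean
  # Lap Phi = s  <=>  -crossprod(G) Phi = s
  sol <- cg_normal(ops$G, -s, tol = tol, nullsp = ops$nullsp)
  phi <- sol$x - mean(sol$x)
  out <- matrix(0, grid$nx, grid$ny)
  out[ops$fluid] <- phi
  potential_field(grid, out,
                  metadata = list(residual = sol$resid, iters = sol$iters,
                                  removed_source_mean = smean))
}

#' Project a drift field onto its solenoidal part
#'
#' Computes `v_L = v* - grad(Phi)` where `Phi` solves the least-squares
#' problem `min ||v* - grad(Phi)||_2` over the fluid cells — equivalently the
#' Poisson problem `div(v*) = Lap(Phi)` with Neumann boundaries. The result
#' is the divergence-free mean Lagrangian velocity suitable for conservative
#' solute transport.
#'
#' @param raw a [steady_velocity_field()] (typically role `"lagrangian_raw"`).
#' @param tol relative CG tolerance.
#' @return a list with `field` (role `"lagrangian_solenoidal"`), `potential`
#'   (a [potential_field()]), `grad_potential` (role `"potential_gradient"`),
#'   and `diagnostics` (max/mean absolute divergence before and after, CG
#'   residual).
#' @export
project_solenoidal <- function(raw, tol = 1e-10) {
  grid <- raw$grid
  ops <- grad_operator(grid)
  w <- field_vec(raw, ops)
  b <- as.numeric(Matrix::crossprod(ops$G, w))
  gmax <- max(abs(ops$G))
  sol <- cg_normal(ops$G, b, tol = tol, nullsp = ops$nullsp,
                   bscale = gmax * sqrt(sum(w^2)))
  phi <- sol$x - mean(sol$x)
  gphi <- as.numeric(ops$G %*% phi)
  wl <- w - gphi
  div_before <- divergence(raw, ops)
  fld <- vec_field(wl, grid, ops, "lagrangian_solenoidal",
                   metadata = raw$metadata)
  div_after <- divergence(fld, ops)
  phimat <- matrix(0, grid$nx, grid$ny)
  phimat[ops$fluid] <- phi
  list(
    field = fld,
    potential = potential_field(grid, phimat,
                                metadata = list(residual = sol$resid)),
    grad_potential = vec_field(gphi, grid, ops, "potential_gradient"),
    diagnostics = list(
      max_div_before = max(abs(div_before)),
      max_div_after = max(abs(div_after)),
      mean_div_before = mean(abs(div_before[ops$fluid])),
      mean_div_after = mean(abs(div_after[ops$fluid])),
      cg_residual = sol$resid, cg_iters = sol$iters)
  )
}
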