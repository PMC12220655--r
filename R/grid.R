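#' Rectilinear computational grid with solid-obstacle mask
#'
#' Builds the structured grid on which all velocity fields and concentration
#' histories live: a uniform rectilinear lattice of `nx` by `ny` cells, an
#' optional solid mask marking obstacle interiors (stair-step representation
#' of nerve rootlets, denticulate ligaments or any blockage), and periodicity
#' flags per axis. The axial direction `x` is periodic for single-segment flow
#' solves and open (outflow at both ends) for the replicated transport domain;
#' the transverse direction `y` is bounded by no-slip walls unless declared
#' periodic (used by manufactured fixtures).
#'
#' @param nx,ny number of cells along the axial (`x`) and transverse (`y`)
#'   axes.
#' @param dx,dy cell spacing in cm; must be positive.
#' @param x0,y0 coordinates (cm) of the lower-left corner of the domain.
#' @param mask logical `nx` by `ny` matrix, `TRUE` marking solid (obstacle)
#'   cells. `NULL` means fully open.
#' @param periodic_x,periodic_y periodicity flags. Non-periodic `y` boundaries
#'   are no-slip walls when `wall_y = TRUE` (the default), open otherwise.
#' @param wall_y are the `y` boundaries solid walls? Ignored when
#'   `periodic_y = TRUE`.
#' @param n_segments number of axial replicas used when the single-segment
#'   velocity field is tiled for transport.
#'
#' @return An object of class `structured_grid` with the lattice geometry,
#'   the mask, and the open cross-sectional area per axial station
#'   `A(x)` (cm^2, unit out-of-plane depth).
#' @export
structured_grid <- function(nx, ny, dx, dy, x0 = 0, y0 = 0, mask = NULL,
                            periodic_x = TRUE, periodic_y = FALSE,
                            wall_y = TRUE, n_segments = 1L) {
  stopifnot(nx >= 2, ny >= 2)
  if (!(dx > 0 && dy > 0)) stop("grid spacing must be positive on every axis")
  if (is.null(mask)) mask <- matrix(FALSE, nx, ny)
  mask <- as.matrix(mask)
  if (!identical(dim(mask), c(as.integer(nx), as.integer(ny)))) {
    stop("mask must be an nx by ny logical matrix")
  }
  storage.mode(mask) <- "logical"
  open_area <- rowSums(!mask) * dy
  if (any(open_area <= 0)) {
    stop("grid has a fully blocked axial station: A(x) must be positive everywhere")
  }
  if (periodic_x && !identical(mask[1L, ], mask[nx, ])) {
    stop("axial-periodic grid must have identical masks at the first and last axial stations")
  }
  g <- structure(list(
    nx = as.integer(nx), ny = as.integer(ny),
    dx = dx, dy = dy, x0 = x0, y0 = y0,
    Lx = nx * dx, Ly = ny * dy,
    mask = mask,
    periodic_x = isTRUE(periodic_x),
    periodic_y = isTRUE(periodic_y),
    wall_y = isTRUE(wall_y) && !isTRUE(periodic_y),
    L_seg = nx * dx,
    n_segments = as.integer(n_segments),
    open_area = open_area
  ), class = "structured_grid")
  holes <- isolated_fluid_cells(g)
  if (any(holes)) {
    stop("mask leaves isolated single-cell fluid holes; solids must form closed shapes")
  }
  g
}

#' @method print structured_grid
#' @export
print.structured_grid <- function(x, ...) {
  cat(sprintf(
    "<structured_grid> %d x %d cells, dx = %.4g cm, dy = %.4g cm\n",
    x$nx, x$ny, x$dx, x$dy))
  cat(sprintf("  domain: x in [%.4g, %.4g] cm, y in [%.4g, %.4g] cm\n",
              x$x0, x$x0 + x$Lx, x$y0, x$y0 + x$Ly))
  cat(sprintf("  periodic_x: %s, periodic_y: %s, wall_y: %s\n",
              x$periodic_x, x$periodic_y, x$wall_y))
  cat(sprintf("  solid cells: %d of %d; min open area %.4g cm^2\n",
              sum(x$mask), x$nx * x$ny, min(x$open_area)))
  invisible(x)
}

# fluid cells whose 4 neighbours (with wrapping where periodic) are all solid;
# beyond an open boundary counts as fluid, beyond a wall as solid
isolated_fluid_cells <- function(g) {
  m <- g$mask
  nx <- g$nx; ny <- g$ny
  solid_e <- if (g$periodic_x) m[c(2:nx, 1L), , drop = FALSE] else
    rbind(m[-1L, , drop = FALSE], rep(FALSE, ny))
  solid_w <- if (g$periodic_x) m[c(nx, 1:(nx - 1)), , drop = FALSE] else
    rbind(rep(FALSE, ny), m[-nx, , drop = FALSE])
  solid_n <- if (g$periodic_y) m[, c(2:ny, 1L), drop = FALSE] else
    cbind(m[, -1L, drop = FALSE], rep(g$wall_y, nx))
  solid_s <- if (g$periodic_y) m[, c(ny, 1:(ny - 1)), drop = FALSE] else
    cbind(rep(g$wall_y, nx), m[, -ny, drop = FALSE])
  (!m) & solid_e & solid_w & solid_n & solid_s
}

#' Cell-center and face coordinates of a grid
#'
#' @param grid a [structured_grid()].
#' @return `cell_centers()` gives a list with numeric vectors `x` and `y`;
#'   `face_coords()` gives the face-line coordinates (`xf` of length `nx + 1`,
#'   `yf` of length `ny + 1`).
#' @export
cell_centers <- function(grid) {
  list(x = grid$x0 + (seq_len(grid$nx) - 0.5) * grid$dx,
       y = grid$y0 + (seq_len(grid$ny) - 0.5) * grid$dy)
}

#' @rdname cell_centers
#' @export
face_coords <- function(grid) {
  list(xf = grid$x0 + (0:grid$nx) * grid$dx,
       yf = grid$y0 + (0:grid$ny) * grid$dy)
}

#' Open cross-sectional area per axial station
#'
#' @param grid a [structured_grid()].
#' @return numeric vector `A(x)` in cm^2 (unit depth), one value per axial
#'   station.
#' @export
open_area <- function(grid) grid$open_area

# face solidity: a u-face is solid when either adjacent cell is solid; the
# outermost x-faces of a non-periodic grid are open (domain boundary), and
# wall y-faces are solid.
u_face_solid <- function(g) {
  m <- g$mask
  nx <- g$nx
  if (g$periodic_x) {
    left <- m[c(nx, seq_len(nx - 1)), , drop = FALSE]
    sol <- m | left                       # face i sits left of cell i
    rbind(sol, sol[1L, ])                 # duplicate seam face nx+1
  } else {
    inner <- m[-nx, , drop = FALSE] | m[-1L, , drop = FALSE]
    rbind(m[1L, ], inner, m[nx, ])        # boundary faces solid iff cell solid
  }
}

v_face_solid <- function(g) {
  m <- g$mask
  ny <- g$ny
  if (g$periodic_y) {
    below <- m[, c(ny, seq_len(ny - 1)), drop = FALSE]
    sol <- m | below
    cbind(sol, sol[, 1L])
  } else {
    inner <- m[, -ny, drop = FALSE] | m[, -1L, drop = FALSE]
    bot <- if (g$wall_y) rep(TRUE, g$nx) else m[, 1L]
    top <- if (g$wall_y) rep(TRUE, g$nx) else m[, ny]
    cbind(bot, inner, top)
  }
}

#' Replicate a segment grid axially for transport
#'
#' The single-segment flow domain is tiled `n_segments` times along `x` to
#' form the transport domain; the tiled grid is open (non-periodic) in `x`
#' so that solute can leave through the rostral and caudal ends.
#'
#' @param grid a periodic single-segment [structured_grid()].
#' @param n_segments number of axial replicas; defaults to `grid$n_segments`.
#' @param x0 axial origin of the tiled domain (cm); defaults to the segment's.
#' @return a [structured_grid()] covering `n_segments` replicas.
#' @export
tile_grid <- function(grid, n_segments = grid$n_segments, x0 = grid$x0) {
  stopifnot(n_segments >= 1)
  mask <- do.call(rbind, rep(list(grid$mask), n_segments))
  structured_grid(grid$nx * n_segments, grid$ny, grid$dx, grid$dy,
                  x0 = x0, y0 = grid$y0, mask = mask,
                  periodic_x = FALSE, periodic_y = grid$periodic_y,
                  wall_y = grid$wall_y, n_segments = 1L)
}
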