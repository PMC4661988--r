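# Staggered Cartesian grid, lumen masks, and field containers.
#
# Index conventions (used everywhere, including stacked vectors and sparse
# matrices): cells are addressed as (i, j, k) with 1 <= i <= nx etc., and the
# linear index runs x fastest, then y, then z -- i.e. R's native array order
# for an (nx, ny, nz) array.  Velocity components live on cell faces:
#   u[i, j, k], dim (nx+1, ny, nz): face between cells (i-1, j, k) and (i, j, k)
#   v[i, j, k], dim (nx, ny+1, nz): face between cells (i, j-1, k) and (i, j, k)
#   w[i, j, k], dim (nx, ny, nz+1): face between cells (i, j, k-1) and (i, j, k)
# Pressure and all MRI-comparable quantities are cell-centered.  All internal
# units are SI (m, s, kg, Pa); velocity I/O helpers accept/emit cm/s.

#' Cell labels for the lumen mask
#'
#' Integer labels used in [lumen_mask()] volumes: solid wall, fluid interior,
#' and inlet/outlet layers on the boundary z-planes.
#' @name mask-labels
#' @export
MASK_WALL <- 0L

#' @rdname mask-labels
#' @export
MASK_FLUID <- 1L

#' @rdname mask-labels
#' @export
MASK_INLET <- 2L

#' @rdname mask-labels
#' @export
MASK_OUTLET <- 3L

#' Define a Cartesian grid
#'
#' A grid of `nx * ny * nz` pressure cells with uniform spacing per axis.
#' The origin is the world position of the center of cell (1, 1, 1).
#'
#' @param n integer vector of 3 positive cell counts `(nx, ny, nz)`.
#' @param spacing numeric vector of 3 positive spacings in meters.
#' @param origin numeric 3-vector, meters. Default `c(0, 0, 0)`.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(c(2, 2, 2), rep(1e-3, 3))
#' cell_count(g)  # 8
#' @export
grid_spec <- function(n, spacing, origin = c(0, 0, 0)) {
  n <- as.integer(n)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(n) != 3L || anyNA(n) || any(n < 1L))
    stop("`n` must be 3 positive integer cell counts", call. = FALSE)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
    stop("`spacing` must be 3 positive lengths (meters)", call. = FALSE)
  if (length(origin) != 3L || anyNA(origin))
    stop("`origin` must be a numeric 3-vector", call. = FALSE)
  structure(list(n = n, spacing = spacing, origin = origin),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d cells, spacing %g x %g x %g mm, N = %d\n",
              x$n[1], x$n[2], x$n[3],
              1e3 * x$spacing[1], 1e3 * x$spacing[2], 1e3 * x$spacing[3],
              cell_count(x)))
  invisible(x)
}

#' Total number of pressure cells
#' @param grid a [grid_spec()].
#' @return `nx * ny * nz` as a double (may exceed integer range).
#' @export
cell_count <- function(grid) prod(as.numeric(grid$n))

#' Physical extent of the grid
#' @param grid a [grid_spec()].
#' @return numeric 3-vector, meters.
#' @export
grid_extent <- function(grid) as.numeric(grid$n) * grid$spacing

#' Coordinates of cell centers along one axis
#' @param grid a [grid_spec()].
#' @param axis 1, 2 or 3.
#' @return numeric vector of world coordinates (meters).
#' @export
axis_centers <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$n[axis]) - 1L) * grid$spacing[axis]
}

face_dim <- function(grid, comp) {
  d <- grid$n
  d[match(comp, c("u", "v", "w"))] <- d[match(comp, c("u", "v", "w"))] + 1L
  d
}

#' Lumen mask on a grid
#'
#' Wraps an integer label volume (see [MASK_WALL] and friends) and checks the
#' structural invariants: at least one fluid cell; inlet and outlet cells only
#' on the boundary z-planes; every fluid cell 6-connected to another
#' fluid/inlet/outlet cell (isolated single-cell pores are rejected).
#'
#' @param labels integer array of dim `grid$n` with values 0..3.
#' @param grid a [grid_spec()].
#' @return An object of class `lumen_mask` (the validated label array with the
#'   grid attached as attribute `grid`).
#' @export
lumen_mask <- function(labels, grid) {
  labels <- as.array(labels)
  if (!identical(dim(labels), as.integer(grid$n)))
    stop("mask dimensions do not match the grid", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || any(labels < 0L | labels > 3L))
    stop("mask labels must be integers in 0..3", call. = FALSE)
  if (!any(labels == MASK_FLUID))
    stop("mask contains no FLUID cell", call. = FALSE)
  io <- labels == MASK_INLET | labels == MASK_OUTLET
  if (any(io)) {
    kk <- arrayInd(which(io), dim(labels))[, 3]
    if (!all(kk == 1L | kk == grid$n[3]))
      stop("INLET/OUTLET cells must lie on the boundary z-planes", call. = FALSE)
  }
  open <- labels != MASK_WALL
  nb <- shift_or(open)
  iso <- open & !nb
  if (any(iso))
    stop(sprintf("%d fluid cell(s) have no open 6-neighbor", sum(iso)),
         call. = FALSE)
  structure(labels, class = "lumen_mask", grid = grid)
}

#' Fluid cells away from the staircase wall
#'
#' Logical array marking FLUID cells none of whose in-plane (x, y) 4-neighbors
#' is a WALL cell.  On voxelized curved geometries the wall-adjacent cells
#' carry the O(h) position ambiguity of the staircase boundary, so profile
#' comparisons against smooth-geometry analytic solutions are made on this
#' resolved interior.
#'
#' @param mask a [lumen_mask()].
#' @return logical array of dim `grid$n`.
#' @export
resolved_fluid_cells <- function(mask) {
  m <- unclass(mask)
  d <- dim(m)
  wall <- m == MASK_WALL
  near <- array(FALSE, d)
  near[-1, , ] <- near[-1, , ] | wall[-d[1], , ]
  near[-d[1], , ] <- near[-d[1], , ] | wall[-1, , ]
  near[, -1, ] <- near[, -1, ] | wall[, -d[2], ]
  near[, -d[2], ] <- near[, -d[2], ] | wall[, -1, ]
  m == MASK_FLUID & !near
}

# logical OR of the six 6-neighbours of each voxel (FALSE outside the domain)
shift_or <- function(a) {
  d <- dim(a)
  out <- array(FALSE, d)
  out[-1, , ] <- out[-1, , ] | a[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | a[-1, , ]
  out[, -1, ] <- out[, -1, ] | a[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | a[, -1, ]
  out[, , -1] <- out[, , -1] | a[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | a[, , -1]
  out
}

#' @export
print.lumen_mask <- function(x, ...) {
  cat(sprintf("<lumen_mask> %s cells: %d fluid, %d wall, %d inlet, %d outlet\n",
              paste(dim(x), collapse = " x "),
              sum(x == MASK_FLUID), sum(x == MASK_WALL),
              sum(x == MASK_INLET), sum(x == MASK_OUTLET)))
  invisible(x)
}

#' Fluid properties
#' @param rho density, kg/m^3 (blood ~ 1060; the carotid phantom fluid ~ 1100).
#' @param mu dynamic viscosity, Pa s (blood ~ 0.0032-0.005).
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(rho, mu) {
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho <= 0)
    stop("`rho` must be a positive number", call. = FALSE)
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0)
    stop("`mu` must be a positive number", call. = FALSE)
  structure(list(rho = rho, mu = mu), class = "fluid_properties")
}

#' Staggered (MAC) velocity field
#'
#' Holds the three face-centered component arrays.  Missing components are
#' filled with `value`.
#'
#' @param grid a [grid_spec()].
#' @param u,v,w optional arrays of dims `(nx+1, ny, nz)`, `(nx, ny+1, nz)`,
#'   `(nx, ny, nz+1)`; m/s.
#' @param value fill value for omitted components.
#' @return An object of class `staggered_field` with elements `u`, `v`, `w`.
#' @export
staggered_field <- function(grid, u = NULL, v = NULL, w = NULL, value = 0) {
  mk <- function(a, comp) {
    d <- face_dim(grid, comp)
    if (is.null(a)) return(array(value, d))
    a <- as.array(a)
    if (!identical(dim(a), as.integer(d)))
      stop(sprintf("component %s must have dim (%s)", comp,
                   paste(d, collapse = ", ")), call. = FALSE)
    storage.mode(a) <- "double"
    a
  }
  structure(list(u = mk(u, "u"), v = mk(v, "v"), w = mk(w, "w"),
                 grid = grid),
            class = "staggered_field")
}

#' @export
print.staggered_field <- function(x, ...) {
  cat(sprintf("<staggered_field> on %d x %d x %d cells, max |u,v,w| = %.4g, %.4g, %.4g m/s\n",
              x$grid$n[1], x$grid$n[2], x$grid$n[3],
              max(abs(x$u)), max(abs(x$v)), max(abs(x$w))))
  invisible(x)
}

#' Average staggered velocities to cell centers
#'
#' Each component is the arithmetic mean of its two bounding faces, producing
#' cell-centered volumes directly comparable with PC-MRI voxel data.  The map
#' is linear and reproduces globally-linear fields exactly (midpoint rule).
#'
#' @param field a [staggered_field()].
#' @param grid a [grid_spec()]; defaults to the field's own grid.
#' @return list with arrays `u`, `v`, `w` of dim `grid$n`.
#' @export
stagger_to_centers <- function(field, grid = field$grid) {
  stopifnot(inherits(field, "staggered_field"))
  n <- grid$n
  if (!identical(as.integer(dim(field$u)), as.integer(c(n[1] + 1L, n[2], n[3]))))
    stop("field/grid shape mismatch", call. = FALSE)
  list(
    u = 0.5 * (field$u[-(n[1] + 1L), , , drop = FALSE] + field$u[-1L, , , drop = FALSE]),
    v = 0.5 * (field$v[, -(n[2] + 1L), , drop = FALSE] + field$v[, -1L, , drop = FALSE]),
    w = 0.5 * (field$w[, , -(n[3] + 1L), drop = FALSE] + field$w[, , -1L, drop = FALSE])
  )
}

#' Discrete divergence of a staggered field
#'
#' Net outflow per unit volume of every pressure cell:
#' `(u_e - u_w)/dx + (v_n - v_s)/dy + (w_t - w_b)/dz`, units 1/s.  This is the
#' quantity the solver drives to zero (mass conservation).
#'
#' @inheritParams stagger_to_centers
#' @return array of dim `grid$n`, 1/s.
#' @export
divergence <- function(field, grid = field$grid) {
  stopifnot(inherits(field, "staggered_field"))
  n <- grid$n
  if (!identical(as.integer(dim(field$u)), as.integer(c(n[1] + 1L, n[2], n[3]))))
    stop("field/grid shape mismatch", call. = FALSE)
  h <- grid$spacing
  (field$u[-1L, , , drop = FALSE] - field$u[-(n[1] + 1L), , , drop = FALSE]) / h[1] +
    (field$v[, -1L, , drop = FALSE] - field$v[, -(n[2] + 1L), , drop = FALSE]) / h[2] +
    (field$w[, , -1L, drop = FALSE] - field$w[, , -(n[3] + 1L), drop = FALSE]) / h[3]
}

#' Sparse face-to-center averaging operator
#'
#' Returns the `N x n_faces` sparse matrix `A` with
#' `A %*% as.vector(field[[comp]])` equal to the vectorized cell-centered
#' component from [stagger_to_centers()].  Used to compose the MRI blurring
#' operator with the solver's staggered unknowns.
#'
#' @param grid a [grid_spec()].
#' @param comp one of `"u"`, `"v"`, `"w"`.
#' @return a `dgCMatrix`.
#' @export
face_average_operator <- function(grid, comp) {
  comp <- match.arg(comp, c("u", "v", "w"))
  n <- grid$n
  fd <- face_dim(grid, comp)
  N <- prod(n)
  cells <- seq_len(N)
  ijk <- arrayInd(cells, n)
  ax <- match(comp, c("u", "v", "w"))
  lo <- ijk
  hi <- ijk
  hi[, ax] <- hi[, ax] + 1L
  lin <- function(m) (m[, 3] - 1L) * (fd[1] * fd[2]) + (m[, 2] - 1L) * fd[1] + m[, 1]
  Matrix::sparseMatrix(i = c(cells, cells), j = c(lin(lo), lin(hi)),
                       x = 0.5, dims = c(N, prod(fd)))
}
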