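# Boundary conditions.
#
# A face is a solver unknown ("free") only when both adjacent cells are FLUID.
# Every other face carries a Dirichlet value taken from a `flow_bc` object:
#   * faces touching WALL cells: no-slip (0), or a prescribed wall-tangential
#     velocity (moving lid) stored at the ghost face inside the wall;
#   * faces of INLET/OUTLET cells: the measured/synthetic boundary profile,
#     held constant through the one-cell-thick boundary layer;
#   * transverse links that leave the rectangular box entirely are treated as
#     symmetry planes (zero diffusive flux), so genuinely 2-D problems can be
#     run with a single cell in z.
# Wall-ghost links (both neighbour cells WALL) act at half a cell spacing, so
# their diffusive conductance is doubled during assembly.

#' Face-ownership mask for one velocity component
#'
#' `TRUE` where the face is a solver unknown (both adjacent cells FLUID).
#'
#' @param mask a [lumen_mask()].
#' @param comp `"u"`, `"v"` or `"w"`.
#' @return logical array with the component's face dimensions.
#' @export
free_faces <- function(mask, comp) {
  comp <- match.arg(comp, c("u", "v", "w"))
  grid <- attr(mask, "grid")
  n <- grid$n
  fl <- unclass(mask) == MASK_FLUID
  fd <- face_dim(grid, comp)
  out <- array(FALSE, fd)
  if (comp == "u") {
    if (n[1] >= 2L)
      out[2:n[1], , ] <- fl[-n[1], , , drop = FALSE] & fl[-1, , , drop = FALSE]
  } else if (comp == "v") {
    if (n[2] >= 2L)
      out[, 2:n[2], ] <- fl[, -n[2], , drop = FALSE] & fl[, -1, , drop = FALSE]
  } else {
    if (n[3] >= 2L)
      out[, , 2:n[3]] <- fl[, , -n[3], drop = FALSE] & fl[, , -1, drop = FALSE]
  }
  out
}

#' Dirichlet boundary values for a staggered field
#'
#' Creates a zero-filled container of face-value arrays; fill in inlet/outlet
#' profiles with [set_axial_profiles()] or [bc_from_measurement()], or assign
#' wall-tangential (lid) values directly.
#'
#' @param grid a [grid_spec()].
#' @return object of class `flow_bc` with arrays `u`, `v`, `w`.
#' @export
flow_bc <- function(grid) {
  structure(list(u = array(0, face_dim(grid, "u")),
                 v = array(0, face_dim(grid, "v")),
                 w = array(0, face_dim(grid, "w")),
                 grid = grid),
            class = "flow_bc")
}

#' Set axial inlet/outlet velocity profiles
#'
#' Writes the axial (w) profile onto both z-faces of every INLET cell and, for
#' the outlet, optionally rescales so the outlet volume flux exactly balances
#' the inlet flux (prescribed-velocity boundaries otherwise make the pressure
#' equation incompatible).
#'
#' @param bc a [flow_bc()].
#' @param mask a [lumen_mask()].
#' @param w_in,w_out numeric `(nx, ny)` matrices of axial velocity (m/s) over
#'   the inlet / outlet planes (values outside inlet/outlet cells are ignored).
#'   `w_out` defaults to `w_in`.
#' @param balance rescale outlet flux to match inlet flux exactly (default TRUE).
#' @return the updated `flow_bc`.
#' @export
set_axial_profiles <- function(bc, mask, w_in, w_out = w_in, balance = TRUE) {
  grid <- bc$grid
  n <- grid$n
  m <- unclass(mask)
  inlet_k <- unique(arrayInd(which(m == MASK_INLET), n)[, 3])
  outlet_k <- unique(arrayInd(which(m == MASK_OUTLET), n)[, 3])
  if (length(inlet_k) != 1L || length(outlet_k) != 1L)
    stop("expected a single inlet plane and a single outlet plane", call. = FALSE)
  w_in <- as.matrix(w_in); w_out <- as.matrix(w_out)
  sel_in <- m[, , inlet_k] == MASK_INLET
  sel_out <- m[, , outlet_k] == MASK_OUTLET
  flux_in <- sum(w_in[sel_in])
  flux_out <- sum(w_out[sel_out])
  if (balance && flux_in != 0) {
    if (flux_out == 0) stop("cannot balance a zero outlet flux against a nonzero inlet",
                            call. = FALSE)
    w_out <- w_out * (flux_in / flux_out)
  }
  put <- function(k, prof, sel) {
    sl1 <- bc$w[, , k]; sl2 <- bc$w[, , k + 1L]
    sl1[sel] <- prof[sel]; sl2[sel] <- prof[sel]
    bc$w[, , k] <<- sl1; bc$w[, , k + 1L] <<- sl2
  }
  put(inlet_k, w_in, sel_in)
  put(outlet_k, w_out, sel_out)
  bc
}

#' Derive boundary conditions from an MRI measurement
#'
#' Uses all three measured velocity components on the boundary z-planes as the
#' inlet/outlet conditions: the axial component through [set_axial_profiles()]
#' (flux-balanced), and the in-plane components on the lateral faces of the
#' boundary layers.
#'
#' @param mask a [lumen_mask()].
#' @param meas an [mri_measurement()] on the same grid.
#' @param balance passed to [set_axial_profiles()].
#' @return a `flow_bc`.
#' @export
bc_from_measurement <- function(mask, meas, balance = TRUE) {
  grid <- attr(mask, "grid")
  n <- grid$n
  if (!identical(dim(meas$w), as.integer(n)))
    stop("measurement grid must match the mask grid for boundary extraction",
         call. = FALSE)
  m <- unclass(mask)
  bc <- flow_bc(grid)
  bc <- set_axial_profiles(bc, mask, w_in = meas$w[, , 1], w_out = meas$w[, , n[3]],
                           balance = balance)
  # in-plane components on faces interior to the inlet/outlet layers
  io <- m == MASK_INLET | m == MASK_OUTLET
  both_u <- io[-n[1], , , drop = FALSE] & io[-1, , , drop = FALSE]
  cu <- 0.5 * (meas$u[-n[1], , , drop = FALSE] + meas$u[-1, , , drop = FALSE])
  tmp <- bc$u[2:n[1], , , drop = FALSE]; tmp[both_u] <- cu[both_u]
  bc$u[2:n[1], , ] <- tmp
  both_v <- io[, -n[2], , drop = FALSE] & io[, -1, , drop = FALSE]
  cv <- 0.5 * (meas$v[, -n[2], , drop = FALSE] + meas$v[, -1, , drop = FALSE])
  tmp <- bc$v[, 2:n[2], , drop = FALSE]; tmp[both_v] <- cv[both_v]
  bc$v[, 2:n[2], ] <- tmp
  bc
}

#' Write Dirichlet values into a staggered field
#'
#' Overwrites every non-free face of `state` with its boundary value, leaving
#' solver unknowns untouched.  The solver maintains this invariant after every
#' iteration, so fixed faces can always be read directly off the state.
#'
#' @param state a [staggered_field()].
#' @param mask a [lumen_mask()].
#' @param bc a [flow_bc()].
#' @return the updated field.
#' @export
enforce_bc <- function(state, mask, bc) {
  for (comp in c("u", "v", "w")) {
    fixed <- !free_faces(mask, comp)
    state[[comp]][fixed] <- bc[[comp]][fixed]
  }
  state
}

#' Volume flux through the inlet plane
#' @param state a [staggered_field()] with boundary values enforced.
#' @param mask a [lumen_mask()].
#' @return list with `inlet` and `outlet` volumetric fluxes (m^3/s, positive
#'   along +z).
#' @export
boundary_fluxes <- function(state, mask) {
  grid <- attr(mask, "grid")
  n <- grid$n
  m <- unclass(mask)
  A <- grid$spacing[1] * grid$spacing[2]
  sel_in <- m[, , 1] == MASK_INLET
  sel_out <- m[, , n[3]] == MASK_OUTLET
  list(inlet = sum(state$w[, , 1][sel_in]) * A,
       outlet = sum(state$w[, , n[3] + 1L][sel_out]) * A)
}
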