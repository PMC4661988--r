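# Synthetic ground-truth flows and PC-MRI measurement emulation.
#
# The measurement chain mirrors the physics of a 3DFT phase-contrast
# acquisition: true field -> truncated-sinc blur -> resampling onto the MRI
# grid -> i.i.d. zero-mean Gaussian velocity noise per component -> optional
# VENC phase wrapping -> optional residual linear (eddy-current) offset.
# Convolution uses zero padding: velocities vanish outside the lumen, so the
# zero extension is the physically correct boundary model.

#' PC-MRI noise / encoding model
#'
#' @param sigma standard deviation of the additive velocity noise, m/s
#'   per component (a typical noise study uses 0.08 m/s = 8 cm/s).
#' @param seed integer RNG seed; identical models give identical measurements.
#' @param venc velocity-encoding limit, m/s (velocities beyond +-VENC alias);
#'   `Inf` disables wrapping.
#' @param offset optional list with per-component linear offset coefficients
#'   `(a, b, c, d)`: the plane `a x + b y + c z + d` (m/s, coordinates in
#'   meters) added to that component, emulating eddy-current residuals.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(sigma = 0, seed = 1L, venc = Inf, offset = NULL) {
  if (!is.numeric(sigma) || sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (!is.numeric(venc) || venc <= 0) stop("`venc` must be > 0", call. = FALSE)
  if (!is.null(offset)) {
    stopifnot(is.list(offset), all(names(offset) %in% c("u", "v", "w")))
    for (cc in names(offset)) stopifnot(length(offset[[cc]]) == 4L)
  }
  structure(list(sigma = sigma, seed = as.integer(seed), venc = venc,
                 offset = offset),
            class = "noise_model")
}

#' Cell-centered PC-MRI velocity measurement
#'
#' @param u,v,w cell-centered component arrays, m/s, common dims.
#' @param grid the [grid_spec()] the voxels live on.
#' @param venc velocity-encoding limit, m/s.
#' @param sigma noise standard deviation the volumes carry, m/s (metadata).
#' @param seed RNG seed used (metadata).
#' @param static_mask optional logical array marking stationary-tissue voxels.
#' @return object of class `mri_measurement`.
#' @export
mri_measurement <- function(u, v, w, grid, venc = Inf, sigma = NA_real_,
                            seed = NA_integer_, static_mask = NULL) {
  u <- as.array(u); v <- as.array(v); w <- as.array(w)
  if (!identical(dim(u), dim(v)) || !identical(dim(u), dim(w)))
    stop("components must share a shape", call. = FALSE)
  if (!identical(dim(u), as.integer(grid$n)))
    stop("component shape does not match the grid", call. = FALSE)
  structure(list(u = u, v = v, w = w, grid = grid, venc = venc,
                 sigma = sigma, seed = seed, static_mask = static_mask),
            class = "mri_measurement")
}

#' @export
print.mri_measurement <- function(x, ...) {
  cat(sprintf("<mri_measurement> %s voxels, VENC %s m/s, sigma %s m/s\n",
              paste(dim(x$u), collapse = " x "),
              format(x$venc), format(x$sigma)))
  invisible(x)
}

#' Synthetic Poiseuille pipe phantom
#'
#' A straight circular pipe along z with the analytic Hagen-Poiseuille
#' profile `w(r) = w_max (1 - r^2/R^2)` sampled at face centers; `u = v = 0`.
#' The mask has a one-cell inlet layer at `k = 1` and outlet layer at
#' `k = nz`, wall cells elsewhere outside the lumen.
#'
#' @param grid a [grid_spec()]; the lumen axis runs through the domain center.
#' @param radius pipe radius, m.
#' @param w_max peak (centerline) velocity, m/s.
#' @param blunt profile bluntness exponent: the axial profile is
#'   `w_max (1 - (r/R)^blunt)`.  `2` is the steady parabola; larger values
#'   give the flattened profiles seen at peak systole in pulsatile flow.
#' @return list with `mask` ([lumen_mask()]), `truth` ([staggered_field()]),
#'   and `bc` ([flow_bc()]) carrying the inlet/outlet profiles.
#' @export
generate_poiseuille <- function(grid, radius, w_max, blunt = 2) {
  n <- grid$n
  h <- grid$spacing
  cx <- grid$origin[1] + (n[1] - 1) * h[1] / 2
  cy <- grid$origin[2] + (n[2] - 1) * h[2] / 2
  if (radius > min(n[1] * h[1], n[2] * h[2]) / 2)
    stop("pipe exceeds the grid cross-section", call. = FALSE)
  xc <- axis_centers(grid, 1); yc <- axis_centers(grid, 2)
  r2c <- outer((xc - cx)^2, (yc - cy)^2, "+")
  lumen2d <- r2c < radius^2
  labels <- array(MASK_WALL, n)
  for (k in seq_len(n[3])) labels[, , k][lumen2d] <- MASK_FLUID
  labels[, , 1][lumen2d] <- MASK_INLET
  labels[, , n[3]][lumen2d] <- MASK_OUTLET
  mask <- lumen_mask(labels, grid)

  prof <- function(r2) {
    val <- w_max * (1 - (sqrt(r2) / radius)^blunt)
    val[r2 >= radius^2] <- 0
    val
  }
  wprof <- prof(r2c)
  truth <- staggered_field(grid)
  for (k in seq_len(n[3] + 1L)) truth$w[, , k] <- wprof
  bc <- flow_bc(grid)
  bc <- set_axial_profiles(bc, mask, w_in = wprof, w_out = wprof,
                           balance = FALSE)
  list(mask = mask, truth = truth, bc = bc)
}

#' Synthetic planar bifurcation phantom
#'
#' A voxelized Y-geometry: a parent vessel along z that splits into two
#' daughter branches whose centerlines separate linearly in x beyond the
#' bifurcation plane.  The inlet profile is parabolic, scaled to the
#' requested peak velocity.
#'
#' @param grid a [grid_spec()].
#' @param r_parent,r_branch parent/daughter radii, m.
#' @param w_max peak inlet velocity, m/s.
#' @param split_frac fraction of the domain length at which the vessel
#'   splits (default 0.45).
#' @param spread_angle half-angle between the branch centerlines, radians.
#' @return list with `mask`, `bc`, and the inlet profile matrix `w_in`.
#' @export
generate_bifurcation <- function(grid, r_parent, r_branch, w_max,
                                 split_frac = 0.45, spread_angle = 0.25) {
  n <- grid$n
  h <- grid$spacing
  cx <- grid$origin[1] + (n[1] - 1) * h[1] / 2
  cy <- grid$origin[2] + (n[2] - 1) * h[2] / 2
  xc <- axis_centers(grid, 1); yc <- axis_centers(grid, 2)
  zc <- axis_centers(grid, 3)
  zsplit <- grid$origin[3] + split_frac * (n[3] - 1) * h[3]
  labels <- array(MASK_WALL, n)
  for (k in seq_len(n[3])) {
    if (zc[k] <= zsplit) {
      r2 <- outer((xc - cx)^2, (yc - cy)^2, "+")
      labels[, , k][r2 < r_parent^2] <- MASK_FLUID
    } else {
      dxc <- (zc[k] - zsplit) * tan(spread_angle)
      r2a <- outer((xc - (cx - dxc))^2, (yc - cy)^2, "+")
      r2b <- outer((xc - (cx + dxc))^2, (yc - cy)^2, "+")
      labels[, , k][r2a < r_branch^2 | r2b < r_branch^2] <- MASK_FLUID
    }
  }
  op <- labels[, , n[3]] == MASK_FLUID
  if (!any(op)) stop("branches left the domain before the outlet plane",
                     call. = FALSE)
  labels[, , 1][labels[, , 1] == MASK_FLUID] <- MASK_INLET
  labels[, , n[3]][op] <- MASK_OUTLET
  mask <- lumen_mask(labels, grid)
  r2 <- outer((xc - cx)^2, (yc - cy)^2, "+")
  w_in <- w_max * pmax(1 - r2 / r_parent^2, 0)
  bc <- flow_bc(grid)
  bc <- set_axial_profiles(bc, mask, w_in = w_in, w_out = w_in, balance = FALSE)
  # crude outlet guess: plug over the outlet cells, flux-balanced
  A <- h[1] * h[2]
  flux_in <- sum(w_in[unclass(mask)[, , 1] == MASK_INLET]) * A
  w_out <- matrix(0, n[1], n[2])
  w_out[op] <- flux_in / (sum(op) * A)
  bc <- set_axial_profiles(bc, mask, w_in = w_in, w_out = w_out, balance = TRUE)
  list(mask = mask, bc = bc, w_in = w_in)
}

#' Lid-driven cavity benchmark setup
#'
#' The classical 2-D validation case: a unit square of fluid, no-slip walls,
#' and a lid sliding in +x along the top (y = L) boundary.  Implemented as a
#' single-cell-thick 3-D slab (the spanwise direction is a symmetry plane)
#' with explicit wall-cell layers carrying the lid velocity as a
#' wall-tangential ghost value.
#'
#' @param n_cells interior cells per side.
#' @param L cavity side length, m.
#' @param U_lid lid speed, m/s.
#' @return list with `grid`, `mask`, `bc`.
#' @export
generate_cavity <- function(n_cells, L = 1, U_lid = 1) {
  h <- L / n_cells
  n <- c(n_cells + 2L, n_cells + 2L, 1L)
  grid <- grid_spec(n, c(h, h, L))
  labels <- array(MASK_WALL, n)
  labels[2:(n_cells + 1L), 2:(n_cells + 1L), 1] <- MASK_FLUID
  mask <- lumen_mask(labels, grid)
  bc <- flow_bc(grid)
  # lid: u ghost faces inside the top wall row (tangential Dirichlet)
  bc$u[, n_cells + 2L, 1] <- U_lid
  list(grid = grid, mask = mask, bc = bc)
}

# separable zero-padded convolution of a 3-D array with per-axis kernels
convolve_separable <- function(a, kernels) {
  d <- dim(a)
  for (ax in 1:3) {
    kw <- kernels[[ax]]
    kl <- length(kw)
    if (kl == 1L) { a <- a * kw; next }
    half <- (kl - 1L) %/% 2L
    out <- array(0, d)
    for (t in seq_len(kl)) {
      s <- t - half - 1L          # source shift along ax
      wgt <- kw[t]
      if (wgt == 0) next
      n_ax <- d[ax]
      src_lo <- max(1L, 1L - s); src_hi <- min(n_ax, n_ax - s)
      if (src_lo > src_hi) next
      dst <- src_lo:src_hi
      src <- dst + s
      if (ax == 1) out[dst, , ] <- out[dst, , ] + wgt * a[src, , ]
      else if (ax == 2) out[, dst, ] <- out[, dst, ] + wgt * a[, src, ]
      else out[, , dst] <- out[, , dst] + wgt * a[, , src]
    }
    a <- out
  }
  a
}

wrap_to_venc <- function(x, venc) {
  if (!is.finite(venc)) return(x)
  ((x + venc) %% (2 * venc)) - venc
}

#' Simulate a PC-MRI measurement of a velocity field
#'
#' Applies the full measurement chain to a ground-truth staggered field:
#' face-to-center averaging, truncated-sinc blur (normalized to unit DC
#' gain), sampling onto the MRI grid, seeded Gaussian noise, optional VENC
#' wrapping, optional linear offsets.  All parameters are recorded on the
#' result for provenance.
#'
#' @param truth a [staggered_field()] on `cfd_grid`.
#' @param cfd_grid,mri_grid [grid_spec()]s; the MRI grid must coincide with
#'   the CFD grid or be a coarser grid covered by it.
#' @param psf a [build_psf()] kernel (its blur is skipped when `NULL`,
#'   modeling an idealized measurement).
#' @param noise a [noise_model()].
#' @return an [mri_measurement()] on `mri_grid`.
#' @export
simulate_pcmri <- function(truth, cfd_grid, mri_grid = cfd_grid, psf = NULL,
                           noise = noise_model()) {
  centers <- stagger_to_centers(truth, cfd_grid)
  same <- identical(cfd_grid$n, mri_grid$n) &&
    isTRUE(all.equal(cfd_grid$spacing, mri_grid$spacing))
  if (!same) {
    ratio <- mri_grid$spacing / cfd_grid$spacing
    if (any(abs(ratio - round(ratio)) > 1e-9))
      stop("MRI spacing must be an integer multiple of the CFD spacing",
           call. = FALSE)
  }
  out <- list()
  set.seed(noise$seed)
  # offsets are evaluated at MRI voxel world coordinates
  xs <- axis_centers(mri_grid, 1); ys <- axis_centers(mri_grid, 2)
  zs <- axis_centers(mri_grid, 3)
  for (comp in c("u", "v", "w")) {
    vol <- centers[[comp]]
    if (!is.null(psf)) {
      kern <- lapply(psf$axes, function(a) a$weights / sum(a$weights))
      vol <- convolve_separable(vol, kern)
    }
    if (!same) {
      r <- as.integer(round(mri_grid$spacing / cfd_grid$spacing))
      n_mri <- mri_grid$n
      if (!identical(as.integer(r * n_mri), as.integer(cfd_grid$n)))
        stop("CFD cell counts must be integer multiples of the MRI counts",
             call. = FALSE)
      # box-average the block of CFD cells inside each MRI voxel
      dim(vol) <- c(r[1], n_mri[1], r[2], n_mri[2], r[3], n_mri[3])
      vol <- apply(vol, c(2L, 4L, 6L), mean)
    }
    if (noise$sigma > 0)
      vol <- vol + array(stats::rnorm(length(vol), 0, noise$sigma), dim(vol))
    if (!is.null(noise$offset) && !is.null(noise$offset[[comp]])) {
      co <- noise$offset[[comp]]
      for (k in seq_along(zs)) {
        vol[, , k] <- vol[, , k] +
          outer(co[1] * xs, co[2] * ys, "+") + co[3] * zs[k] + co[4]
      }
    }
    vol <- wrap_to_venc(vol, noise$venc)
    out[[comp]] <- vol
  }
  mri_measurement(out$u, out$v, out$w, mri_grid, venc = noise$venc,
                  sigma = noise$sigma, seed = noise$seed)
}

#' Unwrap aliased velocities
#'
#' Adds one full velocity-encoding period (2 VENC, the velocity image of a
#' 2 pi phase correction) to the flagged voxels of each listed component.
#'
#' @param meas an [mri_measurement()] with finite VENC.
#' @param flagged list with integer (linear) or logical index vectors per
#'   component (`u`, `v`, `w`); omitted components are untouched.
#' @return the corrected measurement.
#' @export
unwrap_velocity <- function(meas, flagged) {
  if (!is.finite(meas$venc))
    stop("measurement has no finite VENC; nothing to unwrap", call. = FALSE)
  for (comp in names(flagged)) {
    idx <- flagged[[comp]]
    if (is.logical(idx)) idx <- which(idx)
    if (length(idx) == 0) next
    if (any(idx < 1L | idx > length(meas[[comp]])))
      stop("flagged voxel index out of range", call. = FALSE)
    meas[[comp]][idx] <- meas[[comp]][idx] + 2 * meas$venc
  }
  meas
}

#' Remove residual linear velocity offsets
#'
#' Fits `a x + b y + c z + d` (least squares) to each component over the
#' stationary-tissue voxels and subtracts the fitted plane from the whole
#' volume, emulating the standard eddy-current correction.
#'
#' @param meas an [mri_measurement()].
#' @param static_mask logical array of stationary-tissue voxels (defaults to
#'   the measurement's own `static_mask`).
#' @return list with the corrected measurement (`meas`) and the fitted
#'   coefficient table (`coef`, one `(a, b, c, d)` row per component).
#' @export
remove_linear_offset <- function(meas, static_mask = meas$static_mask) {
  if (is.null(static_mask)) stop("no static-tissue mask available", call. = FALSE)
  idx <- which(static_mask)
  if (length(idx) < 4L)
    stop("static region must contain at least 4 voxels", call. = FALSE)
  g <- meas$grid
  ijk <- arrayInd(idx, g$n)
  X <- cbind(x = axis_centers(g, 1)[ijk[, 1]],
             y = axis_centers(g, 2)[ijk[, 2]],
             z = axis_centers(g, 3)[ijk[, 3]])
  # degenerate (coplanar) static regions make the design rank deficient
  if (qr(cbind(X, 1))$rank < 4L)
    stop("static region is degenerate (coplanar voxels)", call. = FALSE)
  xs <- axis_centers(g, 1); ys <- axis_centers(g, 2); zs <- axis_centers(g, 3)
  coef <- matrix(NA_real_, 3, 4,
                 dimnames = list(c("u", "v", "w"), c("a", "b", "c", "d")))
  for (comp in c("u", "v", "w")) {
    fit <- stats::lm.fit(cbind(X, 1), meas[[comp]][idx])
    co <- fit$coefficients
    coef[comp, ] <- co
    for (k in seq_along(zs))
      meas[[comp]][, , k] <- meas[[comp]][, , k] -
        (outer(co[1] * xs, co[2] * ys, "+") + co[3] * zs[k] + co[4])
  }
  list(meas = meas, coef = coef)
}
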