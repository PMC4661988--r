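# Volume and configuration I/O.
#
# Masks and velocity volumes travel as NIfTI (spacing in the header; velocity
# in cm/s at the file boundary, SI internally); fields can additionally be
# exported as legacy-ASCII VTK structured points for visualization.  Run
# configuration uses YAML with full defaulting.

CM_PER_M <- 100

#' Read / write a lumen mask as NIfTI
#'
#' Labels: 0 = WALL, 1 = FLUID, 2 = INLET, 3 = OUTLET.  Spacing is taken
#' from (written to) the header in millimeters, converted to meters.
#'
#' @param mask a [lumen_mask()].
#' @param path `.nii` / `.nii.gz` path.
#' @return `read_mask_nifti` returns a [lumen_mask()].
#' @export
write_mask_nifti <- function(mask, path) {
  grid <- attr(mask, "grid")
  img <- RNifti::asNifti(unclass(mask) * 1.0)
  RNifti::pixdim(img) <- grid$spacing * 1e3
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_mask_nifti
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3] * 1e-3
  a <- round(as.array(img))
  grid <- grid_spec(dim(a), sp)
  lumen_mask(array(as.integer(a), dim(a)), grid)
}

#' Read / write cell-centered velocity volumes as NIfTI
#'
#' One 4-D file with the three components stacked along the fourth dimension,
#' stored in cm/s; a JSON sidecar carries VENC, noise sigma, and seed.
#'
#' @param meas an [mri_measurement()].
#' @param path `.nii` / `.nii.gz` path; the sidecar is `<path>.json`.
#' @return `read_velocity_nifti` returns an [mri_measurement()].
#' @export
write_velocity_nifti <- function(meas, path) {
  grid <- meas$grid
  vol4 <- array(0, c(grid$n, 3L))
  vol4[, , , 1] <- meas$u * CM_PER_M
  vol4[, , , 2] <- meas$v * CM_PER_M
  vol4[, , , 3] <- meas$w * CM_PER_M
  img <- RNifti::asNifti(vol4)
  RNifti::pixdim(img) <- c(grid$spacing * 1e3, 1)
  RNifti::writeNifti(img, path)
  meta <- list(venc_cm_s = if (is.finite(meas$venc)) meas$venc * CM_PER_M else "Inf",
               sigma_cm_s = if (is.na(meas$sigma)) "NA" else meas$sigma * CM_PER_M,
               seed = if (is.na(meas$seed)) "NA" else meas$seed,
               spacing_mm = grid$spacing * 1e3,
               units = "cm/s", components = c("u", "v", "w"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_mask_nifti
#' @export
read_velocity_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 4L || dim(a)[4] != 3L)
    stop("expected a 4-D volume with 3 components", call. = FALSE)
  sp <- RNifti::pixdim(img)[1:3] * 1e-3
  grid <- grid_spec(dim(a)[1:3], sp)
  meta_path <- paste0(path, ".json")
  venc <- Inf; sigma <- NA_real_; seed <- NA_integer_
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!identical(meta$venc_cm_s, "Inf")) venc <- as.numeric(meta$venc_cm_s) / CM_PER_M
    if (!identical(meta$sigma_cm_s, "NA")) sigma <- as.numeric(meta$sigma_cm_s) / CM_PER_M
    if (!identical(meta$seed, "NA")) seed <- as.integer(meta$seed)
  }
  mri_measurement(a[, , , 1] / CM_PER_M, a[, , , 2] / CM_PER_M,
                  a[, , , 3] / CM_PER_M, grid, venc = venc, sigma = sigma,
                  seed = seed)
}

#' Export a velocity field as legacy-ASCII VTK structured points
#'
#' Cell-centered vectors (m/s) for ParaView-style visualization.
#'
#' @param centers list of arrays `u`, `v`, `w` (see [stagger_to_centers()]).
#' @param grid a [grid_spec()].
#' @param path `.vtk` path.
#' @param name data-array name.
#' @export
write_velocity_vtk <- function(centers, grid, path, name = "velocity") {
  n <- grid$n
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "velocity field", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", n[1], n[2], n[3]),
               sprintf("ORIGIN %g %g %g", grid$origin[1], grid$origin[2],
                       grid$origin[3]),
               sprintf("SPACING %g %g %g", grid$spacing[1], grid$spacing[2],
                       grid$spacing[3]),
               sprintf("POINT_DATA %d", prod(n)),
               sprintf("VECTORS %s double", name)), con)
  m <- cbind(as.vector(centers$u), as.vector(centers$v), as.vector(centers$w))
  writeLines(sprintf("%.10g %.10g %.10g", m[, 1], m[, 2], m[, 3]), con)
  invisible(path)
}

#' Load an experiment configuration from YAML
#'
#' Reads a key/value config and merges it over the package defaults (fluid
#' properties, solver settings, lambda weights, noise model, paths).  The
#' merged configuration is returned with the full provenance echo attached.
#'
#' @param path YAML file; `NULL` returns pure defaults.
#' @param overrides named list applied on top of the file.
#' @return a nested list of class `experiment_config_raw`.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    fluid = list(rho = 1100, mu = 0.005),
    solver = list(dt = 1e-3, eps = 1e-3, div_tol = 1e-4, max_outer = 500,
                  max_inner = 30, lin_tol = 1e-8, relax_u = 0.7,
                  relax_p = 0.3),
    lambda = list(u = 0, v = 0, w = 0),
    noise = list(sigma_cm_s = 0, venc_cm_s = "Inf", seed = 1),
    mode = "pure_cfd",
    paths = list()
  )
  cfg <- defaults
  if (!is.null(path)) cfg <- modify_list_deep(cfg, yaml::read_yaml(path))
  cfg <- modify_list_deep(cfg, overrides)
  structure(cfg, class = "experiment_config_raw")
}

modify_list_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    else base[[nm]] <- new[[nm]]
  }
  base
}
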