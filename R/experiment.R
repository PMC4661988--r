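# Experiment orchestration: the three solver modes, measurement-guided runs,
# and the denoising lambda sweep.
#
# Modes follow the comparison design used throughout: "pure_cfd" uses the
# measurements only as inlet/outlet boundary data (all lambda = 0);
# "cfd_1d" additionally penalizes disagreement of the axial component w with
# its measurement (lambda_w > 0, lambda_u = lambda_v = 0); "cfd_3d"
# penalizes all three components.

#' Experiment configuration
#'
#' Validates the mode/lambda consistency rules: `pure_cfd` forces all weights
#' to zero and `cfd_1d` zeroes the in-plane weights.
#'
#' @param mode `"pure_cfd"`, `"cfd_1d"` or `"cfd_3d"`.
#' @param lambda numeric length-3 vector `(lambda_u, lambda_v, lambda_w)`; a
#'   single number is applied to whatever components the mode penalizes.
#' @param solver a [solver_config()].
#' @param fluid a [fluid_properties()].
#' @param noise optional [noise_model()] for synthetic runs.
#' @param seed integer master seed.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(mode = c("pure_cfd", "cfd_1d", "cfd_3d"),
                              lambda = 1, solver = solver_config(),
                              fluid = fluid_properties(1100, 0.005),
                              noise = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (length(lambda) == 1L) lambda <- rep(lambda, 3L)
  stopifnot(length(lambda) == 3L, all(lambda >= 0))
  lambda <- switch(mode,
    pure_cfd = c(0, 0, 0),
    cfd_1d = c(0, 0, lambda[3]),
    cfd_3d = lambda)
  if (mode != "pure_cfd" && all(lambda == 0))
    stop(sprintf("mode %s needs a positive lambda", mode), call. = FALSE)
  structure(list(mode = mode, lambda = lambda, solver = solver,
                 fluid = fluid, noise = noise, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run one measurement-guided steady-state solve
#'
#' Builds boundary conditions from the measurement's boundary z-planes,
#' assembles the blurring operator (identity when the grids coincide), runs
#' [run_steady_state()] in the configured mode, and reports SER against the
#' measurement over the lumen.
#'
#' @param mask a [lumen_mask()].
#' @param meas an [mri_measurement()] (constraint + boundary data).
#' @param config an [experiment_config()].
#' @param mri_grid grid of the measurement (defaults to the mask's grid; when
#'   different, the truncated-sinc operator couples the two).
#' @param initial optional initial [staggered_field()].
#' @return list with the [run_steady_state()] `result`, the `ser` report
#'   vs the measurement, the cell-centered `centers`, and the `config`.
#' @export
run_experiment <- function(mask, meas, config, mri_grid = NULL,
                           initial = NULL) {
  grid <- attr(mask, "grid")
  if (is.null(mri_grid)) mri_grid <- meas$grid
  bc <- bc_from_measurement(mask, meas)
  lam <- config$lambda
  reg <- NULL
  if (any(lam > 0)) {
    same <- identical(grid$n, mri_grid$n) &&
      isTRUE(all.equal(grid$spacing, mri_grid$spacing))
    psf <- build_psf(mri_grid$spacing, grid$spacing)
    op <- build_gamma(psf, grid, mri_grid, identity = same,
                      lambda_u = lam[1], lambda_v = lam[2], lambda_w = lam[3])
    rows <- NULL
    if (same) {
      lum <- which(unclass(mask) == MASK_FLUID)
      rows <- list(u = lum, v = lum, w = lum)
    }
    reg <- attach_measurement(op, meas, rows = rows)
  }
  if (is.null(initial)) initial <- initial_plug_field(grid, mask, bc)
  result <- run_steady_state(initial, bc, config$fluid, grid, mask,
                             config$solver, reg = reg)
  centers <- stagger_to_centers(result$state, grid)
  rep <- if (identical(grid$n, meas$grid$n))
    ser(centers, meas, mask) else NULL
  list(result = result, ser = rep, centers = centers, config = config)
}

#' Compare the three solver modes on one dataset
#'
#' Runs `pure_cfd`, `cfd_1d` and `cfd_3d` on the same mask/measurement and
#' returns the per-mode results with an SER comparison table and the outer
#' pseudo-time-step counts (measurement-guided runs converge in fewer steps).
#'
#' @inheritParams run_experiment
#' @param lambda weight(s) used by the guided modes (default 1, the
#'   equal-resolution working value).
#' @param solver,fluid see [experiment_config()].
#' @return list with `runs` (per mode), `table` (SER), `outer_steps`.
#' @export
compare_modes <- function(mask, meas, lambda = 1,
                          solver = solver_config(),
                          fluid = fluid_properties(1100, 0.005)) {
  modes <- c("pure_cfd", "cfd_1d", "cfd_3d")
  runs <- lapply(modes, function(md) {
    cfg <- experiment_config(md, lambda = lambda, solver = solver,
                             fluid = fluid)
    run_experiment(mask, meas, cfg)
  })
  names(runs) <- modes
  list(runs = runs,
       table = ser_table(lapply(runs, `[[`, "ser")),
       outer_steps = vapply(runs, function(r) r$result$outer_steps, numeric(1)))
}

#' Denoising lambda sweep
#'
#' For each weight in `lambdas` (zero included by passing it explicitly) the
#' all-component guided solve is run against the noisy measurement, and SER is
#' computed both against the clean reference (`truth_centers`) and against the
#' noisy input.  Mirrors the classic Tikhonov trade-off: an interior lambda
#' recovers more of the truth than either the flow model alone or the noisy
#' data alone.
#'
#' @param mask a [lumen_mask()].
#' @param noisy an [mri_measurement()] with added noise.
#' @param truth_centers list of clean cell-centered arrays `u`, `v`, `w`.
#' @param lambdas numeric vector of weights (0 allowed).
#' @param solver,fluid see [experiment_config()].
#' @return data.frame with one row per lambda: outer steps, converged flag,
#'   `ser_truth` (total dB vs truth), `ser_noisy` (vs noisy input); plus the
#'   reference row attributes `ser_noisy_vs_truth`.
#' @export
denoise_sweep <- function(mask, noisy, truth_centers, lambdas,
                          solver = solver_config(),
                          fluid = fluid_properties(1100, 0.005)) {
  grid <- attr(mask, "grid")
  rows <- lapply(lambdas, function(lam) {
    cfg <- if (lam == 0)
      experiment_config("pure_cfd", solver = solver, fluid = fluid)
    else
      experiment_config("cfd_3d", lambda = lam, solver = solver, fluid = fluid)
    run <- run_experiment(mask, noisy, cfg)
    st <- ser(run$centers, truth_centers, mask)
    sn <- ser(run$centers, noisy, mask)
    data.frame(lambda = lam, outer_steps = run$result$outer_steps,
               converged = run$result$converged,
               ser_truth = st$ser_total, ser_noisy = sn$ser_total)
  })
  out <- do.call(rbind, rows)
  input_rep <- ser(noisy, truth_centers, mask)
  attr(out, "ser_noisy_vs_truth") <- input_rep$ser_total
  out
}
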