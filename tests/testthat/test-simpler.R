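props_blood <- fluid_properties(1100, 0.005)

test_that("zero inflow converges immediately to the zero field", {
  g <- grid_spec(c(6, 6, 8), rep(1e-3, 3))
  mask <- duct_mask(g)
  bc <- set_axial_profiles(flow_bc(g), mask, matrix(0, 6, 6))
  cfg <- solver_config(dt = 0.01, eps = 1e-6, div_tol = 1e-8, max_outer = 5)
  res <- run_steady_state(staggered_field(g), bc, props_blood, g, mask, cfg)
  expect_true(res$converged)
  expect_identical(res$outer_steps, 1L)
  expect_equal(max(abs(res$state$w)), 0, tolerance = 1e-12)
})

test_that("a converged state is a fixed point of the solver", {
  g <- grid_spec(c(8, 8, 12), c(1e-3, 1e-3, 1e-3))
  ph <- generate_poiseuille(g, radius = 3.2e-3, w_max = 0.1)
  cfg <- solver_config(dt = 0.05, eps = 1e-5, div_tol = 1e-4, max_outer = 500)
  res <- run_steady_state(initial_plug_field(g, ph$mask, ph$bc), ph$bc,
                          props_blood, g, ph$mask, cfg)
  expect_true(res$converged)
  # restart from the converged state (and its pressure): one step, no drift
  cfg2 <- solver_config(dt = 0.05, eps = 5e-4, div_tol = 1e-4, max_outer = 500)
  res2 <- run_steady_state(res$state, ph$bc, props_blood, g, ph$mask, cfg2,
                           pressure0 = res$pressure)
  expect_true(res2$converged)
  expect_identical(res2$outer_steps, 1L)
  expect_lt(max(abs(res2$state$w - res$state$w)), 1e-5)
})

test_that("converged flow conserves mass between inlet and outlet", {
  g <- grid_spec(c(8, 8, 12), c(1e-3, 1e-3, 1e-3))
  ph <- generate_poiseuille(g, radius = 3.2e-3, w_max = 0.1)
  cfg <- solver_config(dt = 0.05, eps = 5e-4, div_tol = 1e-5, max_outer = 300)
  res <- run_steady_state(initial_plug_field(g, ph$mask, ph$bc), ph$bc,
                          props_blood, g, ph$mask, cfg)
  expect_true(res$converged)
  fl <- boundary_fluxes(res$state, ph$mask)
  domain_vol <- prod(grid_extent(g))
  expect_lt(abs(fl$inlet - fl$outlet), cfg$div_tol * domain_vol)
  # continuity contract over FLUID cells
  expect_lte(divergence_stats(res$state, g, ph$mask)$max, cfg$div_tol)
})

test_that("continuity residual is reduced within each pseudo-time step", {
  g <- grid_spec(c(8, 8, 12), c(1e-3, 1e-3, 1e-3))
  ph <- generate_poiseuille(g, radius = 3.2e-3, w_max = 0.1)
  cfg <- solver_config(dt = 0.05, div_tol = 1e-5)
  state <- enforce_bc(initial_plug_field(g, ph$mask, ph$bc), ph$mask, ph$bc)
  div0 <- divergence_stats(state, g, ph$mask)$max
  it <- simpler_iteration(state, array(0, g$n), props_blood, g, ph$mask, cfg)
  expect_lt(it$div_max, div0)
  expect_lt(it$div_max, cfg$div_tol)
})

test_that("vanishing regularization reproduces the plain SIMPLER pass", {
  g <- grid_spec(c(8, 8, 12), c(1e-3, 1e-3, 1e-3))
  ph <- generate_poiseuille(g, radius = 3.2e-3, w_max = 0.1)
  cfg <- solver_config(dt = 0.05, eps = 5e-4, div_tol = 1e-5, max_outer = 100)
  meas <- simulate_pcmri(ph$truth, g, g, psf = NULL,
                         noise = noise_model(sigma = 0.01, seed = 2))
  psf <- build_psf(g$spacing, g$spacing)
  lum <- which(unclass(ph$mask) == MASK_FLUID)

  run_with_lambda <- function(lam) {
    op <- build_gamma(psf, g, g, identity = TRUE, lambda_u = lam,
                      lambda_v = lam, lambda_w = lam)
    reg <- if (lam == 0) NULL else
      attach_measurement(op, meas, rows = list(u = lum, v = lum, w = lum))
    run_steady_state(initial_plug_field(g, ph$mask, ph$bc), ph$bc,
                     props_blood, g, ph$mask, cfg, reg = reg)
  }
  res0 <- run_with_lambda(0)
  res_tiny <- run_with_lambda(1e-25)     # penalty far below solver tolerance
  expect_lt(max(abs(res_tiny$state$w - res0$state$w)), 1e-6)
  # and the regularized steady state still satisfies continuity
  res1 <- run_with_lambda(1)
  expect_lte(divergence_stats(res1$state, g, ph$mask)$max, cfg$div_tol)
})

test_that("non-convergence is flagged, not silently returned", {
  g <- grid_spec(c(8, 8, 12), c(1e-3, 1e-3, 1e-3))
  ph <- generate_poiseuille(g, radius = 3.2e-3, w_max = 0.1)
  cfg <- solver_config(dt = 0.05, eps = 1e-12, div_tol = 1e-5, max_outer = 3)
  res <- run_steady_state(initial_plug_field(g, ph$mask, ph$bc), ph$bc,
                          props_blood, g, ph$mask, cfg)
  expect_false(res$converged)
  expect_identical(res$outer_steps, 3L)
})
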