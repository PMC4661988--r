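# flood fill over the 6-connected open cells, used for connectivity checks
connected_components <- function(open) {
  d <- dim(open)
  lab <- array(0L, d)
  nxt <- 0L
  idx_all <- which(open)
  strides <- c(1L, d[1], d[1] * d[2])
  for (start in idx_all) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ijk <- arrayInd(cur, d)
      for (ax in 1:3) for (s in c(-1L, 1L)) {
        co <- ijk[ax] + s
        if (co < 1L || co > d[ax]) next
        nb <- cur + s * strides[ax]
        if (open[nb] && lab[nb] == 0L) { lab[nb] <- nxt; queue <- c(queue, nb) }
      }
    }
  }
  nxt
}

test_that("poiseuille phantom matches the analytic parabola", {
  g <- grid_spec(c(24, 24, 8), c(0.25e-3, 0.25e-3, 1e-3))
  R <- 2.5e-3; wmax <- 0.3
  ph <- generate_poiseuille(g, radius = R, w_max = wmax)
  cen <- stagger_to_centers(ph$truth, g)
  n <- g$n
  mid <- n[1] / 2   # even count: centerline straddles two cells
  centerline <- max(cen$w[, , 3])
  expect_equal(centerline, wmax, tolerance = 0.01)
  # mean over the lumen equals w_max/2 (analytic integral of the parabola)
  lum <- unclass(ph$mask) == MASK_FLUID
  expect_equal(mean(cen$w[, , 3][lum[, , 3]]), wmax / 2, tolerance = 0.02)
  # zero outside the lumen radius
  expect_true(all(cen$w[!lum & unclass(ph$mask) != MASK_INLET &
                          unclass(ph$mask) != MASK_OUTLET] == 0))
  expect_error(generate_poiseuille(g, radius = 5e-3, w_max = 0.1), "exceeds")
})

test_that("bifurcation phantom is connected with balanced, accurate fluxes", {
  g <- grid_spec(c(40, 24, 32), c(0.25e-3, 0.25e-3, 1e-3))
  R <- 2.2e-3; wmax <- 0.4
  bi <- generate_bifurcation(g, r_parent = R, r_branch = 1.6e-3, w_max = wmax)
  m <- unclass(bi$mask)
  # both branch cross-sections open at the outlet plane
  expect_gt(sum(m[1:20, , g$n[3]] == MASK_OUTLET), 0)
  expect_gt(sum(m[21:40, , g$n[3]] == MASK_OUTLET), 0)
  # one connected open component
  expect_identical(connected_components(m != MASK_WALL), 1L)
  # voxelized inlet flux within 2% of the analytic parabola flux
  A <- g$spacing[1] * g$spacing[2]
  flux <- sum(bi$bc$w[, , 1][m[, , 1] == MASK_INLET]) * A
  expect_equal(flux, wmax * pi * R^2 / 2, tolerance = 0.02)
  # outlet flux balanced against inlet exactly
  st <- enforce_bc(staggered_field(g), bi$mask, bi$bc)
  fl <- boundary_fluxes(st, bi$mask)
  expect_equal(fl$inlet, fl$outlet, tolerance = 1e-12)
})

test_that("degenerate measurement chain returns the centered truth", {
  g <- grid_spec(c(8, 8, 10), rep(1e-3, 3))
  ph <- generate_poiseuille(g, radius = 3.2e-3, w_max = 0.2)
  meas <- simulate_pcmri(ph$truth, g, g, psf = NULL,
                         noise = noise_model(sigma = 0))
  cen <- stagger_to_centers(ph$truth, g)
  expect_equal(meas$w, cen$w, tolerance = 1e-14)
  expect_equal(meas$u, cen$u, tolerance = 1e-14)
})

test_that("noise statistics and seeding behave as configured", {
  g <- grid_spec(c(12, 12, 12), rep(1e-3, 3))   # 1728 voxels >= 1000
  truth <- staggered_field(g, value = 0.2)      # uniform velocity region
  nm <- noise_model(sigma = 0.08, seed = 42)
  meas <- simulate_pcmri(truth, g, g, psf = NULL, noise = nm)
  expect_equal(sd(meas$w), 0.08, tolerance = 0.1)    # sampling statistics
  expect_equal(mean(meas$w), 0.2, tolerance = 0.01)
  # identical seeds -> identical volumes; different seeds differ
  meas2 <- simulate_pcmri(truth, g, g, psf = NULL, noise = nm)
  expect_identical(meas$w, meas2$w)
  meas3 <- simulate_pcmri(truth, g, g, psf = NULL,
                          noise = noise_model(sigma = 0.08, seed = 43))
  expect_false(identical(meas$w, meas3$w))
})

test_that("unit-DC blur reproduces linear fields away from the volume edge", {
  # a symmetric kernel with unit row sum is exact on affine fields, so the
  # interior of a linear ramp must pass through the blur unchanged
  g <- grid_spec(c(16, 16, 16), rep(1e-3, 3))
  xs <- axis_centers(g, 1)
  truth <- staggered_field(g)
  for (k in seq_len(g$n[3] + 1))
    truth$w[, , k] <- outer(0.3 + 5 * xs, rep(1, g$n[2]))
  psf <- build_psf(rep(2e-3, 3), g$spacing)
  meas <- simulate_pcmri(truth, g, g, psf = psf, noise = noise_model(sigma = 0))
  cen <- stagger_to_centers(truth, g)
  core <- 5:12    # kernel support is 4 cells per side
  expect_equal(meas$w[core, core, core], cen$w[core, core, core],
               tolerance = 1e-12)
})

test_that("VENC aliasing wraps as the phase model dictates", {
  g <- grid_spec(c(4, 4, 4), rep(1e-3, 3))
  venc <- 0.5
  truth <- staggered_field(g, value = 0)
  truth$w[] <- 1.2 * venc
  meas <- simulate_pcmri(truth, g, g, psf = NULL,
                         noise = noise_model(sigma = 0, venc = venc))
  expect_equal(meas$w[2, 2, 2], -0.8 * venc, tolerance = 1e-12)
})

test_that("wrap -> flag -> unwrap round trip is exact", {
  g <- grid_spec(c(5, 5, 5), rep(1e-3, 3))
  venc <- 0.4
  set.seed(31)
  # single-wrap regime on the positive side: values in (-VENC, 3 VENC)
  wtrue <- array(runif(prod(g$n), -0.9 * venc, 2.8 * venc), g$n)
  truth <- staggered_field(g)
  for (k in seq_len(g$n[3] + 1))
    truth$w[, , k] <- wtrue[, , min(k, g$n[3])]
  # make face averages equal the cell values (constant in z already ensured)
  cen <- stagger_to_centers(truth, g)
  meas <- simulate_pcmri(truth, g, g, psf = NULL,
                         noise = noise_model(sigma = 0, venc = venc))
  flagged <- which(cen$w > venc)               # known from construction
  fixed <- unwrap_velocity(meas, list(w = flagged))
  expect_equal(fixed$w, cen$w, tolerance = 1e-12)
  # empty flag set is the identity
  expect_identical(unwrap_velocity(meas, list(w = integer(0)))$w, meas$w)
  expect_error(unwrap_velocity(meas, list(w = prod(g$n) + 1L)), "out of range")
})

test_that("planted linear offsets are recovered exactly without noise", {
  g <- grid_spec(c(10, 10, 10), rep(2e-3, 3))
  truth <- staggered_field(g, value = 0.1)
  off <- list(u = c(0.01, -0.02, 0, 0.005), v = c(0, 0, 0, 0),
              w = c(0.004, 0, -0.01, -0.002))
  meas <- simulate_pcmri(truth, g, g, psf = NULL,
                         noise = noise_model(sigma = 0, offset = off))
  static <- array(TRUE, g$n)                  # uniform region: fit everywhere
  res <- remove_linear_offset(meas, static)
  expect_equal(unname(res$coef["u", ]), c(0.01, -0.02, 0, 0.005 + 0.1),
               tolerance = 1e-10)
  expect_equal(max(abs(res$meas$u)), 0, tolerance = 1e-10)
  # zero-offset input is unchanged up to round-off (constant absorbed in d)
  meas0 <- simulate_pcmri(truth, g, g, psf = NULL, noise = noise_model(sigma = 0))
  res0 <- remove_linear_offset(meas0, static)
  expect_equal(unname(res0$coef["w", 1:3]), c(0, 0, 0), tolerance = 1e-12)
})

test_that("offset recovery under noise is within the standard-error bound", {
  g <- grid_spec(c(12, 12, 12), rep(2e-3, 3))
  truth <- staggered_field(g, value = 0)
  sigma <- 0.05
  off <- list(w = c(0.01, -0.02, 0, 0.005))
  meas <- simulate_pcmri(truth, g, g, psf = NULL,
                         noise = noise_model(sigma = sigma, seed = 77,
                                             offset = off))
  static <- array(TRUE, g$n)
  res <- remove_linear_offset(meas, static)
  n_static <- prod(g$n)
  expect_lt(abs(res$coef["w", "d"] - 0.005), 3 * sigma / sqrt(n_static))
})

test_that("degenerate static regions are rejected", {
  g <- grid_spec(c(6, 6, 6), rep(1e-3, 3))
  meas <- simulate_pcmri(staggered_field(g, value = 0.1), g, g, psf = NULL,
                         noise = noise_model(sigma = 0))
  small <- array(FALSE, g$n); small[1, 1, 1] <- TRUE
  expect_error(remove_linear_offset(meas, small), "at least 4")
  plane <- array(FALSE, g$n); plane[, , 3] <- TRUE   # coplanar
  expect_error(remove_linear_offset(meas, plane), "degenerate")
})
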