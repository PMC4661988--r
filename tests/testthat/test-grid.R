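test_that("grid_spec validates and counts cells", {
  g <- grid_spec(c(2, 2, 2), rep(1e-3, 3))
  expect_equal(cell_count(g), 8)
  # phantom-like configuration: 65 x 18 x 41 cells of 0.5 x 0.5 x 1.0 mm
  g2 <- grid_spec(c(65, 18, 41), c(0.5e-3, 0.5e-3, 1.0e-3))
  expect_equal(grid_extent(g2), c(32.5e-3, 9.0e-3, 41.0e-3))
  expect_equal(cell_count(g2), 65 * 18 * 41)
  expect_error(grid_spec(c(0, 2, 2), rep(1e-3, 3)), "positive")
  expect_error(grid_spec(c(2, 2, 2), c(1e-3, 0, 1e-3)), "positive")
})

test_that("lumen_mask enforces structural invariants", {
  g <- tiny_grid()
  expect_s3_class(duct_mask(g), "lumen_mask")
  labels <- array(MASK_WALL, g$n)
  expect_error(lumen_mask(labels, g), "no FLUID")
  # inlet off the boundary z-planes
  labels[2, 2, 2:5] <- MASK_FLUID
  labels[2, 2, 3] <- MASK_INLET
  expect_error(lumen_mask(labels, g), "boundary z-planes")
  # isolated fluid cell
  labels2 <- array(MASK_WALL, g$n)
  labels2[2, 2, 3] <- MASK_FLUID
  expect_error(lumen_mask(labels2, g), "no open 6-neighbor")
  # wrong dims
  expect_error(lumen_mask(array(MASK_FLUID, c(2, 2, 2)), g), "dimensions")
})

test_that("stagger_to_centers averages faces and is exact on linear fields", {
  g <- tiny_grid(c(5, 4, 6))
  # constant field -> constant at centers
  f <- staggered_field(g, value = 1)
  cen <- stagger_to_centers(f, g)
  expect_true(all(cen$u == 1) && all(cen$v == 1) && all(cen$w == 1))
  # zero field -> zero
  cen0 <- stagger_to_centers(staggered_field(g), g)
  expect_true(all(cen0$u == 0))
  # globally linear field: exact midpoint values (closed-form oracle)
  h <- g$spacing
  fx <- function(x, y, z) 2 * x - 3 * y + 0.5 * z + 1
  f2 <- staggered_field(g)
  for (i in seq_len(g$n[1] + 1)) for (j in seq_len(g$n[2]))
    for (k in seq_len(g$n[3]))
      f2$u[i, j, k] <- fx((i - 1.5) * h[1], (j - 1) * h[2], (k - 1) * h[3])
  cen2 <- stagger_to_centers(f2, g)
  for (i in seq_len(g$n[1])) for (j in seq_len(g$n[2]))
    for (k in seq_len(g$n[3]))
      expect_equal(cen2$u[i, j, k],
                   fx((i - 1) * h[1], (j - 1) * h[2], (k - 1) * h[3]),
                   tolerance = 1e-12)
})

test_that("divergence matches hand-evaluated finite differences", {
  g <- tiny_grid(c(4, 4, 4), rep(2e-3, 3))
  # uniform field: zero divergence
  expect_true(all(divergence(staggered_field(g, value = 0.3), g) == 0))
  # u = x on faces, v = w = 0: divergence = 1 1/s everywhere
  f <- staggered_field(g)
  for (i in seq_len(g$n[1] + 1)) f$u[i, , ] <- (i - 1) * g$spacing[1]
  expect_equal(max(abs(divergence(f, g) - 1)), 0, tolerance = 1e-12)
})

test_that("divergence is linear and satisfies the discrete Gauss theorem", {
  g <- tiny_grid(c(5, 6, 7))
  f1 <- random_field(g, seed = 11)
  f2 <- random_field(g, seed = 22)
  a <- 1.7; b <- -0.4
  comb <- staggered_field(g, u = a * f1$u + b * f2$u, v = a * f1$v + b * f2$v,
                          w = a * f1$w + b * f2$w)
  expect_equal(divergence(comb, g),
               a * divergence(f1, g) + b * divergence(f2, g),
               tolerance = 1e-12)
  # sum of div * cellVolume telescopes to the net boundary flux
  for (seed in 1:3) {
    f <- random_field(g, seed = seed)
    vol <- prod(g$spacing)
    n <- g$n; h <- g$spacing
    bflux <- sum(f$u[n[1] + 1, , ] - f$u[1, , ]) * h[2] * h[3] +
      sum(f$v[, n[2] + 1, ] - f$v[, 1, ]) * h[1] * h[3] +
      sum(f$w[, , n[3] + 1] - f$w[, , 1]) * h[1] * h[2]
    expect_equal(sum(divergence(f, g)) * vol, bflux, tolerance = 1e-12)
  }
})

test_that("face_average_operator reproduces stagger_to_centers", {
  g <- tiny_grid(c(4, 3, 5))
  f <- random_field(g, seed = 3)
  cen <- stagger_to_centers(f, g)
  for (comp in c("u", "v", "w")) {
    A <- face_average_operator(g, comp)
    expect_equal(as.numeric(A %*% as.vector(f[[comp]])),
                 as.vector(cen[[comp]]), tolerance = 1e-14)
  }
})

test_that("resolved_fluid_cells strips wall-adjacent cells", {
  g <- grid_spec(c(8, 8, 4), rep(1e-3, 3))
  ph <- generate_poiseuille(g, radius = 3.2e-3, w_max = 0.1)
  res <- resolved_fluid_cells(ph$mask)
  expect_true(all(unclass(ph$mask)[res] == MASK_FLUID))
  expect_lt(sum(res), sum(unclass(ph$mask) == MASK_FLUID))
  expect_gt(sum(res), 0)
})
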