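mk_field <- function(u, v, w) list(u = u, v = v, w = w)

toy_dims <- c(2, 1, 1)
toy <- function(uu, vv = c(0, 0), ww = c(0, 0))
  mk_field(array(uu, toy_dims), array(vv, toy_dims), array(ww, toy_dims))

test_that("SER reproduces hand-evaluated toy cases exactly", {
  ref <- toy(c(1, 1))
  # est = ref: zero error -> infinity sentinel
  expect_identical(ser(ref, ref)$ser_total, Inf)
  expect_identical(ser(ref, ref)$ser_u, Inf)
  # est = 0: error energy equals signal energy -> 0 dB
  expect_equal(ser(toy(c(0, 0)), ref)$ser_total, 0, tolerance = 1e-12)
  # half amplitude: 10*log10(4) = 6.0206 dB
  half <- ser(toy(c(0.5, 0.5)), ref)
  expect_equal(half$ser_u, 10 * log10(4), tolerance = 1e-12)
  expect_equal(half$ser_total, 10 * log10(4), tolerance = 1e-12)
})

test_that("SER errors on degenerate inputs", {
  z <- toy(c(0, 0))
  expect_error(ser(z, z), "zero energy")
  big <- mk_field(array(1, c(3, 1, 1)), array(0, c(3, 1, 1)), array(0, c(3, 1, 1)))
  expect_error(ser(big, toy(c(1, 1))), "mismatch")
  expect_error(ser(toy(c(1, 1)), toy(c(1, 1)), mask = array(FALSE, toy_dims)),
               "empty")
})

test_that("SER is invariant under common rescaling and degrades with noise", {
  set.seed(9)
  d <- c(6, 6, 6)
  ref <- mk_field(array(rnorm(216), d), array(rnorm(216), d), array(rnorm(216), d))
  est <- mk_field(ref$u + 0.1 * rnorm(216), ref$v + 0.1 * rnorm(216),
                  ref$w + 0.1 * rnorm(216))
  s1 <- ser(est, ref)
  c_ <- 3.7
  s2 <- ser(mk_field(c_ * est$u, c_ * est$v, c_ * est$w),
            mk_field(c_ * ref$u, c_ * ref$v, c_ * ref$w))
  expect_equal(s1$ser_total, s2$ser_total, tolerance = 1e-12)
  # monotone degradation: more independent noise lowers SER (over seeds)
  worse <- 0
  for (seed in 1:5) {
    set.seed(seed)
    noisier <- mk_field(est$u + 0.2 * rnorm(216), est$v + 0.2 * rnorm(216),
                        est$w + 0.2 * rnorm(216))
    if (ser(noisier, ref)$ser_total < s1$ser_total) worse <- worse + 1
  }
  expect_identical(worse, 5)
})

test_that("component energy ratios match hand evaluation", {
  d <- c(4, 4, 2)
  u <- array(rnorm(32), d)
  eq <- mk_field(u, u, u)
  expect_equal(unname(component_energy_ratio(eq)), c(0, 0, 0), tolerance = 1e-12)
  twice <- mk_field(u, u, 2 * u)
  expect_equal(component_energy_ratio(twice)[["w_over_u"]], 10 * log10(4),
               tolerance = 1e-12)
  # components with zero energy give the NA sentinel
  pois <- mk_field(array(0, d), array(0, d), u)
  expect_true(is.na(component_energy_ratio(pois)[["u_over_v"]]))
})

test_that("divergence_stats separates solver output from noisy measurements", {
  g <- grid_spec(c(8, 8, 12), rep(1e-3, 3))
  # uniform field: divergence identically zero
  expect_equal(divergence_stats(staggered_field(g, value = 0.2), g)$max, 0)
  # noisy field: divergence far above any solver tolerance inside the lumen
  ph <- generate_poiseuille(g, radius = 3.2e-3, w_max = 0.2)
  noisy <- random_field(g, seed = 2, scale = 0.05)
  stats <- divergence_stats(noisy, g, ph$mask)
  expect_gt(stats$max, 1)
})

test_that("SER reports round-trip losslessly through JSON", {
  ref <- toy(c(1, 1))
  for (rep_ in list(ser(toy(c(0.5, 0.5)), ref), ser(ref, ref))) {
    path <- tempfile(fileext = ".json")
    write_ser_report(rep_, path)
    back <- read_ser_report(path)
    if (is.infinite(rep_$ser_total)) {
      expect_identical(back$ser_total, Inf)   # sentinel survives exactly
    } else {
      expect_equal(back$ser_total, rep_$ser_total, tolerance = 1e-12)
    }
    expect_equal(back$ser_u, rep_$ser_u, tolerance = 1e-12)
    expect_true(is.na(back$ser_v) == is.na(rep_$ser_v))
    unlink(path)
  }
})

test_that("ser_table lays out modes as columns", {
  ref <- toy(c(1, 1))
  tab <- ser_table(list(cfd = ser(toy(c(0.5, 0.5)), ref),
                        guided = ser(toy(c(0.9, 0.9)), ref)))
  expect_identical(colnames(tab), c("cfd", "guided"))
  expect_identical(rownames(tab), c("SER_u", "SER_v", "SER_w", "SER_total"))
  expect_gt(tab["SER_total", "guided"], tab["SER_total", "cfd"])
})
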