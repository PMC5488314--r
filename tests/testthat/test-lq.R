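test_that("BED reproduces the standard LQ worked points", {
  expect_identical(bed("5x10", alpha_beta = 10), 100)
  expect_equal(bed("3x15"), 45 * 2.5)           # 112.5 Gy
  expect_equal(bed(fraction_scheme(1, 30)), 30 * 4)
  # BED strictly exceeds the physical dose for every positive d
  for (d in c(0.5, 2, 8, 18, 30)) {
    expect_gt(bed(fraction_scheme(3, d)), 3 * d)
  }
})

test_that("EQD2 worked points and the 2 Gy identity", {
  expect_equal(eqd2("1x2"), 2)
  expect_equal(eqd2("1x30"), 100)
  expect_equal(eqd2("5x10"), ORACLE$eqd2_5x10)
  # equals physical dose exactly when d = 2
  for (n in c(1L, 10L, 30L)) {
    expect_equal(eqd2(fraction_scheme(n, 2)), 2 * n)
  }
})

test_that("BED is monotone in dose per fraction, fraction count, and
           hypofractionation at fixed total dose", {
  d_grid <- seq(1, 30, by = 0.5)
  b <- vapply(d_grid, function(d) bed(fraction_scheme(4, d)), numeric(1))
  expect_true(all(diff(b) > 0))
  n_grid <- 1:12
  b_n <- vapply(n_grid, function(n) bed(fraction_scheme(n, 8)), numeric(1))
  expect_true(all(diff(b_n) > 0))
  # 60 Gy total in fewer fractions carries more biological punch
  b_total <- vapply(c(30L, 15L, 10L, 5L, 3L, 1L),
                    function(n) bed(fraction_scheme(n, 60 / n)), numeric(1))
  expect_true(all(diff(b_total) > 0))
})

test_that("invalid schemes and alpha/beta are rejected", {
  expect_error(fraction_scheme(0, 10), "positive integer")
  expect_error(fraction_scheme(3, 0), "positive")
  expect_error(fraction_scheme(2.5, 10), "integer")
  expect_error(bed("5x10", alpha_beta = 0), "alpha_beta")
  expect_error(bed("5x10", alpha_beta = -3), "alpha_beta")
})

test_that("scheme strings parse, render and round-trip", {
  s <- parse_scheme("5x10")
  expect_identical(s$n_fractions, 5L)
  expect_identical(s$dose_per_fraction, 10)
  expect_identical(format(s), "5 x 10 Gy")
  expect_identical(scheme_key(s), "5x10")
  expect_identical(total_dose("3x18"), 54)
  expect_identical(parse_scheme(" 4 X 12.5 ")$dose_per_fraction, 12.5)
  expect_error(parse_scheme("abc"), "cannot parse")
  expect_error(parse_scheme("5x"), "cannot parse")
})

test_that("isocenter scheme scales per fraction and preserves count", {
  p110 <- normalization_scenario("P110")
  iso <- isocenter_scheme("5x10", p110)
  expect_identical(iso$n_fractions, 5L)
  expect_equal(total_dose(iso), 55)
  expect_equal(isocenter_scheme("1x30", normalization_scenario("P120")
                                )$dose_per_fraction, 36)
  # a bare realized factor is accepted; factor 1 is the identity
  expect_equal(isocenter_scheme("3x18", 1)$dose_per_fraction, 18)
  for (f in c(1.05, 1.1, 1.2)) {
    expect_equal(total_dose(isocenter_scheme("4x12", f)), 48 * f)
  }
  expect_error(normalization_scenario("P110", dmax_factor = 0.9),
               "exceed 1")
  expect_error(normalization_scenario("P999"), "unknown scenario")
})
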