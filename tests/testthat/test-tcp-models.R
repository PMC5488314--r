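test_that("logistic curve hits its midpoint, saturates, and stays stable", {
  for (p in list(c(0, 31), c(-1, 80), c(-60.2, 113.3))) {
    expect_identical(logistic_tcp(p[1], tcd50 = p[1], k = p[2]), 0.5)
  }
  expect_identical(logistic_tcp(1e6, 0, 31), 1)
  expect_identical(logistic_tcp(-1e6, 0, 31), 0)
  # no overflow or NaN anywhere up to 10^4 Gy
  x <- seq(-1e4, 1e4, length.out = 4001)
  y <- logistic_tcp(x, tcd50 = -1, k = 80)
  expect_true(all(is.finite(y) & y >= 0 & y <= 1))
  expect_error(logistic_tcp(50, 0, 0), "positive")
  expect_error(logistic_tcp(50, 0, -5), "positive")
})

test_that("logistic curve is point-symmetric about its midpoint", {
  set.seed(7)
  for (i in 1:50) {
    tcd50 <- runif(1, -100, 100)
    k <- runif(1, 5, 150)
    x <- runif(1, -500, 500)
    expect_equal(logistic_tcp(x, tcd50, k) +
                   logistic_tcp(2 * tcd50 - x, tcd50, k),
                 1, tolerance = 1e-12)
  }
})

test_that("model curves match independent closed-form evaluations", {
  expect_equal(logistic_tcp(115.5, tcd50 = -1, k = 80),
               ORACLE$logistic_115p5_m1_80, tolerance = 1e-14)
  expect_equal(martel_tcp(96.25), ORACLE$martel_96p25, tolerance = 1e-14)
  expect_equal(ohri_tcp(100, diameter = 2.5), ORACLE$ohri_bed100_L2p5,
               tolerance = 1e-14)
  expect_equal(gucken_tcp(0), ORACLE$gucken_bed0, tolerance = 1e-14)
})

test_that("Martel crosses 0.5 at D50, is monotone, and supports both
           logistic forms", {
  expect_identical(martel_tcp(72), 0.5)
  expect_equal(martel_tcp(72, form = "exponential_logistic"), 0.5)
  expect_identical(martel_tcp(0), 0)
  D <- seq(1, 200, by = 1)
  for (form in c("logit_power", "exponential_logistic")) {
    y <- martel_tcp(D, form = form)
    expect_true(all(diff(y) > 0))
    expect_true(all(y >= 0 & y <= 1))
  }
  expect_error(martel_tcp(-5), "non-negative")
  expect_error(martel_tcp(80, d50 = 0), "positive")
})

test_that("Ohri adjusts dose by tumor size and rejects bad diameters", {
  # the size penalty exactly cancels the dose at BED = c * L
  for (L in c(0, 1, 2.5, 5)) {
    expect_identical(ohri_tcp(10 * L, diameter = L), 0.5)
  }
  # larger tumors, lower control at fixed dose
  y <- ohri_tcp(100, diameter = seq(0, 6, by = 0.5))
  expect_true(all(diff(y) < 0))
  expect_error(ohri_tcp(100, diameter = -1), "non-negative")
})

test_that("Gucken and Santiago are monotone and quite similar over the
           clinical BED range", {
  bed_grid <- seq(100, 180, by = 0.01)
  g <- gucken_tcp(bed_grid)
  s <- santiago_tcp(bed_grid)
  expect_true(all(diff(g) > 0))
  expect_true(all(diff(s) > 0))
  expect_lte(max(abs(g - s)), 0.03)
})

test_that("the Tai regrowth interface enforces its contracts", {
  expect_error(tai_lc(100, horizon = 2), "config")
  prm <- default_config()$models$tai
  expect_error(tai_lc(100, horizon = 5, params = prm), "2 or 3")
  expect_error(tai_lc(100, horizon = 2,
                      params = list(tcd50_2y = 0, tcd50_3y = -5, k = 50)),
               "follow-up")
  # midpoint of the configured family
  expect_identical(tai_lc(prm$tcd50_2y, 2, prm), 0.5)
  expect_identical(tai_lc(prm$tcd50_3y, 3, prm), 0.5)
  grid <- seq(0, 400, by = 0.5)
  lc2 <- tai_lc(grid, 2, prm)
  lc3 <- tai_lc(grid, 3, prm)
  expect_true(all(diff(lc2) > 0))
  expect_true(all(lc3 <= lc2))
  expect_true(all(lc2 >= 0 & lc2 <= 1))
})

test_that("predict_lc routes dose quantities and enforces the
           model-horizon roster", {
  cfg <- default_config()
  expect_error(predict_lc("Martel", "5x10", 1.1, horizon = 3), "3-year")
  expect_error(predict_lc("Gucken", "5x10", 1.1, horizon = 2), "2-year")
  expect_error(predict_lc("Nonesuch", "5x10", 1.1, horizon = 2), "unknown")
  expect_error(predict_lc("Ohri", "5x10", 1.1, horizon = 2), "diameter")

  # prescription-dose model ignores the normalization scenario
  o110 <- predict_lc("Ohri", "5x10", 1.10, 2, diameter = 2.5)
  o120 <- predict_lc("Ohri", "5x10", 1.20, 2, diameter = 2.5)
  expect_identical(o110, o120)
  # isocenter-dose models do not
  for (m in c("Gucken", "Santiago")) {
    expect_gt(predict_lc(m, "5x10", 1.20, 3),
              predict_lc(m, "5x10", 1.10, 3))
  }
  expect_gt(predict_lc("Martel", "5x10", 1.20, 2),
            predict_lc("Martel", "5x10", 1.10, 2))

  # compositional agreement with the hand-chained calls
  iso <- isocenter_scheme("5x10", 1.10)
  expect_identical(predict_lc("Martel", "5x10", 1.10, 2),
                   martel_tcp(eqd2(iso)))
  expect_identical(predict_lc("Gucken", "5x10", 1.10, 3),
                   gucken_tcp(bed(iso)))
  expect_identical(predict_lc("Santiago", "3x18", 1.20, 3),
                   santiago_tcp(bed(isocenter_scheme("3x18", 1.20))))
  expect_identical(predict_lc("Ohri", "3x15", 1.20, 2, diameter = 1.8),
                   ohri_tcp(bed("3x15"), diameter = 1.8))
  cfg$models$tai$enabled <- TRUE
  expect_identical(predict_lc("Tai", "4x12", 1.10, 3, config = cfg),
                   tai_lc(bed(isocenter_scheme("4x12", 1.10)), 3,
                          cfg$models$tai))
})

test_that("the roster matches the published model-horizon assignment", {
  r <- tcp_model_roster()
  expect_setequal(r$model[r$horizon == 2], c("Martel", "Ohri", "Tai"))
  expect_setequal(r$model[r$horizon == 3], c("Gucken", "Santiago", "Tai"))
  expect_identical(r$dose_input[r$model == "Ohri"], "prescription")
  expect_true(all(r$dose_input[r$model != "Ohri"] == "isocenter"))
})
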