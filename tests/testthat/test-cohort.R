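test_that("the shipped cohort fixture matches the study description", {
  co <- load_table1_fixture()
  expect_identical(nrow(co), 17L)
  expect_identical(sum(co$stage == "T1"), 14L)
  expect_identical(sum(co$stage == "T2"), 3L)
  expect_identical(sum(co$sex == "M"), 9L)
  expect_identical(range(co$age), c(51L, 76L))
  expect_equal(mean(co$age), 65.3, tolerance = 0.001)
  expect_equal(sd(co$age), 7.0, tolerance = 0.01)
})

test_that("cohort tables round-trip losslessly through CSV", {
  co <- impute_diameters(load_table1_fixture(), seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  # the synthetic-diameter provenance attribute lives in the manifest, not
  # the CSV; values themselves round-trip exactly
  expect_equal(back, co, ignore_attr = TRUE)
})

test_that("diameter imputation is seeded, truncated and labelled
           synthetic", {
  co <- load_table1_fixture()
  a <- impute_diameters(co, seed = 5)
  b <- impute_diameters(co, seed = 5)
  c2 <- impute_diameters(co, seed = 6)
  expect_identical(a$diameter_cm, b$diameter_cm)
  expect_false(identical(a$diameter_cm, c2$diameter_cm))
  expect_true(all(a$diameter_cm > 0.5))
  expect_identical(attr(a, "diameter_source"), "synthetic")
  shifted <- impute_diameters(co, seed = 5, t2_shift_cm = 50)
  expect_true(all(shifted$diameter_cm[shifted$stage == "T2"] > 10))
})

test_that("simulated cohorts are reproducible and match the target
           diameter distribution", {
  expect_identical(nrow(simulate_cohort(0, seed = 1)), 0L)
  a <- simulate_cohort(17, seed = 42)
  b <- simulate_cohort(17, seed = 42)
  expect_identical(a, b)
  expect_true(all(a$stage %in% c("T1", "T2")))
  expect_true(all(a$age >= 51 & a$age <= 76))
  expect_true(all(a$diameter_cm > 0.5))
  big <- simulate_cohort(1e5, seed = 9)
  # closed-form mean of the truncated normal the generator draws from
  expect_equal(mean(big$diameter_cm), truncnorm_mean(2.5, 0.9, 0.5),
               tolerance = 0.02)
  expect_equal(mean(big$stage == "T2"), 3 / 17, tolerance = 0.01)
  expect_error(simulate_cohort(-1, seed = 1), "non-negative")
})

test_that("plan simulation covers the patient-by-scheme grid with bounded
           Dmax scatter", {
  co <- simulate_cohort(17, seed = 3)
  schemes <- c("1x30", "3x15", "4x12", "3x18", "5x10")
  plans <- simulate_plans(co, schemes, "P120", jitter_halfwidth = 0.02,
                          seed = 4)
  expect_identical(nrow(plans), 85L)
  expect_identical(nrow(dplyr::distinct(plans, patient_id, scheme)), 85L)
  expect_true(all(abs(plans$achieved_dmax_factor - 1.20) <= 0.02))
  exact <- simulate_plans(co, schemes, "P110", jitter_halfwidth = 0,
                          seed = 4)
  expect_true(all(exact$achieved_dmax_factor == 1.10))
  # same seed, byte-identical CSV
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_plans(simulate_plans(co, schemes, "P120", seed = 8), p1)
  write_plans(simulate_plans(co, schemes, "P120", seed = 8), p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_error(simulate_plans(co, schemes, "P120", jitter_halfwidth = -1),
               ">= 0")
})
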