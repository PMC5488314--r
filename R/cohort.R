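#' The 17-patient study cohort fixture
#'
#' Loads the shipped cohort table: 17 primary stage I NSCLC patients (14
#' T1, 3 T2; ages 51–76) treated with SBRT. Tumor diameters were not
#' published per patient; [impute_diameters()] draws synthetic ones
#' matching the reported cohort summary (2.5 +/- 0.9 cm) when a diameter
#' column is needed (the size-adjusted Ohri model requires it).
#'
#' @return A tibble with columns `id`, `sex` (`"M"`/`"F"`), `age` (years)
#'   and `stage` (`"T1"`/`"T2"`).
#' @examples
#' load_table1_fixture()
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_cohort.csv", package = "sbrtcp",
                      mustWork = TRUE)
  cohort <- readr::read_csv(
    path,
    col_types = readr::cols(id = readr::col_character(),
                            sex = readr::col_character(),
                            age = readr::col_integer(),
                            stage = readr::col_character())
  )
  validate_cohort(cohort, require_diameter = FALSE)
  # guard against a corrupted install: the shipped table is fixed
  ok <- nrow(cohort) == 17L &&
    sum(cohort$stage == "T1") == 14L && sum(cohort$stage == "T2") == 3L &&
    sum(cohort$age) == 1110L && sum(cohort$sex == "M") == 9L
  if (!ok) stop("cohort fixture failed its integrity check; reinstall ",
                "the package", call. = FALSE)
  cohort
}

validate_cohort <- function(cohort, require_diameter = FALSE) {
  need <- c("id", "sex", "age", "stage")
  if (require_diameter) need <- c(need, "diameter_cm")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    stop("cohort table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(cohort$id)) stop("duplicate patient ids", call. = FALSE)
  if (!all(cohort$stage %in% c("T1", "T2"))) {
    stop("`stage` must be T1 or T2", call. = FALSE)
  }
  if (!all(cohort$sex %in% c("M", "F"))) {
    stop("`sex` must be M or F", call. = FALSE)
  }
  if ("diameter_cm" %in% names(cohort) &&
      any(cohort$diameter_cm <= 0, na.rm = TRUE)) {
    stop("`diameter_cm` must be positive", call. = FALSE)
  }
  invisible(cohort)
}

# truncated-normal diameters: redraw below the floor so the distribution is
# a proper truncation, not a clamp piling mass at the floor
rtrunc_norm <- function(n, mean, sd, lower) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(rep(max(mean, lower), n))
  out <- stats::rnorm(n, mean, sd)
  bad <- out < lower
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- out < lower
  }
  out
}

#' Impute synthetic tumor diameters for a cohort
#'
#' Seeded draw from a normal distribution truncated below at `floor_cm`.
#' The imputed values are synthetic stand-ins for unpublished per-patient
#' measurements; the returned tibble carries a `diameter_source` attribute
#' set to `"synthetic"`.
#'
#' @param cohort Cohort tibble (see [load_table1_fixture()]).
#' @param seed Integer seed; imputation is reproducible.
#' @param mean_cm,sd_cm Diameter distribution in cm (defaults match the
#'   reported cohort summary, 2.5 +/- 0.9 cm).
#' @param floor_cm Truncation floor in cm (> 0).
#' @param t2_shift_cm Optional additive shift for T2 tumors (cm); default 0
#'   (no published stage-conditional sizes to emulate).
#' @return The cohort with a `diameter_cm` column appended.
#' @export
impute_diameters <- function(cohort, seed, mean_cm = 2.5, sd_cm = 0.9,
                             floor_cm = 0.5, t2_shift_cm = 0) {
  validate_cohort(cohort)
  stopifnot(floor_cm > 0, sd_cm >= 0)
  set.seed(as.integer(seed))
  mu <- mean_cm + ifelse(cohort$stage == "T2", t2_shift_cm, 0)
  d <- vapply(mu, function(m) rtrunc_norm(1L, m, sd_cm, floor_cm),
              numeric(1))
  out <- cohort
  out$diameter_cm <- d
  attr(out, "diameter_source") <- "synthetic"
  out
}

#' Simulate a synthetic SBRT cohort
#'
#' Generates `n` patients with the statistical structure of the study
#' cohort: tumor diameters from a truncated normal (default 2.5 +/- 0.9 cm,
#' floor 0.5 cm), T2 stage with probability `t2_fraction` (default 3/17),
#' ages uniform over the observed range 51–76, and sexes drawn with the
#' observed 9:8 male:female proportion.
#'
#' @param n Number of patients (>= 0).
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @param diameter_mean,diameter_sd,diameter_floor Diameter distribution (cm).
#' @param t2_fraction Probability a patient is staged T2.
#' @param age_range Integer age range to sample uniformly.
#' @return A cohort tibble with columns `id`, `sex`, `age`, `stage`,
#'   `diameter_cm`.
#' @examples
#' simulate_cohort(5, seed = 1)
#' @export
simulate_cohort <- function(n, seed, diameter_mean = 2.5, diameter_sd = 0.9,
                            diameter_floor = 0.5, t2_fraction = 3 / 17,
                            age_range = c(51L, 76L)) {
  if (length(n) != 1L || !is.finite(n) || n < 0 || n != round(n)) {
    stop("`n` must be a single non-negative integer", call. = FALSE)
  }
  stopifnot(diameter_sd >= 0, diameter_floor > 0,
            t2_fraction >= 0, t2_fraction <= 1)
  n <- as.integer(n)
  set.seed(as.integer(seed))
  if (n == 0L) {
    return(tibble::tibble(id = character(), sex = character(),
                          age = integer(), stage = character(),
                          diameter_cm = numeric()))
  }
  tibble::tibble(
    id = sprintf("S%03d", seq_len(n)),
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(9, 8) / 17),
    age = sample(seq(age_range[1], age_range[2]), n, replace = TRUE),
    stage = ifelse(stats::runif(n) < t2_fraction, "T2", "T1"),
    diameter_cm = rtrunc_norm(n, diameter_mean, diameter_sd, diameter_floor)
  )
}

#' Simulate plan realizations for a cohort
#'
#' One plan per patient x fraction scheme under a given normalization
#' scenario. The realized Dmax factor is the scenario's nominal factor plus
#' uniform jitter on `[-jitter_halfwidth, +jitter_halfwidth]`, emulating
#' planning scatter around the "about 110%/120%" normalization goal;
#' `jitter_halfwidth = 0` yields exactly the nominal factor for every plan.
#'
#' @param cohort Cohort tibble.
#' @param schemes List of [fraction_scheme()]s or `"<n>x<d>"` strings.
#' @param scenario A [normalization_scenario()] or its name.
#' @param jitter_halfwidth Half-width of the uniform Dmax scatter
#'   (dimensionless fraction of prescription, >= 0); default 0.02.
#' @param seed Integer seed.
#' @return A tibble with columns `patient_id`, `scheme` (`"<n>x<d>"` key),
#'   `n_fractions`, `dose_per_fraction`, `scenario`, `nominal_factor`,
#'   `achieved_dmax_factor`.
#' @examples
#' co <- simulate_cohort(3, seed = 1)
#' simulate_plans(co, c("5x10", "1x30"), "P110", seed = 2)
#' @export
simulate_plans <- function(cohort, schemes, scenario,
                           jitter_halfwidth = 0.02, seed = 1L) {
  validate_cohort(cohort)
  if (jitter_halfwidth < 0) stop("`jitter_halfwidth` must be >= 0",
                                 call. = FALSE)
  if (!inherits(scenario, "normalization_scenario")) {
    scenario <- normalization_scenario(scenario)
  }
  schemes <- lapply(schemes, parse_scheme)
  set.seed(as.integer(seed))
  grid <- tidyr::expand_grid(
    patient_id = cohort$id,
    scheme_i = seq_along(schemes)
  )
  scenario_name <- scenario$name
  nominal <- scenario$dmax_factor
  f <- nominal + stats::runif(nrow(grid), -jitter_halfwidth,
                              jitter_halfwidth)
  tibble::tibble(
    patient_id = grid$patient_id,
    scheme = vapply(schemes[grid$scheme_i], scheme_key, character(1)),
    n_fractions = vapply(schemes[grid$scheme_i],
                         function(s) s$n_fractions, integer(1)),
    dose_per_fraction = vapply(schemes[grid$scheme_i],
                               function(s) s$dose_per_fraction, numeric(1)),
    scenario = scenario_name,
    nominal_factor = nominal,
    achieved_dmax_factor = f
  )
}

#' Read and write cohort / plan tables
#'
#' Plain-CSV interchange with a header row, UTF-8, `.` decimal separator.
#' Doses are in Gy and diameters in cm.
#'
#' @param x Tibble to write.
#' @param path File path.
#' @return `read_cohort()`/`read_plans()` return tibbles; the writers
#'   return `path` invisibly.
#' @export
write_cohort <- function(x, path) {
  validate_cohort(x)
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- readr::read_csv(path, col_types = readr::cols(
    id = readr::col_character(), sex = readr::col_character(),
    age = readr::col_integer(), stage = readr::col_character(),
    .default = readr::col_double()))
  validate_cohort(cohort)
  cohort
}

#' @rdname write_cohort
#' @export
write_plans <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_plans <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(), scheme = readr::col_character(),
    scenario = readr::col_character(), n_fractions = readr::col_integer(),
    .default = readr::col_double()))
}
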