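#' Default run configuration
#'
#' The full parameterization of a comparison run. Model blocks default to
#' the published fits (alpha/beta = 10 Gy; Martel D50 = 72.0 Gy,
#' gamma50 = 2.0; Ohri c = 10 Gy/cm, TCD50 = 0 Gy, k = 31 Gy; Gucken
#' TCD50 = -1 Gy, k = 80 Gy; Santiago TCD50 = -60.2 Gy, k = 113.3 Gy).
#' The Tai block is a synthetic placeholder (its published regrowth fit is
#' not distributed here) and ships with `enabled = FALSE`; reports include
#' Tai only when that flag is set explicitly.
#'
#' @return A nested named list; see the vignette for the full key tree.
#' @examples
#' str(default_config())
#' @export
default_config <- function() {
  list(
    alpha_beta = 10,
    models = list(
      martel = list(d50 = 72, gamma50 = 2, form = "logit_power"),
      ohri = list(c_per_cm = 10, tcd50 = 0, k = 31),
      gucken = list(tcd50 = -1, k = 80),
      santiago = list(tcd50 = -60.2, k = 113.3),
      tai = list(enabled = FALSE, tcd50_2y = -20, tcd50_3y = -10, k = 50,
                 source = "synthetic placeholder, not the published fit")
    ),
    schemes = c("1x30", "3x15", "4x12", "3x18", "5x10"),
    scenarios = c("P110", "P120"),
    cohort = list(source = "fixture", path = NULL),
    simulation = list(n = 17, seed = 1, jitter_halfwidth = 0.02,
                      diameter_mean = 2.5, diameter_sd = 0.9,
                      diameter_floor = 0.5, t2_fraction = 3 / 17),
    report = list(models = NULL, zero_policy = "drop", alpha = 0.05,
                  benchmark_2y = "Martel", benchmark_3y = "Gucken")
  )
}

merge_config <- function(defaults, user, path = character()) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key: ",
         paste(c(path, unknown[1]), collapse = "$"), call. = FALSE)
  }
  for (key in names(user)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        key != "report") {
      if (!is.list(user[[key]])) {
        stop("config key ", paste(c(path, key), collapse = "$"),
             " must be a block", call. = FALSE)
      }
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      c(path, key))
    } else if (key == "report" && is.list(user[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      c(path, key))
    } else {
      # `[<-` with a list preserves explicit NULLs instead of deleting
      defaults[key] <- list(user[[key]])
    }
  }
  defaults
}

validate_config <- function(config) {
  check_alpha_beta(config$alpha_beta)
  m <- config$models
  for (nm in c("ohri", "gucken", "santiago", "tai")) {
    if (!is.numeric(m[[nm]]$k) || m[[nm]]$k <= 0) {
      stop("config models$", nm, "$k must be > 0 (Gy)", call. = FALSE)
    }
  }
  if (m$martel$d50 <= 0 || m$martel$gamma50 <= 0) {
    stop("config models$martel requires d50 > 0 and gamma50 > 0",
         call. = FALSE)
  }
  if (!m$martel$form %in% c("logit_power", "exponential_logistic")) {
    stop("config models$martel$form must be \"logit_power\" or ",
         "\"exponential_logistic\"", call. = FALSE)
  }
  if (m$ohri$c_per_cm < 0) {
    stop("config models$ohri$c_per_cm must be >= 0", call. = FALSE)
  }
  if (m$tai$tcd50_3y < m$tai$tcd50_2y) {
    stop("config models$tai$tcd50_3y must be >= tcd50_2y", call. = FALSE)
  }
  lapply(config$schemes, parse_scheme)
  lapply(config$scenarios, normalization_scenario)
  sim <- config$simulation
  if (sim$jitter_halfwidth < 0) {
    stop("config simulation$jitter_halfwidth must be >= 0", call. = FALSE)
  }
  if (sim$n < 0) stop("config simulation$n must be >= 0", call. = FALSE)
  if (!config$cohort$source %in% c("fixture", "simulate", "csv")) {
    stop("config cohort$source must be fixture, simulate or csv",
         call. = FALSE)
  }
  invisible(config)
}

#' Load, merge and validate a run configuration
#'
#' Reads a YAML file, overlays it on [default_config()] and validates the
#' result. An empty file yields the defaults unchanged; unknown keys are
#' rejected with the offending key named.
#'
#' @param path YAML config file.
#' @return A validated config list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  config <- merge_config(default_config(), user)
  validate_config(config)
}

#' @rdname load_config
#' @param config Config list to save.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 17)
  invisible(path)
}

#' Run the full model-comparison pipeline
#'
#' Resolves the cohort (shipped fixture with seeded synthetic diameters,
#' a simulated cohort, or a user CSV), simulates one plan per patient x
#' scheme under each scenario, computes the local-control matrix, builds
#' the per-horizon comparison reports, and writes everything (plus a run
#' manifest echoing every parameter and seed) to `out_dir`. Two runs with
#' the same config produce byte-identical files.
#'
#' @param config Config list (see [default_config()], [load_config()]).
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the `cohort`, `plans`, `lc_matrix` and
#'   `report` tibbles and the written `paths`.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- config$simulation
  seed <- as.integer(sim$seed)

  cohort <- switch(config$cohort$source,
    fixture = impute_diameters(load_table1_fixture(), seed = seed,
                               mean_cm = sim$diameter_mean,
                               sd_cm = sim$diameter_sd,
                               floor_cm = sim$diameter_floor),
    simulate = simulate_cohort(sim$n, seed = seed,
                               diameter_mean = sim$diameter_mean,
                               diameter_sd = sim$diameter_sd,
                               diameter_floor = sim$diameter_floor,
                               t2_fraction = sim$t2_fraction),
    csv = read_cohort(config$cohort$path))

  plans <- dplyr::bind_rows(lapply(seq_along(config$scenarios),
    function(i) {
      simulate_plans(cohort, config$schemes,
                     normalization_scenario(config$scenarios[i]),
                     jitter_halfwidth = sim$jitter_halfwidth,
                     seed = seed + i)
    }))

  roster <- tcp_model_roster()
  if (!is.null(config$report$models)) {
    roster <- roster[roster$model %in% config$report$models, ]
  }
  lc_matrix <- compute_lc_matrix(cohort, plans, roster = roster,
                                 alpha_beta = config$alpha_beta,
                                 config = config)
  benchmarks <- c(`2` = config$report$benchmark_2y,
                  `3` = config$report$benchmark_3y)
  report <- build_report(lc_matrix, benchmarks = benchmarks,
                         zero_policy = config$report$zero_policy,
                         alpha = config$report$alpha)

  paths <- list(cohort = file.path(out_dir, "cohort.csv"),
                plans = file.path(out_dir, "plans.csv"),
                lc_matrix = file.path(out_dir, "lc_matrix.csv"),
                manifest = file.path(out_dir, "manifest.json"))
  write_cohort(cohort, paths$cohort)
  write_plans(plans, paths$plans)
  readr::write_csv(lc_matrix, paths$lc_matrix)
  for (h in unique(report$horizon)) {
    p <- file.path(out_dir, sprintf("report_%dy.csv", h))
    readr::write_csv(report[report$horizon == h, ], p)
    paths[[sprintf("report_%dy", h)]] <- p
  }
  manifest <- list(
    package = "sbrtcp",
    version = as.character(utils::packageVersion("sbrtcp")),
    seed = seed,
    diameter_source = attr(cohort, "diameter_source"),
    config = config,
    files = vapply(paths, basename, character(1)))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(list(cohort = cohort, plans = plans, lc_matrix = lc_matrix,
                 report = report, paths = paths))
}
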