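#' Per-patient local-control prediction matrix
#'
#' Evaluates every rostered model on every plan, producing one probability
#' per valid (patient, scheme, scenario, model, horizon) cell. Horizons
#' follow the model contracts — Martel/Ohri/Tai at 2 years, Gucken/
#' Santiago/Tai at 3 years — so contractually invalid model-horizon cells
#' are simply absent. The Tai model only enters the grid when its
#' config block is explicitly enabled (its shipped parameters are a
#' synthetic placeholder, not the published regrowth fit).
#'
#' @param cohort Cohort tibble; must carry `diameter_cm` when the Ohri
#'   model is rostered (see [impute_diameters()]).
#' @param plans Plan tibble from [simulate_plans()] (possibly row-bound
#'   over scenarios) or [read_plans()].
#' @param roster Model roster tibble, defaulting to [tcp_model_roster()].
#' @param alpha_beta LQ alpha/beta in Gy.
#' @param config Model-parameter config (see [default_config()]).
#' @return A long tibble with columns `patient_id`, `scheme`, `scenario`,
#'   `model`, `horizon`, `lc` (probability in \[0, 1\]).
#' @export
compute_lc_matrix <- function(cohort, plans, roster = tcp_model_roster(),
                              alpha_beta = 10, config = default_config()) {
  validate_cohort(cohort)
  if (!all(plans$patient_id %in% cohort$id)) {
    orphan <- setdiff(unique(plans$patient_id), cohort$id)
    stop("plan(s) reference unknown patient(s): ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  if (!isTRUE(config$models$tai$enabled)) {
    roster <- roster[roster$model != "Tai", ]
  }
  if (nrow(plans) == 0L || nrow(roster) == 0L) {
    return(tibble::tibble(patient_id = character(), scheme = character(),
                          scenario = character(), model = character(),
                          horizon = integer(), lc = numeric()))
  }
  if ("Ohri" %in% roster$model) {
    if (!"diameter_cm" %in% names(cohort)) {
      stop("the Ohri model needs tumor diameters; add a `diameter_cm` ",
           "column (see impute_diameters())", call. = FALSE)
    }
    bad <- cohort$id[is.na(cohort$diameter_cm)]
    if (length(bad)) {
      stop("missing tumor diameter for patient(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }

  ctx <- dplyr::left_join(
    plans,
    cohort[, intersect(c("id", "diameter_cm"), names(cohort))],
    by = c(patient_id = "id"))
  d_iso <- ctx$dose_per_fraction * ctx$achieved_dmax_factor
  ctx$bed_iso <- bed_nd(ctx$n_fractions, d_iso, alpha_beta)
  ctx$eqd2_iso <- eqd2_nd(ctx$n_fractions, d_iso, alpha_beta)
  ctx$bed_rx <- bed_nd(ctx$n_fractions, ctx$dose_per_fraction, alpha_beta)

  mp <- config$models
  cells <- lapply(seq_len(nrow(roster)), function(i) {
    model <- roster$model[i]
    horizon <- roster$horizon[i]
    lc <- switch(model,
      Martel = martel_tcp(ctx$eqd2_iso, d50 = mp$martel$d50,
                          gamma50 = mp$martel$gamma50,
                          form = mp$martel$form),
      Ohri = ohri_tcp(ctx$bed_rx, diameter = ctx$diameter_cm,
                      c_per_cm = mp$ohri$c_per_cm,
                      tcd50 = mp$ohri$tcd50, k = mp$ohri$k),
      Gucken = gucken_tcp(ctx$bed_iso, tcd50 = mp$gucken$tcd50,
                          k = mp$gucken$k),
      Santiago = santiago_tcp(ctx$bed_iso, tcd50 = mp$santiago$tcd50,
                              k = mp$santiago$k),
      Tai = tai_lc(ctx$bed_iso, horizon = horizon, params = mp$tai),
      stop("unknown model in roster: ", sQuote(model), call. = FALSE))
    tibble::tibble(patient_id = ctx$patient_id, scheme = ctx$scheme,
                   scenario = ctx$scenario, model = model,
                   horizon = as.integer(horizon), lc = lc)
  })
  out <- dplyr::bind_rows(cells)
  dplyr::arrange(out, .data$horizon, .data$model, .data$scenario,
                 .data$scheme, .data$patient_id)
}

#' Per-patient differences against a benchmark model
#'
#' Pairs each patient's prediction under `comparator` with the same
#' patient's prediction under `reference` (same scheme, scenario and
#' horizon) and returns `(comparator - reference) * 100`, i.e. percentage
#' points. Negative values mean the comparator predicts poorer control
#' than the benchmark.
#'
#' @param lc_matrix Output of [compute_lc_matrix()].
#' @param comparator,reference Model names; both must predict at `horizon`.
#' @param horizon Follow-up horizon in years.
#' @return Tibble with columns `scheme`, `scenario`, `patient_id`,
#'   `comparator`, `reference`, `diff_pct`.
#' @export
pairwise_difference <- function(lc_matrix, comparator, reference, horizon) {
  for (m in c(comparator, reference)) {
    if (!any(lc_matrix$model == m & lc_matrix$horizon == horizon)) {
      stop(sQuote(m), " has no ", horizon,
           "-year predictions in this matrix", call. = FALSE)
    }
  }
  a <- lc_matrix[lc_matrix$model == comparator &
                   lc_matrix$horizon == horizon, ]
  b <- lc_matrix[lc_matrix$model == reference &
                   lc_matrix$horizon == horizon, ]
  j <- dplyr::inner_join(a, b,
                         by = c("patient_id", "scheme", "scenario"),
                         suffix = c("_cmp", "_ref"))
  tibble::tibble(scheme = j$scheme, scenario = j$scenario,
                 patient_id = j$patient_id,
                 comparator = comparator, reference = reference,
                 diff_pct = (j$lc_cmp - j$lc_ref) * 100)
}

#' Median and range of a paired-difference vector
#'
#' @param differences Non-empty numeric vector of per-patient differences
#'   (percentage points). The median of an even-length vector is the mean
#'   of the central pair.
#' @return A one-row tibble with `median`, `min`, `max`.
#' @export
summarize_differences <- function(differences) {
  if (length(differences) == 0L || all(is.na(differences))) {
    stop("cannot summarize an empty difference vector", call. = FALSE)
  }
  tibble::tibble(median = stats::median(differences),
                 min = min(differences), max = max(differences))
}

#' Wilcoxon signed-rank test for paired model predictions
#'
#' Two-sided paired test. Under the default `"drop"` policy, zero
#' differences are removed before ranking (the classical convention); if
#' every difference is zero the samples are indistinguishable and p = 1.
#' The `"pratt"` policy instead ranks zeros with the rest and removes only
#' their rank contribution (normal approximation). With the drop policy
#' the null distribution is exact for n <= 25 tie-free differences and a
#' continuity-corrected normal approximation beyond (or in the presence of
#' tied absolute differences).
#'
#' @param a,b Equal-length numeric vectors of paired observations.
#' @param zero_policy `"drop"` (default) or `"pratt"`.
#' @return Two-sided p-value.
#' @examples
#' wilcoxon_signed_rank(c(0.90, 0.95, 0.91), c(0.88, 0.91, 0.90))
#' @export
wilcoxon_signed_rank <- function(a, b, zero_policy = c("drop", "pratt")) {
  zero_policy <- match.arg(zero_policy)
  if (length(a) != length(b)) {
    stop("paired samples must have equal length", call. = FALSE)
  }
  if (length(a) == 0L) stop("paired samples must be non-empty",
                            call. = FALSE)
  d <- a - b
  d <- d[!is.na(d)]
  if (zero_policy == "drop") {
    d <- d[d != 0]
    if (length(d) == 0L) return(1)
    res <- suppressWarnings(
      stats::wilcox.test(d, exact = length(d) <= 25, correct = TRUE))
    unname(res$p.value)
  } else {
    n0 <- sum(d == 0)
    r <- rank(abs(d))
    w_pos <- sum(r[d > 0])
    n <- length(d)
    mu <- (n * (n + 1) - n0 * (n0 + 1)) / 4
    tie_tab <- table(r[d != 0])
    sigma2 <- (n * (n + 1) * (2 * n + 1) -
                 n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    if (sigma2 <= 0) return(1)
    z <- (w_pos - mu) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
  }
}

#' Model-comparison report tables
#'
#' For each horizon, compares every rostered non-benchmark model against
#' the horizon's benchmark (2-year: Martel; 3-year: Gucken) within each
#' fraction scheme and normalization scenario: per-patient differences in
#' percentage points, their median and range, and the Wilcoxon signed-rank
#' p-value of the paired predictions. `significant` flags p below `alpha`.
#'
#' @param lc_matrix Output of [compute_lc_matrix()].
#' @param benchmarks Named character vector mapping horizon (as `"2"`,
#'   `"3"`) to the benchmark model.
#' @param zero_policy Zero-difference policy for
#'   [wilcoxon_signed_rank()].
#' @param alpha Significance level; default 0.05.
#' @return Tibble with columns `horizon`, `scheme`, `scenario`,
#'   `comparator`, `reference`, `median_pct`, `min_pct`, `max_pct`,
#'   `p_value`, `significant` — one row per scheme x scenario x comparator
#'   x horizon.
#' @export
build_report <- function(lc_matrix, benchmarks = c(`2` = "Martel",
                                                   `3` = "Gucken"),
                         zero_policy = "drop", alpha = 0.05) {
  out <- list()
  for (h in sort(unique(lc_matrix$horizon))) {
    bench <- benchmarks[[as.character(h)]]
    models_h <- unique(lc_matrix$model[lc_matrix$horizon == h])
    if (is.null(bench) || !bench %in% models_h) next
    for (cmp in setdiff(models_h, bench)) {
      diffs <- pairwise_difference(lc_matrix, cmp, bench, h)
      cells <- dplyr::group_by(diffs, .data$scheme, .data$scenario)
      cells <- dplyr::group_modify(cells, function(g, key) {
        s <- summarize_differences(g$diff_pct)
        # p-value from the paired probabilities themselves (differences
        # scaled by 100 rank identically)
        p <- wilcoxon_signed_rank(g$diff_pct, rep(0, nrow(g)),
                                  zero_policy = zero_policy)
        tibble::tibble(median_pct = s$median, min_pct = s$min,
                       max_pct = s$max, p_value = p)
      })
      cells <- dplyr::ungroup(cells)
      cells$horizon <- as.integer(h)
      cells$comparator <- cmp
      cells$reference <- bench
      out[[length(out) + 1L]] <- cells
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(horizon = integer(), scheme = character(),
                          scenario = character(), comparator = character(),
                          reference = character(), median_pct = numeric(),
                          min_pct = numeric(), max_pct = numeric(),
                          p_value = numeric(), significant = logical()))
  }
  rep_tbl <- dplyr::bind_rows(out)
  rep_tbl$significant <- rep_tbl$p_value < alpha
  dplyr::select(
    dplyr::arrange(rep_tbl, .data$horizon, .data$comparator,
                   .data$scenario, .data$scheme),
    "horizon", "scheme", "scenario", "comparator", "reference",
    "median_pct", "min_pct", "max_pct", "p_value", "significant")
}

#' Render a report as a human-readable table
#'
#' One text table per horizon: rows are fraction schemes, column groups
#' are scenarios; the benchmark column reads `"NA"` and comparator cells
#' read `"median (min~max)"` in one-decimal percentage points, with a
#' dagger marking significant Wilcoxon tests.
#'
#' @param report Output of [build_report()].
#' @param horizon Horizon (years) to render.
#' @return Character vector of table lines (also printed).
#' @export
format_report <- function(report, horizon) {
  rep_h <- report[report$horizon == horizon, ]
  if (nrow(rep_h) == 0L) stop("no rows at horizon ", horizon,
                              call. = FALSE)
  bench <- unique(rep_h$reference)
  cmps <- unique(rep_h$comparator)
  scenarios <- unique(rep_h$scenario)
  schemes <- unique(rep_h$scheme)
  cell <- function(row) {
    sprintf("%.1f (%.1f~%.1f)%s", row$median_pct, row$min_pct,
            row$max_pct, ifelse(row$significant, "†", ""))
  }
  header <- c("FS", unlist(lapply(scenarios, function(sc) {
    c(paste0(sc, ":", bench), paste0(sc, ":", cmps, " (%)"))
  })))
  rows <- lapply(schemes, function(s) {
    vals <- unlist(lapply(scenarios, function(sc) {
      c("NA", vapply(cmps, function(cm) {
        row <- rep_h[rep_h$scheme == s & rep_h$scenario == sc &
                       rep_h$comparator == cm, ]
        if (nrow(row) == 1L) cell(row) else ""
      }, character(1)))
    }))
    c(format(parse_scheme(s)), vals)
  })
  m <- rbind(header, do.call(rbind, rows))
  widths <- apply(nchar(m), 2, max)
  lines <- apply(m, 1, function(r) {
    paste(mapply(formatC, r, width = widths, flag = "-"), collapse = "  ")
  })
  lines <- unname(c(lines[1], strrep("-", sum(widths) + 2 * (ncol(m) - 1)),
                    lines[-1]))
  cat(lines, sep = "\n")
  invisible(lines)
}
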