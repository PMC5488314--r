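#' Linear-quadratic dose conversions
#'
#' `bed()` converts a fraction scheme to biologically effective dose,
#' \eqn{BED = n d (1 + d / (\alpha/\beta))}, and `eqd2()` to the equivalent
#' total dose in 2-Gy fractions, \eqn{EQD2 = n d (d + \alpha/\beta) /
#' (2 + \alpha/\beta)}. Both are the standard LQ conversions used throughout
#' SBRT radiobiology; an \eqn{\alpha/\beta} of 10 Gy is conventional for
#' tumor, and `BED10` denotes BED computed at that value.
#'
#' BED strictly exceeds the total physical dose for any positive dose per
#' fraction, and EQD2 equals the physical dose exactly when the dose per
#' fraction is 2 Gy.
#'
#' @param scheme A [fraction_scheme()] or a `"<n>x<d>"` string.
#' @param alpha_beta The LQ \eqn{\alpha/\beta} ratio in Gy (> 0); default 10.
#' @return Dose in Gy.
#' @examples
#' bed("5x10")        # 100 Gy
#' eqd2("1x30")       # 100 Gy
#' @export
bed <- function(scheme, alpha_beta = 10) {
  s <- parse_scheme(scheme)
  check_alpha_beta(alpha_beta)
  bed_nd(s$n_fractions, s$dose_per_fraction, alpha_beta)
}

#' @rdname bed
#' @export
eqd2 <- function(scheme, alpha_beta = 10) {
  s <- parse_scheme(scheme)
  check_alpha_beta(alpha_beta)
  eqd2_nd(s$n_fractions, s$dose_per_fraction, alpha_beta)
}

# vectorized kernels used by the pipeline (per-plan columns)
bed_nd <- function(n, d, alpha_beta) n * d * (1 + d / alpha_beta)

eqd2_nd <- function(n, d, alpha_beta) n * d * (d + alpha_beta) / (2 + alpha_beta)

check_alpha_beta <- function(alpha_beta) {
  if (length(alpha_beta) != 1L || !is.finite(alpha_beta) || alpha_beta <= 0) {
    stop("`alpha_beta` must be a single positive value in Gy", call. = FALSE)
  }
  invisible(alpha_beta)
}

#' Dose-normalization scenarios
#'
#' A normalization scenario places the plan maximum dose (the isocenter
#' dose, centered in the GTV) at a fixed multiple of the prescription:
#' `P110` at 110% and `P120` at 120%. The multiplier applies per fraction,
#' so the isocenter dose is delivered in the same number of fractions at a
#' proportionally larger fraction size — which matters because BED is
#' nonlinear in the dose per fraction.
#'
#' @param name `"P110"`, `"P120"`, or a custom name when `dmax_factor` is
#'   supplied.
#' @param dmax_factor Dimensionless multiplier of prescription (> 1);
#'   inferred from `name` for the two standard scenarios.
#' @return An object of class `normalization_scenario`.
#' @examples
#' normalization_scenario("P110")
#' @export
normalization_scenario <- function(name, dmax_factor = NULL) {
  if (is.null(dmax_factor)) {
    dmax_factor <- switch(toupper(name),
      P110 = 1.10, P120 = 1.20,
      stop("unknown scenario ", sQuote(name),
           "; supply `dmax_factor` for custom scenarios", call. = FALSE))
  }
  if (!is.finite(dmax_factor) || dmax_factor <= 1) {
    stop("`dmax_factor` must exceed 1", call. = FALSE)
  }
  structure(list(name = toupper(name), dmax_factor = dmax_factor),
            class = "normalization_scenario")
}

#' @export
print.normalization_scenario <- function(x, ...) {
  cat("<scenario> ", x$name, ": Dmax = ", format(100 * x$dmax_factor),
      "% of prescription\n", sep = "")
  invisible(x)
}

#' Isocenter-dose scheme under a normalization scenario
#'
#' Scales the dose per fraction of a prescription by the scenario's Dmax
#' factor (or a realized per-plan factor), keeping the number of fractions.
#' The result is the dose quantity consumed by isocenter-dose models.
#'
#' @inheritParams bed
#' @param scenario A [normalization_scenario()], or a bare numeric factor
#'   (e.g. a realized per-plan Dmax factor such as 1.097).
#' @return A [fraction_scheme()] with the scaled dose per fraction.
#' @examples
#' isocenter_scheme("5x10", normalization_scenario("P110"))  # 5 x 11 Gy
#' @export
isocenter_scheme <- function(scheme, scenario) {
  s <- parse_scheme(scheme)
  f <- if (inherits(scenario, "normalization_scenario")) {
    scenario$dmax_factor
  } else if (is.numeric(scenario) && length(scenario) == 1L) {
    scenario
  } else {
    stop("`scenario` must be a normalization_scenario or a numeric factor",
         call. = FALSE)
  }
  if (!is.finite(f) || f <= 0) stop("Dmax factor must be positive",
                                    call. = FALSE)
  fraction_scheme(s$n_fractions, s$dose_per_fraction * f)
}
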