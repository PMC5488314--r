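#' Numerically stable logistic tumor-control curve
#'
#' The shared sigmoid for the BED-based models:
#' \deqn{TCP(x) = \frac{e^{(x - TCD_{50})/k}}{1 + e^{(x - TCD_{50})/k}}}
#' where `x` is a (possibly size-adjusted) biologically effective dose in
#' Gy, `tcd50` the dose at 50% control — a fitted constant that may be
#' negative on the BED scale — and `k > 0` the slope scale in Gy.
#'
#' Computed via the sign-split formulation, so it saturates cleanly to 0 or
#' 1 for very large |x| instead of overflowing.
#'
#' @param x Dose metric in Gy (vectorized).
#' @param tcd50 Midpoint in Gy.
#' @param k Slope scale in Gy, strictly positive.
#' @return Probability in \[0, 1\].
#' @examples
#' logistic_tcp(100, tcd50 = -1, k = 80)
#' @export
logistic_tcp <- function(x, tcd50, k) {
  if (length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("`k` must be a single positive slope scale in Gy", call. = FALSE)
  }
  z <- (x - tcd50) / k
  out <- numeric(length(z))
  pos <- !is.na(z) & z >= 0
  out[pos] <- 1 / (1 + exp(-z[pos]))
  ez <- exp(z[!pos])
  out[!pos] <- ez / (1 + ez)
  out[is.na(z)] <- NA_real_
  out
}

#' The five local-control prediction models
#'
#' Parameterizations follow the published fits: Martel (2-year LC, logistic
#' dose-response on the 2-Gy-equivalent dose, D50 = 72.0 Gy, gamma50 = 2.0),
#' Ohri (2-year, tumor-size-adjusted prescription BED, c = 10 Gy/cm,
#' TCD50 = 0 Gy, k = 31 Gy), Gucken (3-year, isocenter BED, TCD50 = -1 Gy,
#' k = 80 Gy) and Santiago (3-year, isocenter BED, TCD50 = -60.2 Gy,
#' k = 113.3 Gy), all at alpha/beta = 10 Gy. The Tai regrowth model is
#' config-injected (see [tai_lc()]).
#'
#' `martel_tcp()` supports two common logistic forms, selected by `form`:
#' the logit-power form \eqn{1 / (1 + (D_{50}/D)^{4\gamma_{50}})} (default)
#' and the exponential-logistic form
#' \eqn{1 / (1 + e^{4\gamma_{50}(1 - D/D_{50})})}. Both cross 0.5 at
#' \eqn{D = D_{50}} with normalized slope \eqn{\gamma_{50}}.
#'
#' @param dose_2gy_equivalent EQD2 in Gy (Martel).
#' @param d50 Dose at 50% control in Gy.
#' @param gamma50 Normalized slope at the midpoint (dimensionless).
#' @param form Martel functional form, `"logit_power"` or
#'   `"exponential_logistic"`.
#' @return Probability in \[0, 1\] (vectorized over the dose argument).
#' @examples
#' martel_tcp(96.25)
#' ohri_tcp(bed("5x10"), diameter = 2.5)
#' gucken_tcp(bed("5x11"))
#' santiago_tcp(bed("5x11"))
#' @export
martel_tcp <- function(dose_2gy_equivalent, d50 = 72, gamma50 = 2,
                       form = c("logit_power", "exponential_logistic")) {
  form <- match.arg(form)
  if (!is.finite(d50) || d50 <= 0) stop("`d50` must be positive",
                                        call. = FALSE)
  if (!is.finite(gamma50) || gamma50 <= 0) stop("`gamma50` must be positive",
                                                call. = FALSE)
  if (any(dose_2gy_equivalent < 0, na.rm = TRUE)) {
    stop("dose must be non-negative", call. = FALSE)
  }
  D <- dose_2gy_equivalent
  if (form == "logit_power") {
    out <- ifelse(D == 0, 0, 1 / (1 + (d50 / D)^(4 * gamma50)))
  } else {
    out <- logistic_tcp(D, tcd50 = d50, k = d50 / (4 * gamma50))
    out[D == 0] <- 1 / (1 + exp(4 * gamma50))  # exponential form at D = 0
  }
  out
}

#' @rdname martel_tcp
#' @param prescription_bed Prescription BED10 in Gy. Ohri consumes the
#'   treatment (prescription) dose, so its prediction does not change with
#'   the Dmax normalization scenario.
#' @param diameter Greatest tumor diameter in cm (>= 0).
#' @param c_per_cm Size penalty in Gy per cm of diameter.
#' @param tcd50,k Logistic midpoint and slope scale in Gy.
#' @export
ohri_tcp <- function(prescription_bed, diameter, c_per_cm = 10,
                     tcd50 = 0, k = 31) {
  if (!is.finite(c_per_cm) || c_per_cm < 0) {
    stop("`c_per_cm` must be non-negative", call. = FALSE)
  }
  if (any(!is.finite(diameter)) || any(diameter < 0)) {
    stop("tumor `diameter` must be non-negative (cm)", call. = FALSE)
  }
  logistic_tcp(prescription_bed - c_per_cm * diameter, tcd50 = tcd50, k = k)
}

#' @rdname martel_tcp
#' @param isocenter_bed BED10 of the isocenter (maximum) dose in Gy.
#' @export
gucken_tcp <- function(isocenter_bed, tcd50 = -1, k = 80) {
  logistic_tcp(isocenter_bed, tcd50 = tcd50, k = k)
}

#' @rdname martel_tcp
#' @export
santiago_tcp <- function(isocenter_bed, tcd50 = -60.2, k = 113.3) {
  logistic_tcp(isocenter_bed, tcd50 = tcd50, k = k)
}

#' Tai-style regrowth local-control curve (config-injected parameters)
#'
#' Predicts local control at a 2- or 3-year horizon from the isocenter
#' BED10, with the horizon entering through a horizon-specific midpoint:
#' the 3-year midpoint is at least the 2-year midpoint, so at any fixed
#' dose the 3-year prediction never exceeds the 2-year one (tumors can
#' regrow between years 2 and 3, never un-fail).
#'
#' The published multi-institution regrowth fit this interface is designed
#' for is not distributed with the package; `params` must be supplied (from
#' the config's `models$tai` block). The shipped default block is a
#' synthetic placeholder logistic family that satisfies the contracts above
#' but is *not* the published fit, and report generation therefore requires
#' explicitly enabling it (`models$tai$enabled`).
#'
#' @param isocenter_bed BED10 of the isocenter dose in Gy.
#' @param horizon Follow-up time in years, 2 or 3.
#' @param params List with numeric fields `tcd50_2y`, `tcd50_3y`
#'   (>= `tcd50_2y`) and `k` (> 0), all in Gy.
#' @return Probability in \[0, 1\].
#' @export
tai_lc <- function(isocenter_bed, horizon, params) {
  if (missing(params) || is.null(params)) {
    stop("Tai model parameters must be supplied via config ",
         "(`models$tai`): the published regrowth fit (\"Model Fit II\") ",
         "is not distributed with this package", call. = FALSE)
  }
  if (length(horizon) != 1L || !horizon %in% c(2, 3)) {
    stop("Tai `horizon` must be 2 or 3 (years)", call. = FALSE)
  }
  req <- c("tcd50_2y", "tcd50_3y", "k")
  if (!all(req %in% names(params))) {
    stop("Tai parameter block must contain ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (params$tcd50_3y < params$tcd50_2y) {
    stop("Tai `tcd50_3y` must be >= `tcd50_2y` (control cannot improve ",
         "with longer follow-up)", call. = FALSE)
  }
  tcd50 <- if (horizon == 2) params$tcd50_2y else params$tcd50_3y
  logistic_tcp(isocenter_bed, tcd50 = tcd50, k = params$k)
}

#' Model roster
#'
#' The five models and their routing: which dose quantity each consumes and
#' which follow-up horizon each predicts. Martel, Ohri and Tai predict
#' 2-year local control; Gucken, Santiago and Tai predict 3-year local
#' control. Ohri is the only prescription-dose model; all others read the
#' isocenter dose.
#'
#' @return A tibble with columns `model`, `horizon` (years) and
#'   `dose_input` (`"isocenter"` or `"prescription"`).
#' @examples
#' tcp_model_roster()
#' @export
tcp_model_roster <- function() {
  tibble::tibble(
    model      = c("Martel", "Ohri", "Tai", "Gucken", "Santiago", "Tai"),
    horizon    = c(2L, 2L, 2L, 3L, 3L, 3L),
    dose_input = c("isocenter", "prescription", "isocenter",
                   "isocenter", "isocenter", "isocenter")
  )
}

#' Predict local control for one plan context
#'
#' Routes the correct dose quantity — isocenter vs prescription dose, BED
#' vs 2-Gy-equivalent — to the requested model and returns its probability.
#'
#' @param model Model name: `"Martel"`, `"Ohri"`, `"Gucken"`, `"Santiago"`
#'   or `"Tai"`.
#' @param scheme Prescribed [fraction_scheme()] (or `"<n>x<d>"` string).
#' @param dmax_factor Realized isocenter-dose factor (e.g. 1.10 for an
#'   exactly-normalized P110 plan, or a jittered per-plan value).
#' @param horizon Follow-up horizon in years; must match the model's
#'   contract (Martel/Ohri: 2; Gucken/Santiago: 3; Tai: either).
#' @param diameter Tumor diameter in cm; required by Ohri only.
#' @param alpha_beta LQ alpha/beta in Gy.
#' @param config Model-parameter config (see [default_config()]); defaults
#'   reproduce the published parameter values.
#' @return Probability of local control in \[0, 1\].
#' @examples
#' predict_lc("Gucken", "5x10", dmax_factor = 1.2, horizon = 3)
#' @export
predict_lc <- function(model, scheme, dmax_factor, horizon,
                       diameter = NULL, alpha_beta = 10,
                       config = default_config()) {
  scheme <- parse_scheme(scheme)
  roster <- tcp_model_roster()
  hit <- roster[roster$model == model & roster$horizon == horizon, ]
  if (nrow(hit) == 0L) {
    valid <- roster$horizon[roster$model == model]
    if (length(valid) == 0L) {
      stop("unknown model ", sQuote(model), call. = FALSE)
    }
    stop(sQuote(model), " does not predict ", horizon, "-year local ",
         "control (valid horizon: ", paste(valid, collapse = ", "), " y)",
         call. = FALSE)
  }
  iso <- isocenter_scheme(scheme, dmax_factor)
  mp <- config$models
  switch(model,
    Martel = martel_tcp(eqd2(iso, alpha_beta),
                        d50 = mp$martel$d50, gamma50 = mp$martel$gamma50,
                        form = mp$martel$form),
    Ohri = {
      if (is.null(diameter)) {
        stop("the Ohri model requires a tumor `diameter` (cm)",
             call. = FALSE)
      }
      ohri_tcp(bed(scheme, alpha_beta), diameter = diameter,
               c_per_cm = mp$ohri$c_per_cm, tcd50 = mp$ohri$tcd50,
               k = mp$ohri$k)
    },
    Gucken = gucken_tcp(bed(iso, alpha_beta),
                        tcd50 = mp$gucken$tcd50, k = mp$gucken$k),
    Santiago = santiago_tcp(bed(iso, alpha_beta),
                            tcd50 = mp$santiago$tcd50, k = mp$santiago$k),
    Tai = tai_lc(bed(iso, alpha_beta), horizon = horizon, params = mp$tai)
  )
}
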