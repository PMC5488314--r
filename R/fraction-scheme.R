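#' Fraction schemes
#'
#' A fraction scheme is a prescription expressed as a number of fractions
#' and a dose per fraction, e.g. 5 fractions of 10 Gy. The total physical
#' dose is always derived (`n_fractions * dose_per_fraction`), never stored.
#'
#' @param n_fractions Positive integer number of fractions.
#' @param dose_per_fraction Dose per fraction in Gy, strictly positive.
#' @param label Optional display label; defaults to `"<n> x <d> Gy"`.
#'
#' @return An object of class `fraction_scheme` with fields `n_fractions`,
#'   `dose_per_fraction` and `label`.
#' @examples
#' fraction_scheme(5, 10)
#' parse_scheme("3x18")
#' @export
fraction_scheme <- function(n_fractions, dose_per_fraction, label = NULL) {
  if (length(n_fractions) != 1L || !is.finite(n_fractions) ||
      n_fractions < 1 || n_fractions != round(n_fractions)) {
    stop("`n_fractions` must be a single positive integer", call. = FALSE)
  }
  if (length(dose_per_fraction) != 1L || !is.finite(dose_per_fraction) ||
      dose_per_fraction <= 0) {
    stop("`dose_per_fraction` must be a single positive dose in Gy",
         call. = FALSE)
  }
  if (is.null(label)) {
    label <- paste0(format(as.integer(n_fractions)), " x ",
                    format(dose_per_fraction), " Gy")
  }
  structure(
    list(n_fractions = as.integer(n_fractions),
         dose_per_fraction = as.numeric(dose_per_fraction),
         label = label),
    class = "fraction_scheme"
  )
}

#' @rdname fraction_scheme
#' @param x A string of the form `"<n>x<d>"` (e.g. `"5x10"`), as used in
#'   config files and plan tables, or a `fraction_scheme` to format.
#' @export
parse_scheme <- function(x) {
  if (inherits(x, "fraction_scheme")) return(x)
  if (!is.character(x) || length(x) != 1L) {
    stop("scheme must be a single string like \"5x10\"", call. = FALSE)
  }
  m <- regmatches(x, regexec("^\\s*([0-9]+)\\s*[xX]\\s*([0-9.]+)\\s*$", x))[[1]]
  if (length(m) != 3L) {
    stop("cannot parse scheme string: ", sQuote(x),
         " (expected \"<n>x<d>\", e.g. \"5x10\")", call. = FALSE)
  }
  fraction_scheme(as.integer(m[2]), as.numeric(m[3]))
}

#' @rdname fraction_scheme
#' @export
scheme_key <- function(x) {
  s <- parse_scheme(x)
  paste0(s$n_fractions, "x", format(s$dose_per_fraction))
}

#' @rdname fraction_scheme
#' @export
total_dose <- function(x) {
  s <- parse_scheme(x)
  s$n_fractions * s$dose_per_fraction
}

#' @export
format.fraction_scheme <- function(x, ...) x$label

#' @export
print.fraction_scheme <- function(x, ...) {
  cat("<fraction_scheme> ", x$label, " (total ", format(total_dose(x)),
      " Gy)\n", sep = "")
  invisible(x)
}
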