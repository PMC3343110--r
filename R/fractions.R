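#' Percentage summaries of probe counts
#'
#' `percent_value()` turns a numerator/denominator pair into a percentage
#' rounded half-away-from-zero at a given number of decimals.
#' `percent_digits()` gives the reporting precision used in the package's
#' summary tables: whole percents at 10% and above, one decimal down to 0.1%,
#' two decimals below that. `percent_label()` formats the rounded value as a
#' string.
#'
#' @param n Numerator (count).
#' @param d Denominator (count), must be positive.
#' @param digits Decimal places; default chosen by `percent_digits()`.
#' @return `percent_value()`: numeric percentage; `percent_label()`:
#'   character like `"0.8"`.
#' @export
#' @examples
#' percent_value(84, 10316)   # 0.8
#' percent_value(125, 277)    # 45
#' percent_value(512, 19089)  # 2.7
percent_value <- function(n, d, digits = NULL) {
  if (any(d <= 0)) stop("denominator must be positive", call. = FALSE)
  p <- 100 * n / d
  if (is.null(digits)) digits <- percent_digits(p)
  round_half_away(p, digits)
}

#' @rdname percent_value
#' @param p Raw percentage value.
#' @export
percent_digits <- function(p) {
  ifelse(abs(p) >= 10, 0L, ifelse(abs(p) >= 0.1, 1L, 2L))
}

#' @rdname percent_value
#' @export
percent_label <- function(n, d, digits = NULL) {
  v <- percent_value(n, d, digits)
  if (is.null(digits)) digits <- percent_digits(100 * n / d)
  sprintf(paste0("%.", digits, "f"), v)
}

round_half_away <- function(x, digits = 0L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}
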