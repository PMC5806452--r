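# internal numeric/formatting helpers

#' Render a fraction as a whole percent
#'
#' Scores are carried as fractions (or 0-100 scores) at full precision
#' internally; rounding to whole percent happens only at the reporting
#' boundary, half away from zero, so 0.875 renders as 88 and 713/753 as 95.
#'
#' @param x numeric vector of fractions in `[0, 1]`.
#' @return integer vector of whole percents.
#' @export
#' @examples
#' percent(c(700 / 800, 713 / 753, 4 / 9))
percent <- function(x) {
  as.integer(sign(x) * floor(abs(x) * 100 + 0.5))
}

# round half away from zero at `digits` decimals (base round() is half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# sample SD that returns NA (not an error) for n < 2
sd_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(if (length(x) == 1) 0 else NA_real_)
  stats::sd(x)
}

mean_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  mean(x)
}

# weighted mean dropping pairs with NA value or NA/zero weight
wmean_or_na <- function(x, w) {
  keep <- !is.na(x) & !is.na(w) & w > 0
  if (!any(keep)) return(NA_real_)
  sum(x[keep] * w[keep]) / sum(w[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
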