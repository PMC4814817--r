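## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Harmonic number \eqn{a_n = \sum_{i=1}^{n} 1/i}
#' @param n non-negative integer
#' @return numeric
#' @keywords internal
harmonic <- function(n) {
  if (n <= 0) return(0)
  sum(1 / seq_len(n))
}

#' Round half-up to a fixed number of decimals
#'
#' Base [round()] uses round-half-to-even; printed report figures use
#' conventional half-up rounding, so percentages and ratios match the
#' values a reader computes by hand.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count relative to a denominator
#'
#' @param num numerator count
#' @param den denominator count, must be positive
#' @param decimals decimal places (half-up rounding)
#' @return numeric percentage on the 0-100 scale
#' @examples
#' percent_of(10312, 745814, 2) # 1.38
#' @export
percent_of <- function(num, den, decimals = 2) {
  if (length(den) != 1 || !is.finite(den) || den <= 0) {
    stop("percent_of(): denominator must be a single positive number")
  }
  round_half_up(100 * num / den, decimals)
}

## stop() with sprintf-style formatting, no call in message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.finite(x) && x >= 0 && x == floor(x)
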