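#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used by common spreadsheet and
#' statistics software when printing frequencies: 0.5 at the last kept digit
#' always rounds away from zero, unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep.
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(2.5)        # 3
#' round_half_up(13.85, 1)   # 13.9
#' @export
round_half_up <- function(x, digits = 0) {
  z <- x * 10^digits
  # the tiny offset only absorbs binary-representation error just below .5
  sign(z) * floor(abs(z) + 0.5 + 1e-9) / 10^digits
}

# order-independent key for an unordered drug pair
pair_sort <- function(a, b) {
  swap <- a > b
  list(a = ifelse(swap, b, a), b = ifelse(swap, a, b))
}

pair_key <- function(a, b) {
  p <- pair_sort(a, b)
  paste(p$a, p$b, sep = "\r")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# stop() without the call, with sprintf-style formatting
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
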