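#' Round half away from zero
#'
#' Nearest-integer rounding with halves rounded up (0.5 -> 1), unlike base
#' [round()], which rounds halves to even. Used for all reported percentages
#' so that printed category frequencies are reproduced exactly.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(100 * 50 / 122)  # 41
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' @keywords internal
assert_fraction <- function(x, name) {
  if (!is_scalar_number(x) || x < 0 || x > 1)
    stop2(name, " must be a single number in [0, 1]")
  x
}
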