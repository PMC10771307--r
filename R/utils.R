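#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for every percentage printed by
#' the summary tables: exact halves round away from zero, so 43.75 -> 43.8
#' at one decimal. Base R's `round()` rounds half to even and would print
#' 43.8 as 43.7 wherever the quotient lands on an exact half.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(43.75, 1) # 43.8
#' round_half_up(0.25, 1)  # 0.3
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Percentage with fixed decimal precision
#'
#' Shared percentage operation for all summary surfaces: `100 * count /
#' total`, rounded half-up to `digits` decimals.
#'
#' @param count integer vector of category counts, each in `[0, total]`.
#' @param total positive integer total (recycled against `count`).
#' @param digits decimal places (1 for tabular surfaces, 2 for the ranked
#'   reporting-proportion figures).
#' @return numeric vector of percentages.
#' @examples
#' percentage(476, 1088) # 43.8
#' percentage(117, 1088) # 10.8
#' @export
percentage <- function(count, total, digits = 1) {
  if (any(total <= 0)) {
    stop("`total` must be a positive count", call. = FALSE)
  }
  if (any(count < 0) || any(count > total)) {
    stop("`count` must lie in [0, total]", call. = FALSE)
  }
  round_half_up(100 * count / total, digits)
}

# Normalisation key used everywhere names are compared: case-folded,
# trimmed, internal whitespace collapsed.
fold_name <- function(x) {
  stringr::str_squish(stringr::str_to_lower(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
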