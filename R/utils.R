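# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# percent split of a non-negative count vector, rounded; all-zero input -> zeros
#' Percent split of counts
#'
#' Converts a vector of (possibly fractional) counts into percents of their
#' total, rounded to `digits` decimals. Used by every summary table in the
#' package so that per-class ratios are computed and rounded one way only.
#'
#' @param x numeric vector of non-negative counts.
#' @param digits decimals to round to (default 2).
#' @return numeric vector of percents summing to 100 within rounding;
#'   all zeros when `sum(x) == 0`.
#' @examples
#' count_percents(c(het = 9795.97, hom = 4012.28))
#' @export
count_percents <- function(x, digits = 2) {
  stopifnot(is.numeric(x), all(x >= 0 | is.na(x)))
  tot <- sum(x, na.rm = TRUE)
  if (tot == 0) return(round(x * 0, digits))
  round(100 * x / tot, digits)
}

position_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

stop_input <- function(...) stop(sprintf(...), call. = FALSE)
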