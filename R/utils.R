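#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for the report-table percentages
#' and mean peak lengths. Base R's `round()` rounds half to even, which would
#' turn e.g. 0.125 into 0.12 at two digits.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits to keep.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @examples
#' round_half_up(97.265, 2)   # 97.27
#' round_half_up(1350.5, 0)   # 1351
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# internal: stop() with the calling function's name stripped from the message
abort <- function(...) stop(..., call. = FALSE)

# internal: assert a scalar positive number
check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    abort(sprintf("'%s' must be a single positive finite number", name))
  invisible(x)
}

#' The seven genomic feature classes
#'
#' Fixed label set of the genome partition, in reporting order.
#' @return character vector of the seven class names.
#' @export
feature_classes <- function() {
  c("promoter", "utr5", "cds", "intron", "utr3", "downstream", "intergenic")
}

# internal: default label priority when gene annotations overlap
default_priority <- function() {
  c("promoter", "utr5", "cds", "utr3", "downstream", "intron")
}
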