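#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; published tables in this field are
#' conventionally rounded half-up, which is what the per-species proportion
#' report uses.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_up(2.345, 2) # 2.35
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stopf <- function(fmt, ...) rlang::abort(sprintf(fmt, ...))

`%||%` <- rlang::`%||%`

# Width of the union of 1-based inclusive integer intervals, optionally
# clipped to [lo, hi]. Degenerate/empty input gives 0.
interval_union_width <- function(start, end, lo = NULL, hi = NULL) {
  keep <- !is.na(start) & !is.na(end) & end >= start
  start <- start[keep]; end <- end[keep]
  if (!is.null(lo)) {
    end <- pmin(end, hi)
    start <- pmax(start, lo)
    keep <- end >= start
    start <- start[keep]; end <- end[keep]
  }
  if (length(start) == 0L) return(0)
  r <- IRanges::reduce(IRanges::IRanges(start = start, end = end))
  sum(IRanges::width(r))
}

# Validate that required columns are present in a data frame.
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stopf("%s is missing column(s): %s", what, paste(missing, collapse = ", "))
  }
  invisible(df)
}
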