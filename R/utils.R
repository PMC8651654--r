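#' Centred boxcar (moving-average) smoothing with edge truncation
#'
#' Windows are centred on each frame and truncated at the trace edges, so the
#' output has the same length as the input and no padding value is invented.
#' For even window sizes the window extends one frame further to the right.
#'
#' @param x numeric vector.
#' @param k window size in frames (`k = 1` returns `x` unchanged).
#' @return numeric vector of the same length as `x`.
#' @export
boxcar_smooth <- function(x, k) {
  stopifnot(is.numeric(x), k >= 1)
  n <- length(x)
  if (k == 1 || n == 0) return(x)
  lo <- floor((k - 1) / 2)
  hi <- ceiling((k - 1) / 2)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  a <- pmax(i - lo, 1L)
  b <- pmin(i + hi, n)
  (cs[b + 1] - cs[a]) / (b - a + 1)
}

#' Rolling percentile over a truncated centred window
#'
#' @param x numeric vector.
#' @param halfwidth half window width in frames; the window at frame `i` is
#'   `[i - halfwidth, i + halfwidth]` clipped to the trace.
#' @param p percentile in `[0, 1]`; linear interpolation between order
#'   statistics (the `stats::quantile()` default definition).
#' @return numeric vector of per-frame window percentiles.
#' @export
rolling_percentile <- function(x, halfwidth, p) {
  stopifnot(is.numeric(x), halfwidth >= 0, p >= 0, p <= 1)
  roll_quantile_trunc(as.numeric(x), as.integer(halfwidth), as.numeric(p))
}

# runs of TRUE in a logical vector -> data.frame(start, end) (1-based, inclusive)
true_runs <- function(mask) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# let data.table's `[` keep data.table semantics inside this package
.datatable.aware <- TRUE

stop_if_not_scalar_pos <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(what, " must be a positive scalar", call. = FALSE)
  invisible(x)
}
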