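#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals do not disturb
#' the caller's RNG stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Snap a value expected to sit on an integer grid; tolerance absorbs the
# float error of second->bin conversions at 20 Hz.
snap_int <- function(x, tol = 1e-6) {
  r <- round(x)
  if (any(abs(x - r) > tol)) {
    stop("value not on the bin grid: ", paste(x[abs(x - r) > tol], collapse = ", "))
  }
  as.integer(r)
}

#' Bin indices covered by a time interval
#'
#' A bin belongs to the half-open epoch `[start, end)` iff its left edge lies
#' in the interval (0-based bins of width `1/bin_rate`); returned as 1-based
#' R indices clipped to `[1, n_bins]`.
#'
#' @param start,end Epoch boundaries in seconds.
#' @param bin_rate Bins per second.
#' @param n_bins Total number of bins available.
#' @return Integer vector of bin indices (possibly empty).
#' @keywords internal
epoch_bins <- function(start, end, bin_rate, n_bins) {
  i0 <- ceiling(start * bin_rate - 1e-6)   # first 0-based left edge >= start
  i1 <- ceiling(end * bin_rate - 1e-6) - 1 # last 0-based left edge < end
  i0 <- max(i0, 0)
  i1 <- min(i1, n_bins - 1)
  if (i1 < i0) return(integer(0))
  seq.int(i0, i1) + 1L
}
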