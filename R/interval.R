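#' Construct a finite interval
#'
#' Intervals appear in two roles throughout the package: the moment interval
#' `[a, b]` over which raw moments are taken, and the validity interval
#' `[a', b']` on which a fitted polynomial is required to be a genuine density
#' (nonnegative, unit mass). The two need not coincide.
#'
#' @param lo,hi Finite endpoints with `lo < hi`.
#' @return A numeric vector of length two with class `"interval"`.
#' @examples
#' interval(0, 5)
#' @export
interval <- function(lo, hi) {
  if (!is.numeric(lo) || !is.numeric(hi) || length(lo) != 1L || length(hi) != 1L)
    stop("interval endpoints must be numeric scalars", call. = FALSE)
  if (!is.finite(lo) || !is.finite(hi))
    stop("interval endpoints must be finite", call. = FALSE)
  if (lo >= hi)
    stop(sprintf("invalid interval: lo (%g) must be strictly below hi (%g)", lo, hi),
         call. = FALSE)
  structure(c(lo = lo, hi = hi), class = "interval")
}

#' @export
print.interval <- function(x, ...) {
  cat(sprintf("[%g, %g]\n", x[[1L]], x[[2L]]))
  invisible(x)
}

as_interval <- function(x) {
  if (inherits(x, "interval")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(interval(x[[1L]], x[[2L]]))
  stop("expected an interval or a numeric vector of length 2", call. = FALSE)
}

interval_lo <- function(x) unname(x[[1L]])
interval_hi <- function(x) unname(x[[2L]])
interval_width <- function(x) unname(x[[2L]] - x[[1L]])
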