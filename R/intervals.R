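#' Interval utilities (0-based, half-open)
#'
#' All genomic arithmetic in the package runs on plain two-column integer
#' matrices of 0-based half-open intervals. IRanges does the heavy lifting;
#' these helpers only translate between the two coordinate conventions.
#'
#' @param start,end integer vectors of interval bounds (0-based half-open).
#' @return `iv()` returns an n x 2 integer matrix with columns `start`, `end`.
#' @keywords internal
iv <- function(start = integer(0), end = integer(0)) {
  m <- cbind(start = as.integer(start), end = as.integer(end))
  if (nrow(m) && any(m[, 2] < m[, 1])) stop("interval end < start")
  m
}

iv_empty <- function() iv()

iv_to_ir <- function(m) {
  if (is.null(m) || nrow(m) == 0) return(IRanges::IRanges())
  IRanges::IRanges(start = m[, 1] + 1L, end = m[, 2])
}

ir_to_iv <- function(r) {
  iv(IRanges::start(r) - 1L, IRanges::end(r))
}

#' @keywords internal
iv_reduce <- function(m) ir_to_iv(IRanges::reduce(iv_to_ir(m)))

#' @keywords internal
iv_length <- function(m) {
  if (is.null(m) || nrow(m) == 0) return(0L)
  sum(m[, 2] - m[, 1])
}

#' @keywords internal
iv_intersect <- function(a, b) {
  ir_to_iv(IRanges::intersect(iv_to_ir(a), iv_to_ir(b)))
}

#' @keywords internal
iv_setdiff <- function(a, b) {
  ir_to_iv(IRanges::setdiff(iv_to_ir(a), iv_to_ir(b)))
}

#' @keywords internal
iv_overlap_length <- function(a, b) iv_length(iv_intersect(a, b))

#' @keywords internal
iv_overlaps <- function(a, b) iv_overlap_length(a, b) > 0L

#' Disjoint sorted interval set with cached total length
#'
#' The container used for counting regions and mask windows.
#'
#' @param intervals two-column matrix of 0-based half-open intervals.
#' @param flagged logical; `TRUE` when the region is degenerate (e.g. the end
#'   masks consumed the whole CDS) and the gene must be excluded from counting.
#' @return an object of class `IntervalSet` with elements `intervals`
#'   (disjoint, sorted) and `total_length`.
#' @export
interval_set <- function(intervals = iv_empty(), flagged = FALSE) {
  intervals <- iv_reduce(intervals)
  structure(
    list(intervals = intervals, total_length = iv_length(intervals),
         flagged = flagged),
    class = "IntervalSet"
  )
}

#' @export
print.IntervalSet <- function(x, ...) {
  cat("IntervalSet:", nrow(x$intervals), "interval(s),",
      x$total_length, "nt", if (x$flagged) "[flagged]" else "", "\n")
  invisible(x)
}
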