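#' Centered moving-average smoother with shrinking edge windows
#'
#' Smooths a numeric series with a centered moving average of the given
#' width. Near the edges the window shrinks symmetrically so that every
#' output point is an average of observed values only (no padding), which
#' preserves a constant series exactly.
#'
#' @param x numeric vector.
#' @param window integer window width in points (default 10). Even widths
#'   use \code{floor((window - 1) / 2)} points before and
#'   \code{floor(window / 2)} after the center.
#' @return numeric vector of the same length as \code{x}.
#' @export
moving_average <- function(x, window = 10L) {
  stopifnot(is.numeric(x), length(window) == 1L, window >= 1)
  n <- length(x)
  if (n == 0L || window == 1L) return(x)
  before <- floor((window - 1) / 2)
  after  <- floor(window / 2)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - before)
    hi <- min(n, i + after)
    mean(x[lo:hi])
  }, numeric(1))
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
stop_input <- function(...) {
  stop(structure(class = c("phytowave_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' @keywords internal
#' @noRd
assert_increasing <- function(x, name = "times") {
  if (any(diff(x) <= 0)) stop_input(name, " must be strictly increasing")
  invisible(x)
}
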