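#' Knee-point detection on a descending curve
#'
#' Kneedle-style knee detection for a ranked, descending sequence of values
#' (e.g. feature importances or mean distances sorted high to low). Both axes
#' are min-max normalized and the knee is the index maximizing the vertical
#' gap between the anti-diagonal `1 - x` and the normalized curve — the point
#' where the curve bends from steep to flat. Exactly linear inputs have no
#' knee.
#'
#' @param values numeric vector sorted in descending order (>= 5 values).
#' @param sensitivity minimum normalized gap for a knee to be declared.
#' @return Integer index of the knee, or `NULL` when the curve is straight.
#' @export
find_inflection <- function(values, sensitivity = 1e-6) {
  values <- as.numeric(values)
  if (length(values) < 5) stop("need >= 5 values")
  if (is.unsorted(rev(values))) {
    # tolerate numerical jitter but not genuinely increasing input
    if (any(diff(values) > 1e-9 * max(abs(values), 1))) {
      stop("`values` must be sorted in descending order")
    }
  }
  n <- length(values)
  rng <- max(values) - min(values)
  if (rng <= 0) return(NULL)
  y <- (values - min(values)) / rng
  x <- (seq_len(n) - 1) / (n - 1)
  gap <- (1 - x) - y
  if (max(gap) <= sensitivity) return(NULL)
  which.max(gap)
}
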