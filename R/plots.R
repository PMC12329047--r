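#' Plot an alignment result
#'
#' Pseudotime density of aligned cells colored by stage, with status counts
#' in the subtitle.
#'
#' @param object a [ptalign_align()] tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ptalign_alignment <- function(object, ...) {
  aligned <- dplyr::filter(object, .data$status == "aligned")
  counts <- table(object$status)
  ggplot2::ggplot(aligned, ggplot2::aes(x = .data$pseudotime,
                                        fill = .data$stage)) +
    ggplot2::geom_histogram(bins = 40, boundary = 0) +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(
      x = "aligned pseudotime", y = "cells",
      subtitle = paste(names(counts), as.integer(counts),
                       sep = ": ", collapse = ", ")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a DTW correlation matrix with its traceback path
#'
#' @param object a `ptx_dtw` from [traceback_max_correlation()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ptx_dtw <- function(object, ...) {
  m <- object$matrix
  df <- tidyr::expand_grid(ref_bin = seq_len(nrow(m)),
                           query_bin = seq_len(ncol(m)))
  df$correlation <- m[cbind(df$ref_bin, df$query_bin)]
  path <- tibble(ref_bin = object$path[, 1], query_bin = object$path[, 2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$query_bin, y = .data$ref_bin)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$correlation)) +
    ggplot2::geom_path(data = path, color = "black", linewidth = 0.8) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "query bin", y = "reference bin") +
    ggplot2::theme_minimal()
}

#' Plot simulated population dynamics
#'
#' Stage abundances over time on a log scale, with tE and tD marked.
#'
#' @param object a `ptx_simulation` from [simulate_growth()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ptx_simulation <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trajectory, c("Q", "A", "D"),
                              names_to = "stage", values_to = "cells")
  long$stage <- factor(long$stage, levels = c("Q", "A", "D"))
  long <- long[long$cells > 0, ]  # log scale

  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$cells,
                                          color = .data$stage)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (division units)", y = "cells") +
    ggplot2::theme_minimal()
  if (!is.na(object$tE)) {
    p <- p + ggplot2::geom_vline(xintercept = object$tE, linetype = "dashed")
  }
  if (!is.na(object$tD)) {
    p <- p + ggplot2::geom_vline(xintercept = object$tD, linetype = "dotted")
  }
  p
}

#' Plot expression dynamics curves
#'
#' @param splines named list of `ptx_spline` objects (names become the
#'   legend).
#' @param normalized plot unit-area curves (default) or raw values.
#' @return A ggplot object.
#' @export
plot_dynamics <- function(splines, normalized = TRUE) {
  rows <- lapply(names(splines), function(nm) {
    s <- splines[[nm]]
    v <- if (normalized && s$expressed) s$normalized else s$values
    tibble(curve = nm, pseudotime = s$grid, value = v)
  })
  df <- dplyr::bind_rows(rows)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pseudotime, y = .data$value,
                                   color = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = if (normalized) "density" else "expression") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
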