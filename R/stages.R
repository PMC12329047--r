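#' Stage boundaries along lineage pseudotime
#'
#' Pseudotime cutpoints separating the dormant, quiescent (Q), active (A) and
#' differentiated (D) compartments of a non-branching stem-cell lineage.
#' Defaults are the published v-SVZ reference cutoffs: quiescence spans
#' pseudotime 0-0.282 (0-0.141 dormant astrocytic), activation 0.282-0.676,
#' differentiation beyond 0.676.
#'
#' @param b_dormant dormant/quiescent boundary.
#' @param b_qa quiescence/activation boundary.
#' @param b_ad activation/differentiation boundary.
#' @return A `ptx_boundaries` object.
#' @export
stage_boundaries <- function(b_dormant = 0.141, b_qa = 0.282, b_ad = 0.676) {
  if (!(0 < b_dormant && b_dormant < b_qa && b_qa < b_ad && b_ad < 1)) {
    stop("require 0 < b_dormant < b_qa < b_ad < 1")
  }
  structure(list(b_dormant = b_dormant, b_qa = b_qa, b_ad = b_ad),
            class = "ptx_boundaries")
}

#' @export
print.ptx_boundaries <- function(x, ...) {
  cat(sprintf("<stage boundaries> dormant<%.3f | Q<%.3f | A<=%.3f | D>%.3f\n",
              x$b_dormant, x$b_qa, x$b_ad, x$b_ad))
  invisible(x)
}

#' Detect stage boundaries from the pseudotime density
#'
#' Fits a Gaussian KDE (Scott's bandwidth rule, 1001-point grid over `[0,1]`)
#' to the non-cycling pseudotime sample and places the Q/A and A/D boundaries
#' at the density minima between the first three density modes. Duplicate
#' pseudotime values are collapsed before the fit, so the result depends only
#' on the set of distinct pseudotimes. The dormant boundary is not
#' identifiable from a three-mode density and is kept at its default.
#'
#' @param pseudotimes numeric vector in `[0,1]`.
#' @param bandwidth `"scott"` or a positive numeric bandwidth.
#' @param b_dormant dormant boundary carried into the result.
#' @return A `ptx_boundaries` object.
#' @export
detect_stage_boundaries <- function(pseudotimes, bandwidth = "scott",
                                    b_dormant = 0.141) {
  pt <- unique(as.numeric(pseudotimes))
  pt <- pt[is.finite(pt)]
  if (any(pt < 0 | pt > 1)) stop("pseudotimes must lie in [0,1]")
  bw <- if (identical(bandwidth, "scott")) stats::bw.nrd(pt) else as.numeric(bandwidth)
  d <- density(pt, bw = bw, n = 1001, from = 0, to = 1)
  y <- d$y
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n], FALSE)
  modes <- which(is_max)
  if (length(modes) < 3) {
    stop("fewer than 3 pseudotime density modes; use default boundaries ",
         "(0.141, 0.282, 0.676)")
  }
  modes <- modes[1:3]
  min_between <- function(i, j) {
    seg <- i:j
    d$x[seg[which.min(y[seg])]]
  }
  b_qa <- min_between(modes[1], modes[2])
  b_ad <- min_between(modes[2], modes[3])
  if (b_dormant >= b_qa) b_dormant <- b_qa / 2
  stage_boundaries(b_dormant = b_dormant, b_qa = b_qa, b_ad = b_ad)
}

#' Assign QAD stages from pseudotime
#'
#' Maps pseudotimes to lineage stages under the boundary convention:
#' Q for `pt < b_qa` (with the dormant sub-label for `pt < b_dormant`),
#' A for `b_qa <= pt <= b_ad` (closed interval), D for `pt > b_ad`.
#'
#' @param pt numeric vector of pseudotimes in `[0,1]` (`NA` allowed).
#' @param boundaries a [stage_boundaries()] object.
#' @return A tibble with columns `pseudotime`, `stage` (factor Q/A/D) and
#'   `dormant` (logical sub-label within Q).
#' @export
assign_stages <- function(pt, boundaries = stage_boundaries()) {
  pt <- as.numeric(pt)
  ok <- !is.na(pt)
  if (any(pt[ok] < 0 | pt[ok] > 1)) stop("pseudotime outside [0,1]")
  stage <- rep(NA_character_, length(pt))
  stage[ok & pt < boundaries$b_qa] <- "Q"
  stage[ok & pt >= boundaries$b_qa & pt <= boundaries$b_ad] <- "A"
  stage[ok & pt > boundaries$b_ad] <- "D"
  tibble(
    pseudotime = pt,
    stage = factor(stage, levels = c("Q", "A", "D")),
    dormant = ifelse(ok, pt < boundaries$b_dormant & pt < boundaries$b_qa, NA)
  )
}
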