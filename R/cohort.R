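#' Specificity-based biomarker cut point
#'
#' Computes a cut point as a high percentile of a disease-free reference
#' distribution, so that only a small fraction of unaffected individuals
#' exceed it. The default convention is the linear-interpolation quantile
#' between order statistics, \code{q = x_(1 + (n - 1) p)} on the sorted
#' sample (the sorted sequence 1..100 at the 95th percentile gives 95.05).
#'
#' @param reference_volumes numeric vector of reference values (e.g. WMH
#'   volumes in mm^3 from cognitively intact individuals); at least 20
#'   non-negative values.
#' @param percentile percentile in (0, 100), default 95.
#' @param type quantile convention passed to \code{stats::quantile}
#'   (default 7, the linear-interpolation rule above).
#' @return An object of class \code{cut_point}: list with \code{value},
#'   \code{percentile}, \code{n_reference}, \code{method}.
#' @export
compute_cutpoint <- function(reference_volumes, percentile = 95, type = 7) {
  v <- reference_volumes[!is.na(reference_volumes)]
  if (length(v) < 20)
    stop("insufficient reference sample: need >= 20 values, got ",
         length(v), call. = FALSE)
  if (any(v < 0)) stop("reference volumes must be >= 0", call. = FALSE)
  if (percentile <= 0 || percentile > 100)
    stop("`percentile` must be in (0, 100]", call. = FALSE)
  q <- unname(stats::quantile(v, percentile / 100, type = type))
  structure(list(value = q, percentile = percentile,
                 n_reference = length(v),
                 method = paste0("quantile type ", type)),
            class = "cut_point")
}

#' @export
print.cut_point <- function(x, ...) {
  cat(sprintf("Cut point: %.6g (%gth percentile of %d reference values, %s)\n",
              x$value, x$percentile, x$n_reference, x$method))
  invisible(x)
}

#' Dichotomize a cohort by a biomarker cut point
#'
#' Label 1 for volumes strictly above the cut value, 0 otherwise: a value
#' exactly at the cut goes to the lower group. In the WMH application
#' label 1 is the vascular (vMCI) group.
#'
#' @param volumes numeric vector of per-subject volumes (>= 0).
#' @param cut a \code{cut_point} or a single numeric cut value.
#' @return Integer 0/1 labels with attribute \code{"counts"} (table of
#'   group sizes). A warning is issued when either group is empty.
#' @export
assign_groups <- function(volumes, cut) {
  value <- if (inherits(cut, "cut_point")) cut$value else cut
  stopifnot(is.numeric(value), length(value) == 1L)
  if (any(volumes < 0, na.rm = TRUE))
    stop("volumes must be >= 0", call. = FALSE)
  labels <- as.integer(volumes > value)
  counts <- table(factor(labels, levels = c(0L, 1L)))
  if (any(counts == 0L))
    warning("one group is empty; downstream group tests are undefined",
            call. = FALSE)
  attr(labels, "counts") <- counts
  labels
}
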