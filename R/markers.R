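#' Cluster-average power marker
#'
#' Reduces a cluster to one scalar per subject: the mean relative power
#' over all (node, frequency-bin) cells of the cluster. These markers are
#' the interface between the cluster inference and scalar statistics
#' (group tests, score correlations).
#'
#' @param power a \code{power_matrix} or node x freq x subject array.
#' @param cluster a cluster from a \code{\link{cbpt}} fit (a list with a
#'   \code{cells} matrix), or a cells matrix directly.
#' @param node_ids node ids labelling the power rows (defaults to the ids
#'   stored in the \code{power_matrix}, else \code{1:n_nodes}).
#' @return Numeric vector, one marker value per subject.
#' @export
extract_marker <- function(power, cluster, node_ids = NULL) {
  arr <- as_power_array(power)
  cells <- if (is.matrix(cluster)) cluster else cluster$cells
  if (is.null(cells) || nrow(cells) == 0L)
    stop("empty cluster", call. = FALSE)
  if (is.null(node_ids)) node_ids <- seq_len(dim(arr)[1])
  rows <- match(cells[, "node"], node_ids)
  if (anyNA(rows) || any(cells[, "freq_bin"] < 1L) ||
      any(cells[, "freq_bin"] > dim(arr)[2]))
    stop("cluster cells outside the power matrix", call. = FALSE)
  idx <- rows + (cells[, "freq_bin"] - 1L) * dim(arr)[1]
  apply(arr, 3L, function(m) mean(m[idx]))
}

#' Spearman association between a marker and a score
#'
#' Average-rank Spearman correlation with a two-sided p-value from the t
#' approximation on n - 2 degrees of freedom. Pairs with a missing value
#' in either input are dropped listwise.
#'
#' @param marker,score paired numeric vectors.
#' @param marker_name,score_name labels carried into the result.
#' @return List of class \code{association_result}: \code{marker},
#'   \code{score}, \code{rho}, \code{p_value}, \code{n}.
#' @export
spearman_assoc <- function(marker, score, marker_name = "marker",
                           score_name = "score") {
  ok <- stats::complete.cases(marker, score)
  x <- marker[ok]; y <- score[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input", call. = FALSE)
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), n - 2)
  }
  structure(list(marker = marker_name, score = score_name, rho = rho,
                 p_value = p, n = n), class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s ~ %s: Spearman rho = %.3f, p = %.4g (n = %d)\n",
              x$marker, x$score, x$rho, x$p_value, x$n))
  invisible(x)
}

#' Scalar group comparison with optional covariate adjustment
#'
#' The same nested-model F statistic as the per-cell CBPT engine, applied
#' to one scalar outcome: full model \code{value ~ group + covariates}
#' against the reduced model without \code{group}. With an empty covariate
#' list this is a one-way ANOVA (and equals the squared two-sample t
#' statistic). The effect size is the partial eta squared
#' \code{SS_effect / (SS_effect + SSE_full)}.
#'
#' @param values numeric outcome, one per subject.
#' @param design design data.frame with \code{group} and any covariates.
#' @param covariates character vector of covariate names (may be empty).
#' @return List with \code{F}, \code{p_value}, \code{eta_squared},
#'   \code{df}.
#' @export
scalar_group_test <- function(values, design,
                              covariates = c("age", "wm_volume")) {
  stopifnot(length(values) == nrow(design))
  Y <- matrix(as.numeric(values), ncol = 1L)
  eng <- make_ancova_engine(Y, design, covariates)
  r <- eng(as.numeric(design$group))
  df2 <- r$df[2]
  f <- r$F[1]
  # recover SS ratio for eta^2: F = (SS_eff / 1) / (SSE_full / df2)
  eta2 <- if (is.infinite(f)) 1 else if (f == 0) 0 else f / (f + df2)
  p <- if (is.infinite(f)) 0 else stats::pf(f, 1, df2, lower.tail = FALSE)
  list(F = f, p_value = p, eta_squared = eta2, df = c(1L, df2))
}

#' Marker-by-score association report
#'
#' For every surviving cluster marker and every score column: the Spearman
#' correlation with its p-value; plus, per marker, the covariate-adjusted
#' group ANCOVA. P-values are uncorrected by default; set
#' \code{p_adjust = "BH"} (or any \code{stats::p.adjust} method) to adjust
#' the correlation p-values across the whole table.
#'
#' @param markers data.frame or matrix of marker values (one column per
#'   cluster, one row per subject).
#' @param scores data.frame of score columns, same subjects.
#' @param design design data.frame with \code{group} and covariates.
#' @param covariates covariate names for the per-marker group test.
#' @param p_adjust multiplicity correction method, default \code{"none"}.
#' @return List of class \code{association_report} with
#'   \code{associations} (data.frame: marker, score, n, rho, p_value, and
#'   p_adjusted when requested), \code{group_tests} (data.frame: marker,
#'   F, p_value, eta_squared), and \code{sign_summary} (dominant
#'   correlation sign per marker).
#' @export
association_report <- function(markers, scores, design,
                               covariates = c("age", "wm_volume"),
                               p_adjust = "none") {
  markers <- as.data.frame(markers)
  scores <- as.data.frame(scores)
  stopifnot(nrow(markers) == nrow(scores),
            nrow(markers) == nrow(design))
  rows <- list()
  for (m in names(markers)) for (s in names(scores)) {
    a <- spearman_assoc(markers[[m]], scores[[s]], m, s)
    rows[[length(rows) + 1L]] <-
      data.frame(marker = m, score = s, n = a$n, rho = a$rho,
                 p_value = a$p_value)
  }
  assoc <- do.call(rbind, rows)
  if (p_adjust != "none")
    assoc$p_adjusted <- stats::p.adjust(assoc$p_value, method = p_adjust)
  gt <- do.call(rbind, lapply(names(markers), function(m) {
    r <- scalar_group_test(markers[[m]], design, covariates)
    data.frame(marker = m, F = r$F, p_value = r$p_value,
               eta_squared = r$eta_squared)
  }))
  sign_summary <- vapply(names(markers), function(m) {
    rh <- assoc$rho[assoc$marker == m]
    if (all(rh == 0)) 0 else sign(sum(sign(rh)))
  }, numeric(1))
  structure(list(associations = assoc, group_tests = gt,
                 sign_summary = sign_summary),
            class = "association_report")
}

#' @export
print.association_report <- function(x, ...) {
  cat("Marker-score associations (Spearman):\n")
  print(x$associations, row.names = FALSE, digits = 3)
  cat("\nPer-marker group ANCOVA:\n")
  print(x$group_tests, row.names = FALSE, digits = 4)
  invisible(x)
}
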