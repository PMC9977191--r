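#' Run the full analysis pipeline on a synthetic or ingested cohort
#'
#' Chains the package's stages in study order: cohort simulation (or
#' ingestion from a directory written by \code{\link{write_cohort}}),
#' input validation, specificity-based cut point on a reference volume
#' sample, dichotomization of the cohort by WMH volume, the
#' cluster-based permutation test, and marker extraction with score
#' associations for the significant clusters. Every stage's parameters
#' and seeds are echoed into a manifest so a run can be reproduced
#' bit-identically.
#'
#' @param sim a \code{\link{sim_config}} describing the cohort to
#'   simulate, or a directory path to ingest.
#' @param cbpt_cfg a \code{\link{cbpt_config}}.
#' @param reference_volumes reference sample for the cut point; default
#'   simulates 346 volumes with \code{\link{simulate_reference_volumes}}
#'   seeded from \code{cbpt_cfg$seed}.
#' @param percentile cut-point percentile (default 95).
#' @param score_cols score columns for the association report; defaults to
#'   the generator's score set intersected with the covariate table.
#' @param out optional directory; when given, the cohort, cluster table,
#'   association table and manifest are written there as text files.
#' @return List of class \code{pipeline_result}: \code{cohort},
#'   \code{validation}, \code{cutpoint}, \code{design} (with assigned
#'   groups), \code{fit} (the \code{cbpt_fit}), \code{markers},
#'   \code{associations}, \code{manifest}.
#' @export
run_pipeline <- function(sim, cbpt_cfg = cbpt_config(),
                         reference_volumes = NULL, percentile = 95,
                         score_cols = NULL, out = NULL) {
  cohort <- if (is.character(sim)) read_cohort(sim)
            else simulate_cohort(sim)
  validation <- validate_inputs(cohort$power, cohort$covariates,
                                required = c("age", "wm_volume",
                                             "wmh_volume"))
  if (!attr(validation, "ok"))
    stop("input validation failed:\n",
         paste(utils::capture.output(print(validation)), collapse = "\n"),
         call. = FALSE)
  if (is.null(reference_volumes))
    reference_volumes <- simulate_reference_volumes(346,
                                                    seed = cbpt_cfg$seed)
  cutpoint <- compute_cutpoint(reference_volumes, percentile)
  design <- cohort$covariates
  design$group <- assign_groups(design$wmh_volume, cutpoint)
  fit <- cbpt(cohort$power, design, cohort$space, cbpt_cfg)

  sig <- Filter(function(cl) cl$significant, fit$clusters)
  markers <- NULL; associations <- NULL
  if (length(sig)) {
    markers <- as.data.frame(lapply(sig, function(cl)
      extract_marker(cohort$power, cl, node_ids = fit$node_ids)))
    names(markers) <- vapply(sig, `[[`, character(1), "marker_name")
    if (is.null(score_cols))
      score_cols <- intersect(c("mmse", "immediate_recall",
                                "delayed_recall", "digit_backward",
                                "semantic_fluency", "lhv", "rhv"),
                              names(cohort$covariates))
    if (length(score_cols))
      associations <- association_report(markers,
                                         cohort$covariates[, score_cols,
                                                           drop = FALSE],
                                         design)
  }
  manifest <- list(
    simulated = !is.character(sim),
    sim_config = if (!is.character(sim)) unclass(sim) else sim,
    cbpt_config = unclass(cbpt_cfg),
    cutpoint = unclass(cutpoint),
    percentile = percentile,
    n_reference = length(reference_volumes),
    group_counts = as.list(table(design$group)),
    n_clusters = length(fit$clusters),
    n_significant = length(sig),
    package_version = as.character(utils::packageVersion("megclust")))
  res <- structure(list(cohort = cohort, validation = validation,
                        cutpoint = cutpoint, design = design, fit = fit,
                        markers = markers, associations = associations,
                        manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(out)) {
    if (!dir.exists(out)) dir.create(out, recursive = TRUE)
    write_cohort(cohort, file.path(out, "cohort"))
    utils::write.csv(summary(fit)$clusters,
                     file.path(out, "clusters.csv"), row.names = FALSE)
    if (!is.null(associations))
      utils::write.csv(associations$associations,
                       file.path(out, "associations.csv"),
                       row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n")
  print(x$cutpoint)
  counts <- table(x$design$group)
  cat(sprintf("Groups by cut point: %d below (label 0), %d above (label 1)\n",
              counts["0"], counts["1"]))
  print(x$fit)
  if (!is.null(x$associations)) {
    cat("\n")
    print(x$associations)
  }
  invisible(x)
}
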