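# Plain-text cohort container: power matrix, geometry and tables are
# written as CSV, ground truth and metadata as JSON. The layout mirrors
# the array container used upstream (power[node, freq, subject], freqs,
# coords, adjacency edge list, covariate table).

#' Write a cohort to a directory of text files
#'
#' @param cohort list as returned by \code{\link{simulate_cohort}}
#'   (elements \code{power}, \code{covariates}, \code{space}; optional
#'   \code{truth}).
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  arr <- cohort$power$power
  d <- dim(arr)
  flat <- matrix(arr, d[1] * d[2], d[3])
  colnames(flat) <- cohort$power$subjects
  utils::write.csv(flat, file.path(dir, "power.csv"), row.names = FALSE)
  utils::write.csv(data.frame(freq_hz = cohort$power$freqs),
                   file.path(dir, "freqs.csv"), row.names = FALSE)
  sp <- cohort$space
  geom <- data.frame(node_id = sp$node_ids, sp$coords)
  if (!is.null(sp$roi_labels)) geom$roi <- sp$roi_labels
  utils::write.csv(geom, file.path(dir, "coords.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(sp$adjacency),
                   file.path(dir, "adjacency.csv"), row.names = FALSE)
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  meta <- list(n_nodes = d[1], n_freqs = d[2], n_subjects = d[3],
               spacing = sp$spacing)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(cohort$truth)) {
    tr <- cohort$truth
    tr$effects <- lapply(tr$effects, function(e)
      list(cells = apply(e$cells, 2, as.integer),
           nodes = as.integer(e$nodes), sign = e$sign))
    jsonlite::write_json(tr, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a cohort written by \code{\link{write_cohort}}
#'
#' @param dir directory containing the cohort files.
#' @return List with \code{power} (a \code{power_matrix}),
#'   \code{covariates}, \code{space}, and \code{truth} when present.
#' @export
read_cohort <- function(dir) {
  need <- c("power.csv", "freqs.csv", "coords.csv", "adjacency.csv",
            "covariates.csv", "meta.json")
  paths <- file.path(dir, need)
  if (!all(file.exists(paths)))
    stop("missing cohort file(s): ",
         paste(need[!file.exists(paths)], collapse = ", "), call. = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  flat <- as.matrix(utils::read.csv(file.path(dir, "power.csv"),
                                    check.names = FALSE))
  freqs <- utils::read.csv(file.path(dir, "freqs.csv"))$freq_hz
  arr <- array(flat, dim = c(meta$n_nodes, meta$n_freqs, meta$n_subjects))
  geom <- utils::read.csv(file.path(dir, "coords.csv"))
  adj <- as.matrix(utils::read.csv(file.path(dir, "adjacency.csv")))
  storage.mode(adj) <- "integer"
  space <- structure(list(node_ids = as.integer(geom$node_id),
                          coords = as.matrix(geom[, c("x", "y", "z")]),
                          spacing = meta$spacing,
                          roi_labels = if ("roi" %in% names(geom))
                            as.character(geom$roi) else NULL,
                          adjacency = adj),
                     class = "source_space")
  covariates <- utils::read.csv(file.path(dir, "covariates.csv"))
  power <- structure(list(power = arr, freqs = freqs,
                          subjects = colnames(flat)),
                     class = "power_matrix")
  out <- list(power = power, covariates = covariates, space = space)
  tpath <- file.path(dir, "truth.json")
  if (file.exists(tpath)) {
    tr <- jsonlite::read_json(tpath, simplifyVector = TRUE)
    tr$effects <- lapply(tr$effects, function(e) {
      cells <- matrix(as.integer(as.matrix(e$cells)), ncol = 2)
      colnames(cells) <- c("node", "freq_bin")
      list(cells = cells, nodes = as.integer(e$nodes),
           sign = as.integer(e$sign))
    })
    out$truth <- tr
  }
  out
}

#' Validate a cohort's inputs for analysis
#'
#' Checks that the power array and covariate table describe the same
#' subjects, that every per-node per-subject spectrum is normalised over
#' the band (sum 1 within tolerance), and that the covariates needed for
#' adjustment are complete.
#'
#' @param power a \code{power_matrix}.
#' @param covariates covariate data.frame.
#' @param required character vector of required covariate columns.
#' @param tol tolerance on band sums (default 1e-9).
#' @return Data.frame of class \code{validation_report} with columns
#'   \code{check}, \code{pass}, \code{detail}; attribute \code{"ok"} is
#'   \code{TRUE} iff every check passed.
#' @export
validate_inputs <- function(power, covariates,
                            required = c("group", "age", "wm_volume"),
                            tol = 1e-9) {
  checks <- list()
  add <- function(name, pass, detail = "")
    checks[[length(checks) + 1L]] <<- data.frame(check = name, pass = pass,
                                                 detail = detail)
  arr <- as_power_array(power)
  d <- dim(arr)
  add("subject_alignment", d[3] == nrow(covariates),
      sprintf("%d power subjects vs %d covariate rows", d[3],
              nrow(covariates)))
  if (inherits(power, "power_matrix") && !is.null(power$subjects) &&
      "subject_id" %in% names(covariates))
    add("subject_ids", identical(as.character(power$subjects),
                                 as.character(covariates$subject_id)),
        "subject id order")
  sums <- apply(arr, c(1, 3), sum)
  bad <- which(abs(sums - 1) > tol, arr.ind = TRUE)
  add("band_normalization", nrow(bad) == 0L,
      if (nrow(bad)) sprintf("node %d subject %d band sum %.6g",
                             bad[1, 1], bad[1, 2],
                             sums[bad[1, 1], bad[1, 2]]) else
        sprintf("all band sums within %g of 1", tol))
  have <- intersect(required, names(covariates))
  add("covariate_columns", length(have) == length(required),
      paste("missing:", paste(setdiff(required, have), collapse = ", ")))
  if (length(have))
    add("covariate_completeness",
        !anyNA(covariates[, have, drop = FALSE]),
        "NA values in required covariates")
  rep <- do.call(rbind, checks)
  attr(rep, "ok") <- all(rep$pass)
  class(rep) <- c("validation_report", "data.frame")
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Input validation:", if (attr(x, "ok")) "PASS" else "FAIL", "\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
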