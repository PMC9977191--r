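#' CBPT configuration
#'
#' Parameters of the cluster-based permutation test. Defaults follow the
#' standard source-space protocol: a 0.005 cell-level cluster-forming
#' alpha, 10,000 permutations, a minimum spatial extent of 1% of the
#' nodes, and a 0.05 cluster-level alpha.
#'
#' @param cluster_alpha cell-level p-value used to derive the
#'   cluster-forming F threshold (default 0.005).
#' @param n_permutations number of label permutations (default 10000).
#' @param min_extent_fraction minimum fraction of grid nodes a cluster
#'   must span (default 0.01).
#' @param cluster_level_alpha significance level for cluster p-values
#'   (default 0.05).
#' @param seed integer seed for the permutation draws.
#' @param null_pooling \code{"pooled"} (default) keeps one max-mass null
#'   over both signs per permutation; \code{"per_sign"} keeps separate
#'   nulls for positive and negative clusters.
#' @param pvalue_correction if \code{TRUE}, use the (1+count)/(1+B)
#'   permutation p-value; default \code{FALSE} is the plain proportion
#'   count(null >= observed)/B.
#' @param extent_rule \code{"unique_nodes"} (default) counts the unique
#'   spatial nodes of the whole spatio-spectral cluster against the
#'   minimum extent; \code{"per_freq_slice"} requires some single
#'   frequency bin to meet it.
#' @param mass_cap mass contributed by an infinite-F (perfect separation)
#'   cell (default 1e12), keeping cluster masses finite.
#' @return A validated list of class \code{cbpt_config}.
#' @export
cbpt_config <- function(cluster_alpha = 0.005, n_permutations = 10000L,
                        min_extent_fraction = 0.01,
                        cluster_level_alpha = 0.05, seed = 1L,
                        null_pooling = c("pooled", "per_sign"),
                        pvalue_correction = FALSE,
                        extent_rule = c("unique_nodes", "per_freq_slice"),
                        mass_cap = 1e12) {
  stopifnot(cluster_alpha > 0, cluster_alpha < 1,
            cluster_level_alpha > 0, cluster_level_alpha < 1,
            n_permutations >= 1,
            min_extent_fraction > 0, min_extent_fraction < 1,
            mass_cap > 0)
  structure(list(cluster_alpha = cluster_alpha,
                 n_permutations = as.integer(n_permutations),
                 min_extent_fraction = min_extent_fraction,
                 cluster_level_alpha = cluster_level_alpha,
                 seed = as.integer(seed),
                 null_pooling = match.arg(null_pooling),
                 pvalue_correction = isTRUE(pvalue_correction),
                 extent_rule = match.arg(extent_rule),
                 mass_cap = mass_cap),
            class = "cbpt_config")
}

# ---- design handling -------------------------------------------------------

validate_design <- function(design, covariates) {
  stopifnot(is.data.frame(design))
  need <- c("group", covariates)
  miss <- setdiff(need, names(design))
  if (length(miss))
    stop("design table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  used <- design[, need, drop = FALSE]
  if (anyNA(used))
    stop("missing values in design columns ", paste(need, collapse = ", "),
         call. = FALSE)
  g <- design$group
  if (!all(g %in% c(0, 1)))
    stop("`group` must be binary 0/1", call. = FALSE)
  if (length(unique(g)) < 2L)
    stop("both groups must be non-empty", call. = FALSE)
  n <- nrow(design)
  p <- length(covariates)
  if (n < p + 3L)
    stop("need at least ", p + 3L, " subjects for ", p, " covariate(s)",
         call. = FALSE)
  X <- cbind(1, g, as.matrix(design[, covariates, drop = FALSE]))
  storage.mode(X) <- "double"
  if (qr(X)$rank < ncol(X))
    stop("degenerate design: group and covariates are collinear",
         call. = FALSE)
  X
}

# Fast nested-model ANCOVA engine. Precomputes the reduced-model
# (intercept + covariates) projection once; each call with a group vector
# costs one n x ncells matrix-vector product. F compares the full model
# (reduced + group) against the reduced model; the sign is the sign of the
# group coefficient.
make_ancova_engine <- function(Y, design, covariates) {
  n <- nrow(Y)
  validate_design(design, covariates)
  Xred <- cbind(rep(1, n),
                as.matrix(design[, covariates, drop = FALSE]))
  storage.mode(Xred) <- "double"
  Q <- qr.Q(qr(Xred))
  Yr <- Y - Q %*% crossprod(Q, Y)
  sse_red <- .colSums(Yr^2, n, ncol(Y))
  # zero-variance convention: constant cells get F = 0, sign = 0
  const_cell <- matrixStats_colvar_zero(Y)
  df2 <- n - 2L - length(covariates)
  eps <- .Machine$double.eps
  function(g) {
    gp <- g - Q %*% crossprod(Q, g)
    ssg <- sum(gp^2)
    if (ssg <= eps * n)
      stop("degenerate design: group is collinear with covariates",
           call. = FALSE)
    v <- as.numeric(crossprod(gp, Yr))
    num <- v^2 / ssg
    sse_full <- pmax(sse_red - num, 0)
    f <- num * df2 / sse_full          # Inf where sse_full == 0 and num > 0
    f[num == 0] <- 0
    s <- sign(v)
    f[const_cell] <- 0
    s[const_cell] <- 0
    list(F = f, sign = s, df = c(1L, df2))
  }
}

matrixStats_colvar_zero <- function(Y) {
  rng_max <- apply(Y, 2L, max)
  rng_min <- apply(Y, 2L, min)
  rng_max == rng_min
}

as_power_array <- function(power) {
  if (inherits(power, "power_matrix")) power$power
  else if (is.array(power) && length(dim(power)) == 3L) power
  else stop("`power` must be a power_matrix or a 3-d array", call. = FALSE)
}

#' Covariate-adjusted F map over all (node, frequency) cells
#'
#' For every cell, fits the linear model
#' \code{power ~ intercept + group + covariates} and compares it against
#' the model without \code{group}:
#' \code{F = (SSE_reduced - SSE_full) / (SSE_full / (n - p - 2))} on
#' (1, n - p - 2) degrees of freedom, where p is the number of
#' covariates. The sign map holds the sign of the adjusted group
#' coefficient (group 1 minus group 0). Cells with zero variance across
#' subjects get F = 0 and sign 0; perfectly separated cells get an
#' infinite-F sentinel.
#'
#' @param power a \code{power_matrix} or node x freq x subject array.
#' @param design data.frame with \code{group} (0/1) and the covariate
#'   columns; rows align with the subject dimension of \code{power}.
#' @param covariates character vector of covariate column names
#'   (default \code{c("age", "wm_volume")}).
#' @return A \code{stat_map}: list with \code{F} and \code{sign}
#'   (node x freq matrices) and \code{df}.
#' @export
ancova_f_map <- function(power, design, covariates = c("age", "wm_volume")) {
  arr <- as_power_array(power)
  d <- dim(arr)
  if (d[3] != nrow(design))
    stop("subject dimension of power (", d[3],
         ") does not match design rows (", nrow(design), ")", call. = FALSE)
  Y <- t(matrix(arr, d[1] * d[2], d[3]))
  eng <- make_ancova_engine(Y, design, covariates)
  r <- eng(as.numeric(design$group))
  structure(list(F = matrix(r$F, d[1], d[2]),
                 sign = matrix(r$sign, d[1], d[2]),
                 df = r$df),
            class = "stat_map")
}

#' Cluster-forming F threshold
#'
#' Upper-tail quantile of the F distribution: the critical value an F
#' statistic must reach for a cell-level p below \code{cell_alpha}.
#'
#' @param cell_alpha cell-level alpha in (0, 1).
#' @param df length-2 degrees of freedom (numerator, denominator).
#' @return The F threshold.
#' @export
critical_f <- function(cell_alpha, df) {
  stopifnot(cell_alpha > 0, cell_alpha < 1, length(df) == 2, all(df > 0))
  stats::qf(1 - cell_alpha, df[1], df[2])
}

#' Threshold an F map and split by sign of the group difference
#'
#' @param stat a \code{stat_map} from \code{\link{ancova_f_map}}.
#' @param threshold cluster-forming F value (> 0).
#' @return List with logical matrices \code{positive} (F >= threshold and
#'   group 1 > group 0) and \code{negative}; the masks are disjoint.
#' @export
binarize_and_split <- function(stat, threshold) {
  stopifnot(inherits(stat, "stat_map"), threshold > 0)
  supra <- stat$F >= threshold
  list(positive = supra & stat$sign > 0,
       negative = supra & stat$sign < 0)
}

# Union-find over masked cells of the node x freq lattice. `idx` holds
# linear indices (node-major: cell = node + (f-1) * n_nodes); `adj` is the
# spatial adjacency list by node position. Returns component labels.
cluster_components <- function(idx, n_nodes, nf, adj) {
  m <- length(idx)
  if (m == 0L) return(integer(0))
  pos <- integer(n_nodes * nf)
  pos[idx] <- seq_len(m)
  node <- (idx - 1L) %% n_nodes + 1L
  f <- (idx - 1L) %/% n_nodes + 1L
  # frequency edges: same node, consecutive bins
  sel <- f < nf
  cand <- idx[sel] + n_nodes
  keep <- pos[cand] > 0L
  e1 <- which(sel)[keep]; e2 <- pos[cand[keep]]
  # spatial edges: neighbouring nodes, same bin
  deg <- lengths(adj)[node]
  if (sum(deg) > 0L) {
    owner <- rep.int(seq_len(m), deg)
    nb <- unlist(adj[node], use.names = FALSE)
    cand <- nb + (f[owner] - 1L) * n_nodes
    keep <- pos[cand] > 0L
    e1 <- c(e1, owner[keep]); e2 <- c(e2, pos[cand[keep]])
  }
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(e1)) {
    a <- find(e1[k]); b <- find(e2[k])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(m), find, integer(1))
  match(roots, unique(roots))
}

#' Form spatio-spectral clusters from a binary mask
#'
#' Connected components of the graph whose vertices are masked
#' (node, frequency-bin) cells, with edges between spatially adjacent
#' nodes at the same bin and between consecutive bins at the same node.
#'
#' @param mask logical node x freq matrix (rows ordered as
#'   \code{space$node_ids}).
#' @param space a \code{source_space}.
#' @param freqs frequency vector (Hz), one entry per mask column.
#' @return List of clusters; each has \code{cells} (matrix with columns
#'   \code{node} — original node ids — and \code{freq_bin}),
#'   \code{n_nodes_unique}, \code{freq_range} (Hz), and
#'   \code{extent_by_freq} (named node counts per bin).
#' @export
form_clusters <- function(mask, space, freqs) {
  stopifnot(inherits(space, "source_space"), is.logical(mask),
            nrow(mask) == length(space$node_ids),
            ncol(mask) == length(freqs))
  idx <- which(mask)
  if (!length(idx)) return(list())
  adj <- adjacency_list(space)
  labs <- cluster_components(idx, nrow(mask), ncol(mask), adj)
  node_pos <- (idx - 1L) %% nrow(mask) + 1L
  fbin <- (idx - 1L) %/% nrow(mask) + 1L
  lapply(seq_len(max(labs)), function(k) {
    sel <- labs == k
    np <- node_pos[sel]; fb <- fbin[sel]
    ext <- table(factor(fb, levels = sort(unique(fb))))
    extent <- as.integer(ext)
    names(extent) <- as.character(freqs[as.integer(names(ext))])
    list(cells = cbind(node = space$node_ids[np], freq_bin = fb),
         cell_index = idx[sel],
         n_nodes_unique = length(unique(np)),
         freq_range = range(freqs[fb]),
         extent_by_freq = extent)
  })
}

#' Minimum spatial extent of a cluster
#'
#' \code{max(1, floor(fraction * n_nodes))}: with 1202 nodes and the
#' default 1% fraction this is the familiar 12-node minimum.
#'
#' @param n_nodes number of nodes in the clustering universe.
#' @param fraction minimum fraction of nodes, in (0, 1).
#' @return Integer minimum node count.
#' @export
min_extent <- function(n_nodes, fraction = 0.01) {
  stopifnot(n_nodes >= 1, fraction > 0, fraction < 1)
  max(1L, as.integer(floor(fraction * n_nodes)))
}

#' Cluster-mass statistic
#'
#' Sum of the F statistic over all member cells; infinite-F sentinel cells
#' contribute \code{mass_cap} each.
#'
#' @param cells cluster cell matrix (columns \code{node}, \code{freq_bin});
#'   node entries must be original node ids present in \code{stat}'s rows
#'   via \code{node_ids}.
#' @param stat a \code{stat_map}.
#' @param node_ids node ids labelling the rows of \code{stat$F} (default
#'   \code{1:nrow}).
#' @param mass_cap value substituted for infinite F (default 1e12).
#' @return The cluster mass.
#' @export
cluster_mass <- function(cells, stat, node_ids = seq_len(nrow(stat$F)),
                         mass_cap = 1e12) {
  stopifnot(inherits(stat, "stat_map"))
  rows <- match(cells[, "node"], node_ids)
  if (anyNA(rows) || any(cells[, "freq_bin"] < 1L) ||
      any(cells[, "freq_bin"] > ncol(stat$F)))
    stop("cluster cells outside the stat map", call. = FALSE)
  f <- stat$F[cbind(rows, cells[, "freq_bin"])]
  sum(pmin(f, mass_cap))
}

# Shared core: compute surviving clusters (both signs) of one F/sign map.
# Returns list of clusters with sign and mass attached.
clusters_of_map <- function(fvec, svec, threshold, n_nodes, nf, adj,
                            min_nodes, extent_rule, mass_cap,
                            node_ids, freqs, cells_wanted = TRUE) {
  out <- list()
  for (sgn in c(1, -1)) {
    idx <- which(fvec >= threshold & svec == sgn)
    if (!length(idx)) next
    labs <- cluster_components(idx, n_nodes, nf, adj)
    node_pos <- (idx - 1L) %% n_nodes + 1L
    fb <- (idx - 1L) %/% n_nodes + 1L
    for (k in seq_len(max(labs))) {
      sel <- labs == k
      np <- node_pos[sel]
      keep <- if (extent_rule == "unique_nodes")
        length(unique(np)) >= min_nodes
      else max(table(fb[sel])) >= min_nodes
      if (!keep) next
      mass <- sum(pmin(fvec[idx[sel]], mass_cap))
      cl <- list(sign = sgn, mass = mass,
                 n_nodes_unique = length(unique(np)))
      if (cells_wanted) {
        fbk <- fb[sel]
        ext <- table(factor(fbk, levels = sort(unique(fbk))))
        extent <- as.integer(ext)
        names(extent) <- as.character(freqs[as.integer(names(ext))])
        cl$cells <- cbind(node = node_ids[np], freq_bin = fbk)
        cl$freq_range <- range(freqs[fbk])
        cl$extent_by_freq <- extent
      }
      out[[length(out) + 1L]] <- cl
    }
  }
  out
}

#' Max-statistic permutation null of cluster masses
#'
#' Repeats the full pipeline (covariate-adjusted F map, thresholding,
#' sign-split clustering, minimum-extent filter) after shuffling the group
#' labels over subjects — covariates stay attached to their subjects —
#' and records the maximum surviving cluster mass per permutation (0 when
#' no cluster survives). When the number of distinct group relabellings
#' \code{choose(n, n1)} does not exceed \code{n_permutations}, all of them
#' are enumerated instead of sampling.
#'
#' @param power a \code{power_matrix} or node x freq x subject array.
#' @param design design data.frame (see \code{\link{ancova_f_map}}).
#' @param space a \code{source_space}.
#' @param config a \code{\link{cbpt_config}}.
#' @param covariates covariate column names.
#' @return For pooled nulls, a numeric vector of max masses (attribute
#'   \code{"exhaustive"} says whether relabellings were enumerated); for
#'   \code{null_pooling = "per_sign"}, a two-column matrix
#'   (\code{positive}, \code{negative}).
#' @export
permutation_null <- function(power, design, space, config = cbpt_config(),
                             covariates = c("age", "wm_volume")) {
  fit_parts <- cbpt_prepare(power, design, space, config, covariates)
  with_seed(config$seed,
            cbpt_null_impl(fit_parts, config))
}

cbpt_prepare <- function(power, design, space, config, covariates) {
  arr <- as_power_array(power)
  d <- dim(arr)
  if (d[1] != length(space$node_ids))
    stop("power node dimension (", d[1], ") does not match source space (",
         length(space$node_ids), " nodes)", call. = FALSE)
  if (d[3] != nrow(design))
    stop("subject dimension of power (", d[3],
         ") does not match design rows (", nrow(design), ")", call. = FALSE)
  freqs <- if (inherits(power, "power_matrix")) power$freqs else
    seq_len(d[2])
  Y <- t(matrix(arr, d[1] * d[2], d[3]))
  eng <- make_ancova_engine(Y, design, covariates)
  g <- as.numeric(design$group)
  df <- c(1L, d[3] - 2L - length(covariates))
  list(engine = eng, g = g, n_nodes = d[1], nf = d[2], freqs = freqs,
       adj = adjacency_list(space), node_ids = space$node_ids, df = df,
       threshold = critical_f(config$cluster_alpha, df),
       min_nodes = min_extent(d[1], config$min_extent_fraction))
}

cbpt_null_impl <- function(fp, config) {
  B <- config$n_permutations
  n <- length(fp$g)
  n1 <- sum(fp$g == 1)
  n_distinct <- choose(n, n1)
  exhaustive <- is.finite(n_distinct) && n_distinct <= B
  perms <- if (exhaustive) {
    combs <- utils::combn(n, n1)
    lapply(seq_len(ncol(combs)), function(j) {
      g <- numeric(n); g[combs[, j]] <- 1; g
    })
  } else {
    lapply(seq_len(B), function(j) sample(fp$g))
  }
  per_sign <- config$null_pooling == "per_sign"
  res <- matrix(0, length(perms), 2L)
  for (b in seq_along(perms)) {
    st <- fp$engine(perms[[b]])
    cl <- clusters_of_map(st$F, st$sign, fp$threshold, fp$n_nodes, fp$nf,
                          fp$adj, fp$min_nodes, config$extent_rule,
                          config$mass_cap, fp$node_ids, fp$freqs,
                          cells_wanted = FALSE)
    if (length(cl)) {
      signs <- vapply(cl, `[[`, numeric(1), "sign")
      masses <- vapply(cl, `[[`, numeric(1), "mass")
      res[b, 1L] <- max(0, masses[signs > 0])
      res[b, 2L] <- max(0, masses[signs < 0])
    }
  }
  out <- if (per_sign) {
    colnames(res) <- c("positive", "negative")
    res
  } else pmax(res[, 1L], res[, 2L])
  attr(out, "exhaustive") <- exhaustive
  out
}

#' Permutation p-value of a cluster mass
#'
#' Plain proportion of the null distribution at or above the observed
#' mass: \code{count(null >= observed) / length(null)}. With
#' \code{correction = TRUE} the positively biased
#' \code{(1 + count) / (1 + B)} estimate is returned instead.
#'
#' @param observed_mass observed cluster mass.
#' @param null numeric vector of permutation max masses.
#' @param correction logical, default \code{FALSE}.
#' @return p-value in [0, 1].
#' @export
cbpt_pvalue <- function(observed_mass, null, correction = FALSE) {
  if (!length(null)) stop("empty null distribution", call. = FALSE)
  ct <- sum(null >= observed_mass)
  if (correction) (1 + ct) / (1 + length(null)) else ct / length(null)
}

#' Covariate-adjusted spatio-spectral cluster-based permutation test
#'
#' Fits the full CBPT: a per-cell ANCOVA F map of group differences in
#' relative power adjusted for nuisance covariates, thresholded at the
#' cluster-forming alpha, split by sign of the adjusted group difference,
#' grouped into spatio-spectral clusters (spatial adjacency within a
#' frequency bin, linkage across consecutive bins), filtered by minimum
#' spatial extent, and calibrated against a max-statistic permutation null
#' that controls the family-wise error rate at the cluster level.
#'
#' @param power a \code{power_matrix} (as produced by
#'   \code{\link{simulate_cohort}} or \code{\link{read_cohort}}) or a
#'   node x freq x subject array of relative power.
#' @param design data.frame with \code{group} (0/1) and covariate columns,
#'   one row per subject in the order of the power array.
#' @param space the \code{source_space} the power rows live on.
#' @param config a \code{\link{cbpt_config}}.
#' @param covariates covariate column names
#'   (default \code{c("age", "wm_volume")}).
#' @return An object of class \code{cbpt_fit} with elements
#'   \code{clusters} (list sorted by p-value; each has \code{cells},
#'   \code{sign}, \code{mass}, \code{p_value}, \code{freq_range},
#'   \code{extent_by_freq}, \code{n_nodes_unique}, \code{marker_name},
#'   \code{significant}), \code{null_max}, \code{stat} (the observed
#'   \code{stat_map}), \code{threshold}, \code{df}, \code{config},
#'   \code{covariates}, \code{freqs}, \code{n_subjects}.
#' @seealso \code{\link{extract_marker}} to turn significant clusters into
#'   per-subject power markers.
#' @examples
#' cfg <- sim_config(n_per_group = 10, grid_shape = c(3, 3, 2),
#'                   noise_sd = 0.002, seed = 7)
#' coh <- simulate_cohort(cfg)
#' fit <- cbpt(coh$power, coh$covariates, coh$space,
#'             cbpt_config(n_permutations = 200, seed = 7))
#' print(fit)
#' @export
cbpt <- function(power, design, space, config = cbpt_config(),
                 covariates = c("age", "wm_volume")) {
  stopifnot(inherits(config, "cbpt_config"))
  fp <- cbpt_prepare(power, design, space, config, covariates)
  st <- fp$engine(fp$g)
  observed <- clusters_of_map(st$F, st$sign, fp$threshold, fp$n_nodes,
                              fp$nf, fp$adj, fp$min_nodes,
                              config$extent_rule, config$mass_cap,
                              fp$node_ids, fp$freqs, cells_wanted = TRUE)
  null <- with_seed(config$seed, cbpt_null_impl(fp, config))
  per_sign <- config$null_pooling == "per_sign"
  for (i in seq_along(observed)) {
    nv <- if (per_sign) {
      if (observed[[i]]$sign > 0) null[, "positive"] else null[, "negative"]
    } else null
    observed[[i]]$p_value <- cbpt_pvalue(observed[[i]]$mass, nv,
                                         config$pvalue_correction)
    observed[[i]]$significant <-
      observed[[i]]$p_value < config$cluster_level_alpha
  }
  if (length(observed)) {
    ord <- order(vapply(observed, `[[`, numeric(1), "p_value"),
                 -vapply(observed, `[[`, numeric(1), "mass"))
    observed <- observed[ord]
    for (i in seq_along(observed))
      observed[[i]]$marker_name <-
        paste0(ifelse(observed[[i]]$sign > 0, "pos", "neg"), i)
  }
  structure(list(clusters = observed, null_max = null,
                 stat = structure(list(F = matrix(st$F, fp$n_nodes, fp$nf),
                                       sign = matrix(st$sign, fp$n_nodes,
                                                     fp$nf),
                                       df = st$df),
                                  class = "stat_map"),
                 threshold = fp$threshold, df = fp$df, config = config,
                 covariates = covariates, freqs = fp$freqs,
                 node_ids = fp$node_ids, n_subjects = length(fp$g),
                 call = match.call()),
            class = "cbpt_fit")
}

#' @export
print.cbpt_fit <- function(x, ...) {
  cat("Cluster-based permutation test (covariate-adjusted ANCOVA)\n")
  cat(sprintf("  %d subjects, F(%d, %d) threshold %.3f (alpha %.4g), %d permutations%s\n",
              x$n_subjects, x$df[1], x$df[2], x$threshold,
              x$config$cluster_alpha,
              if (is.matrix(x$null_max)) nrow(x$null_max) else
                length(x$null_max),
              if (isTRUE(attr(x$null_max, "exhaustive")))
                " (exhaustive)" else ""))
  if (!length(x$clusters)) {
    cat("  No clusters survived the minimum-extent filter.\n")
    return(invisible(x))
  }
  cat(sprintf("  %d cluster(s), %d significant at alpha %.3g:\n",
              length(x$clusters),
              sum(vapply(x$clusters, `[[`, logical(1), "significant")),
              x$config$cluster_level_alpha))
  show <- utils::head(x$clusters, 10L)
  for (cl in show)
    cat(sprintf("    %-5s sign %+d  %5.2f-%5.2f Hz  %4d nodes  mass %10.1f  p = %.4g%s\n",
                cl$marker_name, cl$sign, cl$freq_range[1], cl$freq_range[2],
                cl$n_nodes_unique, cl$mass, cl$p_value,
                if (cl$significant) " *" else ""))
  if (length(x$clusters) > 10L)
    cat("    ... and", length(x$clusters) - 10L, "more\n")
  invisible(x)
}

#' @export
summary.cbpt_fit <- function(object, ...) {
  cl <- object$clusters
  df <- if (length(cl)) data.frame(
    marker = vapply(cl, `[[`, character(1), "marker_name"),
    sign = vapply(cl, `[[`, numeric(1), "sign"),
    freq_lo = vapply(cl, function(c) c$freq_range[1], numeric(1)),
    freq_hi = vapply(cl, function(c) c$freq_range[2], numeric(1)),
    n_nodes = vapply(cl, `[[`, numeric(1), "n_nodes_unique"),
    n_cells = vapply(cl, function(c) nrow(c$cells), numeric(1)),
    mass = vapply(cl, `[[`, numeric(1), "mass"),
    p_value = vapply(cl, `[[`, numeric(1), "p_value"),
    significant = vapply(cl, `[[`, logical(1), "significant"))
  else data.frame()
  structure(list(clusters = df, threshold = object$threshold,
                 df = object$df, config = object$config,
                 n_subjects = object$n_subjects), class = "summary.cbpt_fit")
}

#' @export
print.summary.cbpt_fit <- function(x, ...) {
  cat(sprintf("CBPT summary: %d subjects, threshold F(%d,%d) = %.3f\n",
              x$n_subjects, x$df[1], x$df[2], x$threshold))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  else cat("no clusters\n")
  invisible(x)
}

#' Plot a CBPT fit
#'
#' Two panels: per-cluster spatial extent across frequency (node count per
#' bin, one line per surviving cluster) and the permutation null of max
#' cluster masses with the observed masses marked.
#'
#' @param x a \code{cbpt_fit}.
#' @param ... passed to \code{plot}.
#' @export
plot.cbpt_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  cl <- x$clusters
  if (length(cl)) {
    xl <- range(x$freqs)
    yl <- c(0, max(vapply(cl, function(c) max(c$extent_by_freq),
                          numeric(1))))
    graphics::plot(NA, xlim = xl, ylim = yl, xlab = "Frequency (Hz)",
                   ylab = "Nodes in cluster", main = "Cluster extent", ...)
    for (i in seq_along(cl)) {
      f <- as.numeric(names(cl[[i]]$extent_by_freq))
      graphics::lines(f, cl[[i]]$extent_by_freq, col = i, lwd = 2)
    }
    graphics::legend("topright",
                     legend = vapply(cl, `[[`, character(1), "marker_name"),
                     col = seq_along(cl), lwd = 2, bty = "n")
  } else {
    graphics::plot.new(); graphics::title("No clusters")
  }
  nul <- if (is.matrix(x$null_max)) as.numeric(x$null_max) else
    as.numeric(x$null_max)
  graphics::hist(nul, breaks = 30, main = "Permutation null",
                 xlab = "Max cluster mass")
  if (length(cl))
    graphics::abline(v = vapply(cl, `[[`, numeric(1), "mass"),
                     col = seq_along(cl), lwd = 2)
  invisible(x)
}
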