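# Independent reference implementations used as oracles: explicit lm()
# model comparisons for the F map, breadth-first flood fill for the
# clustering, and a loop-based CBPT that mirrors the permutation draw
# order of the fast engine.

naive_f_map <- function(arr, design, covariates = c("age", "wm_volume")) {
  d <- dim(arr)
  n <- d[3]
  df2 <- n - 2L - length(covariates)
  Fm <- matrix(0, d[1], d[2])
  Sm <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    y <- arr[i, j, ]
    if (max(y) == min(y)) next
    dat <- data.frame(y = y, g = as.numeric(design$group))
    for (cv in covariates) dat[[cv]] <- design[[cv]]
    full <- stats::lm(stats::reformulate(c("g", covariates), "y"), dat)
    red <- stats::lm(
      stats::reformulate(if (length(covariates)) covariates else "1", "y"),
      dat)
    sse_f <- sum(stats::resid(full)^2)
    sse_r <- sum(stats::resid(red)^2)
    Fm[i, j] <- if (sse_f <= 1e-25 * max(sse_r, 1e-300)) Inf
                else (sse_r - sse_f) / (sse_f / df2)
    Sm[i, j] <- sign(unname(stats::coef(full)["g"]))
  }
  list(F = Fm, sign = Sm)
}

# flood-fill components of a masked node x freq lattice; spatial
# neighbours queried through the public API
naive_clusters <- function(mask, space, freqs) {
  nn <- nrow(mask); nf <- ncol(mask)
  visited <- matrix(FALSE, nn, nf)
  row_of <- function(id) match(id, space$node_ids)
  out <- list()
  for (r0 in seq_len(nn)) for (c0 in seq_len(nf)) {
    if (!mask[r0, c0] || visited[r0, c0]) next
    queue <- list(c(r0, c0))
    visited[r0, c0] <- TRUE
    cells <- matrix(integer(0), 0, 2)
    while (length(queue)) {
      cell <- queue[[1]]; queue <- queue[-1]
      cells <- rbind(cells, cell)
      cand <- list()
      if (cell[2] > 1) cand <- c(cand, list(c(cell[1], cell[2] - 1L)))
      if (cell[2] < nf) cand <- c(cand, list(c(cell[1], cell[2] + 1L)))
      for (nb in spatial_neighbors(space, space$node_ids[cell[1]]))
        cand <- c(cand, list(c(row_of(nb), cell[2])))
      for (cc in cand) {
        if (mask[cc[1], cc[2]] && !visited[cc[1], cc[2]]) {
          visited[cc[1], cc[2]] <- TRUE
          queue <- c(queue, list(cc))
        }
      }
    }
    out[[length(out) + 1L]] <-
      cbind(node = space$node_ids[cells[, 1]], freq_bin = cells[, 2])
  }
  out
}

# canonical form of a cluster list for set comparison
cluster_key <- function(cells) {
  o <- order(cells[, 1], cells[, 2])
  paste(cells[o, 1], cells[o, 2], sep = ":", collapse = ";")
}

# loop-based CBPT sharing the permutation draw order of the fast engine
naive_cbpt <- function(arr, design, space, config,
                       covariates = c("age", "wm_volume")) {
  d <- dim(arr)
  freqs <- seq_len(d[2])
  n <- d[3]
  df2 <- n - 2L - length(covariates)
  thr <- stats::qf(1 - config$cluster_alpha, 1, df2)
  min_nodes <- max(1L, floor(config$min_extent_fraction * d[1]))
  surviving <- function(des) {
    st <- naive_f_map(arr, des, covariates)
    res <- list()
    for (sgn in c(1, -1)) {
      mask <- st$F >= thr & st$sign == sgn
      for (cl in naive_clusters(mask, space, freqs)) {
        if (length(unique(cl[, "node"])) < min_nodes) next
        rows <- match(cl[, "node"], space$node_ids)
        f <- st$F[cbind(rows, cl[, "freq_bin"])]
        res[[length(res) + 1L]] <-
          list(cells = cl, sign = sgn,
               mass = sum(pmin(f, config$mass_cap)))
      }
    }
    res
  }
  observed <- surviving(design)
  g <- as.numeric(design$group)
  n1 <- sum(g == 1)
  B <- config$n_permutations
  exhaustive <- choose(n, n1) <= B
  null <- megclust:::with_seed(config$seed, {
    perms <- if (exhaustive) {
      combs <- utils::combn(n, n1)
      lapply(seq_len(ncol(combs)), function(j) {
        gg <- numeric(n); gg[combs[, j]] <- 1; gg
      })
    } else lapply(seq_len(B), function(j) sample(g))
    vapply(perms, function(gp) {
      des <- design; des$group <- gp
      cl <- surviving(des)
      if (length(cl)) max(vapply(cl, `[[`, numeric(1), "mass")) else 0
    }, numeric(1))
  })
  for (i in seq_along(observed))
    observed[[i]]$p_value <- sum(null >= observed[[i]]$mass) / length(null)
  list(clusters = observed, null = null, threshold = thr)
}

# small cohort fixture builders -------------------------------------------

toy_design <- function(n, seed = 1) {
  megclust:::with_seed(seed, data.frame(
    group = rep(c(0, 1), length.out = n),
    age = stats::rnorm(n, 72, 5),
    wm_volume = stats::rnorm(n, 390e3, 50e3)))
}

toy_power <- function(n_nodes, nf, n, seed = 1) {
  megclust:::with_seed(seed, {
    arr <- array(stats::rexp(n_nodes * nf * n), dim = c(n_nodes, nf, n))
    for (s in seq_len(n)) arr[, , s] <- arr[, , s] / rowSums(arr[, , s])
    arr
  })
}

jaccard_nodes <- function(a, b) length(intersect(a, b)) / length(union(a, b))
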