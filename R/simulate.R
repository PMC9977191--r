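# Evaluate an expression with a temporary RNG state seeded by `seed`,
# restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulation configuration for synthetic MEG cohorts
#'
#' Bundles and validates every knob of the cohort generator. Defaults
#' describe the reference study conditions used throughout the package's
#' validation: a 150-node grid (5 x 6 x 5, 10 mm spacing), the 2--30 Hz
#' band at 0.25 Hz resolution (113 bins), a widespread central theta-band
#' power increase, bilateral lateral beta-band decreases, an age confound
#' (group 1 older by \code{age_group_shift} years), and cognitive /
#' hippocampal scores linked monotonically to the planted cluster power.
#'
#' @param n_per_group subjects per group.
#' @param grid_shape integer 3-vector of grid dimensions.
#' @param grid_spacing grid spacing in mm.
#' @param freq_band analysis band in Hz.
#' @param freq_step frequency resolution in Hz.
#' @param theta_effect_nodes node ids carrying the theta increase;
#'   \code{NULL} = central block (default widespread set).
#' @param theta_effect_range Hz range of the theta effect.
#' @param theta_effect_size multiplicative increase (>= 0) applied to group
#'   1 relative power in the theta cells before renormalisation.
#' @param beta_effect_nodes_left,beta_effect_nodes_right node ids of the
#'   lateral beta decreases; \code{NULL} = default lateral blocks.
#' @param beta_effect_range_left,beta_effect_range_right Hz ranges.
#' @param beta_effect_size multiplicative decrease (>= 0, < 1).
#' @param age_group_shift mean age difference (years) of group 1 over
#'   group 0 (confound exercised by covariate adjustment).
#' @param age_power_slope optional per-year multiplicative tilt of
#'   theta-band power with centred age, at all nodes (default 0; used to
#'   study confounding).
#' @param noise_sd SD of additive cell-level noise in relative-power units.
#' @param subject_jitter scale factor on between-subject variation of the
#'   baseline spectrum shape (0 disables jitter).
#' @param score_link_strength correlation-like strength in [-1, 1] between
#'   planted cluster power and generated scores.
#' @param seed integer seed; fully determines all outputs.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_per_group = 30,
                       grid_shape = c(5L, 6L, 5L),
                       grid_spacing = 10,
                       freq_band = c(2, 30),
                       freq_step = 0.25,
                       theta_effect_nodes = NULL,
                       theta_effect_range = c(4.75, 8),
                       theta_effect_size = 0.25,
                       beta_effect_nodes_left = NULL,
                       beta_effect_nodes_right = NULL,
                       beta_effect_range_left = c(12.25, 19.5),
                       beta_effect_range_right = c(11.75, 19.5),
                       beta_effect_size = 0.3,
                       age_group_shift = 3,
                       age_power_slope = 0,
                       noise_sd = 0.0015,
                       subject_jitter = 1,
                       score_link_strength = 0.5,
                       seed = 1L) {
  stopifnot(n_per_group >= 2, length(grid_shape) == 3, all(grid_shape >= 1),
            grid_spacing > 0, freq_step > 0, length(freq_band) == 2,
            freq_band[1] < freq_band[2],
            theta_effect_size >= 0, beta_effect_size >= 0,
            beta_effect_size < 1, noise_sd >= 0, subject_jitter >= 0,
            abs(score_link_strength) <= 1)
  n_nodes <- prod(grid_shape)
  shape <- as.integer(grid_shape)
  ijk <- as.matrix(expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                               k = seq_len(shape[3])))
  centre <- (shape + 1) / 2
  if (is.null(theta_effect_nodes)) {
    # widespread central block: indices within 75% of the half-extent
    half <- pmax((shape - 1) / 2, 0.5)
    d <- sweep(abs(sweep(ijk, 2, centre)), 2, half, "/")
    dmax <- apply(d, 1, max)
    theta_effect_nodes <- which(dmax <= 0.75)
    if (!length(theta_effect_nodes))          # tiny grids: nearest to centre
      theta_effect_nodes <- which(dmax == min(dmax))
  }
  lateral_block <- function(side) {
    w <- max(1L, min(shape[1] - 1L, ceiling(shape[1] * 0.4)))
    xs <- if (side == "left") seq_len(w) else seq(shape[1] - w + 1L, shape[1])
    mid_j <- ijk[, 2] >= ceiling(shape[2] / 4) &
             ijk[, 2] <= shape[2] - floor(shape[2] / 4)
    mid_k <- ijk[, 3] >= ceiling(shape[3] / 4) &
             ijk[, 3] <= shape[3] - floor(shape[3] / 4)
    which(ijk[, 1] %in% xs & mid_j & mid_k)
  }
  if (is.null(beta_effect_nodes_left)) beta_effect_nodes_left <- lateral_block("left")
  if (is.null(beta_effect_nodes_right)) beta_effect_nodes_right <- lateral_block("right")
  for (s in list(theta_effect_nodes, beta_effect_nodes_left,
                 beta_effect_nodes_right))
    if (length(s) && (any(s < 1) || any(s > n_nodes)))
      stop("effect node set outside grid (1..", n_nodes, ")", call. = FALSE)
  in_band <- function(r) r[1] >= freq_band[1] && r[2] <= freq_band[2]
  if (!in_band(theta_effect_range) || !in_band(beta_effect_range_left) ||
      !in_band(beta_effect_range_right))
    stop("effect frequency ranges must lie within freq_band", call. = FALSE)
  structure(list(n_per_group = as.integer(n_per_group), grid_shape = shape,
                 grid_spacing = grid_spacing, freq_band = freq_band,
                 freq_step = freq_step,
                 theta_effect_nodes = as.integer(theta_effect_nodes),
                 theta_effect_range = theta_effect_range,
                 theta_effect_size = theta_effect_size,
                 beta_effect_nodes_left = as.integer(beta_effect_nodes_left),
                 beta_effect_nodes_right = as.integer(beta_effect_nodes_right),
                 beta_effect_range_left = beta_effect_range_left,
                 beta_effect_range_right = beta_effect_range_right,
                 beta_effect_size = beta_effect_size,
                 age_group_shift = age_group_shift,
                 age_power_slope = age_power_slope,
                 noise_sd = noise_sd, subject_jitter = subject_jitter,
                 score_link_strength = score_link_strength,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a synthetic MCI cohort with planted spectral effects
#'
#' Generates relative power spectra for two groups on a regular source
#' grid, together with covariates, scores, and the ground truth of every
#' planted effect. Per subject and node the baseline relative spectrum is
#' a 1/f trend plus a Gaussian alpha peak near 9.5 Hz, with subject-level
#' jitter of slope, peak height and peak position. Group 1 has the theta
#' cells multiplied by \code{1 + theta_effect_size} and the beta cells by
#' \code{1 - beta_effect_size}; spectra are renormalised per node so every
#' band sum is exactly 1 (the renormalisation couples bands, as relative
#' power does). Truncated-at-zero Gaussian noise is added cell-wise,
#' followed by a final renormalisation. Ages carry the configured group
#' shift, white-matter volume is independent of group, WMH volumes are
#' lognormal and straddle the 3448 mm^3 reference cut point, and scores
#' are monotone in the subject's planted-cluster mean power with strength
#' \code{score_link_strength}.
#'
#' @param config a \code{\link{sim_config}}.
#' @return List with \code{power} (a \code{power_matrix}: array
#'   node x freq x subject plus \code{freqs}), \code{covariates}
#'   (data.frame, one row per subject), \code{space} (the
#'   \code{source_space}), \code{truth} (planted cells per effect with
#'   signs, true cut point, score link directions) and \code{config}.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  space <- make_grid(cfg$grid_shape, cfg$grid_spacing)
  freqs <- seq(cfg$freq_band[1], cfg$freq_band[2], by = cfg$freq_step)
  n_nodes <- prod(cfg$grid_shape)
  nf <- length(freqs)
  n <- 2L * cfg$n_per_group
  group <- rep(c(0L, 1L), each = cfg$n_per_group)

  bins_in <- function(r) which(freqs >= r[1] - 1e-9 & freqs <= r[2] + 1e-9)
  theta_bins <- bins_in(cfg$theta_effect_range)
  betaL_bins <- bins_in(cfg$beta_effect_range_left)
  betaR_bins <- bins_in(cfg$beta_effect_range_right)

  # subject-level spectral shape parameters
  jit <- cfg$subject_jitter
  slope <- 1 + jit * stats::rnorm(n, 0, 0.08)
  alpha_amp <- 0.35 * exp(jit * stats::rnorm(n, 0, 0.25))
  alpha_mu <- 9.5 + jit * stats::rnorm(n, 0, 0.4)

  age <- stats::rnorm(n, 72.1 + cfg$age_group_shift * group,
                      ifelse(group == 1L, 4.2, 5.1))

  pow <- array(0, dim = c(n_nodes, nf, n))
  age_c <- age - mean(age)
  for (s in seq_len(n)) {
    base <- freqs^(-slope[s]) +
      alpha_amp[s] * exp(-(freqs - alpha_mu[s])^2 / 2)
    base <- base / sum(base)
    mat <- matrix(base, n_nodes, nf, byrow = TRUE)
    if (cfg$age_power_slope != 0)
      mat[, theta_bins] <- mat[, theta_bins] *
        (1 + cfg$age_power_slope * age_c[s])
    if (group[s] == 1L) {
      if (cfg$theta_effect_size > 0)
        mat[cfg$theta_effect_nodes, theta_bins] <-
          mat[cfg$theta_effect_nodes, theta_bins] * (1 + cfg$theta_effect_size)
      if (cfg$beta_effect_size > 0) {
        mat[cfg$beta_effect_nodes_left, betaL_bins] <-
          mat[cfg$beta_effect_nodes_left, betaL_bins] * (1 - cfg$beta_effect_size)
        mat[cfg$beta_effect_nodes_right, betaR_bins] <-
          mat[cfg$beta_effect_nodes_right, betaR_bins] * (1 - cfg$beta_effect_size)
      }
    }
    mat <- mat / rowSums(mat)
    if (cfg$noise_sd > 0) {
      mat <- pmax(mat + stats::rnorm(n_nodes * nf, 0, cfg$noise_sd), 0)
      mat <- mat / rowSums(mat)
    }
    pow[, , s] <- mat
  }

  wm_volume <- stats::rnorm(n, 392e3, 53e3)
  # WMH volumes: lognormal, group 1 mostly above / group 0 mostly below
  # the 3448 mm^3 reference cut point
  wmh <- ifelse(group == 1L,
                stats::rlnorm(n, log(8500), 0.6),
                stats::rlnorm(n, log(800), 0.9))

  cells <- function(nodes, bins)
    cbind(node = rep(nodes, times = length(bins)),
          freq_bin = rep(bins, each = length(nodes)))
  truth <- list(
    effects = list(
      theta = list(cells = cells(cfg$theta_effect_nodes, theta_bins),
                   nodes = cfg$theta_effect_nodes, sign = +1L),
      beta_left = list(cells = cells(cfg$beta_effect_nodes_left, betaL_bins),
                       nodes = cfg$beta_effect_nodes_left, sign = -1L),
      beta_right = list(cells = cells(cfg$beta_effect_nodes_right, betaR_bins),
                        nodes = cfg$beta_effect_nodes_right, sign = -1L)),
    cut_point = 3448,
    score_links = data.frame(
      score = c("mmse", "delayed_recall", "immediate_recall",
                "semantic_fluency", "digit_backward", "lhv", "rhv"),
      effect = c("theta", "theta", "beta_left", "beta_left", "beta_right",
                 "beta_left", "beta_right"),
      direction = c(-1L, -1L, 1L, 1L, 1L, 1L, 1L)))

  marker_of <- function(eff) {
    cl <- truth$effects[[eff]]$cells
    idx <- cl[, 1L] + (cl[, 2L] - 1L) * n_nodes
    vapply(seq_len(n), function(s) mean(pow[, , s][idx]), numeric(1))
  }
  markers <- vapply(names(truth$effects), marker_of, numeric(n))

  rho <- cfg$score_link_strength
  score_z <- function(eff, dir) {
    m <- markers[, eff]
    s <- stats::sd(m)
    z <- if (is.finite(s) && s > 0) (m - mean(m)) / s else rep(0, n)
    dir * rho * z + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n)
  }
  zc <- mapply(score_z, truth$score_links$effect, truth$score_links$direction)
  scores <- data.frame(
    mmse = pmin(30, pmax(0, round(26.5 + 2.5 * zc[, 1], 1))),
    delayed_recall = pmax(0, round(5.8 + 4.5 * zc[, 2], 1)),
    immediate_recall = pmax(0, round(15.9 + 6.5 * zc[, 3], 1)),
    semantic_fluency = pmax(0, round(12.1 + 3.4 * zc[, 4], 1)),
    digit_backward = pmax(0, round(4.1 + 1.4 * zc[, 5], 1)),
    lhv = 0.0022 + 0.00035 * zc[, 6],
    rhv = 0.0023 + 0.00035 * zc[, 7])

  covariates <- cbind(
    data.frame(subject_id = sprintf("S%03d", seq_len(n)), group = group,
               age = age, wm_volume = wm_volume, wmh_volume = wmh),
    scores)

  power <- structure(list(power = pow, freqs = freqs,
                          subjects = covariates$subject_id),
                     class = "power_matrix")
  list(power = power, covariates = covariates, space = space,
       truth = truth, config = cfg)
}

#' @export
print.power_matrix <- function(x, ...) {
  d <- dim(x$power)
  cat("Relative power matrix:", d[1], "nodes x", d[2], "frequency bins x",
      d[3], "subjects\n")
  cat("Band:", min(x$freqs), "-", max(x$freqs), "Hz\n")
  invisible(x)
}

#' Simulate a reference distribution of WMH volumes
#'
#' Lognormal WMH volumes emulating a cognitively intact reference sample,
#' from which a specificity-based cut point can be computed. The defaults
#' (median 800 mm^3, log-SD 0.9) put the 95th percentile near the
#' published 3448 mm^3 landmark.
#'
#' @param n number of reference individuals (>= 1).
#' @param median median volume in mm^3.
#' @param sigma_log SD on the log scale (0 gives a point mass at the
#'   median).
#' @param seed integer seed.
#' @return Numeric vector of n positive volumes.
#' @export
simulate_reference_volumes <- function(n, median = 800, sigma_log = 0.9,
                                       seed = 1L) {
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("`n` must be >= 1", call. = FALSE)
  stopifnot(median > 0, sigma_log >= 0)
  with_seed(seed, stats::rlnorm(as.integer(n), log(median), sigma_log))
}
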