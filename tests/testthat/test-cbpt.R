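test_that("ANCOVA F map matches an explicit two-model lm oracle", {
  arr <- toy_power(6, 4, 10, seed = 13)
  des <- toy_design(10, seed = 13)
  st <- ancova_f_map(arr, des)
  oracle <- naive_f_map(arr, des)
  expect_equal(st$F, oracle$F, tolerance = 1e-8)
  expect_equal(st$sign, oracle$sign)
  expect_equal(st$df, c(1L, 6L))
})

test_that("degenerate cells follow the F = 0 and sentinel conventions", {
  arr <- toy_power(2, 2, 10, seed = 3)
  arr[1, 1, ] <- 0.25                      # zero variance
  des <- toy_design(10, seed = 3)
  st <- ancova_f_map(arr, des)
  expect_equal(st$F[1, 1], 0)
  expect_equal(st$sign[1, 1], 0)

  arr[2, 2, ] <- des$group                 # perfect separation
  st2 <- ancova_f_map(arr, des)
  expect_true(is.infinite(st2$F[2, 2]))

  des_bad <- des
  des_bad$age <- des_bad$group             # collinear covariate
  expect_error(ancova_f_map(arr, des_bad), "degenerate design|collinear")
})

test_that("F map is invariant to shifting a cell and rescaling power", {
  arr <- toy_power(4, 3, 12, seed = 8)
  des <- toy_design(12, seed = 8)
  st <- ancova_f_map(arr, des)
  shifted <- arr
  shifted[2, 2, ] <- shifted[2, 2, ] + 5
  expect_equal(ancova_f_map(shifted, des)$F, st$F, tolerance = 1e-9)
  expect_equal(ancova_f_map(arr * 7.3, des)$F, st$F, tolerance = 1e-9)
})

test_that("cluster-forming threshold behaves like an F quantile", {
  expect_equal(critical_f(0.005, c(1, 1e9)), stats::qchisq(0.995, 1),
               tolerance = 1e-5)
  expect_lt(critical_f(0.5, c(1, 30)), 30 / 28)   # median < mean of F(1,30)
  alphas <- c(0.05, 0.01, 0.005, 0.001)
  thr <- vapply(alphas, critical_f, numeric(1), df = c(1, 36))
  expect_true(all(diff(thr) > 0))
})

test_that("binarize-and-split separates signs above the threshold", {
  mk <- function(F, s) structure(list(F = F, sign = s, df = c(1, 10)),
                                 class = "stat_map")
  st <- mk(matrix(1, 2, 2), matrix(1, 2, 2))
  m <- binarize_and_split(st, 5)
  expect_false(any(m$positive) || any(m$negative))

  F1 <- matrix(0, 2, 2); F1[1, 2] <- 9
  s1 <- matrix(0, 2, 2); s1[1, 2] <- 1
  m1 <- binarize_and_split(mk(F1, s1), 5)
  expect_equal(which(m1$positive), 3L)
  expect_false(any(m1$negative))

  # mixed 3 x 2 map against hand enumeration
  F2 <- matrix(c(6, 2, 9, 4, 7, 8), 3, 2)
  s2 <- matrix(c(1, 1, -1, -1, 1, -1), 3, 2)
  m2 <- binarize_and_split(mk(F2, s2), 5)
  expect_equal(which(m2$positive), c(1L, 5L))
  expect_equal(which(m2$negative), c(3L, 6L))
  expect_false(any(m2$positive & m2$negative))
})

test_that("cluster formation matches a flood-fill oracle", {
  sp <- make_grid(c(2, 2, 1), 10)
  freqs <- c(10, 10.25, 10.5)
  empty <- form_clusters(matrix(FALSE, 4, 3), sp, freqs)
  expect_length(empty, 0L)

  m <- matrix(FALSE, 4, 3); m[1, 1] <- TRUE; m[1, 2] <- TRUE
  one <- form_clusters(m, sp, freqs)
  expect_length(one, 1L)
  expect_equal(nrow(one[[1]]$cells), 2L)
  expect_equal(one[[1]]$freq_range, c(10, 10.25))

  # crafted and random masks vs BFS
  sp2 <- make_grid(c(3, 3, 3), 10)
  freqs2 <- seq(2, 4.25, by = 0.25)
  for (seed in 1:5) {
    mask <- megclust:::with_seed(seed,
      matrix(stats::runif(27 * 10) < 0.2, 27, 10))
    got <- form_clusters(mask, sp2, freqs2)
    want <- naive_clusters(mask, sp2, freqs2)
    expect_setequal(vapply(got, function(c) cluster_key(c$cells),
                           character(1)),
                    vapply(want, cluster_key, character(1)))
  }

  # per-frequency extents agree with direct counting
  mask <- megclust:::with_seed(2, matrix(stats::runif(27 * 10) < 0.3, 27, 10))
  for (cl in form_clusters(mask, sp2, freqs2)) {
    cnt <- table(cl$cells[, "freq_bin"])
    expect_equal(unname(cl$extent_by_freq), as.integer(cnt))
  }
})

test_that("minimum extent follows the floor rule", {
  expect_equal(min_extent(1202, 0.01), 12L)
  expect_equal(min_extent(100, 0.01), 1L)
  expect_equal(min_extent(1250, 0.01), 12L)
})

test_that("cluster mass sums member F values with the sentinel cap", {
  st <- structure(list(F = matrix(c(7.5, 8, 9, 10), 2, 2),
                       sign = matrix(1, 2, 2), df = c(1, 10)),
                  class = "stat_map")
  expect_equal(cluster_mass(cbind(node = 1, freq_bin = 1), st), 7.5)
  cells <- cbind(node = c(2, 1, 2), freq_bin = c(1, 2, 2))
  expect_equal(cluster_mass(cells, st), 27)
  st$F[1, 1] <- Inf
  expect_equal(cluster_mass(cbind(node = c(1, 2), freq_bin = c(1, 1)), st),
               1e12 + 8)
  expect_error(cluster_mass(cbind(node = 9, freq_bin = 1), st), "outside")
})

test_that("permutation p-values follow the plain-proportion convention", {
  expect_equal(cbpt_pvalue(2.5, c(1, 2, 3, 4)), 0.5)
  expect_equal(cbpt_pvalue(99, c(1, 2, 3, 4)), 0)
  expect_equal(cbpt_pvalue(4, c(1, 2, 3, 4)), 0.25)
  null <- megclust:::with_seed(1, stats::rexp(40))
  ps <- vapply(sort(null), cbpt_pvalue, numeric(1), null = null)
  expect_true(all(diff(ps) <= 0))              # monotone decreasing
  expect_true(all(ps %in% ((0:40) / 40)))
  expect_equal(cbpt_pvalue(2.5, c(1, 2, 3, 4), correction = TRUE), 3 / 5)
})

test_that("permutation null enumerates exhaustively for small cohorts", {
  coh <- simulate_cohort(sim_config(n_per_group = 3,
                                    grid_shape = c(2, 2, 1), seed = 6))
  cfg <- cbpt_config(n_permutations = 20, cluster_alpha = 0.2, seed = 6)
  null <- permutation_null(coh$power, coh$covariates, coh$space, cfg)
  expect_length(null, 20L)  # choose(6, 3) relabellings
  expect_true(attr(null, "exhaustive"))

  # sampled masses live on the exhaustive support
  cfg19 <- cbpt_config(n_permutations = 19, cluster_alpha = 0.2, seed = 6)
  sampled <- permutation_null(coh$power, coh$covariates, coh$space, cfg19)
  expect_false(attr(sampled, "exhaustive"))
  expect_true(all(sampled %in% null))

  cfg1 <- cbpt_config(n_permutations = 1, cluster_alpha = 0.2, seed = 1)
  coh2 <- simulate_cohort(sim_config(n_per_group = 4,
                                     grid_shape = c(2, 2, 1), seed = 2))
  expect_length(permutation_null(coh2$power, coh2$covariates, coh2$space,
                                 cfg1), 1L)
})

test_that("full CBPT equals the naive loop reference on a small grid", {
  cfg <- sim_config(n_per_group = 6, grid_shape = c(3, 2, 2),
                    freq_step = 4, freq_band = c(2, 30),
                    theta_effect_range = c(6, 6), theta_effect_size = 0.4,
                    beta_effect_range_left = c(14, 18),
                    beta_effect_range_right = c(14, 18), seed = 17)
  coh <- simulate_cohort(cfg)
  ccfg <- cbpt_config(n_permutations = 60, cluster_alpha = 0.05, seed = 17)
  fit <- cbpt(coh$power, coh$covariates, coh$space, ccfg)
  ref <- naive_cbpt(coh$power$power, coh$covariates, coh$space, ccfg)

  expect_equal(sort(fit$null_max), sort(ref$null), tolerance = 1e-10)
  expect_setequal(
    vapply(fit$clusters, function(c) cluster_key(c$cells), character(1)),
    vapply(ref$clusters, function(c) cluster_key(c$cells), character(1)))
  get_p <- function(cl) vapply(cl, `[[`, numeric(1), "p_value")
  get_m <- function(cl) vapply(cl, `[[`, numeric(1), "mass")
  keyed <- function(cl) {
    k <- vapply(cl, function(c) cluster_key(c$cells), character(1))
    o <- order(k); list(k = k[o], p = get_p(cl)[o], m = get_m(cl)[o])
  }
  a <- keyed(fit$clusters); b <- keyed(ref$clusters)
  expect_equal(a$m, b$m, tolerance = 1e-10)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("observed cluster masses are invariant to joint subject reorder", {
  coh <- simulate_cohort(sim_config(n_per_group = 8,
                                    grid_shape = c(3, 3, 1),
                                    freq_step = 1, seed = 23))
  cfg <- cbpt_config(n_permutations = 30, cluster_alpha = 0.05, seed = 23)
  fit <- cbpt(coh$power, coh$covariates, coh$space, cfg)
  perm <- megclust:::with_seed(99, sample(16))
  fit2 <- cbpt(coh$power$power[, , perm], coh$covariates[perm, ],
               coh$space, cfg)
  expect_equal(sort(vapply(fit$clusters, `[[`, numeric(1), "mass")),
               sort(vapply(fit2$clusters, `[[`, numeric(1), "mass")),
               tolerance = 1e-9)
})

test_that("covariate adjustment neutralises an age confound", {
  # age drives theta power and differs by group; no true group effect
  rejections <- function(covars) {
    sum(vapply(1:12, function(s) {
      coh <- simulate_cohort(sim_config(
        n_per_group = 15, grid_shape = c(3, 3, 2), freq_step = 1,
        theta_effect_size = 0, beta_effect_size = 0,
        age_group_shift = 8, age_power_slope = 0.03, seed = 400 + s))
      fit <- cbpt(coh$power, coh$covariates, coh$space,
                  cbpt_config(n_permutations = 120, seed = s),
                  covariates = covars)
      any(vapply(fit$clusters, `[[`, logical(1), "significant"))
    }, logical(1)))
  }
  adj <- rejections(c("age", "wm_volume"))
  unadj <- rejections(character(0))
  expect_lte(adj, 3)          # near-nominal under adjustment
  expect_gt(unadj, adj)       # unadjusted variant inflates
})

test_that("per-sign null option returns one distribution per sign", {
  coh <- simulate_cohort(sim_config(n_per_group = 6,
                                    grid_shape = c(2, 2, 2),
                                    freq_step = 2, seed = 3))
  cfg <- cbpt_config(n_permutations = 25, cluster_alpha = 0.1,
                     null_pooling = "per_sign", seed = 3)
  null <- permutation_null(coh$power, coh$covariates, coh$space, cfg)
  expect_true(is.matrix(null))
  expect_equal(colnames(null), c("positive", "negative"))
  pooled <- permutation_null(coh$power, coh$covariates, coh$space,
                             cbpt_config(n_permutations = 25,
                                         cluster_alpha = 0.1, seed = 3))
  expect_equal(pmax(null[, 1], null[, 2]), as.numeric(pooled))
})
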