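test_that("marker extraction averages cluster cells per subject", {
  arr <- array(0.01, dim = c(4, 5, 3))
  cl <- list(cells = cbind(node = c(1, 2), freq_bin = c(1, 1)))
  expect_equal(extract_marker(arr, cl), rep(0.01, 3))

  arr2 <- toy_power(4, 5, 3, seed = 1)
  single <- list(cells = cbind(node = 3, freq_bin = 4))
  expect_equal(extract_marker(arr2, single), arr2[3, 4, ])

  cells <- cbind(node = c(1, 2, 4), freq_bin = c(2, 3, 5))
  want <- vapply(1:3, function(s)
    mean(c(arr2[1, 2, s], arr2[2, 3, s], arr2[4, 5, s])), numeric(1))
  expect_equal(extract_marker(arr2, list(cells = cells)), want)

  expect_error(extract_marker(arr2, list(cells = NULL)), "empty")
  # linearity: marker of an average equals average of markers
  a <- toy_power(4, 5, 3, seed = 2); b <- toy_power(4, 5, 3, seed = 3)
  expect_equal(extract_marker((a + b) / 2, list(cells = cells)),
               (extract_marker(a, list(cells = cells)) +
                extract_marker(b, list(cells = cells))) / 2)
})

test_that("Spearman association uses average ranks and the t approximation", {
  r1 <- spearman_assoc(1:4, c(10, 20, 30, 40))
  expect_equal(r1$rho, 1)
  expect_equal(spearman_assoc(1:4, c(40, 30, 20, 10))$rho, -1)

  x <- c(1, 2, 2, 3, 5, 5, 5, 8)
  y <- c(2, 1, 4, 4, 6, 9, 7, 8)
  got <- spearman_assoc(x, y)
  # rank-then-Pearson oracle under ties
  rho_oracle <- stats::cor(rank(x), rank(y))
  expect_equal(got$rho, rho_oracle, tolerance = 1e-12)
  expect_equal(got$rho, stats::cor(x, y, method = "spearman"),
               tolerance = 1e-12)
  t_or <- rho_oracle * sqrt(6 / (1 - rho_oracle^2))
  expect_equal(got$p_value, 2 * stats::pt(-abs(t_or), 6), tolerance = 1e-12)

  # invariance under strictly monotone transforms
  expect_equal(spearman_assoc(exp(x), y^3 + 2)$rho, got$rho)
  # listwise deletion
  expect_equal(spearman_assoc(c(x, NA), c(y, 1))$n, 8L)
  expect_error(spearman_assoc(rep(1, 5), 1:5), "constant")
})

test_that("scalar group test reduces to t-squared without covariates", {
  des <- toy_design(14, seed = 4)
  vals <- megclust:::with_seed(4, stats::rnorm(14))
  r <- scalar_group_test(vals, des, covariates = character(0))
  tt <- stats::t.test(vals[des$group == 1], vals[des$group == 0],
                      var.equal = TRUE)
  expect_equal(r$F, unname(tt$statistic)^2, tolerance = 1e-10)

  same <- rep(c(1, 1), 7)
  r0 <- scalar_group_test(rep(2.2, 14), des)
  expect_equal(r0$F, 0)
  expect_equal(r0$eta_squared, 0)

  # matches the per-cell engine on a 1-cell power matrix
  arr <- array(vals, dim = c(1, 1, 14))
  st <- ancova_f_map(arr, des)
  r2 <- scalar_group_test(vals, des)
  expect_equal(r2$F, st$F[1, 1], tolerance = 1e-12)
})

test_that("group F from exact-moment samples matches the summary-stat oracle", {
  # reconstruct two samples with exactly the published moments
  mk <- function(n, m, s, seed) {
    z <- megclust:::with_seed(seed, stats::rnorm(n))
    m + s * (z - mean(z)) / stats::sd(z)
  }
  x1 <- mk(61, 75.26, 4.19, 1)
  x0 <- mk(56, 72.13, 5.11, 2)
  des <- data.frame(group = rep(c(1, 0), c(61, 56)))
  r <- scalar_group_test(c(x1, x0), des, covariates = character(0))
  # closed-form one-way F from the summary statistics
  sp2 <- (60 * 4.19^2 + 55 * 5.11^2) / 115
  f_oracle <- (75.26 - 72.13)^2 / (sp2 * (1 / 61 + 1 / 56))
  expect_equal(r$F, f_oracle, tolerance = 1e-8)
  expect_equal(r$F, 13.2, tolerance = 0.01)
})

test_that("association report recovers planted score links", {
  coh <- simulate_cohort(sim_config(n_per_group = 50,
                                    grid_shape = c(3, 3, 2),
                                    score_link_strength = 0.5, seed = 55))
  markers <- data.frame(
    theta = extract_marker(coh$power, coh$truth$effects$theta$cells),
    beta_left = extract_marker(coh$power,
                               coh$truth$effects$beta_left$cells))
  rep <- association_report(
    markers, coh$covariates[, c("mmse", "delayed_recall",
                                "immediate_recall", "lhv")],
    coh$covariates)
  a <- rep$associations
  th_mmse <- a[a$marker == "theta" & a$score == "mmse", ]
  expect_lt(th_mmse$rho, -0.3)
  bl_ir <- a[a$marker == "beta_left" & a$score == "immediate_recall", ]
  expect_gt(bl_ir$rho, 0.3)
  expect_equal(nrow(rep$group_tests), 2L)
  expect_true(all(c("F", "eta_squared") %in% names(rep$group_tests)))

  with_bh <- association_report(markers, coh$covariates[, "mmse",
                                                        drop = FALSE],
                                coh$covariates, p_adjust = "BH")
  expect_true("p_adjusted" %in% names(with_bh$associations))
})

test_that("null score links stay inside the n-dependent null band", {
  hits <- 0L
  n_seeds <- 10L
  for (s in seq_len(n_seeds)) {
    coh <- simulate_cohort(sim_config(n_per_group = 30,
                                      grid_shape = c(2, 2, 2),
                                      score_link_strength = 0,
                                      seed = 700 + s))
    m <- extract_marker(coh$power, coh$truth$effects$theta$cells)
    rho <- spearman_assoc(m, coh$covariates$mmse)$rho
    if (abs(rho) < 1.96 / sqrt(59)) hits <- hits + 1L
  }
  expect_gte(hits, round(0.9 * n_seeds))
})
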