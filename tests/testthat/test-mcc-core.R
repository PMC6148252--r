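test_that("conjugate block posteriors match the closed forms", {
  hp <- mcc_hyperparameters()

  # no data: posterior equals prior
  bp0 <- block_posterior(numeric(0), "numerical", hp)
  expect_equal(bp0$mu, 0)
  expect_equal(bp0$lambda, 1 / 100)
  expect_equal(bp0$shape, 1 / 200)
  expect_equal(bp0$rate, (1 / 100) * (1 / 100) / 2)

  # Normal-Gamma on {1, 2, 3}: hand-computed
  x <- c(1, 2, 3)
  bp <- block_posterior(x, "numerical", hp)
  lam_n <- 0.01 + 3
  mu_n <- (0.01 * 0 + 6) / lam_n
  expect_equal(bp$lambda, lam_n)
  expect_equal(bp$mu, mu_n)
  expect_equal(bp$shape, 0.005 + 1.5)
  expect_equal(bp$rate, 0.00005 + 0.5 * (14 - lam_n * mu_n^2))

  # Dirichlet(1) with counts (3, 1): posterior mean (4/6, 2/6)
  bd <- block_posterior(c(1, 1, 1, 2), "categorical", hp, n_levels = 2)
  expect_equal(bd$rho, c(4, 2))
  expect_equal(bd$prob, c(4 / 6, 2 / 6))

  # Gamma(1, 1) with Poisson counts summing 7 over 3 entries: Gamma(8, 4)
  bg <- block_posterior(c(2, 4, 1), "integer", hp)
  expect_equal(bg$shape, 8)
  expect_equal(bg$rate, 4)
  expect_equal(bg$rate_mean, 2)

  expect_error(block_posterior(c(-1, 2), "integer", hp))
})

test_that("a strongly separated Gaussian split is recovered exactly", {
  set.seed(21)
  X <- matrix(rnorm(40, mean = rep(c(-5, 5), each = 20)), ncol = 1)
  fit <- mcc_fit_single(numeric_mcc_data(X), truncation = c(2, 2, 4), seed = 13)
  expect_equal(fit$n_views, 1)
  k <- fit$subject_assignments$cluster
  expect_equal(adjusted_rand_index(k, rep(1:2, each = 20)), 1)
  expect_equal(length(unique(k)), 2)
})

test_that("all-constant data collapses to a single view and cluster", {
  X <- matrix(2.5, nrow = 12, ncol = 5)
  fit <- mcc_fit_single(numeric_mcc_data(X), truncation = c(3, 3, 3), seed = 2)
  expect_equal(fit$n_views, 1)
  expect_equal(unique(fit$feature_assignments$feature_cluster), 1L)
  expect_equal(unique(fit$subject_assignments$cluster), 1L)
})

test_that("the ELBO trace is non-decreasing for every restart", {
  fx <- make_recovery_fixture(301)
  small <- fx$data
  # restrict to a manageable subset for speed: first 40 features
  keep <- fx$plan$feature[1:40]
  tab <- small$values[, c("subject_id", keep)]
  data <- mcc_data(tab, small$specs[match(keep, small$specs$feature), ])
  for (s in 1:5) {
    fit <- mcc_fit_single(data, truncation = c(4, 3, 5), seed = 100 + s)
    tr <- fit$elbo_trace
    expect_true(all(diff(tr) >= -1e-8 * abs(tr[-length(tr)])))
  }
})

test_that("plug-in likelihood and ELBO are invariant to cluster relabeling", {
  set.seed(33)
  X <- matrix(rnorm(60, rep(c(-4, 0, 4), each = 20)), ncol = 2)
  data <- numeric_mcc_data(X)
  fit <- mcc_fit_single(data, truncation = c(2, 2, 4), seed = 3)

  # relabel subject clusters by a permutation and recompute the plug-in score
  enc <- mvcoclust:::encode_mcc_data(data)
  assign <- list(feature_assignments = fit$feature_assignments,
                 subject_assignments = fit$subject_assignments,
                 n_views = fit$n_views)
  base <- mvcoclust:::hard_blocks_and_loglik(enc, assign, fit$hyperparameters)
  perm <- assign
  ks <- sort(unique(perm$subject_assignments$cluster))
  relab <- rev(seq_along(ks))
  perm$subject_assignments$cluster <- relab[perm$subject_assignments$cluster]
  permuted <- mvcoclust:::hard_blocks_and_loglik(enc, perm, fit$hyperparameters)
  expect_equal(permuted$loglik, base$loglik, tolerance = 1e-10)
})

test_that("single-view truncation reduces to one-view co-clustering", {
  set.seed(8)
  X <- matrix(rnorm(34 * 8, mean = rep(c(-3, 3), each = 17)), 34, 8)
  data <- numeric_mcc_data(X)
  full <- mcc_fit(data, truncation = c(3, 2, 4), n_restarts = 5, seed = 4)
  lbm <- mcc_fit(data, truncation = c(1, 2, 4), n_restarts = 5, seed = 4)
  expect_equal(full$n_views, 1)
  expect_equal(lbm$n_views, 1)
  expect_equal(adjusted_rand_index(full$subject_assignments$cluster,
                                   lbm$subject_assignments$cluster), 1)
})

test_that("a fully-missing feature does not perturb other view assignments", {
  set.seed(41)
  X <- matrix(rnorm(30 * 6, mean = rep(c(-3, 3), each = 15)), 30, 6)
  X2 <- cbind(X, empty = NA_real_)
  base <- mcc_fit(numeric_mcc_data(X), truncation = c(2, 2, 3),
                  n_restarts = 4, seed = 6)
  with_na <- mcc_fit(numeric_mcc_data(X2), truncation = c(2, 2, 3),
                     n_restarts = 4, seed = 6)
  shared <- base$feature_assignments$feature
  v1 <- base$feature_assignments$view
  v2 <- with_na$feature_assignments$view[
    match(shared, with_na$feature_assignments$feature)]
  expect_equal(adjusted_rand_index(v1, v2), 1)
  k1 <- base$subject_assignments$cluster
  k2 <- with_na$subject_assignments$cluster[
    match(paste(base$subject_assignments$subject_id, base$subject_assignments$view),
          paste(with_na$subject_assignments$subject_id, with_na$subject_assignments$view))]
  expect_equal(adjusted_rand_index(k1, k2), 1)
})

test_that("pruning relabels clusters contiguously and keeps co-membership", {
  set.seed(17)
  X <- matrix(rnorm(24 * 4, mean = rep(c(-4, 4), each = 12)), 24, 4)
  fit <- mcc_fit_single(numeric_mcc_data(X), truncation = c(4, 3, 6), seed = 19)
  fa <- fit$feature_assignments
  sa <- fit$subject_assignments
  expect_equal(sort(unique(fa$view)), seq_len(fit$n_views))
  for (v in seq_len(fit$n_views)) {
    ks <- sa$cluster[sa$view == v]
    expect_equal(sort(unique(ks)), seq_len(max(ks)))
    gs <- fa$feature_cluster[fa$view == v]
    expect_equal(sort(unique(gs)), seq_len(max(gs)))
  }
})

test_that("restart machinery honours its contracts", {
  set.seed(55)
  X <- matrix(rnorm(20 * 4, mean = rep(c(-3, 3), each = 10)), 20, 4)
  data <- numeric_mcc_data(X)

  # n_restarts = 1 is identical to fit_single at the derived seed
  one <- mcc_fit(data, truncation = c(2, 2, 3), n_restarts = 1, seed = 9)
  single <- mcc_fit_single(data, truncation = c(2, 2, 3),
                           seed = one$restart_scores$seed[1])
  expect_equal(one$feature_assignments, single$feature_assignments)
  expect_equal(one$elbo, single$elbo)

  # the selected solution maximizes the selection score
  many <- mcc_fit(data, truncation = c(2, 2, 3), n_restarts = 6, seed = 9)
  expect_gte(many$elbo, max(many$restart_scores$elbo) - 1e-10)
  by_ll <- mcc_fit(data, truncation = c(2, 2, 3), n_restarts = 6, seed = 9,
                   select = "loglik")
  expect_gte(by_ll$logLik, max(by_ll$restart_scores$logLik) - 1e-10)

  # determinism: same seed, same solution
  again <- mcc_fit(data, truncation = c(2, 2, 3), n_restarts = 6, seed = 9)
  expect_identical(many$feature_assignments, again$feature_assignments)
  expect_identical(many$subject_assignments, again$subject_assignments)
  expect_identical(many$elbo, again$elbo)
})
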