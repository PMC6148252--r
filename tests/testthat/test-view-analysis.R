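# minimal hand-built solution object for the analysis helpers that only
# need assignments and block parameters
fake_fit <- function(feature_assignments, subject_assignments, blocks = NULL) {
  structure(list(feature_assignments = feature_assignments,
                 subject_assignments = subject_assignments,
                 n_views = max(feature_assignments$view),
                 blocks = blocks),
            class = "mcc_fit")
}

test_that("adjusted Rand index matches its conventions and the pair-count oracle", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(1:6, rep(1, 6)), 0)
  a <- c(1, 1, 2, 2); b <- c(1, 2, 1, 2)
  expect_equal(adjusted_rand_index(a, b), ari_pair_counting(a, b))
  expect_error(adjusted_rand_index(c(1, 2), c(1, 2, 3)),
               class = "mvcoclust_partition_error")
})

test_that("adjusted Rand index agrees with brute force on all small partitions", {
  parts5 <- all_partitions(5)
  for (a in parts5) {
    for (b in parts5) {
      expect_equal(adjusted_rand_index(a, b), ari_pair_counting(a, b),
                   tolerance = 1e-12)
    }
  }
  # partitions of 6, cross-checked against both the oracle and mclust
  parts6 <- all_partitions(6)
  set.seed(2)
  idx <- sample(length(parts6), 40)
  for (i in idx) {
    for (j in sample(length(parts6), 10)) {
      a <- parts6[[i]]; b <- parts6[[j]]
      expect_equal(adjusted_rand_index(a, b), ari_pair_counting(a, b),
                   tolerance = 1e-12)
      expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                   tolerance = 1e-12)
    }
  }
})

test_that("first-PC scores recover a planted factor with the sign convention", {
  set.seed(12)
  n <- 500
  f <- rnorm(n)
  X <- sapply(1:10, function(j) 0.95 * f + rnorm(n, sd = sqrt(1 - 0.95^2)))
  s <- first_pc_scores(X)
  expect_gte(abs(cor(s, f)), 0.99)
  # majority of loadings nonnegative
  expect_gte(mean(attr(s, "loadings") >= 0), 0.5)
  # the orientation rule resolves the PCA sign indeterminacy deterministically:
  # negating every feature negates the oriented scores
  s2 <- first_pc_scores(-X)
  expect_equal(as.numeric(s2), -as.numeric(s), tolerance = 1e-8)
  expect_gte(mean(attr(s2, "loadings") >= 0), 0.5)
  # rank-1 case: scores proportional to either feature
  X2 <- cbind(f, 2 * f)
  s3 <- first_pc_scores(X2)
  expect_equal(abs(cor(s3, f)), 1, tolerance = 1e-12)
})

test_that("PC correlation matrix is symmetric with unit diagonal and detects independence", {
  set.seed(31)
  n <- 120
  # two independent planted two-cluster factors, one per view
  z1 <- sample(c(-1.5, 1.5), n, replace = TRUE)
  z2 <- sample(c(-1.5, 1.5), n, replace = TRUE)
  mk <- function(z, m) sapply(seq_len(m), function(j) z + rnorm(n))
  X <- cbind(mk(z1, 6), mk(z2, 6))
  colnames(X) <- paste0("fc", 1:12)
  data <- numeric_mcc_data(X, group = "FC")
  fit <- mcc_fit(data, truncation = c(3, 2, 4), n_restarts = 6, seed = 22)
  expect_equal(fit$n_views, 2)
  M <- pc_correlation_matrix(fit, data)
  expect_equal(M, t(M))
  eligible <- which(attr(M, "eligible"))
  expect_true(all(diag(M)[eligible] == 1))
  off <- M[eligible[1], eligible[2]]
  expect_lt(abs(off), 4 / sqrt(n))
})

test_that("depression-related proportion follows the FC exclusion rule", {
  fa <- tibble::tibble(
    feature = c(paste0("fc", 1:3), paste0("q", 1:5)),
    dtype = "numerical", view = 1L, feature_cluster = 1L)
  sa <- tibble::tibble(subject_id = "S1", view = 1L, cluster = 1L)
  specs <- dplyr::bind_rows(
    feature_spec(paste0("fc", 1:3), "numerical", group = "FC"),
    feature_spec(paste0("q", 1:5), "numerical",
                 depression_related = c(TRUE, TRUE, TRUE, FALSE, FALSE)))
  tab <- tibble::as_tibble(setNames(as.list(rep(0, 8)), specs$feature))
  tab <- tibble::add_column(tab, subject_id = "S1", .before = 1)
  data <- mcc_data(tab, specs)
  fit <- fake_fit(fa, sa)

  res <- depression_feature_proportion(fit, data, 1)
  expect_equal(res$proportion, 3 / 5)       # 3 flagged of 5 counted (non-FC)
  expect_equal(res$proportion_all, 3 / 8)

  # a view of only FC features scores 0
  fa_fc <- fa[1:3, ]
  res2 <- depression_feature_proportion(fake_fit(fa_fc, sa), data, 1)
  expect_equal(res2$proportion, 0)

  # all flags true scores 1
  specs$depression_related[4:8] <- TRUE
  data3 <- mcc_data(tab, specs)
  expect_equal(depression_feature_proportion(fit, data3, 1)$proportion, 1)
})

test_that("average Cohen's d follows the neighboring-means formula and eligibility", {
  mk_fit <- function(mu, prec = 1) {
    G <- nrow(mu); K <- ncol(mu)
    fa <- tibble::tibble(
      feature = sprintf("fc%02d", seq_len(4 * G)), dtype = "numerical",
      view = 1L, feature_cluster = rep(seq_len(G), each = 4))
    ids <- sprintf("S%02d", seq_len(5 * K))
    sa <- tibble::tibble(subject_id = ids, view = 1L,
                         cluster = rep(seq_len(K), each = 5))
    blocks <- list(list(numerical = list(
      mu = mu, lambda = matrix(1, G, K),
      shape = matrix(prec, G, K), rate = matrix(1, G, K))))
    specs <- feature_spec(fa$feature, "numerical", group = "FC")
    tab <- tibble::as_tibble(setNames(as.list(rep(0, nrow(fa))), fa$feature))
    tab <- tab[rep(1, length(ids)), ]
    tab <- tibble::add_column(tab, subject_id = ids, .before = 1)
    labels <- tibble::tibble(subject_id = ids, label = "depressed")
    list(fit = fake_fit(fa, sa, blocks), data = mcc_data(tab, specs, labels))
  }

  # two blocks, means 0 and 0.8, both sd 1 -> d = 0.8
  z <- mk_fit(matrix(c(0, 0.8), 1, 2))
  expect_equal(as.numeric(average_cohens_d(z$fit, z$data, 1)), 0.8)

  # means {0, 1, 3}, sd 1 -> neighboring d {1, 2}, average 1.5
  z2 <- mk_fit(matrix(c(0, 1, 3), 1, 3))
  expect_equal(as.numeric(average_cohens_d(z2$fit, z2$data, 1)), 1.5)

  # equal means -> 0
  z3 <- mk_fit(matrix(c(1, 1), 1, 2))
  expect_equal(as.numeric(average_cohens_d(z3$fit, z3$data, 1)), 0)

  # invariant under adding an ineligible (small) feature cluster
  z4 <- mk_fit(matrix(c(0, 1, 3, 9, 9, 9), 2, 3, byrow = TRUE))
  z4$fit$feature_assignments$feature_cluster[5:8] <- c(2L, 2L, 2L, 2L)
  # cluster 2 now has 4 features (eligible); shrink it to 3 to make ineligible
  z4$fit$feature_assignments <- z4$fit$feature_assignments[-8, ]
  expect_equal(as.numeric(average_cohens_d(z4$fit, z4$data, 1)), 1.5)

  # no eligible feature cluster -> not applicable
  z5 <- mk_fit(matrix(c(0, 1), 1, 2))
  z5$fit$feature_assignments <- z5$fit$feature_assignments[1:3, ]
  res <- average_cohens_d(z5$fit, z5$data, 1)
  expect_true(is.na(res))
  expect_false(attr(res, "applicable"))
})

test_that("the significance screen applies per-type Bonferroni thresholds", {
  set.seed(61)
  n <- 40
  k <- rep(1:2, each = n / 2)
  tab <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:n),
    strong = rnorm(n, mean = c(-5, 5)[k]),
    flat = rnorm(n),
    const = rep(1, n),
    cat1 = ifelse(k == 1, sample(c("a", "b"), n, TRUE, c(.9, .1)),
                  sample(c("a", "b"), n, TRUE, c(.1, .9))))
  specs <- dplyr::bind_rows(
    feature_spec(c("strong", "flat", "const"), "numerical"),
    feature_spec("cat1", "categorical", levels = list(c("a", "b"))))
  data <- mcc_data(tab, specs)
  fa <- tibble::tibble(feature = c("strong", "flat", "const", "cat1"),
                       dtype = c("numerical", "numerical", "numerical", "categorical"),
                       view = 1L, feature_cluster = 1L)
  sa <- tibble::tibble(subject_id = tab$subject_id, view = 1L, cluster = k)
  fit <- fake_fit(fa, sa)

  res <- feature_significance(fit, data, 1)
  expect_equal(res$m[res$dtype == "numerical"], rep(3L, 3))
  expect_equal(unique(res$threshold[res$dtype == "numerical"]), 0.05 / 3)
  # single categorical feature: threshold exactly 0.05
  expect_equal(res$threshold[res$feature == "cat1"], 0.05)
  expect_true(res$significant[res$feature == "strong"])
  expect_false(res$significant[res$feature == "flat"])
  # constant feature: p = 1, never significant
  expect_equal(res$p_value[res$feature == "const"], 1)
  expect_false(res$significant[res$feature == "const"])
})

test_that("Hamming consensus distances are exact membership-disagreement ratios", {
  ids <- sprintf("S%d", 1:4)
  mk_sa <- function(mat) {
    dplyr::bind_rows(lapply(seq_len(ncol(mat)), function(v)
      tibble::tibble(subject_id = ids, view = v, cluster = mat[, v])))
  }
  fa <- tibble::tibble(feature = sprintf("f%d", 1:15), dtype = "numerical",
                       view = rep(1:15, each = 1), feature_cluster = 1L)

  # identical memberships in every view -> distance 0
  same <- matrix(1L, 4, 15)
  cons <- hamming_consensus(fake_fit(fa, mk_sa(same)))
  expect_true(all(cons$distance == 0))

  # subjects 1 and 2 differing in every view -> 1; in 3 of 15 views -> 0.2
  m <- matrix(1L, 4, 15)
  m[2, ] <- 2L                      # subject 2 differs everywhere
  m[3, 1:3] <- 2L                   # subject 3 differs in 3 views
  m[2, 1:3] <- 2L; m[3, 1:3] <- 2L  # keep 2 and 3 together in those views
  cons2 <- hamming_consensus(fake_fit(fa, mk_sa(m)))
  expect_equal(cons2$distance["S1", "S2"], 1)
  expect_equal(cons2$distance["S1", "S3"], 3 / 15)
  expect_equal(cons2$distance, t(cons2$distance))
  expect_true(all(diag(cons2$distance) == 0))
  expect_true(all(cons2$distance >= 0 & cons2$distance <= 1))
  expect_match(cons2$newick, "^\\(")
})

test_that("sensitivity sweep reports one row per grid point with exact self-agreement", {
  set.seed(71)
  X <- matrix(rnorm(30 * 6, mean = rep(c(-4, 4), each = 15)), 30, 6)
  data <- numeric_mcc_data(X)
  grid <- tibble::tibble(alpha1 = c(1, 1.5), beta = c(1, 0.5))
  res <- sensitivity_sweep(data, grid, truncation = c(2, 2, 3),
                           n_restarts = 3, seed = 14)
  expect_equal(nrow(res), 2)
  # zero-perturbation row with the identical seed reproduces the baseline
  expect_equal(res$view_ari[1], 1)
  expect_equal(res$subject_ari[1], 1)
  # strong planted structure survives a 50% perturbation
  expect_gte(res$subject_ari[2], 0.9)
})

test_that("the per-view report assembles the characterization statistics", {
  fx <- make_recovery_fixture(401)
  keep <- fx$plan$feature[c(1:20, 121:140)]
  data <- mcc_data(
    dplyr::bind_cols(fx$data$values[, c("subject_id", keep)]),
    fx$data$specs[match(keep, fx$data$specs$feature), ],
    tibble::tibble(subject_id = fx$data$values$subject_id,
                   label = rep(c("control", "depressed"), length.out = 134)))
  fit <- mcc_fit(data, truncation = c(3, 2, 4), n_restarts = 4, seed = 3)
  rep_ <- view_report(fit, data)
  expect_s3_class(rep_, "mcc_view_report")
  expect_equal(nrow(rep_), fit$n_views)
  expect_true(all(rep_$ari_diagnosis >= -1 & rep_$ari_diagnosis <= 1))
  expect_true(all(rep_$depression_proportion >= 0 & rep_$depression_proportion <= 1))
  expect_equal(sum(rep_$n_features), 40)
})
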