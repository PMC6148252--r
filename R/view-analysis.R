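#' Adjusted Rand index
#'
#' Hubert-Arabie chance-corrected agreement between two partitions of the
#' same subjects: 0 at chance level, 1 for complete agreement.
#'
#' @param a,b cluster label vectors over the same subjects (same length, no
#'   missing entries).
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  assert_that(length(a) == length(b) && length(a) > 0,
              "partitions must cover the same subject set",
              class = "mvcoclust_partition_error")
  assert_that(!anyNA(a) && !anyNA(b), "partitions must not contain missing labels",
              class = "mvcoclust_partition_error")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# subject cluster vector of one view, ordered like data subjects
view_subject_clusters <- function(fit, view, subject_ids = NULL) {
  sv <- fit$subject_assignments[fit$subject_assignments$view == view, ]
  assert_that(nrow(sv) > 0, "view ", view, " not present in solution")
  if (is.null(subject_ids)) subject_ids <- sv$subject_id
  sv$cluster[match(subject_ids, sv$subject_id)]
}

view_features <- function(fit, data, view, dtype = NULL, group = NULL) {
  fa <- fit$feature_assignments[fit$feature_assignments$view == view, ]
  assert_that(nrow(fa) > 0, "view ", view, " not present in solution")
  sp <- data$specs[match(fa$feature, data$specs$feature), ]
  keep <- rep(TRUE, nrow(fa))
  if (!is.null(dtype)) keep <- keep & fa$dtype %in% dtype
  if (!is.null(group)) keep <- keep & sp$group %in% group
  fa[keep, ]
}

#' First principal-component subject scores
#'
#' The leading principal component of a standardized numerical feature
#' submatrix, with the sign oriented so that the majority of loadings are
#' nonnegative. The `mcc_fit` method restricts the matrix to a view's
#' numerical FC features and imputes missing entries with the fitted block
#' posterior mean, so every subject receives a score; a view with fewer than
#' two FC features yields an explicit not-applicable result (all-`NA` scores
#' with attribute `applicable = FALSE`).
#'
#' @param x a numeric matrix/data frame of subject-by-feature scores, or an
#'   `mcc_fit`.
#' @param ... further arguments for methods.
#' @return for the default method, a numeric score vector with attribute
#'   `loadings`; for `mcc_fit`, a tibble `subject_id`, `score` with
#'   attributes `loadings` and `applicable`.
#' @export
first_pc_scores <- function(x, ...) UseMethod("first_pc_scores")

#' @rdname first_pc_scores
#' @export
first_pc_scores.default <- function(x, ...) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  assert_that(ncol(X) >= 2, "need >= 2 features for a principal component")
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  scores <- pc$x[, 1]
  load <- pc$rotation[, 1]
  if (sum(load >= 0) < length(load) / 2) {
    scores <- -scores
    load <- -load
  }
  attr(scores, "loadings") <- load
  scores
}

#' @rdname first_pc_scores
#' @param data the [mcc_data] the model was fitted to.
#' @param view view index in the fitted solution.
#' @export
first_pc_scores.mcc_fit <- function(x, data, view, ...) {
  fa <- view_features(x, data, view, dtype = "numerical", group = "FC")
  ids <- data$values$subject_id
  if (nrow(fa) < 2) {
    out <- tibble::tibble(subject_id = ids, score = NA_real_)
    attr(out, "applicable") <- FALSE
    return(out)
  }
  X <- as.matrix(data$values[, fa$feature, drop = FALSE])
  k_of <- view_subject_clusters(x, view, ids)
  mu <- x$blocks[[view]]$numerical$mu
  for (j in seq_len(ncol(X))) {
    nas <- which(is.na(X[, j]))
    if (length(nas)) X[nas, j] <- mu[fa$feature_cluster[j], k_of[nas]]
  }
  scores <- first_pc_scores.default(X)
  out <- tibble::tibble(subject_id = ids, score = as.numeric(scores))
  attr(out, "applicable") <- TRUE
  attr(out, "loadings") <- attr(scores, "loadings")
  out
}

#' Between-view correlations of first principal components
#'
#' Pearson correlation between the per-subject first-PC scores of the FC
#' features of every pair of eligible views (those with at least two FC
#' features). Ineligible views are kept in the matrix as `NA` rows/columns.
#'
#' @param fit an `mcc_fit`.
#' @param data the fitted [mcc_data].
#' @return a symmetric view-by-view matrix with unit diagonal on eligible
#'   views; attribute `eligible` flags the views entering the analysis.
#' @export
pc_correlation_matrix <- function(fit, data) {
  V <- fit$n_views
  scores <- lapply(seq_len(V), function(v) first_pc_scores(fit, data, v))
  eligible <- vapply(scores, function(s) isTRUE(attr(s, "applicable")), TRUE)
  assert_that(sum(eligible) >= 2, "need >= 2 views with >= 2 FC features")
  M <- matrix(NA_real_, V, V)
  for (v in which(eligible)) {
    for (w in which(eligible)) {
      M[v, w] <- stats::cor(scores[[v]]$score, scores[[w]]$score)
    }
    M[v, v] <- 1
  }
  attr(M, "eligible") <- eligible
  M
}

#' Proportion of depression-related features in a view
#'
#' Counts features flagged depression-related (clinical questionnaire items
#' and the like) among a view's features. FC features are never counted in
#' either the numerator or the primary denominator; the all-feature
#' denominator is also reported since either reading is defensible.
#'
#' @param fit an `mcc_fit`.
#' @param data the fitted [mcc_data].
#' @param view view index.
#' @return a one-row tibble: `view`, `n_flagged`, `n_non_fc`, `n_total`,
#'   `proportion` (non-FC denominator), `proportion_all` (all-feature
#'   denominator).
#' @export
depression_feature_proportion <- function(fit, data, view) {
  fa <- view_features(fit, data, view)
  sp <- data$specs[match(fa$feature, data$specs$feature), ]
  non_fc <- sp$group != "FC"
  n_flag <- sum(sp$depression_related & non_fc)
  tibble::tibble(
    view = view, n_flagged = n_flag, n_non_fc = sum(non_fc),
    n_total = nrow(fa),
    proportion = if (sum(non_fc) == 0) 0 else n_flag / sum(non_fc),
    proportion_all = n_flag / nrow(fa)
  )
}

#' Average Cohen's d of a view's FC feature clusters
#'
#' For each eligible FC feature cluster the fitted Gaussian block means over
#' the eligible subject clusters are sorted and Cohen's
#' `d = (mu2 - mu1) / sqrt((sigma1^2 + sigma2^2) / 2)` is evaluated between
#' each pair of neighboring means (`mu1 < mu2`, so every d is nonnegative);
#' all d values in the view are then averaged. Eligibility is read strictly
#' from the study's conditioning rules: feature clusters with more than three
#' (i.e. at least four) FC features, and subject clusters with more than
#' three depressed subjects. Block standard deviations are the inverse square
#' root of the posterior-mean precision.
#'
#' @param fit an `mcc_fit`.
#' @param data the fitted [mcc_data]; its `labels` identify depressed
#'   subjects (without labels, all subjects count toward eligibility).
#' @param view view index.
#' @return the average Cohen's d (`NA` with attribute `applicable = FALSE`
#'   if no eligible cluster pair exists).
#' @export
average_cohens_d <- function(fit, data, view) {
  fa <- view_features(fit, data, view, dtype = "numerical")
  sp <- data$specs[match(fa$feature, data$specs$feature), ]
  fc_per_cluster <- tapply(sp$group == "FC", fa$feature_cluster, sum)
  eligible_g <- as.integer(names(fc_per_cluster)[fc_per_cluster >= 4])

  ids <- data$values$subject_id
  k_of <- view_subject_clusters(fit, view, ids)
  depressed <- if (!is.null(data$labels)) {
    data$labels$label[match(ids, data$labels$subject_id)] == "depressed"
  } else rep(TRUE, length(ids))
  dep_per_cluster <- tapply(depressed, k_of, sum)
  eligible_k <- as.integer(names(dep_per_cluster)[dep_per_cluster >= 4])

  bl <- fit$blocks[[view]]$numerical
  ds <- numeric(0)
  if (!is.null(bl) && length(eligible_k) >= 2) {
    for (g in eligible_g) {
      mu <- bl$mu[g, eligible_k]
      sd_ <- sqrt(bl$rate[g, eligible_k] / bl$shape[g, eligible_k])
      o <- order(mu)
      mu <- mu[o]; sd_ <- sd_[o]
      ds <- c(ds, diff(mu) / sqrt((sd_[-length(sd_)]^2 + sd_[-1]^2) / 2))
    }
  }
  if (length(ds) == 0) {
    return(structure(NA_real_, applicable = FALSE))
  }
  structure(mean(ds), applicable = TRUE)
}

#' Per-feature significance screen within a view
#'
#' Tests each of a view's features against its subject clusters: one-way
#' ANOVA for numerical features, chi-squared independence test on the
#' cluster-by-value crosstable for categorical and integer features.
#' Significance is assessed at 0.05 with Bonferroni correction within each
#' feature type (threshold `0.05 / m`, `m` = features of that type tested in
#' the view). Constant features get `p = 1`.
#'
#' @param fit an `mcc_fit`.
#' @param data the fitted [mcc_data].
#' @param view view index.
#' @return a tibble: `feature`, `dtype`, `statistic`, `p_value`, `m`,
#'   `threshold`, `significant`.
#' @export
feature_significance <- function(fit, data, view) {
  fa <- view_features(fit, data, view)
  ids <- data$values$subject_id
  k_of <- view_subject_clusters(fit, view, ids)
  assert_that(length(unique(k_of)) >= 2,
              "view ", view, " has fewer than 2 subject clusters")

  res <- lapply(seq_len(nrow(fa)), function(i) {
    f <- fa$feature[i]
    x <- data$values[[f]]
    obs <- !is.na(x)
    cl <- k_of[obs]; xv <- x[obs]
    stat <- NA_real_; p <- 1
    if (length(unique(xv)) >= 2 && length(unique(cl)) >= 2) {
      if (fa$dtype[i] == "numerical") {
        ft <- tryCatch(summary(stats::aov(xv ~ factor(cl)))[[1]],
                       error = function(e) NULL)
        if (!is.null(ft) && !is.na(ft$`F value`[1])) {
          stat <- ft$`F value`[1]
          p <- ft$`Pr(>F)`[1]
        }
      } else {
        ct <- suppressWarnings(stats::chisq.test(table(cl, xv)))
        stat <- unname(ct$statistic)
        p <- ct$p.value
      }
    }
    tibble::tibble(feature = f, dtype = fa$dtype[i], statistic = stat, p_value = p)
  })
  out <- dplyr::bind_rows(res)
  out <- out |>
    dplyr::group_by(.data$dtype) |>
    dplyr::mutate(m = dplyr::n(), threshold = 0.05 / .data$m,
                  significant = .data$p_value < .data$threshold) |>
    dplyr::ungroup()
  out
}

#' Hamming-distance consensus over views
#'
#' Distance between two subjects is the fraction of views in which their
#' subject-cluster memberships differ; the distances feed an average-linkage
#' hierarchical clustering. Distances are symmetric, zero on the diagonal and
#' in `[0, 1]`.
#'
#' @param fit an `mcc_fit`.
#' @return a list of class `mcc_consensus`: `distance` (subject matrix),
#'   `hclust` (average-linkage tree), `newick` (tree in Newick text).
#' @export
hamming_consensus <- function(fit) {
  sa <- fit$subject_assignments
  ids <- unique(sa$subject_id)
  V <- fit$n_views
  M <- matrix(0L, length(ids), V)
  for (v in seq_len(V)) M[, v] <- view_subject_clusters(fit, v, ids)
  D <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (v in seq_len(V)) D <- D + outer(M[, v], M[, v], `!=`)
  D <- D / V
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  hc$labels <- ids
  newick <- ape::write.tree(ape::as.phylo(hc))
  structure(list(distance = D, hclust = hc, newick = newick),
            class = "mcc_consensus")
}

#' Hyperparameter sensitivity sweep
#'
#' Refits the model under perturbed hyperparameter settings and reports the
#' agreement of each perturbed solution with the baseline: adjusted Rand
#' index of the feature-to-view partition, and the mean ARI of per-view
#' subject partitions (perturbed views matched to baseline views by feature
#' overlap).
#'
#' @param data an [mcc_data].
#' @param grid a data frame whose columns are hyperparameter names (any
#'   subset of the [mcc_hyperparameters()] fields); each row is one perturbed
#'   setting.
#' @param hp baseline hyperparameters.
#' @inheritParams mcc_fit
#' @return a tibble with one row per grid point: the perturbed values plus
#'   `view_ari`, `subject_ari`, `n_views`, `logLik`.
#' @export
sensitivity_sweep <- function(data, grid, hp = mcc_hyperparameters(),
                              truncation = c(15L, 12L, 10L), n_restarts = 5L,
                              seed = 1L, tol = 1e-6, max_iter = 500L) {
  grid <- tibble::as_tibble(grid)
  assert_that(nrow(grid) >= 1, "grid must be nonempty")
  bad <- setdiff(names(grid), names(unclass(hp)))
  assert_that(length(bad) == 0, "unknown hyperparameter(s): ",
              paste(bad, collapse = ", "))
  baseline <- mcc_fit(data, hp, truncation, n_restarts, seed, tol, max_iter)

  rows <- lapply(seq_len(nrow(grid)), function(i) {
    hp2 <- unclass(hp)
    for (nm in names(grid)) hp2[[nm]] <- grid[[nm]][i]
    fit2 <- mcc_fit(data, do.call(mcc_hyperparameters, hp2), truncation,
                    n_restarts, seed, tol, max_iter)
    agr <- solution_agreement(baseline, fit2)
    dplyr::bind_cols(grid[i, ], tibble::tibble(
      view_ari = agr$view_ari, subject_ari = agr$subject_ari,
      n_views = fit2$n_views, logLik = fit2$logLik))
  })
  dplyr::bind_rows(rows)
}

# feature-view partition ARI plus matched per-view subject-partition ARI
solution_agreement <- function(ref, other) {
  fa1 <- ref$feature_assignments
  fa2 <- other$feature_assignments
  m <- match(fa1$feature, fa2$feature)
  view_ari <- adjusted_rand_index(fa1$view, fa2$view[m])
  ids <- unique(ref$subject_assignments$subject_id)
  aris <- vapply(seq_len(ref$n_views), function(v) {
    feats <- fa1$feature[fa1$view == v]
    match_view <- as.integer(names(which.max(table(fa2$view[match(feats, fa2$feature)]))))
    adjusted_rand_index(view_subject_clusters(ref, v, ids),
                        view_subject_clusters(other, match_view, ids))
  }, 0.0)
  list(view_ari = view_ari, subject_ari = mean(aris))
}

#' Per-view characterization report
#'
#' Summarizes a fitted solution one row per view: feature counts by type,
#' agreement of the view's subject clusters with the control/depression
#' labels (adjusted Rand index), the depression-related feature proportion,
#' the average Cohen's d of its FC feature clusters, and the number of
#' features passing the Bonferroni significance screen.
#'
#' @param fit an `mcc_fit`.
#' @param data the fitted [mcc_data] (labels required for the ARI column).
#' @return a tibble of class `mcc_view_report`.
#' @export
view_report <- function(fit, data) {
  ids <- data$values$subject_id
  labels <- if (!is.null(data$labels)) {
    data$labels$label[match(ids, data$labels$subject_id)]
  }
  rows <- lapply(seq_len(fit$n_views), function(v) {
    fa <- view_features(fit, data, v)
    sp <- data$specs[match(fa$feature, data$specs$feature), ]
    k_of <- view_subject_clusters(fit, v, ids)
    nsig <- if (length(unique(k_of)) >= 2) {
      sum(feature_significance(fit, data, v)$significant)
    } else 0L
    prop <- depression_feature_proportion(fit, data, v)
    d <- average_cohens_d(fit, data, v)
    tibble::tibble(
      view = v,
      n_features = nrow(fa),
      n_numerical = sum(fa$dtype == "numerical"),
      n_categorical = sum(fa$dtype == "categorical"),
      n_integer = sum(fa$dtype == "integer"),
      n_fc = sum(sp$group == "FC"),
      n_subject_clusters = length(unique(k_of)),
      ari_diagnosis = if (!is.null(labels)) adjusted_rand_index(k_of, labels)
                      else NA_real_,
      depression_proportion = prop$proportion,
      depression_proportion_all = prop$proportion_all,
      avg_cohens_d = as.numeric(d),
      n_significant = nsig
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mcc_view_report", class(out))
  out
}
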