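# log density of a multivariate Gaussian via Cholesky; jitters toward a
# ridge if the covariance is numerically singular
logdmvnorm <- function(X, mu, sigma, ridge = 1e-6) {
  d <- length(mu)
  jittered <- FALSE
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    sigma <- sigma + diag(ridge * max(1, mean(diag(sigma))), d)
    ch <- chol(sigma)
    jittered <- TRUE
  }
  ctr <- sweep(X, 2, mu)
  z <- backsolve(ch, t(ctr), transpose = TRUE)
  val <- -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
  attr(val, "jittered") <- jittered
  val
}

#' Leave-one-out Gaussian-mixture membership prediction
#'
#' Predicts each depressed subject's cluster membership from a numerical
#' predictor matrix by leave-one-out cross-validation of a supervised
#' Gaussian mixture: with one subject held out, per-cluster means, full
#' covariances and mixing weights are estimated from the remaining subjects'
#' known memberships (no EM; memberships are observed), and the held-out
#' subject is assigned to the maximum-posterior component. Missing predictor
#' entries are imputed with training-fold means, so the held-out subject
#' never enters estimation. Singular covariances are ridge-regularized with
#' a logged jitter count.
#'
#' @param predictors numeric subject-by-predictor matrix or data frame.
#' @param memberships cluster labels (e.g. `D1`/`D2`/`D3`), one per row of
#'   `predictors`; at least two clusters with at least two members each.
#' @param ridge relative ridge added when a covariance is singular.
#' @return a list of class `mcc_loocv`: `predictions` (tibble `subject`,
#'   `true`, `predicted`, `correct`), `accuracy` (proportion correct) and
#'   `n_jittered`.
#' @export
loocv_gmm_accuracy <- function(predictors, memberships, ridge = 1e-6) {
  X <- as.matrix(predictors)
  storage.mode(X) <- "double"
  y <- as.character(memberships)
  assert_that(nrow(X) == length(y), "predictors and memberships disagree in length")
  cls <- sort(unique(y))
  assert_that(length(cls) >= 2 && all(table(y) >= 2),
              "need >= 2 clusters with >= 2 members each")
  n <- nrow(X)
  pred <- character(n)
  n_jittered <- 0L
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    mu_all <- colMeans(Xtr, na.rm = TRUE)
    for (j in seq_len(ncol(Xtr))) {
      nas <- is.na(Xtr[, j])
      if (any(nas)) Xtr[nas, j] <- mu_all[j]
    }
    xte <- X[i, ]
    xte[is.na(xte)] <- mu_all[is.na(xte)]
    logpost <- vapply(cls, function(cl) {
      Xc <- Xtr[ytr == cl, , drop = FALSE]
      mu <- colMeans(Xc)
      sg <- stats::cov(Xc)
      ld <- logdmvnorm(matrix(xte, 1), mu, sg, ridge)
      if (isTRUE(attr(ld, "jittered"))) n_jittered <<- n_jittered + 1L
      log(nrow(Xc) / nrow(Xtr)) + as.numeric(ld)
    }, 0.0)
    pred[i] <- cls[which.max(logpost)]
  }
  predictions <- tibble::tibble(
    subject = rownames(X) %||% as.character(seq_len(n)),
    true = y, predicted = pred, correct = pred == y
  )
  structure(list(predictions = predictions,
                 accuracy = mean(predictions$correct),
                 n_jittered = n_jittered),
            class = "mcc_loocv")
}

#' Leave-one-out accuracy over incremental predictor sets
#'
#' Convenience wrapper running [loocv_gmm_accuracy()] for a sequence of
#' predictor sets (e.g. CATS, then + FC score, then + BDI, then + the rest),
#' reporting one accuracy per set.
#'
#' @param predictors numeric subject-by-predictor table.
#' @param memberships cluster labels, one per subject.
#' @param predictor_sets named list of column-name vectors.
#' @param ... passed to [loocv_gmm_accuracy()].
#' @return a tibble: `predictor_set`, `n_predictors`, `accuracy`.
#' @export
loocv_predictor_curve <- function(predictors, memberships, predictor_sets, ...) {
  predictors <- as.data.frame(predictors)
  rows <- lapply(names(predictor_sets), function(nm) {
    cols <- predictor_sets[[nm]]
    assert_that(all(cols %in% names(predictors)),
                "unknown predictor column(s) in set '", nm, "'")
    res <- loocv_gmm_accuracy(predictors[, cols, drop = FALSE], memberships, ...)
    tibble::tibble(predictor_set = nm, n_predictors = length(cols),
                   accuracy = res$accuracy)
  })
  dplyr::bind_rows(rows)
}

#' Fit the two-step FC/CATS threshold classifier
#'
#' Learns the two dashed-line thresholds of the subtype classifier from
#' scores and memberships: first an AG-related FC score threshold separating
#' D3 (low FC) from the rest, chosen to maximize D3-vs-rest accuracy over
#' midpoints between sorted unique FC scores; then a CATS threshold
#' separating D2 (low CATS) from D1 among the non-D3 subjects, likewise.
#' Ties are broken toward the lower threshold. The outcome map follows the
#' study's remission pattern: D1 is treatment-resistant, D2 and D3
#' responsive.
#'
#' @param fc_scores numeric AG-related FC scores (first-PC scores of the
#'   diagnosis view's FC features).
#' @param cats_scores numeric CATS (childhood adversity) scores.
#' @param memberships labels containing all of `D1`, `D2`, `D3`.
#' @return an object of class `mcc_subtype_classifier` with fields
#'   `fc_threshold`, `cats_threshold`, `label_map`, `outcome_map`, and the
#'   training scores/memberships.
#' @export
fit_threshold_classifier <- function(fc_scores, cats_scores, memberships) {
  y <- as.character(memberships)
  assert_that(length(fc_scores) == length(y) && length(cats_scores) == length(y),
              "scores and memberships disagree in length")
  assert_that(all(c("D1", "D2", "D3") %in% y),
              "all three clusters D1, D2, D3 must be represented",
              class = "mvcoclust_classifier_error")
  ok <- !is.na(fc_scores) & !is.na(cats_scores)
  fc <- fc_scores[ok]; cats <- cats_scores[ok]; y <- y[ok]

  best_threshold <- function(score, positive) {
    u <- sort(unique(score))
    cand <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
    acc <- vapply(cand, function(t) mean((score < t) == positive), 0.0)
    cand[which.max(acc)]   # which.max takes the first (lowest) maximizer
  }
  fc_threshold <- best_threshold(fc, y == "D3")
  non_d3 <- y != "D3"
  cats_threshold <- best_threshold(cats[non_d3], y[non_d3] == "D2")

  structure(list(
    fc_threshold = fc_threshold,
    cats_threshold = cats_threshold,
    label_map = c(low_fc = "D3", high_fc_low_cats = "D2", high_fc_high_cats = "D1"),
    outcome_map = c(D1 = "resistant", D2 = "responsive", D3 = "responsive"),
    training = tibble::tibble(fc = fc, cats = cats, membership = y)
  ), class = "mcc_subtype_classifier")
}

#' @export
print.mcc_subtype_classifier <- function(x, ...) {
  cat("<mcc_subtype_classifier>\n")
  cat("  FC score  < ", format(x$fc_threshold), " -> D3 (responsive)\n", sep = "")
  cat("  else CATS < ", format(x$cats_threshold), " -> D2 (responsive)\n", sep = "")
  cat("  else                -> D1 (resistant)\n")
  invisible(x)
}

#' Classify subjects with the two-step threshold rule
#'
#' Applies the fitted rule: FC score below the FC threshold gives D3
#' (responsive); otherwise a CATS score below the CATS threshold gives D2
#' (responsive), else D1 (resistant). A missing score yields an explicit
#' unclassifiable result (`NA` subtype and outcome).
#'
#' @param clf an [fit_threshold_classifier()] result.
#' @param fc_scores,cats_scores numeric score vectors.
#' @return a tibble: `fc`, `cats`, `subtype`, `outcome`.
#' @export
classify_subjects <- function(clf, fc_scores, cats_scores) {
  assert_that(inherits(clf, "mcc_subtype_classifier"), "clf must be a fitted classifier")
  assert_that(length(fc_scores) == length(cats_scores), "score lengths differ")
  subtype <- ifelse(is.na(fc_scores) | (fc_scores >= clf$fc_threshold & is.na(cats_scores)),
                    NA_character_,
             ifelse(fc_scores < clf$fc_threshold, "D3",
             ifelse(cats_scores < clf$cats_threshold, "D2", "D1")))
  outcome <- unname(clf$outcome_map[subtype])
  tibble::tibble(fc = fc_scores, cats = cats_scores,
                 subtype = subtype, outcome = outcome)
}

#' @rdname classify_subjects
#' @param fc_score,cats_score scalar scores for a single subject.
#' @export
classify_subject <- function(clf, fc_score, cats_score) {
  classify_subjects(clf, fc_score, cats_score)
}

#' Cluster profile table
#'
#' Per-cluster and per-feature means and standard deviations with a
#' high/moderate/low tag relative to the tercile boundaries of the pooled
#' values across the profiled subjects (a cluster mean strictly below the
#' lower tercile is `low`, strictly above the upper tercile `high`, else
#' `moderate`).
#'
#' @param data an [mcc_data] or plain subject table (first column
#'   `subject_id`).
#' @param memberships named cluster labels: a tibble `subject_id`, `cluster`
#'   or a vector named by subject id.
#' @param features character vector of numerical feature columns to profile.
#' @return a tibble with one row per (cluster, feature): `cluster`,
#'   `feature`, `mean`, `sd`, `tag`.
#' @export
characterize_clusters <- function(data, memberships, features) {
  values <- if (inherits(data, "mcc_data")) data$values else tibble::as_tibble(data)
  if (is.data.frame(memberships)) {
    mem <- memberships$cluster
    names(mem) <- memberships$subject_id
  } else {
    mem <- memberships
  }
  assert_that(!is.null(names(mem)), "memberships must be named by subject_id")
  idx <- match(names(mem), values$subject_id)
  assert_that(!anyNA(idx), "memberships refer to unknown subjects")
  sub <- values[idx, , drop = FALSE]
  assert_that(all(features %in% names(sub)), "unknown feature column(s)")

  rows <- lapply(features, function(f) {
    x <- as.numeric(sub[[f]])
    q <- stats::quantile(x, c(1 / 3, 2 / 3), na.rm = TRUE, names = FALSE)
    dplyr::bind_rows(lapply(sort(unique(mem)), function(cl) {
      xc <- x[mem == cl]
      m <- mean(xc, na.rm = TRUE)
      tibble::tibble(cluster = as.character(cl), feature = f, mean = m,
                     sd = stats::sd(xc[!is.na(xc)]),
                     tag = if (m < q[1]) "low" else if (m > q[2]) "high" else "moderate")
    }))
  })
  dplyr::bind_rows(rows)
}
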