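#' Planted multi-view co-cluster structure
#'
#' Describes the ground truth of a synthetic mixed-type dataset: an exclusive
#' partition of features into views, a feature clustering within each view, a
#' subject partition per view, and one parametric block distribution per
#' (view, feature cluster, subject cluster) cell — Gaussian for numerical
#' features, a categorical probability vector, or a Poisson rate.
#'
#' @param n_subjects number of subjects.
#' @param features tibble with columns `feature`, `view`, `dtype`,
#'   `feature_cluster`, and optionally `group`, `depression_related`,
#'   `levels` (list-column, categorical only). All features of one
#'   `(view, feature_cluster)` must share a dtype.
#' @param subject_partitions list indexed by view id: integer cluster vectors
#'   of length `n_subjects`.
#' @param blocks tibble with columns `view`, `feature_cluster`,
#'   `subject_cluster` and the parameter columns `mean`, `sd` (numerical),
#'   `probs` (list-column, categorical) or `rate` (integer).
#' @param missing_rate fraction in `[0, 1)` of entries masked missing,
#'   independently Bernoulli per cell.
#' @param seed integer RNG seed; with a fixed seed the simulated output is
#'   bit-identical across runs.
#' @return an object of class `mcc_planted_structure`.
#' @export
planted_structure <- function(n_subjects, features, subject_partitions, blocks,
                              missing_rate = 0, seed = 1L) {
  features <- tibble::as_tibble(features)
  blocks <- tibble::as_tibble(blocks)
  assert_that(n_subjects >= 1, "n_subjects must be >= 1")
  assert_that(all(c("feature", "view", "dtype", "feature_cluster") %in% names(features)),
              "features needs columns feature, view, dtype, feature_cluster")
  assert_that(!anyDuplicated(features$feature),
              "every feature must belong to exactly one view")
  assert_that(missing_rate >= 0 && missing_rate < 1, "missing_rate must be in [0, 1)")
  if (!"group" %in% names(features)) features$group <- "questionnaire"
  if (!"depression_related" %in% names(features)) features$depression_related <- FALSE
  if (!"levels" %in% names(features)) features$levels <- rep(list(NULL), nrow(features))

  key <- paste(features$view, features$feature_cluster)
  mixed <- tapply(features$dtype, key, function(d) length(unique(d)) > 1)
  assert_that(!any(unlist(mixed)), "a feature cluster mixes dtypes")

  for (v in unique(features$view)) {
    p <- subject_partitions[[v]]
    assert_that(!is.null(p) && length(p) == n_subjects && !anyNA(p),
                "subject partition for view ", v,
                " must assign every subject exactly one cluster")
  }

  needed <- unique(features[, c("view", "feature_cluster", "dtype")])
  for (i in seq_len(nrow(needed))) {
    vv <- needed$view[i]; gg <- needed$feature_cluster[i]; tp <- needed$dtype[i]
    ks <- sort(unique(subject_partitions[[vv]]))
    have <- blocks$view == vv & blocks$feature_cluster == gg
    assert_that(all(ks %in% blocks$subject_cluster[have]),
                "missing block parameters for view ", vv, ", feature cluster ", gg,
                class = "mvcoclust_config_error")
    b <- blocks[have & blocks$subject_cluster %in% ks, ]
    if (tp == "numerical") {
      assert_that(all(is.finite(b$mean)) && all(b$sd > 0),
                  "numerical blocks need finite mean and sd > 0",
                  class = "mvcoclust_config_error")
    } else if (tp == "categorical") {
      ok <- vapply(b$probs, function(p) {
        !is.null(p) && all(p >= 0) && abs(sum(p) - 1) < 1e-8
      }, TRUE)
      assert_that(all(ok), "categorical block probability vectors must sum to 1",
                  class = "mvcoclust_config_error")
      Ls <- vapply(b$probs, length, 1L)
      assert_that(length(unique(Ls)) == 1,
                  "categorical blocks of one feature cluster must share a level count",
                  class = "mvcoclust_config_error")
    } else {
      assert_that(all(b$rate >= 0), "Poisson rates must be >= 0",
                  class = "mvcoclust_config_error")
    }
  }

  structure(list(n_subjects = n_subjects, features = features,
                 subject_partitions = subject_partitions, blocks = blocks,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "mcc_planted_structure")
}

#' Simulate data from a planted structure
#'
#' Draws every cell i.i.d. from the block distribution of its
#' (view, feature cluster, subject cluster), then masks entries missing
#' completely at random at the structure's `missing_rate`. Ground truth at all
#' three levels is returned alongside the data.
#'
#' @param structure an [planted_structure()].
#' @return a list with elements `data` (an [mcc_data]) and `truth` (a list of
#'   tibbles `feature_views`, `feature_clusters`, `subject_clusters`).
#' @export
simulate_planted <- function(structure) {
  assert_that(inherits(structure, "mcc_planted_structure"),
              "structure must be an mcc_planted_structure")
  set.seed(structure$seed)
  n <- structure$n_subjects
  ft <- structure$features
  bl <- structure$blocks
  ids <- sprintf("S%03d", seq_len(n))

  values <- vector("list", nrow(ft))
  levels_out <- vector("list", nrow(ft))
  bkey <- paste(bl$view, bl$feature_cluster, bl$subject_cluster)

  for (j in seq_len(nrow(ft))) {
    vv <- ft$view[j]; gg <- ft$feature_cluster[j]; tp <- ft$dtype[j]
    k <- structure$subject_partitions[[vv]]
    rows <- match(paste(vv, gg, k), bkey)
    if (tp == "numerical") {
      values[[j]] <- stats::rnorm(n, mean = bl$mean[rows], sd = bl$sd[rows])
    } else if (tp == "categorical") {
      L <- length(bl$probs[[rows[1]]])
      lev <- ft$levels[[j]] %||% as.character(seq_len(L))
      x <- character(n)
      for (kk in unique(k)) {
        idx <- which(k == kk)
        p <- bl$probs[[match(paste(vv, gg, kk), bkey)]]
        x[idx] <- sample(lev, length(idx), replace = TRUE, prob = p)
      }
      values[[j]] <- x
      levels_out[[j]] <- lev
    } else {
      values[[j]] <- stats::rpois(n, lambda = bl$rate[rows])
    }
  }

  names(values) <- ft$feature
  tab <- tibble::as_tibble(values)
  if (structure$missing_rate > 0) {
    mask <- matrix(stats::runif(n * nrow(ft)) < structure$missing_rate, n, nrow(ft))
    for (j in seq_len(nrow(ft))) tab[[j]][mask[, j]] <- NA
  }
  tab <- tibble::add_column(tab, subject_id = ids, .before = 1)

  specs <- feature_spec(ft$feature, dtype = ft$dtype, group = ft$group,
                        depression_related = ft$depression_related,
                        levels = levels_out)
  data <- mcc_data(tab, specs)

  truth <- list(
    feature_views = tibble::tibble(feature = ft$feature, view = ft$view),
    feature_clusters = tibble::tibble(feature = ft$feature, view = ft$view,
                                      feature_cluster = ft$feature_cluster),
    subject_clusters = dplyr::bind_rows(lapply(unique(ft$view), function(vv) {
      tibble::tibble(subject_id = ids, view = vv,
                     cluster = structure$subject_partitions[[vv]])
    }))
  )
  list(data = data, truth = truth)
}

#' Simulate ROI-averaged BOLD time series
#'
#' Generates zero-mean multivariate Gaussian series whose population pairwise
#' correlation matrix equals a given target, one ROI-by-time matrix per
#' subject. Used to exercise [compute_fc_features()].
#'
#' @param n_rois number of ROIs.
#' @param series_length number of time points (>= 3).
#' @param target_cor symmetric positive semi-definite matrix with unit
#'   diagonal; defaults to the identity (independent ROIs).
#' @param seed integer RNG seed.
#' @param n_subjects number of subjects to simulate.
#' @param roi_names optional ROI names (default `ROI01`, `ROI02`, ...).
#' @return a list with `series` (named list of ROI x time matrices) and
#'   `roi_names`.
#' @export
simulate_roi_timeseries <- function(n_rois, series_length, target_cor = NULL,
                                    seed = 1L, n_subjects = 1L, roi_names = NULL) {
  assert_that(n_rois >= 1 && series_length >= 3, "need n_rois >= 1, series_length >= 3")
  if (is.null(target_cor)) target_cor <- diag(n_rois)
  target_cor <- as.matrix(target_cor)
  assert_that(nrow(target_cor) == n_rois && ncol(target_cor) == n_rois,
              "target_cor must be n_rois x n_rois", class = "mvcoclust_config_error")
  assert_that(max(abs(target_cor - t(target_cor))) < 1e-8,
              "target_cor must be symmetric", class = "mvcoclust_config_error")
  assert_that(max(abs(diag(target_cor) - 1)) < 1e-8,
              "target_cor must have unit diagonal", class = "mvcoclust_config_error")
  ev <- eigen(target_cor, symmetric = TRUE, only.values = TRUE)$values
  assert_that(min(ev) > -1e-8, "target_cor must be positive semi-definite",
              class = "mvcoclust_config_error")
  roi_names <- roi_names %||% sprintf("ROI%02d", seq_len(n_rois))
  set.seed(seed)
  series <- lapply(seq_len(n_subjects), function(s) {
    x <- t(MASS::mvrnorm(series_length, mu = rep(0, n_rois), Sigma = target_cor,
                         tol = 1e-6))
    rownames(x) <- roi_names
    x
  })
  names(series) <- sprintf("S%03d", seq_len(n_subjects))
  list(series = series, roi_names = roi_names)
}

#' Configuration of the synthetic depression-study fixture
#'
#' Defaults mirror the study conditions this package emulates: 67 control and
#' 67 depressed subjects, 2701 FC-style numerical features, questionnaire
#' scores, categorical (sex/SNP-like) and two integer count features, with a
#' planted three-view structure (diagnosis-linked, nuisance-demographic,
#' noise). Between-cluster separations default to 3 standard deviations; the
#' post-treatment outcome score has residual noise sd 0.5.
#'
#' @param n_control,n_depressed subject counts (default 67 each).
#' @param n_fc_features total FC features (>= 20; 20 are diagnosis-linked).
#' @param n_questionnaire_features total questionnaire features (>= 23).
#' @param n_categorical total categorical features (>= 4).
#' @param n_integer number of integer count features.
#' @param effect_size between-cluster mean separation in sd units.
#' @param outcome_noise_sd residual sd of the post-treatment outcome score.
#' @param missing_rate fraction of matrix entries masked missing.
#' @param seed integer RNG seed.
#' @return a list of class `mcc_study_config`.
#' @export
study_fixture_config <- function(n_control = 67L, n_depressed = 67L,
                                 n_fc_features = 2701L,
                                 n_questionnaire_features = 60L,
                                 n_categorical = 20L, n_integer = 2L,
                                 effect_size = 3, outcome_noise_sd = 0.5,
                                 missing_rate = 0.05, seed = 1L) {
  cfg <- list(n_control = as.integer(n_control), n_depressed = as.integer(n_depressed),
              n_fc_features = as.integer(n_fc_features),
              n_questionnaire_features = as.integer(n_questionnaire_features),
              n_categorical = as.integer(n_categorical), n_integer = as.integer(n_integer),
              effect_size = effect_size, outcome_noise_sd = outcome_noise_sd,
              missing_rate = missing_rate, seed = as.integer(seed))
  assert_that(all(unlist(cfg[1:6]) >= 0), "all counts must be >= 0",
              class = "mvcoclust_config_error")
  assert_that(cfg$n_fc_features >= 20, "need n_fc_features >= 20",
              class = "mvcoclust_config_error")
  assert_that(cfg$n_questionnaire_features >= 23, "need n_questionnaire_features >= 23",
              class = "mvcoclust_config_error")
  assert_that(cfg$n_categorical >= 4, "need n_categorical >= 4",
              class = "mvcoclust_config_error")
  assert_that(cfg$effect_size >= 0 && cfg$outcome_noise_sd > 0,
              "effect_size >= 0 and outcome_noise_sd > 0 required",
              class = "mvcoclust_config_error")
  structure(cfg, class = "mcc_study_config")
}

#' Simulate a depression-study-like dataset with planted subtypes
#'
#' Generates the full synthetic study fixture: a mixed-type matrix over
#' control and depressed subjects with a planted diagnosis-linked view (two
#' control clusters C1/C2 and three depressed clusters D1/D2/D3), a
#' nuisance-demographic view, and a noise view holding the bulk of the FC
#' features. The D1/D2/D3 profiles follow the pattern: D1 high CATS, high
#' AG-FC, low baseline severity, high (poor) post-treatment outcome; D2 low
#' CATS, moderate AG-FC, low outcome; D3 high CATS, low AG-FC, high baseline
#' severity, low outcome. FC features are generated directly on the
#' control-referenced standardized scale. A per-subject outcome score
#' (post-treatment severity, depressed subjects only) is returned with its
#' planted resistant/responsive dichotomy.
#'
#' @param config an [study_fixture_config()].
#' @return a list with `data` (labelled [mcc_data]), `outcome` (tibble
#'   `subject_id`, `outcome`, `outcome_class`), and `truth` (planted
#'   structure, per-level assignment tibbles, subtype labels, outcome
#'   threshold).
#' @export
simulate_depression_study <- function(config = study_fixture_config()) {
  assert_that(inherits(config, "mcc_study_config"),
              "config must come from study_fixture_config()")
  s <- config$effect_size
  n_c <- config$n_control
  n_d <- config$n_depressed
  n <- n_c + n_d

  # view 1 subject clusters: C1, C2 (controls), D1, D2, D3 (depressed)
  n_c1 <- ceiling(n_c / 2)
  d_sizes <- diff(round(seq(0, n_d, length.out = 4)))
  part1 <- c(rep(1L, n_c1), rep(2L, n_c - n_c1),
             rep(3L, d_sizes[1]), rep(4L, d_sizes[2]), rep(5L, d_sizes[3]))

  feat <- function(name, view, dtype, fcluster, group, rel) {
    tibble::tibble(feature = name, view = view, dtype = dtype,
                   feature_cluster = fcluster, group = group,
                   depression_related = rel)
  }
  gauss_blocks <- function(view, g, means, sd = 1) {
    tibble::tibble(view = view, feature_cluster = g,
                   subject_cluster = seq_along(means), mean = means, sd = sd,
                   probs = rep(list(NULL), length(means)), rate = NA_real_)
  }
  cat_blocks <- function(view, g, probs_list) {
    tibble::tibble(view = view, feature_cluster = g,
                   subject_cluster = seq_along(probs_list), mean = NA_real_,
                   sd = NA_real_, probs = probs_list, rate = NA_real_)
  }
  pois_blocks <- function(view, g, rates) {
    tibble::tibble(view = view, feature_cluster = g,
                   subject_cluster = seq_along(rates), mean = NA_real_,
                   sd = NA_real_, probs = rep(list(NULL), length(rates)),
                   rate = rates)
  }

  features <- dplyr::bind_rows(
    # diagnosis view: CATS (F1), AG-FC (F2), baseline severity (F3),
    # correlated FC (F4), post-treatment scores (F5), categorical items
    feat(c("CATS_total", "CATS_N", "CATS_P", "CATS_E"), 1L, "numerical", 1L,
         "questionnaire", TRUE),
    feat(sprintf("FC_AG_%02d", 1:12), 1L, "numerical", 2L, "FC", FALSE),
    feat(c("BDI", "PHQ9", "HRSD17", "SHAPS", "STAI", "PANAS_N"), 1L,
         "numerical", 3L, "questionnaire", TRUE),
    feat(sprintf("FC_DMN_%02d", 1:8), 1L, "numerical", 4L, "FC", FALSE),
    feat(c("BDI_6w", "PHQ9_6w", "HRSD_6w"), 1L, "numerical", 5L,
         "questionnaire", TRUE),
    feat(sprintf("MINI_%d", 1:4), 1L, "categorical", 6L, "questionnaire", TRUE),
    # nuisance-demographic view
    feat(sprintf("demo_%02d", 1:10), 2L, "numerical", 1L, "questionnaire", FALSE),
    feat(c("sex", sprintf("SNP_%02d", seq_len(config$n_categorical - 5L))),
         2L, "categorical", 2L, "biological", FALSE),
    if (config$n_integer > 0)
      feat(c("episode_count", "recurrence_count")[seq_len(min(2L, config$n_integer))],
           2L, "integer", 3L, "biological", FALSE),
    if (config$n_integer > 2)
      feat(sprintf("count_%02d", seq_len(config$n_integer - 2L)), 2L, "integer",
           3L, "biological", FALSE),
    # noise view
    feat(sprintf("FC_bg_%04d", seq_len(config$n_fc_features - 20L)), 3L,
         "numerical", 1L, "FC", FALSE),
    feat(sprintf("psy_%02d", seq_len(config$n_questionnaire_features - 23L)),
         3L, "numerical", 2L, "questionnaire", FALSE)
  )

  set.seed(config$seed + 1L)
  part2 <- sample(c(1L, 2L), n, replace = TRUE)

  blocks <- dplyr::bind_rows(
    gauss_blocks(1L, 1L, c(-s / 2, -s / 2, s / 2, -s / 2, s / 2)),   # CATS
    gauss_blocks(1L, 2L, c(0, 0, s / 2, 0, -s / 2)),                 # AG-FC
    gauss_blocks(1L, 3L, c(-s, -s, 0, 0, s)),                        # baseline severity
    gauss_blocks(1L, 4L, c(-s / 2, s / 2, s / 2, 0, -s / 2)),        # correlated FC
    gauss_blocks(1L, 5L, c(-s / 2, -s / 2, s / 2, -s / 2, -s / 2)),  # after-6-week scores
    cat_blocks(1L, 6L, list(c(0.6, 0.3, 0.1), c(0.6, 0.3, 0.1),
                            c(0.1, 0.3, 0.6), c(0.3, 0.4, 0.3),
                            c(0.1, 0.3, 0.6))),
    gauss_blocks(2L, 1L, c(-s / 2, s / 2)),
    cat_blocks(2L, 2L, list(c(0.7, 0.2, 0.1), c(0.1, 0.2, 0.7))),
    if (config$n_integer > 0) pois_blocks(2L, 3L, c(2, 6)),
    gauss_blocks(3L, 1L, c(0)),
    gauss_blocks(3L, 2L, c(0))
  )

  structure_ <- planted_structure(
    n_subjects = n, features = features,
    subject_partitions = list(part1, part2, rep(1L, n)),
    blocks = blocks, missing_rate = config$missing_rate, seed = config$seed
  )
  sim <- simulate_planted(structure_)

  ids <- sim$data$values$subject_id
  labels <- tibble::tibble(
    subject_id = ids,
    label = c(rep("control", n_c), rep("depressed", n_d))
  )
  sim$data <- mcc_data(sim$data$values, sim$data$specs, labels)

  subtype <- c("C1", "C2", "D1", "D2", "D3")[part1]
  out_mean <- c(NA, NA, s, 0, 0)[part1]
  set.seed(config$seed + 2L)
  outcome <- out_mean + stats::rnorm(n, sd = config$outcome_noise_sd)
  outcome[seq_len(n_c)] <- NA
  threshold <- s / 2
  outcome_class <- ifelse(is.na(outcome), NA_character_,
                          ifelse(outcome > threshold, "resistant", "responsive"))

  list(
    data = sim$data,
    outcome = tibble::tibble(subject_id = ids, outcome = outcome,
                             outcome_class = outcome_class),
    truth = c(sim$truth,
              list(structure = structure_,
                   subtype = tibble::tibble(subject_id = ids, subtype = subtype),
                   outcome_threshold = threshold))
  )
}

#' Canonical planted recovery benchmark
#'
#' A fixed three-view mixed-type benchmark used to exercise model recovery:
#' 134 subjects, 200 features (120 numerical in a three-cluster view with two
#' feature clusters; 30 numerical, 12 categorical and 8 integer features in a
#' two-cluster view; 30 numerical features in a second two-cluster view),
#' between-cluster mean gaps of 3 sd, Poisson rates 2 vs 10, and 10% missing
#' entries.
#'
#' @param seed integer RNG seed driving both the partitions and the draws.
#' @return as [simulate_planted()], plus the per-view planted subject
#'   partitions (`p1`, `p2`, `p3`) and the feature plan (`plan`).
#' @export
recovery_fixture <- function(seed) {
  set.seed(seed)
  n <- 134
  p1 <- sample(rep(1:3, length.out = n))
  p2 <- sample(rep(1:2, length.out = n))
  p3 <- sample(rep(1:2, length.out = n))
  ft <- dplyr::bind_rows(
    tibble::tibble(feature = sprintf("v1a_%03d", 1:60), view = 1L,
                   dtype = "numerical", feature_cluster = 1L),
    tibble::tibble(feature = sprintf("v1b_%03d", 1:60), view = 1L,
                   dtype = "numerical", feature_cluster = 2L),
    tibble::tibble(feature = sprintf("v2n_%03d", 1:30), view = 2L,
                   dtype = "numerical", feature_cluster = 1L),
    tibble::tibble(feature = sprintf("v2c_%02d", 1:12), view = 2L,
                   dtype = "categorical", feature_cluster = 2L),
    tibble::tibble(feature = sprintf("v2i_%02d", 1:8), view = 2L,
                   dtype = "integer", feature_cluster = 3L),
    tibble::tibble(feature = sprintf("v3n_%02d", 1:30), view = 3L,
                   dtype = "numerical", feature_cluster = 1L))
  no_par <- function(k) rep(list(NULL), k)
  bl <- dplyr::bind_rows(
    tibble::tibble(view = 1L, feature_cluster = 1L, subject_cluster = 1:3,
                   mean = c(-3, 0, 3), sd = 1, probs = no_par(3), rate = NA_real_),
    tibble::tibble(view = 1L, feature_cluster = 2L, subject_cluster = 1:3,
                   mean = c(3, -3, 0), sd = 1, probs = no_par(3), rate = NA_real_),
    tibble::tibble(view = 2L, feature_cluster = 1L, subject_cluster = 1:2,
                   mean = c(-1.5, 1.5), sd = 1, probs = no_par(2), rate = NA_real_),
    tibble::tibble(view = 2L, feature_cluster = 2L, subject_cluster = 1:2,
                   mean = NA_real_, sd = NA_real_,
                   probs = list(c(.8, .1, .1), c(.1, .1, .8)), rate = NA_real_),
    tibble::tibble(view = 2L, feature_cluster = 3L, subject_cluster = 1:2,
                   mean = NA_real_, sd = NA_real_, probs = no_par(2),
                   rate = c(2, 10)),
    tibble::tibble(view = 3L, feature_cluster = 1L, subject_cluster = 1:2,
                   mean = c(-1.5, 1.5), sd = 1, probs = no_par(2), rate = NA_real_))
  st <- planted_structure(n, ft, list(p1, p2, p3), bl,
                          missing_rate = 0.10, seed = seed)
  c(simulate_planted(st), list(p1 = p1, p2 = p2, p3 = p3, plan = ft))
}
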