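#' Pipeline run configuration
#'
#' Merges a YAML config file and/or override list onto the pipeline defaults:
#' the study's non-informative hyperparameters, truncation (15, 12, 10),
#' tolerance 1e-6, 500 max iterations, and a desk-scale default of 10 random
#' restarts (the original analysis used 1000). The seed is mandatory.
#'
#' @param path optional YAML config file.
#' @param overrides optional named list overriding file/default entries.
#' @return a validated config list of class `mcc_run_config`.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  cfg <- list(
    data_dir = "data", solution_dir = "solution", report_dir = "reports",
    hyperparameters = unclass(mcc_hyperparameters()),
    truncation = c(15L, 12L, 10L), n_restarts = 10L,
    tol = 1e-6, max_iter = 500L, seed = NULL,
    standardize = TRUE, simulate = list(),
    classify_view = NULL
  )
  if (!is.null(path)) {
    assert_that(file.exists(path), "config file not found: ", path)
    cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  }
  cfg <- utils::modifyList(cfg, overrides)
  assert_that(!is.null(cfg$seed), "seed is mandatory in the run config",
              class = "mvcoclust_config_error")
  cfg$hyperparameters <- do.call(mcc_hyperparameters, cfg$hyperparameters)
  assert_that(length(cfg$truncation) == 3 && all(cfg$truncation >= 1),
              "truncation must be three limits >= 1", class = "mvcoclust_config_error")
  structure(cfg, class = "mcc_run_config")
}

write_manifest <- function(dir, step, cfg, inputs = character(0), extra = list()) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  cfg <- unclass(cfg)
  cfg$hyperparameters <- unclass(cfg$hyperparameters)
  manifest <- c(list(
    step = step,
    package = "mvcoclust",
    version = as.character(utils::packageVersion("mvcoclust")),
    config = cfg,
    input_hashes = hashes,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), extra)
  jsonlite::write_json(manifest, file.path(dir, paste0(step, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Pipeline step: simulate the synthetic study fixture
#'
#' Generates the depression-study fixture from the config's `simulate`
#' entries (passed to [study_fixture_config()]) and writes the matrix,
#' sidecar, labels, outcome and ground-truth TSVs plus a manifest under
#' `config$data_dir`.
#'
#' @param config an [run_config()].
#' @return invisibly, the simulation result.
#' @export
pipeline_simulate <- function(config) {
  cfg <- config
  sim_args <- cfg$simulate
  sim_args$seed <- sim_args$seed %||% cfg$seed
  sim <- simulate_depression_study(do.call(study_fixture_config, sim_args))
  dir.create(cfg$data_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- write_mcc_data(sim$data, cfg$data_dir)
  readr::write_tsv(sim$outcome, file.path(cfg$data_dir, "outcome.tsv"), na = "")
  readr::write_tsv(sim$truth$feature_clusters,
                   file.path(cfg$data_dir, "truth_features.tsv"))
  readr::write_tsv(sim$truth$subject_clusters,
                   file.path(cfg$data_dir, "truth_subjects.tsv"))
  readr::write_tsv(sim$truth$subtype, file.path(cfg$data_dir, "truth_subtype.tsv"))
  write_manifest(cfg$data_dir, "simulate", cfg, unname(paths))
  invisible(sim)
}

#' Pipeline step: fit the multiple co-clustering model
#'
#' Reads the matrix/sidecar/labels written by [pipeline_simulate()] (or any
#' files in the same layout), optionally applies the study's standardization
#' (FC features referenced to the control group), fits [mcc_fit()] with the
#' configured restarts, and writes the solution plus manifest to
#' `config$solution_dir`. Identical config and seed give byte-identical
#' solution files.
#'
#' @param config an [run_config()].
#' @return invisibly, the fitted `mcc_fit`.
#' @export
pipeline_fit <- function(config) {
  cfg <- config
  mp <- file.path(cfg$data_dir, "matrix.tsv")
  sp <- file.path(cfg$data_dir, "sidecar.tsv")
  lp <- file.path(cfg$data_dir, "labels.tsv")
  data <- read_mcc_data(mp, sp, if (file.exists(lp)) lp)
  if (isTRUE(cfg$standardize)) {
    ref <- if (!is.null(data$labels)) {
      data$labels$subject_id[data$labels$label == "control"]
    } else data$values$subject_id
    data <- standardize_features(data, fc_reference = ref)
  }
  fit <- mcc_fit(data, cfg$hyperparameters, cfg$truncation,
                 n_restarts = cfg$n_restarts, seed = cfg$seed,
                 tol = cfg$tol, max_iter = cfg$max_iter)
  write_solution(fit, cfg$solution_dir)
  write_manifest(cfg$solution_dir, "fit", cfg,
                 c(mp, sp, if (file.exists(lp)) lp),
                 extra = list(selected_restart = fit$restart,
                              logLik = fit$logLik, elbo = fit$elbo))
  invisible(fit)
}

# refit deterministically from the manifest config (used by downstream steps
# so that every artifact is reproducible from its manifest alone)
pipeline_refit <- function(cfg) pipeline_fit(cfg)

#' Pipeline step: characterize the fitted views
#'
#' Produces the per-view report ([view_report()]), per-view significance
#' tables, the Hamming-distance consensus dendrogram (Newick text) and a
#' JSON copy, written under `config$report_dir`.
#'
#' @param config an [run_config()].
#' @param fit optionally, an already-fitted `mcc_fit` (otherwise refitted
#'   deterministically from the config).
#' @return invisibly, the view report.
#' @export
pipeline_characterize <- function(config, fit = NULL) {
  cfg <- config
  fit <- fit %||% pipeline_refit(cfg)
  data <- pipeline_read_data(cfg)
  rep <- view_report(fit, data)
  dir.create(cfg$report_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(rep, file.path(cfg$report_dir, "view_report.tsv"))
  jsonlite::write_json(rep, file.path(cfg$report_dir, "view_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cons <- hamming_consensus(fit)
  writeLines(cons$newick, file.path(cfg$report_dir, "consensus.nwk"))
  write_manifest(cfg$report_dir, "characterize", cfg)
  invisible(rep)
}

pipeline_read_data <- function(cfg) {
  lp <- file.path(cfg$data_dir, "labels.tsv")
  data <- read_mcc_data(file.path(cfg$data_dir, "matrix.tsv"),
                        file.path(cfg$data_dir, "sidecar.tsv"),
                        if (file.exists(lp)) lp)
  if (isTRUE(cfg$standardize)) {
    ref <- if (!is.null(data$labels)) {
      data$labels$subject_id[data$labels$label == "control"]
    } else data$values$subject_id
    data <- standardize_features(data, fc_reference = ref)
  }
  data
}

#' Pipeline step: fit and apply the subtype classifier
#'
#' Selects the diagnosis view (the view whose subject clusters agree best
#' with the control/depression labels, unless `config$classify_view` pins
#' one), derives the AG-related FC score (first-PC of the view's FC
#' features) and a CATS score (mean of depression-related features whose
#' name starts with `CATS`), fits the two-step threshold classifier on the
#' depressed subjects' view clusters mapped to D1/D2/D3, and writes the
#' classifier JSON plus per-subject predictions TSV.
#'
#' @param config an [run_config()].
#' @param fit optionally, an already-fitted `mcc_fit`.
#' @return invisibly, a list with the classifier and predictions.
#' @export
pipeline_classify <- function(config, fit = NULL) {
  cfg <- config
  fit <- fit %||% pipeline_refit(cfg)
  data <- pipeline_read_data(cfg)
  assert_that(!is.null(data$labels), "classification requires labels",
              class = "mvcoclust_config_error")
  ids <- data$values$subject_id
  labels <- data$labels$label[match(ids, data$labels$subject_id)]

  view <- cfg$classify_view %||% {
    aris <- vapply(seq_len(fit$n_views), function(v)
      adjusted_rand_index(view_subject_clusters(fit, v, ids), labels), 0.0)
    which.max(aris)
  }
  pcs <- first_pc_scores(fit, data, view)
  assert_that(isTRUE(attr(pcs, "applicable")),
              "selected view has < 2 FC features", class = "mvcoclust_config_error")
  cats_cols <- grep("^CATS", data$specs$feature, value = TRUE)
  assert_that(length(cats_cols) > 0, "no CATS-named features found",
              class = "mvcoclust_config_error")
  cats <- rowMeans(as.matrix(data$values[, cats_cols, drop = FALSE]), na.rm = TRUE)

  dep <- labels == "depressed"
  k_of <- view_subject_clusters(fit, view, ids)
  dep_clusters <- sort(unique(k_of[dep]))
  # depressed clusters in the diagnosis view, named D1.. by FC-score rank
  # (D1 highest mean FC score, matching the study's naming)
  kmeans_fc <- vapply(dep_clusters, function(k) mean(pcs$score[dep & k_of == k]), 0.0)
  dnames <- paste0("D", rank(-kmeans_fc, ties.method = "first"))
  mem <- dnames[match(k_of[dep], dep_clusters)]
  assert_that(length(unique(mem)) >= 3, "need >= 3 depressed clusters to classify",
              class = "mvcoclust_classifier_error")

  clf <- fit_threshold_classifier(pcs$score[dep], cats[dep], mem)
  predictions <- dplyr::bind_cols(
    tibble::tibble(subject_id = ids[dep]),
    classify_subjects(clf, pcs$score[dep], cats[dep])
  )
  dir.create(cfg$report_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(fc_threshold = clf$fc_threshold, cats_threshold = clf$cats_threshold,
         outcome_map = as.list(clf$outcome_map), view = view,
         fc_score = "first PC of view FC features, majority-positive loadings",
         cats_score = paste(cats_cols, collapse = "+")),
    file.path(cfg$report_dir, "classifier.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_tsv(predictions, file.path(cfg$report_dir, "predictions.tsv"))
  write_manifest(cfg$report_dir, "classify", cfg)
  invisible(list(classifier = clf, predictions = predictions, view = view))
}
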