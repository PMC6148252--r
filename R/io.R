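#' Read a study dataset from TSV files
#'
#' Reads a subjects-by-features matrix (header row of feature names, first
#' column `subject_id`, empty cell = missing entry), its feature-type sidecar
#' (columns `feature`, `dtype`, `group`, `depression_related`, `levels` with
#' comma-separated level lists for categorical features) and an optional
#' label file (`subject_id`, `label`). Validation failures report the
#' offending column or value.
#'
#' @param matrix_path path to the data matrix TSV.
#' @param sidecar_path path to the feature sidecar TSV.
#' @param labels_path optional path to the subject label TSV.
#' @return an [mcc_data].
#' @export
read_mcc_data <- function(matrix_path, sidecar_path, labels_path = NULL) {
  for (p in c(matrix_path, sidecar_path, labels_path)) {
    assert_that(file.exists(p), "file not found: ", p,
                class = "mvcoclust_parse_error")
  }
  values <- readr::read_tsv(matrix_path, na = "", show_col_types = FALSE,
                            col_types = readr::cols(.default = "c"))
  sidecar <- readr::read_tsv(sidecar_path, na = "", show_col_types = FALSE,
                             col_types = readr::cols(.default = "c"))
  assert_that(all(c("feature", "dtype") %in% names(sidecar)),
              "sidecar needs columns feature, dtype", class = "mvcoclust_parse_error")
  specs <- feature_spec(
    sidecar$feature, sidecar$dtype,
    group = sidecar$group %||% "questionnaire",
    depression_related = as.logical(as.integer(sidecar$depression_related %||% "0")),
    levels = lapply(sidecar$levels %||% rep(NA_character_, nrow(sidecar)),
                    function(s) if (is.na(s) || s == "") NULL
                                else strsplit(s, ",", fixed = TRUE)[[1]])
  )
  labels <- if (!is.null(labels_path)) {
    readr::read_tsv(labels_path, show_col_types = FALSE,
                    col_types = readr::cols(.default = "c"))
  }
  mcc_data(values, specs, labels)
}

#' Write a study dataset to TSV files
#'
#' Inverse of [read_mcc_data()]: subjects as rows, features as columns, empty
#' cells for missing entries. `read_mcc_data(write_mcc_data(x))` round-trips
#' values, missing mask, specs and labels exactly.
#'
#' @param data an [mcc_data].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of paths written.
#' @export
write_mcc_data <- function(data, dir) {
  assert_that(inherits(data, "mcc_data"), "data must be an mcc_data")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(matrix = file.path(dir, "matrix.tsv"),
             sidecar = file.path(dir, "sidecar.tsv"))
  readr::write_tsv(data$values, paths[["matrix"]], na = "")
  sidecar <- tibble::tibble(
    feature = data$specs$feature,
    dtype = data$specs$dtype,
    group = data$specs$group,
    depression_related = as.integer(data$specs$depression_related),
    levels = vapply(data$specs$levels,
                    function(l) if (is.null(l)) "" else paste(l, collapse = ","), "")
  )
  readr::write_tsv(sidecar, paths[["sidecar"]], na = "")
  if (!is.null(data$labels)) {
    paths[["labels"]] <- file.path(dir, "labels.tsv")
    readr::write_tsv(data$labels, paths[["labels"]])
  }
  invisible(paths)
}

#' Write a fitted co-clustering solution
#'
#' Serializes a solution as plain text: one TSV per view with its feature
#' clustering, one TSV of per-view subject clusters, and a JSON run manifest
#' (hyperparameters, truncation, seeds, restart scores, ELBO and plug-in
#' log-likelihood).
#'
#' @param fit an `mcc_fit`.
#' @param dir output directory.
#' @return invisibly, the vector of paths written.
#' @export
write_solution <- function(fit, dir) {
  assert_that(inherits(fit, "mcc_fit"), "fit must be an mcc_fit")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (v in seq_len(fit$n_views)) {
    p <- file.path(dir, sprintf("view%02d_features.tsv", v))
    fa <- fit$feature_assignments
    readr::write_tsv(fa[fa$view == v, c("feature", "dtype", "feature_cluster")], p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "subject_clusters.tsv")
  readr::write_tsv(fit$subject_assignments, p)
  paths <- c(paths, p)

  manifest <- list(
    package = "mvcoclust",
    version = as.character(utils::packageVersion("mvcoclust")),
    hyperparameters = unclass(fit$hyperparameters),
    truncation = fit$truncation,
    stick_mapping = list(alpha1 = "views", alpha2 = "feature clusters",
                         beta = "subject clusters"),
    seed = fit$seed, base_seed = fit$base_seed,
    n_views = fit$n_views, elbo = fit$elbo, logLik = fit$logLik,
    n_iter = fit$n_iter, converged = fit$converged,
    restart_scores = if (!is.null(fit$restart_scores))
      as.list(fit$restart_scores)
  )
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, mp))
}

#' Read a serialized solution
#'
#' @param dir directory written by [write_solution()].
#' @return a list with `feature_assignments`, `subject_assignments` and
#'   `manifest`.
#' @export
read_solution <- function(dir) {
  vfiles <- sort(list.files(dir, pattern = "^view[0-9]+_features\\.tsv$",
                            full.names = TRUE))
  assert_that(length(vfiles) > 0, "no view files found in ", dir,
              class = "mvcoclust_parse_error")
  fa <- dplyr::bind_rows(lapply(seq_along(vfiles), function(v) {
    tb <- readr::read_tsv(vfiles[v], show_col_types = FALSE)
    tb$view <- v
    tb
  }))[, c("feature", "dtype", "view", "feature_cluster")]
  sa <- readr::read_tsv(file.path(dir, "subject_clusters.tsv"),
                        show_col_types = FALSE,
                        col_types = readr::cols(subject_id = "c"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  list(feature_assignments = tibble::as_tibble(fa),
       subject_assignments = tibble::as_tibble(sa), manifest = manifest)
}
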