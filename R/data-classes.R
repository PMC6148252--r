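#' Feature specification table
#'
#' Builds the per-feature metadata table that accompanies a study matrix:
#' feature name, declared type, level set (categorical only), modality group
#' and whether the feature counts as depression-related for the
#' view-characterization statistics. FC (functional-connectivity) features are
#' always numerical and are never counted as depression-related.
#'
#' @param name character vector of feature names (unique).
#' @param dtype one of `"numerical"`, `"categorical"`, `"integer"` per feature.
#' @param group modality tag, one of `"FC"`, `"questionnaire"`, `"biological"`.
#' @param depression_related logical flag per feature.
#' @param levels list of character vectors (one per feature; `NULL` entries for
#'   non-categorical features). Categorical features must declare at least two
#'   levels.
#' @return a tibble with columns `feature`, `dtype`, `group`,
#'   `depression_related` and a list-column `levels`.
#' @export
feature_spec <- function(name, dtype, group = "questionnaire",
                         depression_related = FALSE, levels = NULL) {
  n <- length(name)
  spec <- tibble::tibble(
    feature = as.character(name),
    dtype = rep_len(as.character(dtype), n),
    group = rep_len(as.character(group), n),
    depression_related = rep_len(as.logical(depression_related), n),
    levels = if (is.null(levels)) rep(list(NULL), n) else levels
  )
  validate_feature_spec(spec)
  spec
}

validate_feature_spec <- function(spec) {
  assert_that(all(c("feature", "dtype", "group", "depression_related") %in% names(spec)),
              "feature spec must have columns feature, dtype, group, depression_related")
  if (!"levels" %in% names(spec)) spec$levels <- rep(list(NULL), nrow(spec))
  assert_that(!anyDuplicated(spec$feature), "duplicated feature names in spec")
  bad <- setdiff(unique(spec$dtype), c("numerical", "categorical", "integer"))
  assert_that(length(bad) == 0, "unknown dtype: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(spec$group), c("FC", "questionnaire", "biological"))
  assert_that(length(bad) == 0, "unknown group: ", paste(bad, collapse = ", "))
  fc <- spec$group == "FC"
  assert_that(all(spec$dtype[fc] == "numerical"), "FC features must be numerical")
  cat_rows <- which(spec$dtype == "categorical")
  for (i in cat_rows) {
    assert_that(length(spec$levels[[i]]) >= 2,
                "categorical feature '", spec$feature[i], "' must declare >= 2 levels")
  }
  invisible(spec)
}

#' Study data container
#'
#' Bundles a subjects-by-features table with its feature specification and
#' optional diagnosis labels. Missing entries are `NA`; the missing mask is
#' implicit. This is the single input type consumed by [mcc_fit()].
#'
#' @param values a data frame whose first column is `subject_id` (coerced to
#'   character) followed by one column per feature. Numerical features are
#'   doubles, categorical features characters/factors, integer features
#'   nonnegative integers.
#' @param specs a feature specification as returned by [feature_spec()],
#'   covering every non-id column of `values`.
#' @param labels optional tibble with columns `subject_id` and `label`
#'   (`"control"` or `"depressed"`).
#' @return an object of class `mcc_data`.
#' @export
mcc_data <- function(values, specs, labels = NULL) {
  values <- tibble::as_tibble(values)
  assert_that(names(values)[1] == "subject_id",
              "first column of values must be subject_id")
  values$subject_id <- as.character(values$subject_id)
  assert_that(!anyDuplicated(values$subject_id), "duplicated subject ids")
  specs <- validate_feature_spec(tibble::as_tibble(specs))
  feat_cols <- setdiff(names(values), "subject_id")
  missing_spec <- setdiff(feat_cols, specs$feature)
  assert_that(length(missing_spec) == 0,
              "feature(s) missing from spec: ", paste(missing_spec, collapse = ", "),
              class = "mvcoclust_parse_error")
  extra_spec <- setdiff(specs$feature, feat_cols)
  assert_that(length(extra_spec) == 0,
              "spec covers absent column(s): ", paste(extra_spec, collapse = ", "))
  specs <- specs[match(feat_cols, specs$feature), ]

  for (i in seq_len(nrow(specs))) {
    f <- specs$feature[i]
    x <- values[[f]]
    if (specs$dtype[i] == "numerical") {
      xd <- suppressWarnings(as.double(x))
      bad <- which(is.na(xd) & !is.na(x))
      assert_that(length(bad) == 0,
                  "numerical feature '", f, "' has unparseable entries (row ",
                  paste(utils::head(bad, 3), collapse = ", "), ")",
                  class = "mvcoclust_parse_error")
      values[[f]] <- xd
    } else if (specs$dtype[i] == "categorical") {
      x <- as.character(x)
      obs <- x[!is.na(x)]
      bad <- setdiff(unique(obs), specs$levels[[i]])
      assert_that(length(bad) == 0,
                  "categorical feature '", f, "' has value(s) outside declared levels: ",
                  paste(bad, collapse = ", "), class = "mvcoclust_parse_error")
      values[[f]] <- x
    } else {
      xi <- suppressWarnings(as.double(x))
      obs <- xi[!is.na(xi)]
      assert_that(all(obs >= 0 & obs == round(obs)),
                  "integer feature '", f, "' has non-integer or negative entries",
                  class = "mvcoclust_parse_error")
      values[[f]] <- as.integer(round(xi))
    }
  }

  if (!is.null(labels)) {
    labels <- tibble::as_tibble(labels)
    assert_that(all(c("subject_id", "label") %in% names(labels)),
                "labels must have columns subject_id, label")
    labels$subject_id <- as.character(labels$subject_id)
    bad <- setdiff(unique(labels$label), c("control", "depressed"))
    assert_that(length(bad) == 0, "labels must be control/depressed")
    assert_that(all(values$subject_id %in% labels$subject_id),
                "labels missing for some subjects")
    labels <- labels[match(values$subject_id, labels$subject_id), c("subject_id", "label")]
  }

  structure(list(values = values, specs = specs, labels = labels),
            class = "mcc_data")
}

#' @export
print.mcc_data <- function(x, ...) {
  nt <- table(factor(x$specs$dtype, c("numerical", "categorical", "integer")))
  cat("<mcc_data> ", nrow(x$values), " subjects x ", nrow(x$specs), " features (",
      nt[["numerical"]], " numerical, ", nt[["categorical"]], " categorical, ",
      nt[["integer"]], " integer)\n", sep = "")
  miss <- mean(is.na(as.matrix(x$values[, -1, drop = FALSE])))
  cat("  missing: ", sprintf("%.1f%%", 100 * miss),
      if (!is.null(x$labels)) paste0("; labels: ",
        sum(x$labels$label == "control"), " control / ",
        sum(x$labels$label == "depressed"), " depressed"), "\n", sep = "")
  invisible(x)
}

#' @export
dim.mcc_data <- function(x) c(nrow(x$values), nrow(x$specs))

subject_ids <- function(data) data$values$subject_id

# Internal: split an mcc_data into per-type numeric matrices ready for the
# variational engine. Categorical values are coded 1..L on a common level
# space of size max(L_j); codes a feature never takes keep prior mass only.
encode_mcc_data <- function(data) {
  v <- data$values
  sp <- data$specs
  n <- nrow(v)
  out <- list(n = n, subject_ids = v$subject_id, specs = sp)
  for (tp in c("numerical", "categorical", "integer")) {
    feats <- sp$feature[sp$dtype == tp]
    if (length(feats) == 0) {
      out[[tp]] <- NULL
      next
    }
    if (tp == "categorical") {
      lev <- sp$levels[match(feats, sp$feature)]
      L <- max(vapply(lev, length, 1L))
      X <- matrix(NA_integer_, n, length(feats), dimnames = list(NULL, feats))
      for (i in seq_along(feats)) {
        X[, i] <- match(v[[feats[i]]], lev[[i]])
      }
      out[[tp]] <- list(X = X, L = L, levels = lev, features = feats)
    } else {
      X <- as.matrix(v[, feats, drop = FALSE])
      storage.mode(X) <- "double"
      assert_that(all(is.finite(X) | is.na(X)),
                  "non-finite values in ", tp, " features")
      out[[tp]] <- list(X = X, features = feats)
    }
  }
  out
}
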