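#' Compute functional-connectivity features from ROI time series
#'
#' Functional connectivity between two regions of interest (ROIs) is the
#' Pearson correlation of their average BOLD time series. Given a set of
#' per-subject ROI-by-time matrices, this produces one numerical feature per
#' unordered ROI pair, named `"<roiA>__<roiB>"` with A before B in ROI-list
#' order, walking the strict upper triangle row-major. An inventory of n ROIs
#' yields n(n-1)/2 features. (The study this emulates quotes 2701 features for
#' 78 ROIs although 78*77/2 = 3003; the pair-count formula is implemented
#' literally here.)
#'
#' @param ts a ROI time-series set as returned by [simulate_roi_timeseries()]:
#'   a list with `series` (named list of ROI x time matrices, identical ROI
#'   rownames across subjects) and `roi_names`.
#' @return an [mcc_data] whose features are all of group `"FC"`.
#' @seealso [roi_inventory()]
#' @export
compute_fc_features <- function(ts) {
  assert_that(is.list(ts) && !is.null(ts$series) && length(ts$series) > 0,
              "ts must be a ROI time-series set with a nonempty $series list")
  rois <- ts$roi_names %||% rownames(ts$series[[1]])
  n_roi <- length(rois)
  assert_that(n_roi >= 2, "need at least 2 ROIs")
  subj <- names(ts$series) %||% paste0("S", seq_along(ts$series))

  pairs <- which(upper.tri(diag(n_roi)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  fnames <- paste0(rois[pairs[, 1]], "__", rois[pairs[, 2]])

  vals <- matrix(NA_real_, length(subj), length(fnames),
                 dimnames = list(NULL, fnames))
  for (s in seq_along(subj)) {
    m <- ts$series[[s]]
    assert_that(is.matrix(m) && nrow(m) == n_roi && ncol(m) >= 3,
                "subject ", subj[s], ": series must be an ROI x time matrix, length >= 3")
    v <- apply(m, 1, stats::var)
    if (any(v <= 0 | !is.finite(v))) {
      bad <- rois[which(v <= 0 | !is.finite(v))[1]]
      stop_mvc("zero-variance time series for ROI '", bad, "' (subject ", subj[s], ")",
               class = "mvcoclust_fc_error")
    }
    cm <- stats::cor(t(m))
    vals[s, ] <- cm[pairs]
  }

  values <- tibble::as_tibble(as.data.frame(vals))
  values <- tibble::add_column(values, subject_id = subj, .before = 1)
  specs <- feature_spec(fnames, dtype = "numerical", group = "FC",
                        depression_related = FALSE)
  mcc_data(values, specs)
}

#' Standardize features the way the study pre-processing does
#'
#' FC features are standardized against the mean and standard deviation of a
#' reference (control) subject group, so that the control average becomes the
#' baseline; all other numerical features are standardized using all subjects.
#' Statistics ignore missing entries; the missing mask is unchanged.
#' Categorical and integer features pass through untouched. Standard
#' deviations use the unbiased (n-1) denominator.
#'
#' @param data an [mcc_data].
#' @param fc_reference character vector of subject ids forming the reference
#'   group for FC features (required if the data contain FC features).
#' @return a standardized [mcc_data].
#' @export
standardize_features <- function(data, fc_reference = NULL) {
  assert_that(inherits(data, "mcc_data"), "data must be an mcc_data")
  v <- data$values
  sp <- data$specs
  has_fc <- any(sp$group == "FC" & sp$dtype == "numerical")
  if (has_fc) {
    assert_that(!is.null(fc_reference), "fc_reference subject ids required for FC features")
    ref_idx <- match(fc_reference, v$subject_id)
    assert_that(!anyNA(ref_idx), "fc_reference contains unknown subject ids")
  }
  for (i in which(sp$dtype == "numerical")) {
    f <- sp$feature[i]
    x <- v[[f]]
    idx <- if (sp$group[i] == "FC") ref_idx else seq_along(x)
    xr <- x[idx]
    xr <- xr[!is.na(xr)]
    assert_that(length(xr) >= 2, "feature '", f, "': fewer than 2 observed reference values")
    s <- stats::sd(xr)
    assert_that(is.finite(s) && s > 0, "feature '", f, "' has zero spread in its reference set",
                class = "mvcoclust_standardize_error")
    v[[f]] <- (x - mean(xr)) / s
  }
  data$values <- v
  data
}

#' ROI inventory of the 14 intrinsic connectivity networks
#'
#' Static lookup table of the resting-state network parcellation used for the
#' functional-connectivity features: 14 intrinsic connectivity networks
#' comprising 90 ROIs in total (of which 78 are typically retained after
#' excluding cerebellum-related regions for which reliable images are not
#' available).
#'
#' @return a tibble with columns `network` and `n_rois`.
#' @export
roi_inventory <- function() {
  tibble::tibble(
    network = c("Anterior Salience", "Auditory", "Basal Ganglia",
                "Dorsal Default Mode", "Language", "Left Executive Control",
                "Precuneus", "Posterior Salience", "Right Executive Control",
                "Ventral Default Mode", "Visuospatial", "Primary Visual",
                "Higher Visual", "Sensorimotor"),
    n_rois = c(7L, 3L, 5L, 9L, 7L, 6L, 4L, 12L, 6L, 10L, 11L, 2L, 2L, 6L)
  )
}

#' Number of FC features for an ROI count
#'
#' @param n_rois number of ROIs.
#' @return n(n-1)/2, the number of unordered ROI pairs.
#' @export
fc_feature_count <- function(n_rois) {
  as.integer(n_rois * (n_rois - 1) / 2)
}
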