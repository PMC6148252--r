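#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted multiple co-clustering solution
#'
#' @param x an `mcc_fit`.
#' @param what `"features"` (feature, dtype, view, feature_cluster),
#'   `"subjects"` (subject_id, view, cluster) or `"restarts"` (per-restart
#'   selection scores).
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.mcc_fit <- function(x, what = c("features", "subjects", "restarts"), ...) {
  what <- match.arg(what)
  switch(what,
    features = x$feature_assignments,
    subjects = x$subject_assignments,
    restarts = x$restart_scores %||%
      tibble::tibble(restart = 1L, seed = x$seed, logLik = x$logLik,
                     elbo = x$elbo, n_iter = x$n_iter, converged = x$converged)
  )
}

#' One-row summary of a fitted solution
#'
#' @param x an `mcc_fit`.
#' @param ... unused.
#' @return a one-row tibble: dimensions, number of views, ELBO, plug-in
#'   log-likelihood, iterations and convergence.
#' @export
glance.mcc_fit <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects, n_features = x$n_features,
    n_views = x$n_views, elbo = x$elbo, logLik = x$logLik,
    n_iter = x$n_iter, converged = x$converged,
    n_restarts = if (!is.null(x$restart_scores)) nrow(x$restart_scores) else 1L
  )
}

#' Plot the view structure of a fitted solution
#'
#' Tile display of feature-to-view assignment sizes split by feature type —
#' a compact summary of how the model partitioned the features.
#'
#' @param object an `mcc_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mcc_fit <- function(object, ...) {
  fa <- object$feature_assignments |>
    dplyr::count(.data$view, .data$dtype)
  ggplot2::ggplot(fa, ggplot2::aes(x = factor(.data$view), y = .data$n,
                                   fill = .data$dtype)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "view", y = "features", fill = "type",
                  title = "Feature partition across views") +
    ggplot2::theme_minimal()
}

#' Plot a per-view characterization report
#'
#' Bar panels of the diagnosis-label agreement (adjusted Rand index), the
#' depression-related feature proportion and the average Cohen's d per view.
#'
#' @param object an `mcc_view_report`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mcc_view_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("view", "ari_diagnosis",
                                  "depression_proportion", "avg_cohens_d")],
    -"view", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$view), y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "view", y = NULL, title = "View characterization") +
    ggplot2::theme_minimal()
}

#' Plot the two-step subtype classifier
#'
#' Scatter of the training subjects in the (FC score, CATS score) plane,
#' colored by cluster membership, with the two learned thresholds as dashed
#' lines.
#'
#' @param object an `mcc_subtype_classifier`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mcc_subtype_classifier <- function(object, ...) {
  ggplot2::ggplot(object$training,
                  ggplot2::aes(x = .data$fc, y = .data$cats,
                               color = .data$membership)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$fc_threshold, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = object$cats_threshold, linetype = "dotdash") +
    ggplot2::labs(x = "AG-related FC score", y = "CATS score",
                  title = "Two-step subtype classifier") +
    ggplot2::theme_minimal()
}
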