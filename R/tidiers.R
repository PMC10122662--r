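# broom-style tidiers and ggplot2 autoplot methods

#' @exportS3Method generics::tidy
tidy.brt_fit <- function(x, ...) x$relative_influence

#' @exportS3Method generics::glance
glance.brt_fit <- function(x, ...) {
  tibble::tibble(nt = x$nt, cv_D2 = x$cv_D2,
                 cv_deviance = x$cv_deviance,
                 cv_null_deviance = x$cv_null_deviance,
                 train_deviance = x$train_deviance,
                 null_deviance = x$null_deviance,
                 learning_rate = x$learning_rate,
                 tree_complexity = x$params$tree_complexity,
                 bag_fraction = x$params$bag_fraction,
                 n_folds = x$params$n_folds)
}

#' @exportS3Method generics::tidy
tidy.brt_aggregate <- function(x, ...) x$mean_influence

#' @exportS3Method generics::glance
glance.brt_aggregate <- function(x, ...) {
  tibble::tibble(n_runs = x$n_runs, mean_cv_D2 = x$mean_cv_D2)
}

#' @exportS3Method generics::tidy
tidy.invasion_report <- function(x, ...) x$aggregate$mean_influence

#' @exportS3Method generics::glance
glance.invasion_report <- function(x, ...) {
  tibble::tibble(model = x$model, n_predictors = length(x$predictors),
                 mean_cv_D2 = x$aggregate$mean_cv_D2,
                 n_runs = x$aggregate$n_runs)
}

#' @exportS3Method generics::tidy
tidy.functional_space <- function(x, ...) x$coordinates

#' @exportS3Method generics::glance
glance.functional_space <- function(x, ...) {
  tibble::tibble(n_species = nrow(x$coordinates),
                 n_axes = ncol(x$coordinates) - 1,
                 variance_explained = sum(x$variance_explained),
                 correction = x$correction)
}

#' @exportS3Method generics::tidy
tidy.composite_axes <- function(x, ...) x$scores

#' CV deviance trace of a boosted regression tree fit
#'
#' @param object A [fit_brt()] model.
#' @param ... Unused.
#' @return A ggplot: mean held-out Poisson deviance (± 1 sd) against ensemble
#'   size, with the selected tree count marked.
#' @exportS3Method ggplot2::autoplot
autoplot.brt_fit <- function(object, ...) {
  tr <- object$cv_trace
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$trees, y = .data$mean_deviance)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_deviance - .data$sd_deviance,
      ymax = .data$mean_deviance + .data$sd_deviance), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$nt, linetype = 2) +
    ggplot2::labs(x = "trees", y = "CV Poisson deviance",
                  title = sprintf("nt = %d, CV-D2 = %.3f", object$nt,
                                  object$cv_D2))
}

#' @exportS3Method ggplot2::autoplot
autoplot.pd_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$yhat)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~predictor, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "fitted response")
}

#' Bar chart of mean relative influences
#'
#' @param x An `invasion_report` or `brt_aggregate`.
#' @param top_n Show this many predictors.
#' @return A ggplot.
#' @export
plot_influence <- function(x, top_n = 12L) {
  mi <- if (inherits(x, "invasion_report")) x$aggregate$mean_influence else
    x$mean_influence
  mi <- head(mi, top_n)
  ggplot2::ggplot(mi, ggplot2::aes(
    x = stats::reorder(.data$predictor, .data$mean_influence),
    y = .data$mean_influence)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean relative influence (%)")
}

#' Partial-dependence panel of the most influential predictors
#'
#' @param report An `invasion_report`.
#' @param top_n Number of predictors plotted.
#' @param grid,sample_n Passed to [partial_dependence()].
#' @return A ggplot.
#' @export
plot_partial_dependence <- function(report, top_n = 12L, grid = 20L,
                                    sample_n = 300L) {
  fit <- report$aggregate$last_fit
  preds <- head(report$aggregate$mean_influence$predictor, top_n)
  preds <- preds[vapply(preds, function(p) is.numeric(fit$X[[p]]), TRUE)]
  curves <- dplyr::bind_rows(lapply(preds, function(p) {
    partial_dependence(fit, p, grid = grid, sample_n = sample_n)
  }))
  class(curves) <- c("pd_curve", class(curves))
  autoplot(curves)
}

#' @exportS3Method ggplot2::autoplot
autoplot.interaction_matrix <- function(object, ...) {
  m <- unclass(object)
  df <- tidyr::pivot_longer(
    tibble::as_tibble(m, rownames = "a"), -"a",
    names_to = "b", values_to = "strength")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   fill = .data$strength)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = NULL, y = NULL, fill = "interaction") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
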