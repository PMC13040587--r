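#' Diagnostic plots
#'
#' Simple 2-D diagnostics for a pipeline run: predicted-versus-
#' chronological age, BAG distributions by group, and effect-size
#' rankings. All return ggplot objects.
#'
#' @name plots
NULL

#' Corrected brain age versus chronological age
#'
#' @param predictions the pipeline's prediction tibble (or any tibble with
#'   `age`, `corrected`, `population`).
#' @param populations which populations to show.
#' @return a ggplot.
#' @export
plot_age_prediction <- function(predictions,
                                populations = c("train_cv", "HC_test")) {
  d <- predictions[predictions$population %in% populations, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age, y = .data$corrected)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~population) +
    ggplot2::labs(x = "chronological age (years)",
      y = "corrected brain age (years)") +
    ggplot2::theme_minimal()
}

#' BAG distributions by group
#'
#' @param predictions prediction tibble with `bag`, `group`, `region`.
#' @param regions optional subset of region names to facet.
#' @return a ggplot.
#' @export
plot_bag_by_group <- function(predictions, regions = NULL) {
  d <- predictions[predictions$population != "train_cv", ]
  if (!is.null(regions)) d <- d[d$region %in% regions, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$bag)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~region) +
    ggplot2::labs(x = NULL, y = "brain age gap (years)") +
    ggplot2::theme_minimal()
}

#' Effect sizes of ranked accelerated regions
#'
#' @param rankings the pipeline's ranking tibble (columns `region`,
#'   `partial_eta2`, `comparison`, `modality`).
#' @return a ggplot.
#' @export
plot_effect_sizes <- function(rankings) {
  ggplot2::ggplot(rankings,
    ggplot2::aes(x = stats::reorder(.data$region, .data$partial_eta2),
      y = .data$partial_eta2)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_grid(comparison ~ modality, scales = "free_y") +
    ggplot2::labs(x = NULL, y = expression(partial ~ eta^2)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a pipeline run
#'
#' @param object a `bag_run`.
#' @param type `"prediction"`, `"bag"`, or `"effects"`.
#' @param ... passed to the underlying plot function.
#' @return a ggplot.
#' @method autoplot bag_run
#' @export
autoplot.bag_run <- function(object, type = c("prediction", "bag", "effects"),
                             ...) {
  type <- match.arg(type)
  switch(type,
    prediction = plot_age_prediction(object$predictions, ...),
    bag = plot_bag_by_group(object$predictions, ...),
    effects = plot_effect_sizes(object$rankings, ...))
}
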