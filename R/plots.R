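#' Plot a PGLS fit with confidence and prediction bands
#'
#' @param object a `pgls_fit`.
#' @param level band coverage.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pgls_fit <- function(object, level = 0.95, ...) {
  grid <- tibble(x = seq(min(object$data$x), max(object$data$x), length.out = 80))
  names(grid) <- object$xname
  conf <- predict(object, grid, interval = "confidence", level = level)
  pred <- predict(object, grid, interval = "prediction", level = level)
  band <- dplyr::bind_cols(grid, conf,
    pred_lwr = pred$lwr, pred_upr = pred$upr
  )
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_ribbon(
      data = band,
      ggplot2::aes(
        x = .data[[object$xname]], y = NULL,
        ymin = .data$pred_lwr, ymax = .data$pred_upr
      ),
      fill = "grey85", alpha = 0.6
    ) +
    ggplot2::geom_ribbon(
      data = band,
      ggplot2::aes(
        x = .data[[object$xname]], y = NULL,
        ymin = .data$lwr, ymax = .data$upr
      ),
      fill = "grey70", alpha = 0.6
    ) +
    ggplot2::geom_line(
      data = band,
      ggplot2::aes(x = .data[[object$xname]], y = .data$fit)
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(x = object$xname, y = object$yname) +
    ggplot2::theme_minimal()
}

#' Distribution of branch-specific evolutionary rates
#'
#' Histogram of the signed rate ratios with the neutral N(0, 1) reference
#' density and the +-3 outlier thresholds.
#'
#' @param rates tibble from [branch_rate_ratios()], or several bound together
#'   with a `trait` column.
#' @return a ggplot.
#' @export
plot_rate_distribution <- function(rates) {
  p <- ggplot2::ggplot(rates, ggplot2::aes(x = .data$ratio)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(density)),
      bins = 40, fill = "grey70", colour = "white"
    ) +
    ggplot2::stat_function(fun = stats::dnorm, linetype = 2) +
    ggplot2::geom_vline(xintercept = c(-3, 3), linetype = 3) +
    ggplot2::labs(x = "evolutionary rate (observed / expected change)",
                  y = "density") +
    ggplot2::theme_minimal()
  if ("trait" %in% names(rates)) {
    p <- p + ggplot2::facet_wrap(~trait, scales = "free_y")
  }
  p
}

#' Event timing relative to birth across species
#'
#' Dot plot of signed event days (post-conception day minus gestation) per
#' species, centred on birth.
#'
#' @param timing tibble from [event_day()] with a `species` column.
#' @return a ggplot.
#' @export
plot_event_timeline <- function(timing) {
  ggplot2::ggplot(
    timing,
    ggplot2::aes(
      x = .data$signed_day, y = .data$species,
      colour = .data$classification
    )
  ) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(
      values = c(prenatal = "#4477aa", postnatal = "#cc6677")
    ) +
    ggplot2::labs(x = "days relative to birth", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
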