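#' Plot an elevation profile with its detected refuges
#'
#' @param object A [reef_profile()].
#' @param refuges Optional `refuge_set`; detected on the fly when `TRUE`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reef_profile <- function(object, refuges = TRUE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$z)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "planar distance (m)", y = "elevation (m)") +
    ggplot2::theme_minimal()
  if (isTRUE(refuges)) refuges <- detect_refuges(object)
  if (inherits(refuges, "refuge_set")) {
    marks <- tidy.refuge_set(refuges)
    if (nrow(marks)) {
      zs <- stats::approx(object$x, object$z, xout = marks$x)$y
      p <- p + ggplot2::geom_point(
        data = tibble::tibble(x = marks$x, z = zs, type = marks$type),
        ggplot2::aes(colour = .data$type), size = 2
      )
    }
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Habitat-gradient summary plot of the six metrics
#'
#' Per-habitat means and standard errors of each metric across the reef
#' gradient, faceted by metric: the package analogue of the classic
#' complexity-versus-habitat panel.
#'
#' @param metrics A [study_metrics()] table.
#' @return A ggplot object.
#' @export
plot_habitat_gradient <- function(metrics) {
  long <- tidyr::pivot_longer(
    metrics,
    c("rugosity", "verticality", "coral_cover", "refuge_count",
      "fov_visible", "grazing_area"),
    names_to = "metric", values_to = "value"
  )
  long$habitat <- factor(long$habitat, levels = c("slope", "crest", "outer_flat",
                                                  "mid_flat", "inner_flat"))
  summ <- dplyr::summarise(
    dplyr::group_by(long, .data$habitat, .data$metric),
    mean = mean(.data$value),
    se = stats::sd(.data$value) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$habitat, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      width = 0.2
    ) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot posterior habitat means with HPDI error bars
#'
#' @param object A `reef_fit` from [fit_habitat_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reef_fit <- function(object, ...) {
  s <- object$summary
  s$term <- factor(s$term, levels = s$term)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$term, y = .data$mean)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$hpdi_lower, ymax = .data$hpdi_upper),
      width = 0.15
    ) +
    ggplot2::labs(x = NULL, y = object$response,
                  subtitle = paste0(object$family, " family, back-transformed ",
                                    "posterior means with 95% HPDI")) +
    ggplot2::theme_minimal()
}

#' Fitted fish-distribution curve over grazing surface area
#'
#' Observed unit values with the posterior-mean prediction and its 95% HPDI
#' band from a gamma log-link hierarchical fit.
#'
#' @param fit A `reef_fit` from [fit_fish_model()].
#' @param data The unit-level data used for the fit.
#' @param covariate Covariate to display on the x axis.
#' @return A ggplot object.
#' @export
plot_fish_relationship <- function(fit, data, covariate = "grazing_area") {
  grid <- tibble::tibble(!!covariate := seq(min(data[[covariate]]),
                                            max(data[[covariate]]),
                                            length.out = 100))
  for (cv in setdiff(fit$terms[-1], covariate)) {
    grid[[cv]] <- mean(data[[cv]])
  }
  pred <- predict_fish_model(fit, grid)
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[covariate]],
                                     y = .data[[fit$response]])) +
    ggplot2::geom_ribbon(
      data = pred,
      ggplot2::aes(y = .data$.pred, ymin = .data$.pred_lower,
                   ymax = .data$.pred_upper),
      alpha = 0.25, fill = "steelblue"
    ) +
    ggplot2::geom_line(data = pred, ggplot2::aes(y = .data$.pred),
                       colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::theme_minimal()
}
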