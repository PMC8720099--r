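#' Plot a raster grid
#'
#' @param grid a [raster_grid()].
#' @param name legend title.
#' @return A ggplot object.
#' @export
plot_raster <- function(grid, name = "value") {
  df <- as_tibble(grid)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = name, na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)") +
    ggplot2::theme_minimal()
}

#' @describeIn variance_partition bar chart of the seven pure/shared
#'   fractions (negative fractions shown as-is).
#' @param object a `geodiv_vp` object.
#' @method autoplot geodiv_vp
#' @export
autoplot.geodiv_vp <- function(object, ...) {
  df <- tidy(object)
  df$component <- factor(df$component, levels = rev(df$component))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction, y = .data$component)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "explained deviance fraction", y = NULL,
                  title = sprintf("Variance partition (full deviance %.2f)",
                                  object$full_deviance)) +
    ggplot2::theme_minimal()
}

#' @describeIn run_study paired bars of explained deviance, environment
#'   model versus geodiversity-index model, per response.
#' @param object a `study_result`.
#' @method autoplot study_result
#' @export
autoplot.study_result <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tidy(object)[c("response", "env_deviance", "geodiv_deviance")],
    cols = -"response", names_to = "model", values_to = "deviance")
  df$model <- ifelse(df$model == "env_deviance", "environmental variables",
                     "geodiversity index")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$response, y = .data$deviance,
                                   fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c("environmental variables" = "#31688e",
                                          "geodiversity index" = "#b5de2b"),
                               name = NULL) +
    ggplot2::labs(x = NULL, y = "explained deviance") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_gam partial smooth effects over each predictor's observed
#'   range (other predictors held at their means).
#' @param object a `geodiv_gam` object.
#' @method autoplot geodiv_gam
#' @export
autoplot.geodiv_gam <- function(object, ...) {
  mf <- object$model$model
  grids <- purrr::map(object$predictors, function(p) {
    newd <- as.data.frame(purrr::map(mf[object$predictors],
                                     ~ rep(mean(.x), 100)))
    newd[[p]] <- seq(min(mf[[p]]), max(mf[[p]]), length.out = 100)
    tibble::tibble(predictor = p, x = newd[[p]],
                   fitted = as.numeric(predict(object$model, newdata = newd)))
  })
  df <- dplyr::bind_rows(grids)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$fitted)) +
    ggplot2::geom_line(colour = "#31688e") +
    ggplot2::facet_wrap(~predictor, scales = "free_x") +
    ggplot2::labs(x = NULL, y = object$response) +
    ggplot2::theme_minimal()
}
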