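#' Display a calibrated field
#'
#' Renders the RGB micrograph with ggplot2, optionally overlaying particle
#' centroids coloured by viability class.
#'
#' @param object A [calibrated_field()].
#' @param particles Optional particle tibble (ideally classified) whose
#'   centroids are overlaid for this field.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot calibrated_field
#' @export
autoplot.calibrated_field <- function(object, particles = NULL, ...) {
  d <- dim(object$pixels)
  ras <- grDevices::rgb(object$pixels[, , 1] / 255,
                        object$pixels[, , 2] / 255,
                        object$pixels[, , 3] / 255)
  dim(ras) <- d[1:2]
  p <- ggplot2::ggplot() +
    ggplot2::annotation_raster(ras, xmin = 0.5, xmax = d[2] + 0.5,
                               ymin = -(d[1] + 0.5), ymax = -0.5) +
    ggplot2::xlim(0.5, d[2] + 0.5) +
    ggplot2::ylim(-(d[1] + 0.5), -0.5) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(
      title = object$field_id,
      subtitle = sprintf("%.3g um/px", object$um_per_px),
      x = NULL, y = NULL
    ) +
    ggplot2::theme_void()
  if (!is.null(particles) && nrow(particles) > 0) {
    pp <- particles[particles$field_id == object$field_id, ]
    if (nrow(pp) > 0) {
      if (!"class" %in% names(pp)) pp$class <- "particle"
      p <- p + ggplot2::geom_point(
        data = pp,
        ggplot2::aes(x = .data$centroid_col, y = -.data$centroid_row,
                     shape = .data$class),
        colour = "white", size = 2.5, stroke = 0.8
      ) +
        ggplot2::scale_shape_manual(
          values = c(viable = 1, nonviable = 4, particle = 0))
    }
  }
  p
}

#' Per-field counts of a viability result
#'
#' Stacked bars of viable and non-viable particle counts for every field of
#' the run.
#'
#' @param object A `viability_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot viability_result
#' @export
autoplot.viability_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_field_counts,
                              c("n_viable", "n_nonviable"),
                              names_to = "class", values_to = "n")
  long$class <- factor(ifelse(long$class == "n_viable",
                              "viable", "non-viable"),
                       levels = c("viable", "non-viable"))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$field_id, y = .data$n,
                               fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c("viable" = "#c0392b",
                                          "non-viable" = "#27ae60")) +
    ggplot2::labs(x = "field", y = "particles", fill = NULL,
                  title = sprintf("viable %.1f%%, %.3g cells/ml",
                                  100 * object$viable_fraction,
                                  object$concentration_cells_per_ml)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a mixture-series calibration
#'
#' Estimated versus true viable fraction for a series produced by
#' [render_mixture_series()] and analysed with [run_assay()], with the
#' identity line and the fitted regression.
#'
#' @param estimates Tibble with columns `true_fraction` and
#'   `estimated_fraction` (as returned by [mixture_recovery()]).
#' @return A ggplot object.
#' @export
plot_mixture_series <- function(estimates) {
  ggplot2::ggplot(estimates,
                  ggplot2::aes(x = .data$true_fraction,
                               y = .data$estimated_fraction)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "#2c3e50", linewidth = 0.6) +
    ggplot2::geom_point(size = 2.5, colour = "#c0392b") +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "true viable fraction",
                  y = "estimated viable fraction") +
    ggplot2::theme_minimal()
}

#' Analyse a rendered mixture series
#'
#' Runs the full assay on every run of a mixture series and regresses the
#' estimated viable fraction on the true one — the synthetic analogue of
#' validating the fluorescence assay against a plating series.
#'
#' @param series Output of [render_mixture_series()].
#' @param config Optional [assay_config()] override.
#' @return A list with `estimates` (tibble: `true_fraction`,
#'   `estimated_fraction`, `n_viable`, `n_nonviable`,
#'   `concentration_cells_per_ml`), `slope`, `intercept` and `r_squared` of
#'   the least-squares fit of estimated on true fraction.
#' @export
mixture_recovery <- function(series, config = NULL) {
  est <- purrr::map_dfr(series, function(s) {
    res <- run_assay(s$run, config)
    tibble(
      true_fraction = s$fraction,
      estimated_fraction = res$viable_fraction,
      n_viable = res$n_viable,
      n_nonviable = res$n_nonviable,
      concentration_cells_per_ml = res$concentration_cells_per_ml
    )
  })
  fit <- lm(estimated_fraction ~ true_fraction, data = est)
  list(
    estimates = est,
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = summary(fit)$r.squared
  )
}
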