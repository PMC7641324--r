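# ggplot2 views of lanes and fits.

#' Plot a gel lane densitometry profile
#'
#' Intensity against migration distance, with the marker ladder as labeled
#' vertical guides.
#'
#' @param object A `gel_lane`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gel_lane <- function(object, ...) {
  md <- object$metadata
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$distance_mm, y = .data$intensity)) +
    ggplot2::geom_vline(data = object$markers,
                        ggplot2::aes(xintercept = .data$distance_mm),
                        linetype = "dotted", colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(
      title = sprintf("%s, %g uM inhibitor", md$substrate, md$inhibitor_uM),
      x = "migration distance (mm)", y = "intensity (molecules/mm)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a product-length vs substrate-length fit
#'
#' @param object A `product_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.product_fit <- function(object, ...) {
  df <- object$fit$model
  ggplot2::ggplot(df, ggplot2::aes(x = .data$substrate_length_nt,
                                   y = .data$product_length_nt)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      title = sprintf("product = %.3f S %+.0f nt", object$slope,
                      object$intercept),
      x = "substrate length (nt)", y = "labeled product length (nt)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a dose-response fit
#'
#' Data points with the fitted four-parameter logistic on a log
#' concentration axis (the zero-concentration points are drawn at a pseudo
#' concentration two decades below the smallest nonzero dose).
#'
#' @param object A `dose_response_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dose_response_fit <- function(object, ...) {
  df <- object$data
  pos <- df$inhibitor_uM[df$inhibitor_uM > 0]
  floor_conc <- min(pos) / 100
  df$conc_plot <- pmax(df$inhibitor_uM, floor_conc)
  curve <- tibble::tibble(
    inhibitor_uM = exp(seq(log(floor_conc), log(max(pos)), length.out = 200))
  )
  curve$activity_fraction <- object$bottom +
    (object$top - object$bottom) /
    (1 + (curve$inhibitor_uM / object$ic50_uM)^object$hill)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$conc_plot,
                                   y = .data$activity_fraction)) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$inhibitor_uM,
                                    y = .data$activity_fraction),
                       colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(title = sprintf("IC50 = %.3g uM", object$ic50_uM),
                  x = "inhibitor (uM)", y = "relative nuclease activity") +
    ggplot2::theme_minimal()
}
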