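#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Long-format pixels of a named list of images.
images_long <- function(imgs) {
  purrr::map_dfr(names(imgs), function(nm) {
    m <- imgs[[nm]]
    tibble::tibble(
      panel = nm,
      row = rep(seq_len(nrow(m)), times = ncol(m)),
      col = rep(seq_len(ncol(m)), each = nrow(m)),
      value = as.numeric(m)
    )
  })
}

#' Plot the evolution history
#'
#' Best, mean and best-so-far cost per generation.
#'
#' @param object A `digp_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot digp_fit
#' @export
autoplot.digp_fit <- function(object, ...) {
  d <- tidyr::pivot_longer(object$history, -"generation",
                           names_to = "series", values_to = "cost")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$generation, y = .data$cost,
                                  color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "cost F", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot reconstructions of a report
#'
#' One column per sample with the reconstruction raster (and the measurement /
#' ground truth when a dataset sample list is supplied via `samples`).
#'
#' @param object A `digp_report`.
#' @param samples Optional sample list matching the report, to add
#'   measurement and ground-truth panels.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot digp_report
#' @export
autoplot.digp_report <- function(object, samples = NULL, ...) {
  d <- purrr::map_dfr(seq_along(object$reconstructions), function(i) {
    imgs <- list(reconstruction = object$reconstructions[[i]])
    if (!is.null(samples)) {
      imgs <- c(list(measurement = samples[[i]]$measurement$M_sub,
                     truth = samples[[i]]$anomaly$contrast), imgs)
    }
    dplyr::mutate(images_long(imgs), sample = i)
  })
  d$panel <- factor(d$panel, levels = c("measurement", "truth", "reconstruction"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_grid(panel ~ sample) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "contrast") +
    ggplot2::theme_minimal()
}

#' Plot an anomaly map
#'
#' @param object A `digp_anomaly`.
#' @param ... Unused.
#' @return A ggplot raster of the contrast map.
#' @method autoplot digp_anomaly
#' @export
autoplot.digp_anomaly <- function(object, ...) {
  d <- images_long(list(contrast = object$contrast))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$shape_kind, x = NULL, y = NULL,
                  fill = "contrast") +
    ggplot2::theme_minimal()
}
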