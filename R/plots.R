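#' Plot an action spectra set
#'
#' One sensitivity curve per receptor on the shared wavelength grid.
#'
#' @param object An [action_spectra()] set.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.silsub_action_spectra <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(unclass_tbl(object)),
                              -"wavelength",
                              names_to = "receptor", values_to = "sensitivity")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$wavelength, y = .data$sensitivity, colour = .data$receptor
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "relative sensitivity",
                  colour = "receptor") +
    ggplot2::theme_minimal()
}

#' Plot a device's calibration spectra
#'
#' All calibration measurements, coloured by primary, one line per measured
#' setting.
#'
#' @param device A `silsub_device`.
#' @return A ggplot object.
#' @export
plot_calibration <- function(device) {
  long <- purrr::map_dfr(seq_along(device$settings), function(p) {
    m <- device$spd[[p]]
    purrr::map_dfr(seq_along(device$settings[[p]]), function(i) {
      tibble::tibble(
        primary = device$labels[p],
        setting = device$settings[[p]][i],
        wavelength = device$grid,
        value = m[i, ]
      )
    })
  })
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$wavelength, y = .data$value, colour = .data$primary,
    group = interaction(.data$primary, .data$setting)
  )) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "wavelength (nm)",
                  y = sprintf("spectral output (%s)", device$units),
                  colour = "primary") +
    ggplot2::theme_minimal()
}

#' Plot a solution
#'
#' Predicted background and modulation spectra (left) and the per-receptor
#' alpha-opic irradiances of both arms (right-hand facet).
#'
#' @param object A `silsub_solution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.silsub_solution <- function(object, ...) {
  spd <- tidyr::pivot_longer(object$spectra, -"wavelength",
                             names_to = "arm", values_to = "value")
  ggplot2::ggplot(spd, ggplot2::aes(
    x = .data$wavelength, y = .data$value, colour = .data$arm
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "spectral output",
                  colour = NULL,
                  title = sprintf("silent substitution solution (%s)", object$method),
                  subtitle = sprintf(
                    "target %s | silence %s | max silenced contrast %.2g",
                    paste(object$spec$target, collapse = ","),
                    paste(object$spec$silence, collapse = ","),
                    object$meta$constraint_residual
                  )) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
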