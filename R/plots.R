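#' Plot a simulated spectrum
#'
#' @param spectrum A spectrum tibble (`wavelength`, `value`) or leaf spectra
#'   tibble from [prospect5()].
#' @return A ggplot.
#' @export
plot_spectrum <- function(spectrum) {
  if ("value" %in% names(spectrum)) {
    d <- tibble::tibble(
      wavelength = spectrum$wavelength, value = spectrum$value,
      quantity = "reflectance"
    )
  } else {
    d <- tidyr::pivot_longer(spectrum, -"wavelength",
      names_to = "quantity", values_to = "value"
    )
  }
  ggplot2::ggplot(d, ggplot2::aes(.data$wavelength, .data$value,
    colour = .data$quantity
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength [nm]", y = "fraction", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Observed-versus-estimated scatter for an evaluation
#'
#' One facet per variable (and per approach when present), with the 1:1
#' line; mirrors the standard trait-retrieval validation scatter plots.
#'
#' @param object A `canopy_eval` from [evaluate()] or `canopy_e2e` from
#'   [run_end_to_end()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot canopy_eval
#' @export
autoplot.canopy_eval <- function(object, ...) {
  pairs <- attr(object, "pairs")
  if (is.null(pairs)) rlang::abort("evaluation carries no paired observations")
  ggplot2::ggplot(pairs, ggplot2::aes(.data$observed, .data$estimate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~variable, scales = "free") +
    ggplot2::labs(x = "observed", y = "estimated") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.canopy_eval
#' @method autoplot canopy_e2e
#' @export
autoplot.canopy_e2e <- function(object, ...) {
  pairs <- dplyr::bind_rows(lapply(split(object$results, object$results$approach), function(r) {
    ev <- evaluate(r, object$ground_truth)
    p <- attr(ev, "pairs")
    p$approach <- r$approach[1]
    p
  }))
  ggplot2::ggplot(pairs, ggplot2::aes(.data$observed, .data$estimate,
    colour = .data$approach
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~variable, scales = "free") +
    ggplot2::labs(x = "observed", y = "estimated", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Map a band or label of a synthetic scene
#'
#' @param scene A `synthetic_scene`.
#' @param fill Column of the pixel table to map (band name or `"label"`).
#' @return A ggplot raster map.
#' @export
plot_scene <- function(scene, fill = "label") {
  stopifnot(inherits(scene, "synthetic_scene"), fill %in% names(scene$pixels))
  ggplot2::ggplot(scene$pixels, ggplot2::aes(.data$x, .data$y,
    fill = .data[[fill]]
  )) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_y_reverse() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL, fill = fill)
}
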