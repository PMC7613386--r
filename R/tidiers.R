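#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an empirical-line model
#'
#' One row per band with the fitted slope, intercept and the number of
#' panels used after saturation exclusion.
#'
#' @param x An `elm_model` from [fit_elm()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy elm_model
#' @export
tidy.elm_model <- function(x, ...) {
  tibble::tibble(
    band = x$band, slope = x$slope, intercept = x$intercept,
    n_panels = x$n_panels
  )
}

#' @rdname tidy.elm_model
#' @method glance elm_model
#' @export
glance.elm_model <- function(x, ...) {
  tibble::tibble(
    n_bands = nrow(x),
    min_panels = min(x$n_panels),
    max_panels = max(x$n_panels)
  )
}

#' Tidy a look-up table
#'
#' Returns the row-aligned parameter and band-reflectance tables as one
#' tibble (one row per LUT entry, bands as columns).
#'
#' @param x A `prosail_lut`.
#' @param ... Unused.
#' @return A tibble with `.entry`, the parameter columns and one column per
#'   band.
#' @method tidy prosail_lut
#' @export
tidy.prosail_lut <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(.entry = seq_len(x$n)),
    x$params,
    tibble::as_tibble(x$reflectance)
  )
}

#' @rdname tidy.prosail_lut
#' @method glance prosail_lut
#' @export
glance.prosail_lut <- function(x, ...) {
  tibble::tibble(
    n_entries = x$n, n_bands = ncol(x$reflectance),
    date = x$space$date, seed = x$seed,
    noise_applied = x$noise_applied,
    noise_sd = if (x$noise_applied && !is.null(x$noise_sd)) x$noise_sd else NA_real_
  )
}

#' Tidy an end-to-end evaluation
#'
#' @param x A `canopy_e2e` from [run_end_to_end()] or a `canopy_eval` from
#'   [evaluate()].
#' @param ... Unused.
#' @return The metrics tibble.
#' @method tidy canopy_e2e
#' @export
tidy.canopy_e2e <- function(x, ...) {
  tibble::as_tibble(x$metrics)
}

#' @rdname tidy.canopy_e2e
#' @method glance canopy_e2e
#' @export
glance.canopy_e2e <- function(x, ...) {
  tibble::tibble(
    n_plots = nrow(x$scene$truth),
    n_pixels = nrow(x$scene$pixels),
    lut_entries = x$lut$n,
    approaches = paste(unique(x$results$approach), collapse = "+")
  )
}
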