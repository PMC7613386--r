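# Pixels belonging to one plot: by `plot_id` column when the pixel table
# carries one, otherwise by rectangle containment.
.plot_pixels <- function(pixels, plot) {
  if ("plot_id" %in% names(pixels)) {
    return(pixels[!is.na(pixels$plot_id) & pixels$plot_id == plot$plot_id, ])
  }
  pixels[pixels$x >= plot$xmin & pixels$x <= plot$xmax &
    pixels$y >= plot$ymin & pixels$y <= plot$ymax, ]
}

#' Plot-mean-reflectance inversion
#'
#' The first aggregation strategy: average the band reflectances of each
#' plot's valid pixels into one spectrum, then invert that mean spectrum
#' against the LUT. An optional vegetation mask restricts the mean to
#' sunlit green pixels (used for leaf chlorophyll retrieval); without a
#' mask, soil, shadow and plant pixels all enter the mean (used for LAI and
#' canopy chlorophyll). Plots without any valid pixel are reported with
#' `NA` estimates rather than as an error.
#'
#' @param pixels Pixel tibble with `x`, `y` and one column per LUT band
#'   (optionally a `plot_id` column).
#' @param plots Tibble with `plot_id` and rectangle columns `xmin`, `xmax`,
#'   `ymin`, `ymax`.
#' @param lut A `prosail_lut`.
#' @param mask Optional mask tibble from [hue_mask()] or [chm_mask()].
#' @param top_fraction,cost Passed to [invert_spectrum()].
#' @return A tibble `plot_id`, `variable`, `estimate`, `dispersion`,
#'   `n_pixels`, `n_solutions`.
#' @export
invert_plot_mean <- function(pixels, plots, lut, mask = NULL,
                             top_fraction = 0.05, cost = "rmse") {
  stopifnot(inherits(lut, "prosail_lut"))
  band_names <- lut$bands$band
  missing <- setdiff(band_names, names(pixels))
  if (length(missing) > 0) {
    rlang::abort(paste0("pixel table lacks bands: ", paste(missing, collapse = ", ")))
  }
  if (!is.null(mask)) pixels <- apply_mask(pixels, mask, band_names)
  vars <- names(.default_inversion_variables())
  rows <- lapply(seq_len(nrow(plots)), function(i) {
    px <- .plot_pixels(pixels, plots[i, ])
    bandmat <- as.matrix(px[, band_names])
    valid <- stats::complete.cases(bandmat)
    if (!any(valid)) {
      return(tibble::tibble(
        plot_id = plots$plot_id[i], variable = vars,
        estimate = NA_real_, dispersion = NA_real_,
        n_pixels = 0L, n_solutions = NA_integer_
      ))
    }
    m <- colMeans(bandmat[valid, , drop = FALSE])
    est <- invert_spectrum(m, lut, top_fraction, cost)
    tibble::tibble(
      plot_id = plots$plot_id[i], variable = est$variable,
      estimate = est$estimate, dispersion = est$dispersion,
      n_pixels = sum(valid), n_solutions = est$n_solutions
    )
  })
  dplyr::bind_rows(rows)
}

# Block-mean aggregation of a pixel grid by an integer factor; pixels with
# any missing band are excluded from the block mean.
.block_mean <- function(pixels, band_names, factor) {
  bx <- (pixels$x - 1L) %/% factor
  by <- (pixels$y - 1L) %/% factor
  key <- interaction(bx, by, drop = TRUE)
  bandmat <- as.matrix(pixels[, band_names])
  valid <- stats::complete.cases(bandmat)
  out <- lapply(split(seq_len(nrow(pixels)), key), function(idx) {
    idx_ok <- idx[valid[idx]]
    if (length(idx_ok) == 0) {
      return(NULL)
    }
    vals <- colMeans(bandmat[idx_ok, , drop = FALSE])
    # block centre in native pixel coordinates, so plot rectangles defined
    # on the native grid still select the right cells
    c(
      x = bx[idx[1]] * factor + (factor + 1) / 2,
      y = by[idx[1]] * factor + (factor + 1) / 2,
      n_pixels = length(idx_ok),
      vals
    )
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  tibble::as_tibble(out)
}

#' Per-pixel inversion, optionally at reduced resolution
#'
#' The second aggregation strategy: invert every valid pixel's spectrum
#' independently. For LAI and canopy chlorophyll mapping the grid is first
#' degraded by block-averaging to `target_gsd` (the study uses 0.09 m from
#' 0.015 m native, a factor of 6); leaf chlorophyll is mapped at native
#' resolution (`target_gsd = NULL`). Pixels with any missing band (masked
#' or nodata) are skipped.
#'
#' @param pixels Pixel tibble with integer `x`, `y` and band columns.
#' @param lut A `prosail_lut`.
#' @param gsd Ground sampling distance of `pixels`, metres.
#' @param target_gsd Optional coarser grid size, metres; must be an integer
#'   multiple of `gsd` and not smaller than it.
#' @param top_fraction,cost Passed to the ranking step (see
#'   [invert_spectrum()]).
#' @return A tibble with `x`, `y`, `n_pixels` (pixels averaged into the
#'   cell) and, per retrieved variable, `<var>` and `<var>_sd` columns, plus
#'   `n_solutions`.
#' @export
invert_pixelwise <- function(pixels, lut, gsd = 1, target_gsd = NULL,
                             top_fraction = 0.05, cost = "rmse") {
  stopifnot(inherits(lut, "prosail_lut"))
  band_names <- lut$bands$band
  missing <- setdiff(band_names, names(pixels))
  if (length(missing) > 0) {
    rlang::abort(paste0("pixel table lacks bands: ", paste(missing, collapse = ", ")))
  }
  if (!is.null(target_gsd)) {
    if (target_gsd < gsd) {
      rlang::abort("target_gsd must not be smaller than the source gsd")
    }
    factor <- target_gsd / gsd
    if (abs(factor - round(factor)) > 1e-8) {
      rlang::abort("target_gsd must be an integer multiple of gsd")
    }
    grid <- .block_mean(pixels, band_names, as.integer(round(factor)))
  } else {
    bandmat <- as.matrix(pixels[, band_names])
    valid <- stats::complete.cases(bandmat)
    grid <- dplyr::bind_cols(
      tibble::tibble(
        x = pixels$x[valid], y = pixels$y[valid],
        n_pixels = 1L
      ),
      tibble::as_tibble(bandmat[valid, , drop = FALSE])
    )
  }
  cost_fn <- if (is.function(cost)) cost else lut_cost_functions[[cost]]
  if (is.null(cost_fn)) rlang::abort(sprintf("unknown cost function `%s`", cost))
  vars <- .default_inversion_variables()
  m <- as.matrix(grid[, band_names])
  est <- matrix(NA_real_, nrow(grid), length(vars),
    dimnames = list(NULL, names(vars))
  )
  sds <- est
  k <- NA_integer_
  for (i in seq_len(nrow(grid))) {
    r <- .invert_one(m[i, ], lut, top_fraction, cost_fn, vars)
    est[i, ] <- r$est
    sds[i, ] <- r$sd
    k <- r$k
  }
  colnames(sds) <- paste0(names(vars), "_sd")
  dplyr::bind_cols(
    grid[, c("x", "y", "n_pixels")],
    tibble::as_tibble(est), tibble::as_tibble(sds),
    tibble::tibble(n_solutions = k)
  )
}

#' Plot means of per-pixel retrievals
#'
#' Averages pixel-level parameter estimates over each plot polygon
#' (arithmetic mean of valid pixels), optionally restricted by a mask on
#' the same grid. Plots with no valid pixel are reported with `NA`.
#'
#' @param param_pixels Output of [invert_pixelwise()] (columns `x`, `y` and
#'   variable columns).
#' @param plots Plot rectangles (`plot_id`, `xmin`, `xmax`, `ymin`,
#'   `ymax`).
#' @param variables Variable columns to aggregate (default `LAI`, `Cab`,
#'   `CCC`).
#' @param mask Optional mask tibble on the same grid as `param_pixels`.
#' @return A tibble `plot_id`, `variable`, `estimate`, `n_pixels`.
#' @export
aggregate_plots <- function(param_pixels, plots,
                            variables = c("LAI", "Cab", "CCC"), mask = NULL) {
  stopifnot(all(variables %in% names(param_pixels)))
  if (!is.null(mask)) {
    keep <- dplyr::left_join(param_pixels[, c("x", "y")], mask, by = c("x", "y"))
    param_pixels <- param_pixels[!is.na(keep$retained) & keep$retained, ]
  }
  rows <- lapply(seq_len(nrow(plots)), function(i) {
    px <- .plot_pixels(param_pixels, plots[i, ])
    vals <- vapply(variables, function(v) mean(px[[v]], na.rm = TRUE), numeric(1))
    n <- vapply(variables, function(v) sum(!is.na(px[[v]])), integer(1))
    tibble::tibble(
      plot_id = plots$plot_id[i], variable = variables,
      estimate = unname(ifelse(n > 0, vals, NA_real_)),
      n_pixels = unname(n)
    )
  })
  dplyr::bind_rows(rows)
}
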