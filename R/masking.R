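#' Hue index of an RGB reflectance triple
#'
#' Colour index used to separate green vegetation from soil and shadow:
#' `HI = atan(2 * (B - G - R) / (30.5 * (G - R)))`. For green vegetation the
#' numerator is negative and the denominator positive, so vegetation takes
#' negative index values; bright soil takes positive values. Pixels with
#' `G == R` (undefined index) return `NA`.
#'
#' The exact index of the cited field-phenotyping toolbox is not printed in
#' the sources this package follows, so the index function is pluggable
#' wherever it is consumed ([hue_mask()]); this default is calibrated once
#' on the synthetic scene so vegetation is retained.
#'
#' @param r,g,b Reflectance in the red, green and blue bands.
#' @return Index values (radians); `NA` where `g == r`.
#' @export
#' @examples
#' hue_index(0.05, 0.20, 0.03) # vegetation: negative
#' hue_index(0.30, 0.28, 0.22) # bright soil: positive
hue_index <- function(r, g, b) {
  den <- 30.5 * (g - r)
  out <- atan(2 * (b - g - r) / den)
  out[den == 0] <- NA_real_
  out
}

#' Vegetation mask from an RGB colour index
#'
#' Retains sunlit green vegetation pixels: a pixel is kept when its colour
#' index falls on the configured side of `threshold` (default: index below
#' 0, the vegetation side of the default [hue_index()]). Two auxiliary rules
#' handle degenerate pixels: near-black pixels whose summed R+G+B
#' reflectance is below `brightness_floor` are removed (shadow), and pixels
#' where the index is undefined (`G == R`) are removed and counted in the
#' `"n_undefined"` attribute. Pixels with missing band values are removed.
#'
#' @param pixels Pixel tibble with `x`, `y` and the three colour bands.
#' @param red,green,blue Names of the band columns (defaults: Red668,
#'   Green560, Blue475).
#' @param threshold Index threshold (default 0).
#' @param direction `"below"` (default) retains pixels with index <
#'   threshold; `"above"` retains index > threshold.
#' @param index Index function of `(r, g, b)`; default [hue_index()].
#' @param brightness_floor Minimum summed R+G+B reflectance (default 0.05).
#' @return A mask tibble `x`, `y`, `retained` (logical), with attribute
#'   `n_undefined`.
#' @export
hue_mask <- function(pixels, red = "Red668", green = "Green560",
                     blue = "Blue475", threshold = 0,
                     direction = c("below", "above"), index = hue_index,
                     brightness_floor = 0.05) {
  direction <- match.arg(direction)
  for (b in c(red, green, blue)) {
    if (!b %in% names(pixels)) rlang::abort(sprintf("pixel table lacks band column `%s`", b))
  }
  r <- pixels[[red]]
  g <- pixels[[green]]
  b <- pixels[[blue]]
  hi <- index(r, g, b)
  keep <- if (direction == "below") hi < threshold else hi > threshold
  undefined <- is.na(hi) & !(is.na(r) | is.na(g) | is.na(b))
  keep[is.na(keep)] <- FALSE
  keep[(r + g + b) < brightness_floor] <- FALSE
  keep[is.na(r) | is.na(g) | is.na(b)] <- FALSE
  out <- tibble::tibble(x = pixels$x, y = pixels$y, retained = keep)
  attr(out, "n_undefined") <- sum(undefined)
  out
}

#' Vegetation mask from a crop height model
#'
#' Subtracts the digital terrain model from the digital surface model and
#' retains pixels whose crop height exceeds `min_height`. Used instead of
#' the colour index when senescent (brown) leaves are spectrally similar to
#' soil.
#'
#' @param dsm,dtm Tibbles with `x`, `y`, `elevation` (m) on the same grid.
#' @param min_height Height threshold in metres (default 0.05).
#' @return A mask tibble `x`, `y`, `retained`.
#' @export
chm_mask <- function(dsm, dtm, min_height = 0.05) {
  stopifnot(all(c("x", "y", "elevation") %in% names(dsm)))
  stopifnot(all(c("x", "y", "elevation") %in% names(dtm)))
  if (nrow(dsm) != nrow(dtm)) rlang::abort("DSM and DTM grids differ")
  j <- dplyr::inner_join(dsm, dtm, by = c("x", "y"), suffix = c("_dsm", "_dtm"))
  if (nrow(j) != nrow(dsm)) rlang::abort("DSM and DTM grids differ")
  if (any(!is.finite(j$elevation_dsm)) || any(!is.finite(j$elevation_dtm))) {
    rlang::abort("elevations must be finite")
  }
  tibble::tibble(
    x = j$x, y = j$y,
    retained = (j$elevation_dsm - j$elevation_dtm) > min_height
  )
}

#' Apply a pixel mask to a band table
#'
#' Sets all band columns to `NA` where the mask is not retained; retained
#' pixels are untouched, so applying a mask twice equals applying it once.
#'
#' @param pixels Pixel tibble with `x`, `y` and band columns.
#' @param mask Mask tibble `x`, `y`, `retained` on the same grid.
#' @param band_names Columns to blank; defaults to all numeric columns other
#'   than `x` and `y`.
#' @return The masked pixel tibble.
#' @export
apply_mask <- function(pixels, mask, band_names = NULL) {
  stopifnot(all(c("x", "y", "retained") %in% names(mask)))
  if (nrow(pixels) != nrow(mask)) rlang::abort("pixel table and mask shapes differ")
  ord <- dplyr::left_join(
    pixels[, c("x", "y")], mask,
    by = c("x", "y")
  )
  if (any(is.na(ord$retained))) rlang::abort("mask does not cover the pixel grid")
  if (is.null(band_names)) {
    band_names <- setdiff(
      names(pixels)[vapply(pixels, is.numeric, logical(1))],
      c("x", "y")
    )
  }
  for (b in band_names) {
    pixels[[b]][!ord$retained] <- NA_real_
  }
  pixels
}
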