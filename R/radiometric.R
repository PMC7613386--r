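#' Radiometric calibration parameters for one sensor band
#'
#' Container for the manufacturer's raw-to-radiance calibration: polynomial
#' calibration coefficients `a1`, `a2`, `a3`, sensor gain `g`, exposure time
#' `te` (ms), normalised black level `p_bl` (fraction of full scale) and a
#' vignette function `vignette(x, y)` returning the per-pixel correction
#' factor (supplied as coefficients by the manufacturer; here it is an input,
#' not fitted).
#'
#' @param a1,a2,a3 Radiometric calibration coefficients.
#' @param g Sensor gain setting, > 0.
#' @param te Exposure time in milliseconds, > 0.
#' @param p_bl Normalised black level, in `[0, 1)`.
#' @param vignette A function of pixel column `x` and row `y` returning a
#'   positive factor; defaults to no vignetting.
#' @return A list of class `radiometric_cal`.
#' @export
radiometric_cal <- function(a1, a2 = 0, a3 = 0, g = 1, te = 1, p_bl = 0,
                            vignette = function(x, y) rep(1, length(x))) {
  if (!is.finite(g) || g <= 0) rlang::abort("calibration `g` must be > 0")
  if (!is.finite(te) || te <= 0) rlang::abort("calibration `te` must be > 0")
  if (!is.finite(p_bl) || p_bl < 0 || p_bl >= 1) {
    rlang::abort("calibration `p_bl` must be in [0, 1)")
  }
  structure(
    list(a1 = a1, a2 = a2, a3 = a3, g = g, te = te, p_bl = p_bl, vignette = vignette),
    class = "radiometric_cal"
  )
}

#' Convert raw digital numbers to at-sensor radiance
#'
#' Applies the manufacturer formula
#' `L = V(x, y) * (a1 / g) * (p - p_bl) / (te + a2 * y - a3 * te * y)`
#' with `p = dn / 2^bit_depth` the normalised raw value, `V` the vignette
#' correction and `y` the pixel row. The row-dependent denominator models the
#' rolling-shutter exposure gradient.
#'
#' @param frame A tibble with columns `x`, `y` (pixel column/row indices) and
#'   `dn` (integer digital numbers).
#' @param cal A [radiometric_cal()] object.
#' @param bit_depth Bit depth `B` of the raw data; `dn` must lie in
#'   `[0, 2^B)`.
#' @return The input tibble with a `radiance` column (W/m^2/sr/nm).
#' @export
#' @examples
#' frame <- tibble::tibble(x = 1:4, y = 1L, dn = c(0L, 100L, 1000L, 4095L))
#' raw_to_radiance(frame, radiometric_cal(a1 = 2), bit_depth = 12)
raw_to_radiance <- function(frame, cal, bit_depth = 16) {
  stopifnot(all(c("x", "y", "dn") %in% names(frame)))
  if (any(frame$dn < 0 | frame$dn >= 2^bit_depth)) {
    rlang::abort(sprintf("digital numbers must lie in [0, 2^%d)", bit_depth))
  }
  p <- frame$dn / 2^bit_depth
  den <- cal$te + cal$a2 * frame$y - cal$a3 * cal$te * frame$y
  if (any(den <= 0)) {
    rlang::abort("exposure denominator te + a2*y - a3*te*y is non-positive for some rows")
  }
  v <- cal$vignette(frame$x, frame$y)
  if (any(!is.finite(v) | v <= 0)) {
    rlang::abort("vignette correction must be positive over the frame")
  }
  dplyr::mutate(frame, radiance = v * (cal$a1 / cal$g) * (p - cal$p_bl) / den)
}

#' Fit the empirical line method on calibration panels
#'
#' Per band, ordinary least squares of the panels' field-measured nominal
#' reflectance on their observed at-sensor radiance. Bright panels saturate
#' the visible bands; by default, panels with nominal reflectance above
#' `saturation_threshold` (22 %) are excluded from the fit in visible bands
#' (centre < `visible_cutoff_nm`), while red-edge/NIR bands use all panels.
#' An explicit logical `saturated` column in `panels`, when present, is
#' honoured in addition.
#'
#' @param panels A tibble with columns `panel_id`, `band`,
#'   `nominal_reflectance` (fraction) and `observed_radiance`, optionally
#'   `saturated`.
#' @param bands Band-set tibble used to classify bands as visible vs
#'   red-edge/NIR.
#' @param saturation_threshold Nominal reflectance above which a panel is
#'   considered saturated in the visible bands; set to `Inf` to disable.
#' @param visible_cutoff_nm Band-centre cutoff separating visible from
#'   red-edge/NIR (default 700 nm).
#' @return A tibble of class `elm_model` with columns `band`, `slope`,
#'   `intercept`, `n_panels`.
#' @export
fit_elm <- function(panels, bands = micasense_dual_bands(),
                    saturation_threshold = 0.22, visible_cutoff_nm = 700) {
  stopifnot(all(c("panel_id", "band", "nominal_reflectance", "observed_radiance") %in%
    names(panels)))
  validate_band_set(bands)
  missing_bands <- setdiff(unique(panels$band), bands$band)
  if (length(missing_bands) > 0) {
    rlang::abort(paste0("panel bands not in band set: ", paste(missing_bands, collapse = ", ")))
  }
  fits <- lapply(bands$band, function(b) {
    pb <- panels[panels$band == b, ]
    visible <- bands$center_nm[bands$band == b] < visible_cutoff_nm
    usable <- rep(TRUE, nrow(pb))
    if (visible) usable <- usable & pb$nominal_reflectance <= saturation_threshold
    if ("saturated" %in% names(pb)) usable <- usable & !pb$saturated
    pb <- pb[usable, ]
    if (nrow(pb) < 2) {
      rlang::abort(sprintf("band %s has fewer than 2 usable panels after saturation exclusion", b))
    }
    fit <- stats::lm(nominal_reflectance ~ observed_radiance, data = pb)
    tibble::tibble(
      band = b,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      n_panels = nrow(pb)
    )
  })
  out <- dplyr::bind_rows(fits)
  class(out) <- c("elm_model", class(out))
  out
}

#' Convert radiance pixels to surface reflectance with a fitted ELM
#'
#' Applies the per-band linear mapping `reflectance = slope * radiance +
#' intercept` to a pixel table in which each model band is a radiance
#' column. Results are clipped to the physical range `[0, 1]`; the number of
#' clipped values per band is recorded in the `"clipped"` attribute so
#' nothing is lost silently.
#'
#' @param pixels A tibble with one radiance column per model band (plus any
#'   other columns, which pass through).
#' @param model An `elm_model` from [fit_elm()].
#' @return The pixel tibble with band columns converted to reflectance;
#'   attribute `clipped` is a named integer vector of clip counts.
#' @export
apply_elm <- function(pixels, model) {
  missing <- setdiff(model$band, names(pixels))
  if (length(missing) > 0) {
    rlang::abort(paste0("pixel table lacks radiance columns: ", paste(missing, collapse = ", ")))
  }
  clipped <- stats::setNames(integer(nrow(model)), model$band)
  for (i in seq_len(nrow(model))) {
    b <- model$band[i]
    r <- model$slope[i] * pixels[[b]] + model$intercept[i]
    clipped[b] <- sum(r < 0 | r > 1, na.rm = TRUE)
    pixels[[b]] <- pmin(pmax(r, 0), 1)
  }
  attr(pixels, "clipped") <- clipped
  pixels
}

#' Extract mean panel radiance from a pixel table
#'
#' Averages band values over the eroded interior of each panel rectangle:
#' the rectangle is shrunk on every side by `erosion` times its short side,
#' so edge pixels mixed with background do not bias the panel statistics.
#'
#' @param pixels Pixel tibble with `x`, `y` and band columns.
#' @param panel_rects Tibble with `panel_id`, `xmin`, `xmax`, `ymin`, `ymax`
#'   (pixel coordinates) and `nominal_reflectance`.
#' @param band_names Character vector of band columns to extract.
#' @param erosion Fraction of the short side removed from each edge
#'   (default 0.25).
#' @return A long tibble `panel_id`, `band`, `nominal_reflectance`,
#'   `observed_radiance` suitable for [fit_elm()].
#' @export
extract_panel_radiance <- function(pixels, panel_rects, band_names,
                                   erosion = 0.25) {
  stopifnot(erosion >= 0, erosion < 0.5)
  rows <- lapply(seq_len(nrow(panel_rects)), function(i) {
    p <- panel_rects[i, ]
    short <- min(p$xmax - p$xmin, p$ymax - p$ymin)
    m <- erosion * short
    inside <- pixels$x >= p$xmin + m & pixels$x <= p$xmax - m &
      pixels$y >= p$ymin + m & pixels$y <= p$ymax - m
    vals <- vapply(band_names, function(b) mean(pixels[[b]][inside], na.rm = TRUE), numeric(1))
    tibble::tibble(
      panel_id = p$panel_id,
      band = band_names,
      nominal_reflectance = p$nominal_reflectance,
      observed_radiance = unname(vals)
    )
  })
  dplyr::bind_rows(rows)
}
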