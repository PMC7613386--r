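#' Synthetic leaf optical constants for the plate model
#'
#' The leaf radiative transfer model needs, at every wavelength, the leaf
#' refractive index and the specific absorption coefficient of each absorber
#' (chlorophyll a+b, carotenoids, brown pigment, water, dry matter). The
#' published calibration tables for these constants are distributed with the
#' original model code and are not bundled here; instead this function builds
#' a **synthetic** set of constants from closed-form smooth curves (sums of
#' Gaussian absorption bands placed at the physically correct locations:
#' chlorophyll peaks in the blue and red, carotenoids in the blue-green,
#' brown pigment decaying across the visible, water bands at 970/1200/1450/
#' 1940/2270 nm, dry matter rising into the shortwave infrared).
#'
#' The resulting leaf and canopy spectra are physically plausible (green
#' peak, red absorption trough, NIR plateau, SWIR water features) and every
#' qualitative property of the model holds, but absolute values are not
#' comparable to spectra simulated with the published calibration.
#'
#' @return A tibble with one row per wavelength (400--2500 nm, 1 nm step) and
#'   columns `wavelength`, `nr` (refractive index), `kab` (cm^2/ug), `kcar`
#'   (cm^2/ug), `kbrown` (dimensionless content basis), `kw` (1/cm), `km`
#'   (cm^2/g).
#' @export
#' @examples
#' head(leaf_optical_constants())
leaf_optical_constants <- function() {
  cached <- get0("constants", envir = .canopylut_cache)
  if (!is.null(cached)) {
    return(cached)
  }
  wl <- spectral_grid()
  g <- function(center, width) exp(-0.5 * ((wl - center) / width)^2)

  nr <- 1.40 + 0.13 * exp(-(wl - 400) / 750)

  kab <- 0.065 * g(430, 28) + 0.058 * g(662, 24) + 0.020 * g(560, 90)

  kcar <- 0.055 * g(426, 16) + 0.090 * g(452, 18) + 0.100 * g(480, 20)

  # decays to ~zero before the NIR plateau: brown pigment is a visible-only
  # absorber
  kbrown <- 2.2 * exp(-((wl - 400) / 130)^2)

  kw <- 0.45 * g(970, 35) + 1.2 * g(1200, 45) + 31 * g(1450, 55) +
    5.5 * g(1790, 60) + 88 * g(1940, 70) + 24 * g(2270, 80) +
    45 * g(2600, 120)

  # the broad 1100 nm term gives the leaf a few percent NIR absorptance, as
  # real leaves show on their plateau
  km <- 0.9 * exp((wl - 2500) / 700) + 5 * g(1100, 450) + 6 * g(1730, 60) +
    9 * g(2100, 80) + 14 * g(2300, 90) + 8 * g(2480, 90)

  out <- tibble::tibble(
    wavelength = wl, nr = nr, kab = kab, kcar = kcar,
    kbrown = kbrown, kw = kw, km = km
  )
  assign("constants", out, envir = .canopylut_cache)
  out
}

.canopylut_cache <- new.env(parent = emptyenv())

#' Synthetic soil reflectance spectra
#'
#' Smooth, monotonically increasing reflectance curves typical of bare soil,
#' one brighter "dry" and one darker "wet" variant. They stand in for soil
#' spectra extracted from calibrated orthomosaic pixels, which require field
#' imagery; both are generated in code (synthetic) and serve as the default
#' soil background of the canopy model and the scene generator.
#'
#' @param type `"dry"` or `"wet"`.
#' @return A tibble with columns `wavelength` (400--2500 nm) and `value`.
#' @export
#' @examples
#' soil_spectrum("dry")
soil_spectrum <- function(type = c("dry", "wet")) {
  type <- match.arg(type)
  wl <- spectral_grid()
  value <- switch(type,
    dry = 0.06 + 0.30 * (1 - exp(-(wl - 400) / 1200)),
    wet = 0.035 + 0.21 * (1 - exp(-(wl - 400) / 1400))
  )
  tibble::tibble(wavelength = wl, value = value)
}
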