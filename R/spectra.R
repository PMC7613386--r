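#' The internal wavelength grid
#'
#' All spectra in the package live on a fixed 1 nm grid from 400 to 2500 nm,
#' the standard support of leaf/canopy radiative transfer codes.
#'
#' @return Integer vector `400:2500`.
#' @export
spectral_grid <- function() {
  400:2500
}

#' Build a spectrum tibble on the standard grid
#'
#' @param value Numeric vector of length 2101 (one value per wavelength of
#'   [spectral_grid()]), or a data frame with `wavelength` and `value`
#'   columns covering the grid.
#' @return A tibble with columns `wavelength` and `value`.
#' @export
as_spectrum <- function(value) {
  if (is.data.frame(value)) {
    stopifnot(all(c("wavelength", "value") %in% names(value)))
    v <- .spectrum_values(value)
    return(tibble::tibble(wavelength = spectral_grid(), value = v))
  }
  grid <- spectral_grid()
  if (length(value) == 1L) value <- rep(value, length(grid))
  if (length(value) != length(grid)) {
    rlang::abort("`value` must have one element per wavelength of the 400-2500 nm grid.")
  }
  tibble::tibble(wavelength = grid, value = as.numeric(value))
}

# Extract the numeric values of a spectrum on the standard grid, interpolating
# (linearly) if the input grid differs; errors if it does not cover 400-2500.
.spectrum_values <- function(s) {
  if (is.numeric(s)) {
    if (length(s) != length(spectral_grid())) {
      rlang::abort("numeric spectrum must match the 400-2500 nm, 1 nm grid")
    }
    return(as.numeric(s))
  }
  stopifnot(is.data.frame(s), all(c("wavelength", "value") %in% names(s)))
  grid <- spectral_grid()
  if (nrow(s) == length(grid) && all(s$wavelength == grid)) {
    return(as.numeric(s$value))
  }
  if (min(s$wavelength) > min(grid) || max(s$wavelength) < max(grid)) {
    rlang::abort("spectrum does not cover the 400-2500 nm grid; cannot resample")
  }
  stats::approx(s$wavelength, s$value, xout = grid, ties = "ordered")$y
}

#' Default multispectral band set (dual 10-band camera)
#'
#' Centre wavelengths and bandwidths (FWHM) of the ten bands of the MicaSense
#' RedEdge-MX Dual camera system used as the default sensor.
#'
#' @return A tibble with columns `band`, `center_nm`, `fwhm_nm`.
#' @export
#' @examples
#' micasense_dual_bands()
micasense_dual_bands <- function() {
  tibble::tibble(
    band = c(
      "Blue444", "Blue475", "Green531", "Green560", "Red650",
      "Red668", "RE705", "RE717", "RE740", "NIR840"
    ),
    center_nm = c(444, 475, 531, 560, 650, 668, 705, 717, 740, 842),
    fwhm_nm = c(28, 32, 14, 27, 16, 14, 10, 12, 18, 57)
  )
}

#' Read a band-set definition from CSV
#'
#' The file must have columns `band`, `center_nm`, `fwhm_nm`.
#'
#' @param path Path to a CSV file.
#' @return A validated band-set tibble.
#' @export
read_band_set <- function(path) {
  bands <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  validate_band_set(bands)
  bands
}

#' @rdname read_band_set
#' @param bands A band-set tibble.
#' @export
validate_band_set <- function(bands) {
  stopifnot(all(c("band", "center_nm", "fwhm_nm") %in% names(bands)))
  if (any(diff(bands$center_nm) <= 0)) {
    rlang::abort("band centres must be strictly increasing")
  }
  if (any(bands$fwhm_nm <= 0)) {
    rlang::abort("band FWHM must be positive")
  }
  invisible(bands)
}

# Spectral response weight matrix: one column per band, rows on the standard
# grid; columns are non-negative and sum to 1 (trapezoid-normalised), so band
# values are convex combinations of spectrum values.
.srf_weights <- function(bands, srf = c("gaussian", "boxcar")) {
  srf <- match.arg(srf)
  validate_band_set(bands)
  grid <- spectral_grid()
  # trapezoid quadrature coefficients on the unit-step grid
  tz <- rep(1, length(grid))
  tz[c(1, length(grid))] <- 0.5
  w <- matrix(0, nrow = length(grid), ncol = nrow(bands),
    dimnames = list(NULL, bands$band)
  )
  for (i in seq_len(nrow(bands))) {
    c0 <- bands$center_nm[i]
    fw <- bands$fwhm_nm[i]
    if (srf == "gaussian") {
      sigma <- fw / (2 * sqrt(2 * log(2)))
      if (c0 - 3 * sigma < min(grid) || c0 + 3 * sigma > max(grid)) {
        rlang::abort(sprintf("band %s extends outside the 400-2500 nm grid", bands$band[i]))
      }
      resp <- exp(-0.5 * ((grid - c0) / sigma)^2)
    } else {
      lo <- c0 - fw / 2
      hi <- c0 + fw / 2
      if (lo < min(grid) || hi > max(grid)) {
        rlang::abort(sprintf("band %s extends outside the 400-2500 nm grid", bands$band[i]))
      }
      resp <- as.numeric(grid >= lo & grid <= hi)
    }
    resp <- resp * tz
    w[, i] <- resp / sum(resp)
  }
  w
}

#' Resample a spectrum to sensor bands
#'
#' Convolves a 1 nm spectrum with a normalised spectral response function
#' (SRF) per band. The default SRF is a Gaussian whose FWHM equals the band's
#' stated bandwidth; a boxcar of the same width is available. Each band value
#' is a convex combination of spectrum values (weights are non-negative and
#' sum to one), so resampling is linear and preserves constants.
#'
#' @param spectrum A spectrum tibble (`wavelength`, `value`) or numeric
#'   vector on the standard grid.
#' @param bands A band-set tibble (see [micasense_dual_bands()]).
#' @param srf `"gaussian"` (default) or `"boxcar"`.
#' @return A tibble with columns `band` and `value`.
#' @export
#' @examples
#' s <- as_spectrum(0.3)
#' resample_to_bands(s, micasense_dual_bands())
resample_to_bands <- function(spectrum, bands = micasense_dual_bands(),
                              srf = c("gaussian", "boxcar")) {
  w <- .srf_weights(bands, srf)
  v <- .spectrum_values(spectrum)
  if (any(!is.finite(v))) rlang::abort("spectrum contains non-finite values")
  tibble::tibble(band = bands$band, value = as.numeric(v %*% w))
}

#' Write / read a spectrum as two-column CSV
#'
#' @param spectrum A spectrum tibble.
#' @param path File path.
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.csv(
    tibble::tibble(
      wavelength_nm = spectrum$wavelength,
      value = spectrum$value
    ),
    path,
    row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  d <- utils::read.csv(path)
  tibble::tibble(wavelength = d[[1]], value = d[[2]])
}
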