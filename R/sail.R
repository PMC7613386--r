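#' Canopy parameter set for the four-stream canopy model
#'
#' @param LAI Leaf area index (m^2/m^2), >= 0.
#' @param ALIA Average leaf inclination angle (degrees from horizontal),
#'   strictly between 0 and 90; parameterises an ellipsoidal leaf
#'   inclination distribution.
#' @param hot Hot spot parameter (ratio of leaf size to canopy height),
#'   >= 0.
#' @param SZA,OZA Sun and observer zenith angles (degrees, in `[0, 90)`).
#' @param rAA Relative azimuth angle between sun and observer (degrees).
#' @param soil Soil background reflectance spectrum (tibble `wavelength`,
#'   `value` covering 400--2500 nm).
#' @return A list of class `canopy_params`.
#' @export
#' @examples
#' canopy_params(LAI = 3, ALIA = 45, SZA = 30)
canopy_params <- function(LAI = 3, ALIA = 45, hot = 0.1, SZA = 30,
                          OZA = 0, rAA = 0, soil = soil_spectrum("dry")) {
  canopy <- structure(
    list(
      LAI = LAI, ALIA = ALIA, hot = hot, SZA = SZA, OZA = OZA, rAA = rAA,
      soil = soil
    ),
    class = "canopy_params"
  )
  validate_canopy_params(canopy)
  canopy
}

#' @rdname canopy_params
#' @param canopy A `canopy_params` object.
#' @export
validate_canopy_params <- function(canopy) {
  chk <- function(cond, msg) if (!cond) rlang::abort(msg)
  chk(is.finite(canopy$LAI) && canopy$LAI >= 0, "canopy parameter `LAI` must be >= 0")
  chk(is.finite(canopy$ALIA) && canopy$ALIA > 0 && canopy$ALIA < 90,
    "canopy parameter `ALIA` must be strictly between 0 and 90 degrees")
  chk(is.finite(canopy$hot) && canopy$hot >= 0, "canopy parameter `hot` must be >= 0")
  chk(is.finite(canopy$SZA) && canopy$SZA >= 0 && canopy$SZA < 90,
    "canopy parameter `SZA` must be in [0, 90) degrees")
  chk(is.finite(canopy$OZA) && canopy$OZA >= 0 && canopy$OZA < 90,
    "canopy parameter `OZA` must be in [0, 90) degrees")
  invisible(canopy)
}

# Ellipsoidal (Campbell) leaf inclination distribution discretised over the
# 13 standard angle classes (midpoints 5, 15, ..., 75, 81, 83, 85, 87, 89).
.campbell_lidf <- function(alia) {
  n <- 13L
  bounds_lo <- c(seq(0, 70, by = 10), seq(80, 88, by = 2))
  bounds_hi <- c(seq(10, 80, by = 10), seq(82, 90, by = 2))
  excent <- exp(-1.6184e-5 * alia^3 + 2.1145e-3 * alia^2 -
    1.2390e-1 * alia + 3.2491)
  freq <- numeric(n)
  for (i in seq_len(n)) {
    tl1 <- bounds_lo[i] * pi / 180
    tl2 <- bounds_hi[i] * pi / 180
    x1 <- excent / sqrt(1 + excent^2 * tan(tl1)^2)
    x2 <- excent / sqrt(1 + excent^2 * tan(tl2)^2)
    if (excent == 1) {
      freq[i] <- abs(cos(tl1) - cos(tl2))
    } else {
      alph <- excent / sqrt(abs(1 - excent^2))
      alph2 <- alph^2
      x12 <- x1^2
      x22 <- x2^2
      if (excent > 1) {
        alpx1 <- sqrt(alph2 + x12)
        alpx2 <- sqrt(alph2 + x22)
        dum <- x1 * alpx1 + alph2 * log(x1 + alpx1)
        freq[i] <- abs(dum - (x2 * alpx2 + alph2 * log(x2 + alpx2)))
      } else {
        almx1 <- sqrt(alph2 - x12)
        almx2 <- sqrt(alph2 - x22)
        dum <- x1 * almx1 + alph2 * asin(x1 / alph)
        freq[i] <- abs(dum - (x2 * almx2 + alph2 * asin(x2 / alph)))
      }
    }
  }
  list(angle = (bounds_lo + bounds_hi) / 2, freq = freq / sum(freq))
}

# Geometric factors for one leaf inclination class: fractions of leaf area
# projected toward sun and observer, and the bidirectional scattering areas.
.volscatt <- function(tts, tto, psi, ttl) {
  rd <- pi / 180
  costs <- cos(rd * tts)
  costo <- cos(rd * tto)
  sints <- sin(rd * tts)
  sinto <- sin(rd * tto)
  cospsi <- cos(rd * psi)
  psir <- rd * psi
  costl <- cos(rd * ttl)
  sintl <- sin(rd * ttl)
  cs <- costl * costs
  co <- costl * costo
  ss <- sintl * sints
  so <- sintl * sinto

  cosbts <- 5
  if (abs(ss) > 1e-6) cosbts <- -cs / ss
  cosbto <- 5
  if (abs(so) > 1e-6) cosbto <- -co / so

  if (abs(cosbts) < 1) {
    bts <- acos(cosbts)
    ds <- ss
  } else {
    bts <- pi
    ds <- cs
  }
  chi_s <- 2 / pi * ((bts - pi * 0.5) * cs + sin(bts) * ss)

  if (abs(cosbto) < 1) {
    bto <- acos(cosbto)
    doo <- so
  } else if (tto < 90) {
    bto <- pi
    doo <- co
  } else {
    bto <- 0
    doo <- -co
  }
  chi_o <- 2 / pi * ((bto - pi * 0.5) * co + sin(bto) * so)

  btran1 <- abs(bts - bto)
  btran2 <- pi - abs(bts + bto - pi)
  if (psir <= btran1) {
    bt1 <- psir
    bt2 <- btran1
    bt3 <- btran2
  } else {
    bt1 <- btran1
    if (psir <= btran2) {
      bt2 <- psir
      bt3 <- btran2
    } else {
      bt2 <- btran2
      bt3 <- psir
    }
  }
  t1 <- 2 * cs * co + ss * so * cospsi
  t2 <- 0
  if (bt2 > 0) {
    t2 <- sin(bt2) * (2 * ds * doo + ss * so * cos(bt1) * cos(bt3))
  }
  denom <- 2 * pi^2
  frho <- max(((pi - bt2) * t1 + t2) / denom, 0)
  ftau <- max((-bt1 * t1 + t2) / denom, 0)
  list(chi_s = chi_s, chi_o = chi_o, frho = frho, ftau = ftau)
}

# J functions of the four-stream solution (stable near k == l).
.jfunc1 <- function(k, l, t) {
  del <- (k - l) * t
  out <- numeric(length(l))
  near <- abs(del) < 1e-3
  if (any(!near)) {
    out[!near] <- (exp(-l[!near] * t) - exp(-k * t)) / (k - l[!near])
  }
  if (any(near)) {
    out[near] <- 0.5 * t * (exp(-k * t) + exp(-l[near] * t)) *
      (1 - del[near]^2 / 12)
  }
  out
}

.jfunc2 <- function(k, l, t) {
  (1 - exp(-(k + l) * t)) / (k + l)
}

# Angular coefficients of the four-stream model: extinction toward sun (ks)
# and observer (ko), the mean squared leaf-cosine (bf) and the bidirectional
# scattering areas (sob, sof), integrated over the leaf inclination
# distribution. Depends only on (alia, geometry), not wavelength.
.sail_geom <- function(alia, tts, tto, psi) {
  rd <- pi / 180
  cts <- cos(rd * tts)
  cto <- cos(rd * tto)
  ctscto <- cts * cto
  tants <- tan(rd * tts)
  tanto <- tan(rd * tto)
  cospsi <- cos(rd * psi)
  dso <- sqrt(tants^2 + tanto^2 - 2 * tants * tanto * cospsi)

  lidf <- .campbell_lidf(alia)
  ks <- 0
  ko <- 0
  bf <- 0
  sob <- 0
  sof <- 0
  for (i in seq_along(lidf$angle)) {
    ttl <- lidf$angle[i]
    f <- lidf$freq[i]
    vs <- .volscatt(tts, tto, psi, ttl)
    ks <- ks + vs$chi_s / cts * f
    ko <- ko + vs$chi_o / cto * f
    sob <- sob + vs$frho * pi / ctscto * f
    sof <- sof + vs$ftau * pi / ctscto * f
    bf <- bf + cos(rd * ttl)^2 * f
  }
  list(ks = ks, ko = ko, bf = bf, sob = sob, sof = sof, dso = dso)
}

# Four-stream turbid-medium bidirectional reflectance on plain vectors.
# rho/tau: leaf reflectance/transmittance spectra; rsoil: soil spectrum.
# Returns the canopy bidirectional reflectance factor for direct solar
# illumination (single + multiple scattering + soil interaction terms).
# `geom` allows reuse of precomputed angular coefficients across calls that
# share (alia, tts, tto, psi).
.foursail_brf <- function(rho, tau, lai, alia, hotspot, tts, tto, psi, rsoil,
                          geom = NULL) {
  if (lai <= 0) {
    return(rsoil)
  }
  if (is.null(geom)) geom <- .sail_geom(alia, tts, tto, psi)
  ks <- geom$ks
  ko <- geom$ko
  bf <- geom$bf
  sob <- geom$sob
  sof <- geom$sof
  dso <- geom$dso

  sdb <- 0.5 * (ks + bf)
  sdf <- 0.5 * (ks - bf)
  dob <- 0.5 * (ko + bf)
  dof <- 0.5 * (ko - bf)
  ddb <- 0.5 * (1 + bf)
  ddf <- 0.5 * (1 - bf)

  sigb <- ddb * rho + ddf * tau
  sigf <- ddf * rho + ddb * tau
  att <- 1 - sigf
  m2 <- pmax((att + sigb) * (att - sigb), 0)
  m <- sqrt(m2)
  sb <- sdb * rho + sdf * tau
  sf <- sdf * rho + sdb * tau
  vb <- dob * rho + dof * tau
  vf <- dof * rho + dob * tau
  w <- sob * rho + sof * tau

  e1 <- exp(-m * lai)
  e2 <- e1^2
  sigb <- ifelse(sigb == 0, 1e-36, sigb)
  rinf <- (att - m) / sigb
  rinf2 <- rinf^2
  re <- rinf * e1
  denom <- 1 - rinf2 * e2

  j1ks <- .jfunc1(ks, m, lai)
  j2ks <- .jfunc2(ks, m, lai)
  j1ko <- .jfunc1(ko, m, lai)
  j2ko <- .jfunc2(ko, m, lai)

  ps <- (sf + sb * rinf) * j1ks
  qs <- (sf * rinf + sb) * j2ks
  pv <- (vf + vb * rinf) * j1ko
  qv <- (vf * rinf + vb) * j2ko

  rdd <- rinf * (1 - e2) / denom
  tdd <- (1 - rinf2) * e1 / denom
  tsd <- (ps - re * qs) / denom
  rsd <- (qs - re * ps) / denom
  tdo <- (pv - re * qv) / denom
  rdo <- (qv - re * pv) / denom

  tss <- exp(-ks * lai)
  too <- exp(-ko * lai)
  z <- .jfunc2(ks, ko, lai)
  g1 <- (z - j1ks * too) / (ko + m)
  g2 <- (z - j1ko * tss) / (ks + m)
  tv1 <- (vf * rinf + vb) * g1
  tv2 <- (vf + vb * rinf) * g2
  t1 <- tv1 * (sf + sb * rinf)
  t2 <- tv2 * (sf * rinf + sb)
  t3 <- (rdo * qs + tdo * ps) * rinf
  rsod <- (t1 + t2 - t3) / (1 - rinf2)

  # hot spot: bidirectional gap fraction along the sun-observer path
  alf <- 1e36
  if (hotspot > 0) alf <- (dso / hotspot) * 2 / (ks + ko)
  if (alf == 0) {
    # observer exactly in the sun direction
    tsstoo <- tss
    sumint <- (1 - tss) / (ks * lai)
  } else {
    fhot <- lai * sqrt(ko * ks)
    x1 <- 0
    y1 <- 0
    f1 <- 1
    fint <- (1 - exp(-alf)) * 0.05
    sumint <- 0
    for (i in 1:20) {
      x2 <- if (i < 20) -log(1 - i * fint) / alf else 1
      y2 <- -(ko + ks) * lai * x2 + fhot * (1 - exp(-alf * x2)) / alf
      f2 <- exp(y2)
      sumint <- sumint + (f2 - f1) * (x2 - x1) / (y2 - y1)
      x1 <- x2
      y1 <- y2
      f1 <- f2
    }
    tsstoo <- f1
    if (is.nan(sumint)) sumint <- 0
  }
  rsos <- w * lai * sumint
  rso <- rsos + rsod

  dn <- 1 - rsoil * rdd
  rsodt <- ((tss + tsd) * tdo + (tsd + tss * rsoil * rdd) * too) * rsoil / dn
  rsost <- rso + tsstoo * rsoil
  rsost + rsodt
}

#' Canopy bidirectional reflectance from leaf optical properties
#'
#' Four-stream turbid-medium canopy reflectance model with an ellipsoidal
#' leaf inclination distribution (parameterised by the average leaf
#' inclination angle) and a hot spot correction for the bidirectional gap
#' fraction. Given the leaf reflectance/transmittance spectra and the canopy
#' state, it returns the top-of-canopy bidirectional reflectance factor
#' under direct solar illumination.
#'
#' With `LAI = 0` the canopy is absent and the soil spectrum is returned
#' unchanged.
#'
#' @param leaf_rt Leaf spectra as returned by [prospect5()] (tibble with
#'   `wavelength`, `reflectance`, `transmittance`).
#' @param canopy Canopy parameters from [canopy_params()].
#' @return A tibble with columns `wavelength` and `value` (BRF, in `[0, 1]`).
#' @export
#' @examples
#' brf <- foursail(prospect5(leaf_params()), canopy_params(LAI = 3))
foursail <- function(leaf_rt, canopy = canopy_params()) {
  validate_canopy_params(canopy)
  stopifnot(all(c("wavelength", "reflectance", "transmittance") %in% names(leaf_rt)))
  rsoil <- .spectrum_values(canopy$soil)
  v <- .foursail_brf(
    leaf_rt$reflectance, leaf_rt$transmittance,
    canopy$LAI, canopy$ALIA, canopy$hot,
    canopy$SZA, canopy$OZA, canopy$rAA, rsoil
  )
  tibble::tibble(wavelength = spectral_grid(), value = v)
}

#' Coupled leaf-canopy forward simulation
#'
#' Runs the plate leaf model and feeds its reflectance/transmittance into
#' the four-stream canopy model: `prosail(leaf, canopy)` is exactly
#' `foursail(prospect5(leaf), canopy)`.
#'
#' @inheritParams prospect5
#' @inheritParams foursail
#' @return A tibble with columns `wavelength` and `value`.
#' @export
#' @examples
#' prosail(leaf_params(Cab = 50), canopy_params(LAI = 4, SZA = 28))
prosail <- function(leaf = leaf_params(), canopy = canopy_params()) {
  foursail(prospect5(leaf), canopy)
}
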