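#' Leaf parameter set for the plate model
#'
#' Collects the six state variables of the leaf optical model: the leaf
#' structure index `N` (number of compact layers, dimensionless), chlorophyll
#' a+b content `Cab` (ug/cm^2), carotenoid content `Ccx` (ug/cm^2), brown
#' pigment content `Cbp` (dimensionless), equivalent water thickness `Cw`
#' (g/cm^2, numerically cm) and dry matter content `Cm` (g/cm^2).
#'
#' Defaults follow the retrieval configuration: `Ccx = 8` and `Cw = 0.015`
#' are the fixed constants used when only chlorophyll, structure and dry
#' matter vary.
#'
#' @param N,Cab,Ccx,Cbp,Cw,Cm Numeric scalars, see Description.
#' @return A one-row tibble with the six fields.
#' @export
#' @examples
#' leaf_params(Cab = 55)
leaf_params <- function(N = 1.5, Cab = 40, Ccx = 8, Cbp = 0,
                        Cw = 0.015, Cm = 0.009) {
  leaf <- tibble::tibble(N = N, Cab = Cab, Ccx = Ccx, Cbp = Cbp, Cw = Cw, Cm = Cm)
  validate_leaf_params(leaf)
  leaf
}

#' @rdname leaf_params
#' @param leaf A one-row tibble (or named list) of leaf parameters.
#' @export
validate_leaf_params <- function(leaf) {
  for (f in c("N", "Cab", "Ccx", "Cbp", "Cw", "Cm")) {
    v <- leaf[[f]]
    if (is.null(v) || !is.finite(v)) {
      rlang::abort(sprintf("leaf parameter `%s` is missing or non-finite", f))
    }
  }
  if (leaf$N < 1) rlang::abort("leaf parameter `N` must be >= 1")
  for (f in c("Cab", "Ccx", "Cbp", "Cw", "Cm")) {
    if (leaf[[f]] < 0) {
      rlang::abort(sprintf("leaf parameter `%s` must be non-negative", f))
    }
  }
  invisible(leaf)
}

# Average transmissivity of a dielectric plane surface for radiation incident
# within a cone of half-angle `theta` (degrees), refractive index `ref`
# (vectorised). Closed form after Stern's integration of the Fresnel
# equations.
.tav <- function(theta, ref) {
  if (theta == 0) {
    return(4 * ref / (ref + 1)^2)
  }
  s2 <- sin(theta * pi / 180)^2
  refr2 <- ref^2
  ax <- (ref + 1)^2 / 2
  bx <- -(refr2 - 1)^2 / 4
  b1 <- if (theta == 90) 0 else sqrt((s2 - (refr2 + 1) / 2)^2 + bx)
  b2 <- s2 - (refr2 + 1) / 2
  b0 <- b1 - b2
  ts <- (bx^2 / (6 * b0^3) + bx / b0 - b0 / 2) -
    (bx^2 / (6 * ax^3) + bx / ax - ax / 2)
  tp1 <- -2 * refr2 * (b0 - ax) / (refr2 + 1)^2
  tp2 <- -2 * refr2 * (refr2 + 1) * log(b0 / ax) / (refr2 - 1)^2
  tp3 <- refr2 * (1 / b0 - 1 / ax) / 2
  q1 <- 2 * (refr2 + 1) * b0 - (refr2 - 1)^2
  q2 <- 2 * (refr2 + 1) * ax - (refr2 - 1)^2
  tp4 <- 16 * refr2^2 * (refr2^2 + 1) * log(q1 / q2) /
    ((refr2 + 1)^3 * (refr2 - 1)^2)
  tp5 <- 16 * refr2^3 * (1 / q1 - 1 / q2) / (refr2 + 1)^3
  tp <- tp1 + tp2 + tp3 + tp4 + tp5
  (ts + tp) / (2 * s2)
}

# Core plate-model computation on plain numeric vectors. Returns
# list(reflectance, transmittance) on the standard grid.
.prospect5_rt <- function(N, Cab, Ccx, Cbp, Cw, Cm,
                          const = leaf_optical_constants()) {
  # absorption per elementary layer
  k <- (Cab * const$kab + Ccx * const$kcar + Cbp * const$kbrown +
    Cw * const$kw + Cm * const$km) / N
  tau <- rep(1, length(k))
  pos <- k > 0
  kp <- k[pos]
  tau[pos] <- (1 - kp) * exp(-kp) + kp^2 * pracma::expint_E1(kp)
  tau <- pmin(pmax(tau, 0), 1)

  nr <- const$nr
  talf <- .tav(40, nr)
  ralf <- 1 - talf
  t12 <- .tav(90, nr)
  r12 <- 1 - t12
  t21 <- t12 / nr^2
  r21 <- 1 - t21

  # top layer, incident cone 40 degrees outside / isotropic inside
  denom <- 1 - r21^2 * tau^2
  Ta <- talf * tau * t21 / denom
  Ra <- ralf + r21 * Ta * tau
  t <- t12 * tau * t21 / denom
  r <- r12 + r21 * t * tau

  # stack of N - 1 further layers (Stokes doubling in closed form)
  D <- sqrt(pmax((1 + r + t) * (1 + r - t) * (1 - r + t) * (1 - r - t), 0))
  rq <- r^2
  tq <- t^2
  a <- (1 + rq - tq + D) / (2 * r)
  b <- (1 - rq + tq + D) / (2 * t)
  bNm1 <- b^(N - 1)
  bN2 <- bNm1^2
  a2 <- a^2
  denom2 <- a2 * bN2 - 1
  Rsub <- a * (bN2 - 1) / denom2
  Tsub <- bNm1 * (a2 - 1) / denom2
  # conservative-scattering limit where r + t -> 1
  deg <- (r + t) >= 1
  if (any(deg)) {
    Tsub[deg] <- t[deg] / (t[deg] + (1 - t[deg]) * (N - 1))
    Rsub[deg] <- 1 - Tsub[deg]
  }
  denom3 <- 1 - Rsub * r
  list(
    reflectance = Ra + Ta * Rsub * t / denom3,
    transmittance = Ta * Tsub / denom3
  )
}

#' Simulate leaf reflectance and transmittance (plate model)
#'
#' Generalised plate model of the leaf: a stack of `N` compact layers with
#' rough surfaces, each absorbing according to the summed specific
#' absorption of its constituents (chlorophyll a+b, carotenoids, brown
#' pigment, water, dry matter) and refracting with the leaf refractive
#' index. The transmissivity of one elementary layer uses the exponential
#' integral of the absorption coefficient; the stack is solved in closed
#' form.
#'
#' Spectral constants are the package's synthetic set, see
#' [leaf_optical_constants()].
#'
#' @param leaf Leaf parameters from [leaf_params()].
#' @return A tibble with columns `wavelength`, `reflectance`,
#'   `transmittance` on the 400--2500 nm grid.
#' @export
#' @examples
#' spec <- prospect5(leaf_params(Cab = 40))
#' head(spec)
prospect5 <- function(leaf = leaf_params()) {
  validate_leaf_params(leaf)
  rt <- .prospect5_rt(leaf$N, leaf$Cab, leaf$Ccx, leaf$Cbp, leaf$Cw, leaf$Cm)
  tibble::tibble(
    wavelength = spectral_grid(),
    reflectance = rt$reflectance,
    transmittance = rt$transmittance
  )
}
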