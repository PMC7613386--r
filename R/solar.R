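#' Solar zenith angle at a place and time
#'
#' Computes the solar zenith angle with the NOAA solar calculator equations
#' (a truncated form of Meeus' astronomical algorithms): Julian century,
#' solar declination from the apparent solar longitude and corrected
#' obliquity, the equation of time, then the hour angle at the requested
#' instant. Accuracy is a few hundredths of a degree over the current era,
#' ample for flight-planning geometry.
#'
#' @param lat,lon Latitude and longitude in decimal degrees (north/east
#'   positive).
#' @param time A `POSIXct` (any time zone; converted internally to UTC) or a
#'   string parseable as UTC.
#' @param refraction If `TRUE` (default) return the apparent zenith angle,
#'   corrected for standard atmospheric refraction; otherwise the geometric
#'   angle.
#' @return Solar zenith angle in degrees (vectorised over `time`).
#' @export
#' @examples
#' # 13:00 CEST is 11:00 UTC
#' solar_zenith(50.6167, 6.9833, as.POSIXct("2021-06-23 11:00:00", tz = "UTC"))
solar_zenith <- function(lat, lon, time, refraction = TRUE) {
  stopifnot(is.finite(lat), abs(lat) <= 90, is.finite(lon), abs(lon) <= 360)
  if (is.character(time)) time <- as.POSIXct(time, tz = "UTC")
  stopifnot(inherits(time, "POSIXct"))
  rad <- function(x) x * pi / 180
  deg <- function(x) x * 180 / pi

  secs <- as.numeric(time) # seconds since 1970-01-01 UTC
  jd <- secs / 86400 + 2440587.5
  jc <- (jd - 2451545) / 36525

  gml <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  gma <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  eqc <- sin(rad(gma)) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(rad(2 * gma)) * (0.019993 - 0.000101 * jc) +
    sin(rad(3 * gma)) * 0.000289
  stl <- gml + eqc
  sal <- stl - 0.00569 - 0.00478 * sin(rad(125.04 - 1934.136 * jc))
  moe <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  oc <- moe + 0.00256 * cos(rad(125.04 - 1934.136 * jc))
  decl <- asin(sin(rad(oc)) * sin(rad(sal)))

  vy <- tan(rad(oc / 2))^2
  eot <- 4 * deg(
    vy * sin(2 * rad(gml)) - 2 * ecc * sin(rad(gma)) +
      4 * ecc * vy * sin(rad(gma)) * cos(2 * rad(gml)) -
      0.5 * vy^2 * sin(4 * rad(gml)) - 1.25 * ecc^2 * sin(2 * rad(gma))
  )

  mins_utc <- (secs %% 86400) / 60
  tst <- (mins_utc + eot + 4 * lon) %% 1440
  ha <- ifelse(tst / 4 < 0, tst / 4 + 180, tst / 4 - 180)
  cosz <- sin(rad(lat)) * sin(decl) + cos(rad(lat)) * cos(decl) * cos(rad(ha))
  z <- deg(acos(pmin(pmax(cosz, -1), 1)))

  if (refraction) {
    elev <- 90 - z
    corr <- vapply(elev, function(e) {
      if (e > 85) {
        0
      } else if (e > 5) {
        te <- tan(rad(e))
        (58.1 / te - 0.07 / te^3 + 0.000086 / te^5) / 3600
      } else if (e > -0.575) {
        (1735 + e * (-518.2 + e * (103.4 + e * (-12.79 + e * 0.711)))) / 3600
      } else {
        (-20.772 / tan(rad(e))) / 3600
      }
    }, numeric(1))
    z <- z - corr
  }
  z
}
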