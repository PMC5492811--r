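## Solar position (NOAA/Meeus formulation) and sensor footprint geometry.

#' Solar zenith and azimuth angles
#'
#' Computes the apparent solar position for a site and instant using the
#' NOAA formulation of Meeus' low-precision solar ephemeris (geometric
#' position plus standard atmospheric refraction), accurate to well under
#' 0.1 degree for the years 1900--2100. Azimuth is measured clockwise from
#' geographic north.
#'
#' @param lat,lon site latitude and longitude in decimal degrees (north and
#'   east positive).
#' @param time a `POSIXct` instant, or a string parseable by
#'   [as.POSIXct()]; `tz` gives its zone when the string carries none.
#' @param tz time zone used to interpret a character `time`, e.g.
#'   `"Etc/GMT-2"` for UTC+2. Ignored for `POSIXct` input.
#' @return Named numeric vector with `sza` (solar zenith angle, degrees) and
#'   `saa` (solar azimuth, degrees clockwise from north).
#' @examples
#' solarPosition(51.9917, 5.66332, "2015-06-05 13:24", tz = "Etc/GMT-2")
#' @export
solarPosition <- function(lat, lon, time, tz = "UTC") {
  lat <- unname(lat); lon <- unname(lon)
  if (!inherits(time, "POSIXct")) {
    time <- as.POSIXct(time, tz = tz)
  }
  if (is.na(time)) stop("invalid timestamp")
  tUtc <- time
  attr(tUtc, "tzone") <- "UTC"
  jd <- as.numeric(tUtc) / 86400 + 2440587.5
  jc <- (jd - 2451545) / 36525
  d2r <- pi / 180

  gmls <- (280.46646 + jc * (36000.76983 + jc * 0.0003032)) %% 360
  gmas <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  eeo <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  seqc <- sin(gmas * d2r) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * gmas * d2r) * (0.019993 - 0.000101 * jc) +
    sin(3 * gmas * d2r) * 0.000289
  stl <- gmls + seqc
  omega <- (125.04 - 1934.136 * jc) * d2r
  sal <- stl - 0.00569 - 0.00478 * sin(omega)
  moe <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  oc <- moe + 0.00256 * cos(omega)
  decl <- asin(sin(oc * d2r) * sin(sal * d2r))
  vary <- tan(oc / 2 * d2r)^2
  eqtime <- 4 / d2r * (vary * sin(2 * gmls * d2r) - 2 * eeo * sin(gmas * d2r) +
    4 * eeo * vary * sin(gmas * d2r) * cos(2 * gmls * d2r) -
    0.5 * vary^2 * sin(4 * gmls * d2r) - 1.25 * eeo^2 * sin(2 * gmas * d2r))

  mins <- (jd - 0.5 - floor(jd - 0.5)) * 1440
  tst <- (mins + eqtime + 4 * lon) %% 1440
  ha <- tst / 4 - 180
  if (ha < -180) ha <- ha + 360
  phi <- lat * d2r
  csz <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(ha * d2r)
  szaGeom <- acos(min(1, max(-1, csz))) / d2r
  saa <- ((atan2(sin(ha * d2r),
                 cos(ha * d2r) * sin(phi) - tan(decl) * cos(phi)) / d2r) + 180) %% 360

  el <- 90 - szaGeom
  te <- tan(el * d2r)
  refr <- if (el > 85) 0
    else if (el > 5) (58.1 / te - 0.07 / te^3 + 0.000086 / te^5) / 3600
    else if (el > -0.575)
      (1735 + el * (-518.2 + el * (103.4 + el * (-12.79 + el * 0.711)))) / 3600
    else (-20.772 / te) / 3600
  c(sza = 90 - (el + refr), saa = saa)
}

#' Nadir footprint of a conical field-of-view sensor
#'
#' Diameter and area of the circular ground footprint of a sensor with a
#' conical field of view held at a given height above the canopy:
#' `diameter = 2 * height * tan(fov/2)`.
#'
#' @param fovDeg full field-of-view angle in degrees, in (0, 180).
#' @param heightM sensor height above the target (m), positive.
#' @return Named numeric vector with `diameter` (m) and `area` (m2).
#' @examples
#' sensorFootprint(28, 1)  # handheld radiometer: ~0.5 m diameter, ~0.20 m2
#' @export
sensorFootprint <- function(fovDeg, heightM) {
  if (fovDeg <= 0 || fovDeg >= 180) stop("fovDeg must lie in (0, 180)")
  if (heightM <= 0) stop("heightM must be positive")
  d <- 2 * heightM * tan(fovDeg / 2 * pi / 180)
  c(diameter = d, area = pi * (d / 2)^2)
}
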