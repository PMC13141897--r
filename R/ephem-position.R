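# Time scale helpers ---------------------------------------------------------

# Epoch range supported by the truncated lunar theory used here.
.INSTANT_MIN <- as.POSIXct("1900-01-01 00:00:00", tz = "UTC")
.INSTANT_MAX <- as.POSIXct("2100-01-01 00:00:00", tz = "UTC")

#' Convert a UTC instant to a Julian Date (UTC scale)
#' @noRd
jd_utc <- function(time) {
  as.numeric(time) / 86400 + 2440587.5
}

#' Convert a Julian Date on the UTC scale back to POSIXct
#' @noRd
jd_to_posixct <- function(jd) {
  as.POSIXct((jd - 2440587.5) * 86400, tz = "UTC", origin = "1970-01-01")
}

# Delta-T (TT - UT) in seconds, linear interpolation over decadal almanac
# values; flat extrapolation outside. Sub-minute accuracy is ample at the
# package's whole-hour event resolution.
.DELTA_T_YEARS <- seq(1900, 2030, by = 10)
.DELTA_T_SECS <- c(-2.7, 10.4, 21.2, 24.0, 24.3, 29.1, 33.2, 40.2, 50.5,
                   56.9, 63.8, 66.1, 69.4, 72.0)

#' @noRd
delta_t_seconds <- function(jd) {
  yr <- 2000 + (jd - 2451545) / 365.25
  approx(.DELTA_T_YEARS, .DELTA_T_SECS, xout = yr, rule = 2)$y
}

# Julian centuries of Terrestrial Time since J2000.0, from a UTC instant.
#' @noRd
centuries_tt <- function(time) {
  jd <- jd_utc(time)
  (jd + delta_t_seconds(jd) / 86400 - 2451545) / 36525
}

#' @noRd
deg2rad <- function(x) x * pi / 180

#' @noRd
wrap360 <- function(x) x %% 360

# Lunar position -------------------------------------------------------------

# Truncated ELP-grade periodic series (Chapront lunar theory as abridged in
# standard astronomical-algorithm references). Columns: multiples of the
# fundamental arguments D (mean elongation), M (solar anomaly), Mp (lunar
# anomaly), F (argument of latitude); then the coefficient.
# Longitude coefficients in 1e-6 degrees; distance in 1e-3 km.
.MOON_LR <- matrix(c(
  0, 0, 1, 0,  6288774, -20905355,
  2, 0,-1, 0,  1274027,  -3699111,
  2, 0, 0, 0,   658314,  -2955968,
  0, 0, 2, 0,   213618,   -569925,
  0, 1, 0, 0,  -185116,     48888,
  0, 0, 0, 2,  -114332,     -3149,
  2, 0,-2, 0,    58793,    246158,
  2,-1,-1, 0,    57066,   -152138,
  2, 0, 1, 0,    53322,   -170733,
  2,-1, 0, 0,    45758,   -204586,
  0, 1,-1, 0,   -40923,   -129620,
  1, 0, 0, 0,   -34720,    108743,
  0, 1, 1, 0,   -30383,    104755,
  2, 0, 0,-2,    15327,     10321,
  0, 0, 1, 2,   -12528,         0,
  0, 0, 1,-2,    10980,     79661,
  4, 0,-1, 0,    10675,    -34782,
  0, 0, 3, 0,    10034,    -23210,
  4, 0,-2, 0,     8548,    -21636,
  2, 1,-1, 0,    -7888,     24208,
  2, 1, 0, 0,    -6766,     30824,
  1, 0,-1, 0,    -5163,     -8379,
  1, 1, 0, 0,     4987,    -16675,
  2,-1, 1, 0,     4036,    -12831,
  2, 0, 2, 0,     3994,    -10445,
  4, 0, 0, 0,     3861,    -11650,
  2, 0,-3, 0,     3665,     14403,
  0, 1,-2, 0,    -2689,     -7003,
  2, 0,-1, 2,    -2602,         0,
  2,-1,-2, 0,     2390,     10056,
  1, 0, 1, 0,    -2348,      6322,
  2,-2, 0, 0,     2236,     -9884,
  0, 1, 2, 0,    -2120,      5751,
  0, 2, 0, 0,    -2069,         0,
  2,-2,-1, 0,     2048,     -4950,
  2, 0, 1,-2,    -1773,      4130,
  2, 0, 0, 2,    -1595,         0,
  4,-1,-1, 0,     1215,     -3958,
  0, 0, 2, 2,    -1110,         0,
  3, 0,-1, 0,     -892,      3258,
  2, 1, 1, 0,     -810,      2616,
  4,-1,-2, 0,      759,     -1897,
  0, 2,-1, 0,     -713,     -2117,
  2, 2,-1, 0,     -700,      2354
), ncol = 6, byrow = TRUE)

# Latitude coefficients in 1e-6 degrees.
.MOON_B <- matrix(c(
  0, 0, 0, 1,  5128122,
  0, 0, 1, 1,   280602,
  0, 0, 1,-1,   277693,
  2, 0, 0,-1,   173237,
  2, 0,-1, 1,    55413,
  2, 0,-1,-1,    46271,
  2, 0, 0, 1,    32573,
  0, 0, 2, 1,    17198,
  2, 0, 1,-1,     9266,
  0, 0, 2,-1,     8822,
  2,-1, 0,-1,     8216,
  2, 0,-2,-1,     4324,
  2, 0, 1, 1,     4200,
  2, 1, 0,-1,    -3359,
  2,-1,-1, 1,     2463,
  2,-1, 0, 1,     2211,
  2,-1,-1,-1,     2065,
  0, 1,-1,-1,    -1870,
  4, 0,-1,-1,     1828,
  0, 1, 0, 1,    -1794,
  0, 0, 0, 3,    -1749,
  0, 1,-1, 1,    -1565,
  1, 0, 0, 1,    -1491,
  0, 1, 1, 1,    -1475,
  0, 1, 1,-1,    -1410,
  0, 1, 0,-1,    -1344,
  1, 0, 0,-1,    -1335,
  0, 0, 3, 1,     1107,
  4, 0, 0,-1,     1021,
  4, 0,-1, 1,      833
), ncol = 5, byrow = TRUE)

#' Geocentric lunar position
#'
#' Ecliptic longitude/latitude (degrees), distance (km) and equatorial
#' declination (degrees) of the Moon's centre, from a truncated periodic
#' series of the modern lunar theory. Accuracy is a few hundredths of a
#' degree in longitude/latitude and a few tens of km in distance across
#' 1900--2100, ample for whole-hour event timing.
#'
#' @param time POSIXct vector (UTC).
#' @return A tibble with columns `time`, `longitude`, `latitude`,
#'   `distance_km`, `declination`.
#' @examples
#' moon_position(as.POSIXct("2000-01-01 00:00", tz = "UTC"))
#' @export
moon_position <- function(time) {
  stopifnot(inherits(time, "POSIXct"))
  t <- centuries_tt(time)

  Lp <- wrap360(218.3164477 + 481267.88123421 * t - 0.0015786 * t^2 +
                  t^3 / 538841 - t^4 / 65194000)
  D  <- wrap360(297.8501921 + 445267.1114034 * t - 0.0018819 * t^2 +
                  t^3 / 545868 - t^4 / 113065000)
  M  <- wrap360(357.5291092 + 35999.0502909 * t - 0.0001536 * t^2 +
                  t^3 / 24490000)
  Mp <- wrap360(134.9633964 + 477198.8675055 * t + 0.0087414 * t^2 +
                  t^3 / 69699 - t^4 / 14712000)
  F  <- wrap360(93.2720950 + 483202.0175233 * t - 0.0036539 * t^2 -
                  t^3 / 3526000 + t^4 / 863310000)
  A1 <- wrap360(119.75 + 131.849 * t)
  A2 <- wrap360(53.09 + 479264.290 * t)
  A3 <- wrap360(313.45 + 481266.484 * t)
  E  <- 1 - 0.002516 * t - 0.0000074 * t^2

  sl <- numeric(length(t)); sr <- numeric(length(t))
  for (i in seq_len(nrow(.MOON_LR))) {
    row <- .MOON_LR[i, ]
    arg <- deg2rad(row[1] * D + row[2] * M + row[3] * Mp + row[4] * F)
    ecc <- E^abs(row[2])  # eccentricity damping for terms in the solar anomaly
    sl <- sl + row[5] * ecc * sin(arg)
    sr <- sr + row[6] * ecc * cos(arg)
  }
  sl <- sl + 3958 * sin(deg2rad(A1)) + 1962 * sin(deg2rad(Lp - F)) +
    318 * sin(deg2rad(A2))

  sb <- numeric(length(t))
  for (i in seq_len(nrow(.MOON_B))) {
    row <- .MOON_B[i, ]
    arg <- deg2rad(row[1] * D + row[2] * M + row[3] * Mp + row[4] * F)
    ecc <- E^abs(row[2])
    sb <- sb + row[5] * ecc * sin(arg)
  }
  sb <- sb - 2235 * sin(deg2rad(Lp)) + 382 * sin(deg2rad(A3)) +
    175 * sin(deg2rad(A1 - F)) + 175 * sin(deg2rad(A1 + F)) +
    127 * sin(deg2rad(Lp - Mp)) - 115 * sin(deg2rad(Lp + Mp))

  lambda <- wrap360(Lp + sl / 1e6)
  beta <- sb / 1e6
  dist <- 385000.56 + sr / 1000

  eps <- deg2rad(23.43929111 - 0.01300417 * t)
  lam <- deg2rad(lambda); bet <- deg2rad(beta)
  dec <- asin(sin(bet) * cos(eps) + cos(bet) * sin(eps) * sin(lam)) * 180 / pi

  tibble::tibble(time = time, longitude = lambda, latitude = beta,
                 distance_km = dist, declination = dec)
}

#' Geocentric lunar declination
#'
#' @param time POSIXct vector (UTC), within 1900--2100.
#' @return Numeric vector of declinations in degrees; always within
#'   about +/-29 degrees.
#' @examples
#' lunar_declination(as.POSIXct("2006-09-15 12:00", tz = "UTC"))
#' @export
lunar_declination <- function(time) {
  check_instant_range(time)
  moon_position(time)$declination
}

# Apparent geometric solar longitude (degrees), low-precision theory
# (~0.01 degree), used only to form the Moon-Sun elongation.
#' @noRd
sun_longitude <- function(time) {
  t <- centuries_tt(time)
  L0 <- wrap360(280.46646 + 36000.76983 * t + 0.0003032 * t^2)
  M <- deg2rad(wrap360(357.52911 + 35999.05029 * t - 0.0001537 * t^2))
  C <- (1.914602 - 0.004817 * t - 0.000014 * t^2) * sin(M) +
    (0.019993 - 0.000101 * t) * sin(2 * M) + 0.000289 * sin(3 * M)
  wrap360(L0 + C)
}

#' @noRd
check_instant_range <- function(time) {
  if (any(time < .INSTANT_MIN | time >= .INSTANT_MAX)) {
    stop("instants must lie within [1900-01-01, 2100-01-01) UTC",
         call. = FALSE)
  }
  invisible(time)
}
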