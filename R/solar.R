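# Solar geometry: NOAA solar-calculator equations (Meeus-class accuracy,
# well under 1 minute for years 1900-2100 at |lat| <= 72).
# All instants are POSIXct on the absolute (UTC) timeline.

.d2r <- pi / 180
.r2d <- 180 / pi

#' @keywords internal
julian_day <- function(t) as.numeric(t) / 86400 + 2440587.5

# Declination (degrees) and equation of time (minutes) at julian day jd.
# Vectorized over jd.
sun_params <- function(jd) {
  jc <- (jd - 2451545) / 36525
  L0 <- (280.46646 + jc * (36000.76983 + jc * 0.0003032)) %% 360
  M  <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  e  <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  Mr <- M * .d2r
  C  <- sin(Mr) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
        sin(2 * Mr) * (0.019993 - 0.000101 * jc) +
        sin(3 * Mr) * 0.000289
  true_long <- L0 + C
  omega <- (125.04 - 1934.136 * jc) * .d2r
  app_long <- true_long - 0.00569 - 0.00478 * sin(omega)
  eps0 <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  eps <- eps0 + 0.00256 * cos(omega)
  decl <- asin(sin(eps * .d2r) * sin(app_long * .d2r)) * .r2d
  y <- tan(eps * .d2r / 2)^2
  L0r <- L0 * .d2r
  eqtime <- 4 * .r2d * (y * sin(2 * L0r) - 2 * e * sin(Mr) +
                        4 * e * y * sin(Mr) * cos(2 * L0r) -
                        0.5 * y^2 * sin(4 * L0r) - 1.25 * e^2 * sin(2 * Mr))
  list(decl = decl, eqtime = eqtime)
}

# Solar noon (UTC POSIXct) on calendar date `date` at longitude lon (deg east).
# Vectorized over date. Two fixed-point refinements of the equation of time.
solar_noon <- function(date, lon) {
  midnight <- as.POSIXct(paste(format(date), "00:00:00"), tz = "UTC")
  t <- midnight + (720 - 4 * lon) * 60
  for (i in 1:2) {
    sp <- sun_params(julian_day(t))
    t <- midnight + (720 - 4 * lon - sp$eqtime) * 60
  }
  t
}

# Hour angle (degrees, >= 0) at which the sun's centre sits at altitude
# alt_deg; NA where the sun never reaches that altitude on the given day.
hour_angle <- function(lat, decl, alt_deg) {
  cosH <- (sin(alt_deg * .d2r) - sin(lat * .d2r) * sin(decl * .d2r)) /
          (cos(lat * .d2r) * cos(decl * .d2r))
  H <- rep(NA_real_, length(cosH))
  ok <- is.finite(cosH) & abs(cosH) <= 1
  H[ok] <- acos(cosH[ok]) * .r2d
  H
}

# Instant the sun's centre crosses altitude alt_deg on the morning
# (side = -1) or evening (side = +1) flank of the given solar noon.
# Vectorized; NA where the crossing does not exist.
sun_crossing <- function(noon, lat, alt_deg, side) {
  t <- noon
  for (i in 1:2) {
    sp <- sun_params(julian_day(t))
    H <- hour_angle(lat, sp$decl, alt_deg)
    t <- noon + side * H * 4 * 60
  }
  t
}

# Per-day solar event table for the solar cycle opening at noon of `dates`:
# noon, next noon, nadir (midpoint of noons), evening -0.3/-18 crossings,
# next morning's -18/-0.3 crossings. Vectorized over dates.
solar_day_events <- function(dates, lat, lon) {
  dates <- as.Date(dates)
  noon <- solar_noon(dates, lon)
  noon_next <- solar_noon(dates + 1L, lon)
  data.frame(
    date = dates,
    noon = noon,
    noon_next = noon_next,
    nadir = noon + as.numeric(noon_next - noon, units = "secs") / 2,
    sunset_start = sun_crossing(noon, lat, -0.3, +1),
    dusk_end = sun_crossing(noon, lat, -18, +1),
    dawn_start = sun_crossing(noon_next, lat, -18, -1),
    dawn_end = sun_crossing(noon_next, lat, -0.3, -1)
  )
}
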