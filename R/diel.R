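#' Diel time categories
#'
#' Canonical ordering of the five diel categories used throughout the
#' package. `day` is first and serves as the reference category of the
#' selection model.
#'
#' @return Character vector of length 5.
#' @export
diel_categories <- function() c("day", "dawn", "dusk", "night", "deep_night")

#' Compute the diel-category schedule for one solar cycle
#'
#' Builds the five-category partition of the diel cycle running from the
#' solar noon of `date` to the next solar noon at a given location:
#' \describe{
#'   \item{dawn}{from the start of morning astronomical twilight (sun centre
#'     at -18 deg) until the bottom edge of the sun touches the horizon
#'     (centre at -0.3 deg);}
#'   \item{day}{from the end of dawn to the start of dusk;}
#'   \item{dusk}{from the moment the bottom edge of the sun touches the
#'     horizon in the evening until the end of evening astronomical twilight
#'     (-18 deg);}
#'   \item{deep night}{one hour either side of the solar nadir (the sun's
#'     lowest point), always exactly 2 h;}
#'   \item{night}{the remaining dark intervals between dusk and the
#'     deep-night window, and between the deep-night window and dawn.}
#' }
#' Working on a noon-to-noon cycle keeps the deep-night window contiguous.
#' All boundaries are half-open `[start, end)`: an instant exactly on a
#' boundary belongs to the later category. At latitudes where the evening
#' -18 deg crossing falls inside the deep-night window the dusk (or dawn)
#' interval is clipped at the window edge so the categories still partition
#' the cycle; deep night takes precedence.
#'
#' @param date calendar date (`Date` or coercible) whose solar noon opens
#'   the cycle.
#' @param lat,lon latitude and longitude in decimal degrees
#'   (lat in \[-90, 90\], lon in \[-180, 180\]).
#' @return An object of class `diel_schedule`: a list with `cycle_start`,
#'   `cycle_end`, `nadir` (POSIXct, UTC), `boundaries` (data frame with
#'   `category`, `start`, `end`), `alpha` (named vector of availability
#'   hours per category, summing to the cycle length), and the inputs.
#' @section Errors: at date/latitude combinations where the sun never
#'   reaches -18 deg (no astronomical twilight) or never crosses the
#'   horizon, categorization is undefined and a classed error
#'   (`dieltrsf_no_twilight`) naming the missing solar event is raised.
#' @seealso [schedule_for_instant()], [diel_category()]
#' @examples
#' sch <- diel_schedule("2017-06-01", lat = 41.8, lon = -87.6)
#' sch$alpha
#' @export
diel_schedule <- function(date, lat, lon) {
  check_geo(lat, lon)
  date <- as.Date(date)
  if (is.na(date)) stop("`date` is not a valid calendar date")
  yr <- as.integer(format(date, "%Y"))
  if (yr < 1900 || yr > 2100) stop("`date` must fall within years 1900-2100")
  ev <- solar_day_events(date, lat, lon)
  build_schedule(ev, lat, lon)
}

# Assemble a diel_schedule from one row of solar_day_events().
build_schedule <- function(ev, lat, lon) {
  miss <- function(what) {
    stop(structure(
      class = c("dieltrsf_no_twilight", "error", "condition"),
      list(message = sprintf(
        "diel categorization undefined on %s at latitude %.3f: the %s does not occur",
        format(ev$date), lat, what), call = NULL)))
  }
  if (is.na(ev$sunset_start) || is.na(ev$dawn_end))
    miss("sunset/sunrise (sun bottom edge on the horizon)")
  if (is.na(ev$dusk_end) || is.na(ev$dawn_start))
    miss("astronomical twilight (sun centre at -18 degrees)")

  dn_lo <- ev$nadir - 3600
  dn_hi <- ev$nadir + 3600
  ss <- min(ev$sunset_start, dn_lo)  # deep night takes precedence
  de <- min(ev$dusk_end, dn_lo)
  ds <- max(ev$dawn_start, dn_hi)
  da <- max(ev$dawn_end, dn_hi)

  b <- data.frame(
    category = c("day", "dusk", "night", "deep_night", "night", "dawn", "day"),
    start = c(ev$noon, ss, de, dn_lo, dn_hi, ds, da),
    end   = c(ss, de, dn_lo, dn_hi, ds, da, ev$noon_next)
  )
  b <- b[as.numeric(b$end) - as.numeric(b$start) > 0, , drop = FALSE]
  rownames(b) <- NULL

  dur <- as.numeric(b$end) - as.numeric(b$start)
  alpha <- vapply(diel_categories(),
                  function(k) sum(dur[b$category == k]) / 3600, 0)
  structure(list(
    date = ev$date, lat = lat, lon = lon,
    cycle_start = ev$noon, cycle_end = ev$noon_next, nadir = ev$nadir,
    boundaries = b, alpha = alpha
  ), class = "diel_schedule")
}

#' Find the diel schedule whose solar cycle contains an instant
#'
#' Returns the noon-to-noon [diel_schedule()] containing `t`, so that night
#' and deep-night intervals spanning civil midnight are never split across
#' two schedules. All computation is on the absolute (UTC) timeline, so
#' daylight-saving transitions have no effect beyond the parsing of local
#' timestamps.
#'
#' @param t instant (POSIXct, or a string parseable as UTC).
#' @inheritParams diel_schedule
#' @return A `diel_schedule` with `cycle_start <= t < cycle_end`.
#' @export
schedule_for_instant <- function(t, lat, lon) {
  t <- as_instant(t)
  # guess the solar date: shift to apparent local solar time, step back 12 h
  d <- as.Date(t + lon * 240 - 43200, tz = "UTC")
  for (off in c(0L, -1L, 1L)) {
    sch <- diel_schedule(d + off, lat, lon)
    if (t >= sch$cycle_start && t < sch$cycle_end) return(sch)
  }
  stop("failed to locate the solar cycle containing ", format(t))
}

#' Assign an instant to its diel category
#'
#' Looks up the half-open boundary interval of `schedule` containing `t`.
#' An instant exactly on a boundary belongs to the later category.
#'
#' @param t instant (POSIXct or string, UTC).
#' @param schedule a [diel_schedule()].
#' @return One of `"day"`, `"dawn"`, `"dusk"`, `"night"`, `"deep_night"`.
#' @export
diel_category <- function(t, schedule) {
  stopifnot(inherits(schedule, "diel_schedule"))
  t <- as_instant(t)
  if (t < schedule$cycle_start || t >= schedule$cycle_end)
    stop(structure(
      class = c("dieltrsf_out_of_cycle", "error", "condition"),
      list(message = sprintf(
        "instant %s lies outside the schedule cycle [%s, %s)",
        format(t, usetz = TRUE), format(schedule$cycle_start, usetz = TRUE),
        format(schedule$cycle_end, usetz = TRUE)), call = NULL)))
  b <- schedule$boundaries
  hit <- which(t >= b$start & t < b$end)
  b$category[hit[1L]]
}

#' @export
print.diel_schedule <- function(x, ...) {
  cat(sprintf("Diel schedule %s at (%.3f, %.3f)\n", format(x$date), x$lat, x$lon))
  cat(sprintf("  cycle: %s -> %s (UTC), nadir %s\n",
              format(x$cycle_start, "%Y-%m-%d %H:%M:%S"),
              format(x$cycle_end, "%Y-%m-%d %H:%M:%S"),
              format(x$nadir, "%H:%M:%S")))
  cat("  availability (h): ",
      paste(sprintf("%s=%.2f", names(x$alpha), x$alpha), collapse = ", "), "\n")
  invisible(x)
}

check_geo <- function(lat, lon) {
  if (!is.numeric(lat) || is.na(lat) || lat < -90 || lat > 90)
    stop("`lat` must lie in [-90, 90]")
  if (!is.numeric(lon) || is.na(lon) || lon < -180 || lon > 180)
    stop("`lon` must lie in [-180, 180]")
  invisible(TRUE)
}

# Parse instants: POSIXct passes through (converted to UTC); strings are
# parsed as ISO-8601, assumed UTC when no explicit offset is given.
# Element-wise: unparseable elements become NA rather than aborting.
as_instant <- function(t, tz = "UTC") {
  if (inherits(t, "POSIXct")) {
    attr(t, "tzone") <- "UTC"
    return(t)
  }
  t <- as.character(t)
  out <- rep(as.POSIXct(NA, tz = "UTC"), length(t))
  fmts <- c("%Y-%m-%dT%H:%M:%OS%z", "%Y-%m-%d %H:%M:%OS%z",
            "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
            "%Y-%m-%d %H:%M", "%Y-%m-%d")
  todo <- !is.na(t)
  for (f in fmts) {
    if (!any(todo)) break
    p <- as.POSIXct(strptime(t[todo], format = f, tz = tz))
    hit <- !is.na(p)
    out[which(todo)[hit]] <- p[hit]
    todo[todo] <- !hit
  }
  attr(out, "tzone") <- "UTC"
  out
}
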