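#' Collapse photo bursts into independent detection events
#'
#' Camera traps fire repeatedly while an animal lingers, so raw photos are
#' not independent observations. Within each (station, species) stream this
#' groups photos into detection events under a grouping window: with the
#' default `"chain"` rule, a photo starts a new event iff it is the first of
#' its stream or its gap to the *previous photo* exceeds `window_minutes`
#' (the prevailing camera-trap convention); with `"anchor"`, iff its gap to
#' the *first photo of the current event* exceeds the window. The event
#' timestamp is the first photo's timestamp.
#'
#' @param photos data frame with columns `station_id`, `species`,
#'   `timestamp` (POSIXct or ISO-8601 strings; strings without an explicit
#'   offset are read as UTC).
#' @param window_minutes grouping window in minutes (default 15).
#' @param rule `"chain"` (default) or `"anchor"`; see Details.
#' @return Data frame of event stubs sorted by station, species, time:
#'   `event_id`, `station_id`, `species`, `timestamp`, `n_photos`. Rows of
#'   `photos` with unparseable timestamps are dropped with a warning giving
#'   the count; empty input yields an empty result.
#' @examples
#' ph <- data.frame(station_id = "s1", species = "raccoon",
#'                  timestamp = as.POSIXct("2017-05-01 03:00:00", tz = "UTC") +
#'                    c(0, 10, 20) * 60)
#' dedupe_events(ph)  # gaps of 10 min chain into one event
#' @export
dedupe_events <- function(photos, window_minutes = 15, rule = c("chain", "anchor")) {
  rule <- match.arg(rule)
  stopifnot(is.data.frame(photos),
            all(c("station_id", "species", "timestamp") %in% names(photos)))
  empty <- data.frame(event_id = integer(), station_id = character(),
                      species = character(), timestamp = as_instant(character()),
                      n_photos = integer())
  if (nrow(photos) == 0) return(empty)

  ts <- suppressWarnings(as_instant(photos$timestamp))
  bad <- is.na(ts)
  if (any(bad)) {
    warning(sum(bad), " photo record(s) dropped: unparseable timestamp")
    photos <- photos[!bad, , drop = FALSE]
    ts <- ts[!bad]
  }
  if (nrow(photos) == 0) return(empty)

  ord <- order(photos$station_id, photos$species, ts)
  st <- as.character(photos$station_id)[ord]
  sp <- as.character(photos$species)[ord]
  ts <- ts[ord]

  new_stream <- c(TRUE, st[-1] != st[-length(st)] | sp[-1] != sp[-length(sp)])
  w <- window_minutes * 60
  if (rule == "chain") {
    gap <- c(Inf, as.numeric(diff(ts), units = "secs"))
    new_event <- new_stream | gap > w
  } else {
    # anchor rule needs the running first-photo of the current event
    new_event <- logical(length(ts))
    anchor <- -Inf
    for (i in seq_along(ts)) {
      if (new_stream[i] || as.numeric(ts[i]) - anchor > w) {
        new_event[i] <- TRUE
        anchor <- as.numeric(ts[i])
      }
    }
  }
  eid <- cumsum(new_event)
  first <- which(new_event)
  data.frame(
    event_id = seq_along(first),
    station_id = st[first],
    species = sp[first],
    timestamp = ts[first],
    n_photos = as.integer(tabulate(eid))
  )
}

#' Count trap nights across camera deployments
#'
#' Sampling effort is measured in trap nights: one station operating for one
#' night. Each deployment interval contributes `floor()` of its length in
#' whole nights (so a camera set on the 1st and collected on the 11th
#' contributes 10).
#'
#' @param deployments data frame with `station_id`, `start`, `end`
#'   (`Date` or coercible); intervals at one station must not overlap.
#' @return Integer total of trap nights.
#' @export
compute_trap_nights <- function(deployments) {
  stopifnot(is.data.frame(deployments),
            all(c("station_id", "start", "end") %in% names(deployments)))
  if (nrow(deployments) == 0) return(0L)
  start <- as.Date(deployments$start)
  end <- as.Date(deployments$end)
  if (any(is.na(start) | is.na(end))) stop("unparseable deployment dates")
  if (any(end < start)) stop("deployment interval with end before start")
  for (s in unique(deployments$station_id)) {
    i <- deployments$station_id == s
    if (sum(i) > 1) {
      o <- order(start[i])
      if (any(start[i][o][-1] < end[i][o][-sum(i)]))
        stop("overlapping deployment intervals at station ", s)
    }
  }
  as.integer(sum(floor(as.numeric(end - start))))
}

#' Attach diel categories, availability and temperature to detection events
#'
#' For each event stub this locates the noon-to-noon solar cycle containing
#' the event at its station's coordinates, assigns the diel category of the
#' event timestamp, records the availability hours of all five categories
#' (the model's offset term), and joins the city's mean temperature on the
#' event's civil date (the date of the timestamp in the site's timezone).
#'
#' @param stubs event stubs from [dedupe_events()].
#' @param sites data frame with `station_id`, `site_id`, `city_id`, `lat`,
#'   `lon` and optionally `tz` (IANA name; default `"UTC"`), one row per
#'   station.
#' @param temperatures optional data frame with `city_id`, `date`,
#'   `tavg_c` (daily mean temperature, deg C).
#' @param drop_missing_temperature if `TRUE`, events whose date/city has no
#'   temperature record are dropped (with a message); if `FALSE` (default)
#'   they are kept with `daily_mean_temperature = NA` and flagged in the
#'   `temperature_missing` column.
#' @return Data frame of detection events: the stub columns plus `site_id`,
#'   `city_id`, `category`, `alpha_day` ... `alpha_deep_night`,
#'   `daily_mean_temperature`, `temperature_missing`.
#' @export
assign_categories <- function(stubs, sites, temperatures = NULL,
                              drop_missing_temperature = FALSE) {
  stopifnot(is.data.frame(stubs), is.data.frame(sites))
  need <- c("station_id", "site_id", "city_id", "lat", "lon")
  stopifnot(all(need %in% names(sites)))
  if (is.null(sites$tz)) sites$tz <- "UTC"
  m <- match(as.character(stubs$station_id), as.character(sites$station_id))
  if (anyNA(m))
    stop("no site coordinates for station(s): ",
         paste(unique(stubs$station_id[is.na(m)]), collapse = ", "))

  ts <- as_instant(stubs$timestamp)
  out <- stubs
  out$site_id <- sites$site_id[m]
  out$city_id <- sites$city_id[m]

  K <- diel_categories()
  alpha <- matrix(NA_real_, nrow(stubs), 5, dimnames = list(NULL, paste0("alpha_", K)))
  category <- character(nrow(stubs))

  # one schedule per (station, solar cycle); reuse across events in the cycle
  solar_date <- as.Date(ts + sites$lon[m] * 240 - 43200, tz = "UTC")
  key <- paste(stubs$station_id, solar_date)
  for (kk in unique(key)) {
    i <- which(key == kk)
    sch <- schedule_for_instant(ts[i[1]], sites$lat[m[i[1]]], sites$lon[m[i[1]]])
    # the grouping key is approximate: events within minutes of solar noon
    # can belong to the neighbouring cycle, so verify containment
    inside <- ts[i] >= sch$cycle_start & ts[i] < sch$cycle_end
    ii <- i[inside]
    alpha[ii, ] <- matrix(sch$alpha, length(ii), 5, byrow = TRUE)
    category[ii] <- vapply(ii, function(j) diel_category(ts[j], sch), "")
    for (j in i[!inside]) {
      sj <- schedule_for_instant(ts[j], sites$lat[m[j]], sites$lon[m[j]])
      alpha[j, ] <- sj$alpha
      category[j] <- diel_category(ts[j], sj)
    }
  }
  out$category <- factor(category, levels = K)
  out <- cbind(out, as.data.frame(alpha))

  out$daily_mean_temperature <- NA_real_
  if (!is.null(temperatures)) {
    civil_date <- mapply(function(t, tz) format(t, "%Y-%m-%d", tz = tz),
                         as.list(ts), sites$tz[m])
    tk <- paste(temperatures$city_id, format(as.Date(temperatures$date)))
    tm <- match(paste(out$city_id, civil_date), tk)
    out$daily_mean_temperature <- temperatures$tavg_c[tm]
  }
  out$temperature_missing <- is.na(out$daily_mean_temperature)
  if (drop_missing_temperature && any(out$temperature_missing)) {
    message(sum(out$temperature_missing),
            " event(s) dropped: no temperature record for their date/city")
    out <- out[!out$temperature_missing, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
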