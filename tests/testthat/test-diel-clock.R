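# Diel schedules: partition invariants, seasonality, boundary conventions,
# and agreement with an independent solar-position oracle.

test_that("schedules partition the cycle with exact deep-night hours", {
  set.seed(42)
  n_valid <- 0
  for (r in 1:200) {
    lat <- runif(1, -50, 50)
    lon <- runif(1, -180, 180)
    date <- as.Date("2000-01-01") + sample.int(10958, 1)
    sch <- tryCatch(diel_schedule(date, lat, lon), dieltrsf_no_twilight = identity)
    if (inherits(sch, "condition")) next  # documented high-latitude degeneracy
    n_valid <- n_valid + 1
    b <- sch$boundaries
    expect_equal(as.numeric(b$start[1]), as.numeric(sch$cycle_start))
    expect_equal(as.numeric(b$end[nrow(b)]), as.numeric(sch$cycle_end))
    expect_true(all(abs(as.numeric(b$start[-1]) - as.numeric(b$end[-nrow(b)])) == 0))
    cyc_h <- as.numeric(sch$cycle_end - sch$cycle_start, units = "hours")
    expect_lt(abs(sum(sch$alpha) - cyc_h) * 3600, 1)
    expect_identical(unname(sch$alpha["deep_night"]), 2)
    expect_true(all(sch$alpha >= 0))
  }
  expect_gt(n_valid, 150)
})

test_that("daylight hours follow the seasons at mid-latitudes", {
  jun <- diel_schedule("2017-06-21", 45, -93)
  dec <- diel_schedule("2017-12-21", 45, -93)
  expect_gt(jun$alpha["day"], dec$alpha["day"])
  expect_gt(dec$alpha["night"], jun$alpha["night"])
})

test_that("solar event instants agree with an independent oracle within 2 min", {
  cases <- expand.grid(
    date = as.Date(c("2017-03-20", "2017-06-21", "2017-09-22", "2017-12-21", "2018-02-05")),
    lat = c(-40, -15, 0, 20, 35, 41.8, 45),
    lon = c(-87.6, 10)
  )
  cases <- cases[1:50, ]
  for (i in seq_len(nrow(cases))) {
    sch <- diel_schedule(cases$date[i], cases$lat[i], cases$lon[i])
    # nadir against an oracle altitude minimum
    onadir <- oracle_solar_extreme(sch$nadir, cases$lat[i], cases$lon[i], noon = FALSE)
    expect_lt(abs(as.numeric(sch$nadir) - as.numeric(onadir)), 120)
    # dawn start (-18 deg, morning flank) and dawn end (-0.3 deg)
    b <- sch$boundaries
    dawn <- b[b$category == "dawn", ]
    ods <- oracle_crossing(dawn$start - 5400, dawn$start + 5400,
                           cases$lat[i], cases$lon[i], -18)
    ode <- oracle_crossing(dawn$end - 5400, dawn$end + 5400,
                           cases$lat[i], cases$lon[i], -0.3)
    expect_lt(abs(as.numeric(dawn$start) - as.numeric(ods)), 120)
    expect_lt(abs(as.numeric(dawn$end) - as.numeric(ode)), 120)
  }
})

test_that("equinox day length at the equator matches the oracle", {
  sch <- diel_schedule("2017-03-20", 0, 0)
  b <- sch$boundaries
  rise <- b$end[b$category == "dawn"]                  # bottom edge on horizon
  setl <- b$start[b$category == "dusk"][1]
  orise <- oracle_crossing(rise - 5400, rise + 5400, 0, 0, -0.3)
  oset <- oracle_crossing(setl - 5400, setl + 5400, 0, 0, -0.3)
  expect_lt(abs(as.numeric(setl - rise, units = "secs") -
                as.numeric(oset - orise, units = "secs")), 120)
})

test_that("timestamps land in the right category with half-open boundaries", {
  sch <- diel_schedule("2017-04-10", 41.8, -87.6)
  expect_identical(diel_category(sch$nadir, sch), "deep_night")
  b <- sch$boundaries
  dawn <- b[b$category == "dawn", ]
  expect_identical(diel_category(dawn$start + as.numeric(dawn$end - dawn$start, units = "secs") / 2, sch),
                   "dawn")
  # instant exactly on the day/dusk boundary belongs to the later category
  expect_identical(diel_category(b$start[b$category == "dusk"][1], sch), "dusk")
  expect_identical(diel_category(sch$cycle_start, sch), "day")
  expect_error(diel_category(sch$cycle_end, sch), class = "dieltrsf_out_of_cycle")
  expect_error(diel_category(sch$cycle_start - 1, sch), class = "dieltrsf_out_of_cycle")
})

test_that("schedule_for_instant returns the enclosing solar cycle", {
  noon <- dieltrsf:::solar_noon(as.Date("2017-05-04"), -87.6)
  sch <- schedule_for_instant(noon + 60, 41.8, -87.6)
  expect_true(sch$cycle_start <= noon + 60 && noon + 60 < sch$cycle_end)
  expect_lt(as.numeric(noon + 60 - sch$cycle_start, units = "secs"), 120)
  # civil midnight is inside a night/deep-night interval of its cycle
  mid <- as.POSIXct("2017-05-04 05:00:00", tz = "UTC")  # local midnight Chicago
  sch2 <- schedule_for_instant(mid, 41.8, -87.6)
  expect_true(diel_category(mid, sch2) %in% c("night", "deep_night"))
})

test_that("cycle length is unaffected by daylight-saving transitions", {
  # US spring-forward 2017-03-12: computation runs on the UTC timeline, so
  # the cycle differs from 24 h only by solar-noon drift (seconds), not 1 h
  for (d in c("2017-03-11", "2017-03-12", "2017-03-13")) {
    sch <- diel_schedule(d, 41.8, -87.6)
    len <- as.numeric(sch$cycle_end - sch$cycle_start, units = "secs")
    expect_lt(abs(len - 86400), 120)
    onoon <- oracle_solar_extreme(sch$cycle_start, 41.8, -87.6, noon = TRUE)
    expect_lt(abs(as.numeric(sch$cycle_start) - as.numeric(onoon)), 120)
  }
})

test_that("high latitudes without astronomical twilight fail loudly", {
  expect_error(diel_schedule("2017-06-21", 49.5, 8),
               class = "dieltrsf_no_twilight")
  expect_error(diel_schedule("2017-06-21", 49.5, 8), "astronomical twilight")
  expect_error(diel_schedule("2017-06-21", 75, 8), class = "dieltrsf_no_twilight")
  expect_error(diel_schedule("2017-06-21", 91, 8), "lat")
  expect_error(diel_schedule("1850-06-21", 40, 8), "1900")
})
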