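# Synthetic multi-city camera-trap data with known ground truth, generated
# under the selection model itself so every pipeline stage can be validated
# end to end without field data.

#' Ground truth for the synthetic-data generator
#'
#' Defines a multi-city study design and the true model parameters used by
#' [simulate_sites()] and [simulate_detections()]. Defaults emulate the
#' full study design: 10 cities with 24-113 sites each (mean about 45),
#' two years of sampling (2017-2018), continental-US latitudes, seasonal
#' temperature cycles, and selection-coefficient magnitudes comparable to
#' those reported for common urban mammals (e.g. nocturnal selection
#' rising with human population density, log odds about 0.17 per SD).
#'
#' @param n_cities number of cities.
#' @param sites_per_city integer vector (recycled) of sites per city; when
#'   `NULL`, counts are drawn per city from a lognormal matched to the
#'   design's spread and clamped to 24-113.
#' @param start,end study window dates.
#' @param lat_range,lon_range ranges for city centres, decimal degrees.
#' @param beta true J x 4 selection-coefficient matrix (rows = covariates,
#'   columns dawn, dusk, night, deep_night on the scaled-covariate scale).
#' @param mu,tau true city-intercept means and precisions (length 4).
#' @param between_city_sd,within_city_sd spread of the site covariates on
#'   the latent (pre-transform) scale, across and within cities.
#' @param temp_amplitude_c,temp_noise_sd_c seasonal amplitude and daily
#'   noise of city temperature (deg C); the seasonal minimum falls in
#'   mid-January and the city baseline declines with latitude.
#' @param events_per_site_day Poisson mean of detection events per site per
#'   solar cycle (an abundance stand-in; the selection model itself has no
#'   abundance component).
#' @param photos_per_event_mean mean photos per event (>= 1); extra photos
#'   beyond the first are Poisson, with intra-event gaps drawn uniformly
#'   from `intra_gap_min` (minutes, well inside the 15-min event window).
#' @param intra_gap_min length-2 range of intra-burst photo gaps, minutes.
#' @param seed seed recorded in the truth and used as the default for the
#'   generator functions.
#' @return Object of class `sim_truth`.
#' @export
sim_truth <- function(n_cities = 10, sites_per_city = NULL,
                      start = "2017-01-01", end = "2018-12-31",
                      lat_range = c(30, 45), lon_range = c(-122, -75),
                      beta = NULL, mu = c(-1, 0.3, 0.8, 0.6),
                      tau = rep(4, 4),
                      between_city_sd = 1, within_city_sd = 1,
                      temp_amplitude_c = 12, temp_noise_sd_c = 2.5,
                      events_per_site_day = 0.25,
                      photos_per_event_mean = 2, intra_gap_min = c(0.5, 4),
                      seed = 1L) {
  covs <- c("greenspace", "impervious", "vegetation", "pop_density", "temperature")
  if (is.null(beta)) {
    beta <- matrix(0, 5, 4, dimnames = list(covs, diel_categories()[-1]))
    beta["pop_density", c("night", "deep_night")] <- c(0.17, 0.10)
    beta["greenspace", "night"] <- -0.20
    beta["impervious", c("night", "deep_night")] <- c(0.10, 0.10)
    beta["temperature", c("night", "dawn")] <- c(-0.20, 0.10)
  }
  beta <- as.matrix(beta)
  if (is.null(rownames(beta)))
    rownames(beta) <- covs[seq_len(nrow(beta))]
  stopifnot(ncol(beta) == 4, length(mu) == 4, length(tau) == 4, all(tau > 0),
            n_cities >= 1, events_per_site_day > 0, photos_per_event_mean >= 1)
  structure(list(
    n_cities = as.integer(n_cities), sites_per_city = sites_per_city,
    start = as.Date(start), end = as.Date(end),
    lat_range = lat_range, lon_range = lon_range,
    covariates = rownames(beta), beta = beta, mu = mu, tau = tau,
    between_city_sd = between_city_sd, within_city_sd = within_city_sd,
    temp_amplitude_c = temp_amplitude_c, temp_noise_sd_c = temp_noise_sd_c,
    events_per_site_day = events_per_site_day,
    photos_per_event_mean = photos_per_event_mean,
    intra_gap_min = intra_gap_min, seed = as.integer(seed)
  ), class = "sim_truth")
}

#' Simulate a multi-city site network with covariates and temperatures
#'
#' Draws city centres, per-city site networks, raw site covariates (city
#' mean plus within-city spread: proportion-type covariates on a logistic
#' scale, population density on a log scale), daily city temperature
#' series with a seasonal cycle, and the true city random intercepts.
#'
#' @param truth a [sim_truth()].
#' @param seed seed (default: `truth$seed`); identical seeds give
#'   byte-identical tables.
#' @return List with `sites` (station/site/city ids, lat, lon, tz),
#'   `covariates` (raw site covariates), `temperature` (city_id, date,
#'   tavg_c), `cities` (centres), and `b` (true city intercepts). All
#'   tables carry `seed` and `truth_fingerprint` attributes.
#' @export
simulate_sites <- function(truth, seed = truth$seed) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(seed)
  nc <- truth$n_cities
  cities <- data.frame(
    city_id = sprintf("city%02d", seq_len(nc)),
    lat = stats::runif(nc, truth$lat_range[1], truth$lat_range[2]),
    lon = stats::runif(nc, truth$lon_range[1], truth$lon_range[2]))
  nsites <- if (is.null(truth$sites_per_city)) {
    pmin(113L, pmax(24L, as.integer(round(stats::rlnorm(nc, log(40), 0.55)))))
  } else rep_len(as.integer(truth$sites_per_city), nc)

  # latent city means per covariate; sites spread around them
  cm <- matrix(stats::rnorm(nc * 5, 0, truth$between_city_sd), nc, 5,
               dimnames = list(cities$city_id,
                               c("greenspace", "impervious", "vegetation",
                                 "pop_density", "temperature")))
  rows <- lapply(seq_len(nc), function(c) {
    n <- nsites[c]
    lat <- cities$lat[c] + stats::runif(n, -0.05, 0.05)
    lon <- cities$lon[c] + stats::runif(n, -0.05, 0.05)
    z <- function(j) cm[c, j] + stats::rnorm(n, 0, truth$within_city_sd)
    data.frame(
      station_id = sprintf("%s_s%03d", cities$city_id[c], seq_len(n)),
      site_id = sprintf("%s_s%03d", cities$city_id[c], seq_len(n)),
      city_id = cities$city_id[c], lat = lat, lon = lon, tz = "UTC",
      greenspace = stats::plogis(z("greenspace")),
      impervious = stats::plogis(z("impervious") - 0.5),
      vegetation = stats::plogis(z("vegetation") + 0.5),
      pop_density = exp(7 + 0.5 * z("pop_density")))
  })
  sites <- do.call(rbind, rows)
  rownames(sites) <- NULL

  dates <- seq(truth$start, truth$end, by = "day")
  doy <- as.integer(format(dates, "%j"))
  temperature <- do.call(rbind, lapply(seq_len(nc), function(c) {
    base <- 28 - 0.5 * cities$lat[c]
    data.frame(city_id = cities$city_id[c], date = dates,
               tavg_c = base - truth$temp_amplitude_c * cos(2 * pi * (doy - 15) / 365.25) +
                 stats::rnorm(length(dates), 0, truth$temp_noise_sd_c))
  }))
  rownames(temperature) <- NULL

  b <- sweep(matrix(stats::rnorm(nc * 4), nc, 4,
                    dimnames = list(cities$city_id, diel_categories()[-1])) /
               sqrt(rep(truth$tau, each = nc)),
             2, truth$mu, "+")

  fp <- truth_fingerprint(truth)
  out <- list(sites = sites,
              covariates = sites[, c("site_id", "city_id", "greenspace",
                                     "impervious", "vegetation", "pop_density")],
              temperature = temperature, cities = cities, b = b)
  for (i in seq_along(out)) {
    attr(out[[i]], "seed") <- seed
    attr(out[[i]], "truth_fingerprint") <- fp
  }
  out
}

truth_fingerprint <- function(truth) {
  u <- unlist(truth[setdiff(names(truth), "seed")], use.names = FALSE)
  sprintf("trsf-truth-%08x",
          sum(as.integer(utf8ToInt(paste(format(u, digits = 10), collapse = "|"))) *
                (seq_along(utf8ToInt(paste(format(u, digits = 10), collapse = "|"))) %% 97 + 1)) %% .Machine$integer.max)
}

#' Simulate detection photo records under the selection model
#'
#' For each site and solar cycle, an event count is drawn (Poisson); each
#' event's diel category is drawn from the model's categorical distribution
#' (true coefficients, that cycle's availability, the site's scaled
#' covariates and its city's true intercept), a timestamp is drawn
#' uniformly within the category's interval(s) (for night, over the union
#' proportional to interval lengths), and the event is expanded into a
#' photo burst with intra-event gaps far below the 15-min window. Events
#' whose burst would fall within 15 min of the previous event at the same
#' station are dropped, so deduplication recovers the ledger exactly.
#'
#' Covariates enter on the scale the model sees: city-mean-centred and
#' divided by the global SD (computed here across all sites, and across all
#' city-days for temperature).
#'
#' @param truth a [sim_truth()].
#' @param network output of [simulate_sites()].
#' @param seed seed (default `truth$seed + 1`).
#' @return List with `photos` (station_id, species, timestamp) and `ledger`
#'   (one row per true event: ids, timestamp, true `category`, `alpha_*`
#'   availability hours, scaled covariate values, `n_photos`). Both carry
#'   `seed` and `truth_fingerprint` attributes.
#' @export
simulate_detections <- function(truth, network, seed = truth$seed + 1L) {
  stopifnot(inherits(truth, "sim_truth"), is.list(network))
  set.seed(seed)
  sites <- network$sites
  covs <- truth$covariates
  site_covs <- setdiff(covs, "temperature")

  scaled <- center_and_scale(network$covariates, site_covs, "city_id")
  tw <- network$temperature
  tmean <- tapply(tw$tavg_c, tw$city_id, mean)
  tsd <- stats::sd(tw$tavg_c)
  tw$temp_scaled <- (tw$tavg_c - tmean[as.character(tw$city_id)]) / tsd
  tkey <- paste(tw$city_id, format(as.Date(tw$date)))

  dates <- seq(truth$start, truth$end, by = "day")
  K <- diel_categories()
  # flat accumulators (one slot per event), assembled into frames at the end
  acc <- list(site = integer(), t0 = numeric(), cat = integer(),
              alpha = NULL, x = NULL, temp = numeric(), n_photos = integer(),
              gaps = list())
  alpha_rows <- list(); x_rows <- list()

  for (s in seq_len(nrow(sites))) {
    n_ev <- stats::rpois(length(dates), truth$events_per_site_day)
    act <- which(n_ev > 0)
    if (!length(act)) next
    ev <- solar_day_events(dates[act], sites$lat[s], sites$lon[s])
    xs <- unlist(scaled[s, site_covs, drop = FALSE])
    ci <- match(sites$city_id[s], rownames(network$b))
    tj <- match(paste(sites$city_id[s], format(dates[act])), tkey)
    for (a in seq_along(act)) {
      sch <- build_schedule(ev[a, ], sites$lat[s], sites$lon[s])
      x <- c(xs, temperature = tw$temp_scaled[tj[a]])[covs]
      lam <- c(log(sch$alpha[1]),
               as.numeric(x %*% truth$beta) + network$b[ci, ] + log(sch$alpha[-1]))
      phi <- exp(lam - max(lam)); phi <- phi / sum(phi)
      n <- n_ev[act[a]]
      ks <- sample.int(5, n, replace = TRUE, prob = phi)
      bsec <- as.numeric(sch$boundaries$start); esec <- as.numeric(sch$boundaries$end)
      t0 <- vapply(ks, function(k) {
        rr <- which(sch$boundaries$category == K[k])
        r <- if (length(rr) > 1)
          rr[sample.int(length(rr), 1, prob = esec[rr] - bsec[rr])] else rr
        bsec[r] + stats::runif(1) * (esec[r] - bsec[r])
      }, 0)
      n_extra <- stats::rpois(n, truth$photos_per_event_mean - 1)
      gaps <- lapply(n_extra, function(m)
        stats::runif(m, truth$intra_gap_min[1], truth$intra_gap_min[2]) * 60)
      acc$site <- c(acc$site, rep(s, n))
      acc$t0 <- c(acc$t0, t0)
      acc$cat <- c(acc$cat, ks)
      acc$temp <- c(acc$temp, rep(tw$tavg_c[tj[a]], n))
      acc$n_photos <- c(acc$n_photos, 1L + n_extra)
      acc$gaps <- c(acc$gaps, gaps)
      alpha_rows[[length(alpha_rows) + 1]] <-
        matrix(sch$alpha, n, 5, byrow = TRUE)
      x_rows[[length(x_rows) + 1]] <- matrix(x, n, length(covs), byrow = TRUE)
    }
  }
  if (!length(acc$t0)) stop("no events generated; increase `events_per_site_day`")
  alpha_mat <- do.call(rbind, alpha_rows)
  x_mat <- do.call(rbind, x_rows)
  colnames(alpha_mat) <- paste0("alpha_", K)
  colnames(x_mat) <- covs

  # enforce the 15-min separation the dedup rule assumes: within each
  # station, drop events starting within 15 min of the previous kept burst
  last_photo <- acc$t0 + vapply(acc$gaps, sum, 0)
  ord <- order(acc$site, acc$t0)
  keep <- logical(length(ord))
  last_end <- -Inf; last_st <- -1L
  for (i in ord) {
    if (acc$site[i] != last_st || acc$t0[i] - last_end > 15 * 60) {
      keep[i] <- TRUE
      last_st <- acc$site[i]
      last_end <- last_photo[i]
    }
  }
  sel <- ord[keep[ord]]
  led <- data.frame(
    event_id = seq_along(sel),
    station_id = sites$station_id[acc$site[sel]],
    site_id = sites$site_id[acc$site[sel]],
    city_id = sites$city_id[acc$site[sel]],
    species = "synthetic_species",
    timestamp = as.POSIXct(acc$t0[sel], origin = "1970-01-01", tz = "UTC"),
    category = factor(K[acc$cat[sel]], levels = K),
    alpha_mat[sel, , drop = FALSE], x_mat[sel, , drop = FALSE],
    daily_mean_temperature = acc$temp[sel],
    n_photos = acc$n_photos[sel])
  ph <- data.frame(
    station_id = rep(led$station_id, led$n_photos),
    species = "synthetic_species",
    timestamp = as.POSIXct(
      rep(acc$t0[sel], acc$n_photos[sel]) +
        unlist(lapply(acc$gaps[sel], function(g) c(0, cumsum(g)))),
      origin = "1970-01-01", tz = "UTC"))
  rownames(led) <- rownames(ph) <- NULL
  out <- list(photos = ph, ledger = led)
  fp <- truth_fingerprint(truth)
  for (i in seq_along(out)) {
    attr(out[[i]], "seed") <- seed
    attr(out[[i]], "truth_fingerprint") <- fp
  }
  out
}

#' Simulation-based calibration of the selection model
#'
#' Repeats simulate -> fit -> compare: generates a dataset from `truth`,
#' fits the model to the generator's event ledger, and records whether each
#' true selection coefficient falls in its central 95% credible interval,
#' along with bias, RMSE and convergence diagnostics. Replicates that fail
#' to converge are recorded, never hidden.
#'
#' @param truth a [sim_truth()].
#' @param control a [trsf_control()] for the per-replicate fits.
#' @param n_replicates number of simulate/fit cycles.
#' @param seed master seed; replicate seeds are derived deterministically.
#' @return Object of class `recovery_report`: `details` (one row per
#'   replicate x coefficient: true value, posterior median and interval,
#'   coverage flag), `replicates` (per-replicate max R-hat and convergence
#'   flag), and `summary` (coverage, bias, RMSE, convergence failures).
#' @export
recovery_experiment <- function(truth, control, n_replicates, seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"), inherits(control, "trsf_control"))
  set.seed(seed)
  rep_seeds <- sample.int(1e9L, 3L * n_replicates)
  covs <- truth$covariates
  details <- list(); reps <- list()
  for (r in seq_len(n_replicates)) {
    net <- simulate_sites(truth, seed = rep_seeds[3 * r - 2])
    det <- simulate_detections(truth, net, seed = rep_seeds[3 * r - 1])
    fit <- suppressWarnings(trsf(
      stats::reformulate(covs, response = "category"), det$ledger,
      city = "city_id", control = control, seed = rep_seeds[3 * r]))
    s <- summary(fit)$coefficients
    truev <- as.vector(truth$beta)  # covariates vary fastest, matching param order
    details[[r]] <- data.frame(
      replicate = r, parameter = s$parameter, true = truev,
      median = s$median, lower = s$lower, upper = s$upper,
      covered = s$lower <= truev & truev <= s$upper)
    reps[[r]] <- data.frame(replicate = r,
                            rhat_max = max(fit$samples$rhat, na.rm = TRUE),
                            converged = fit$samples$converged)
  }
  details <- do.call(rbind, details)
  reps <- do.call(rbind, reps)
  structure(list(
    details = details, replicates = reps,
    summary = list(
      coverage = mean(details$covered),
      bias = mean(details$median - details$true),
      rmse = sqrt(mean((details$median - details$true)^2)),
      rhat_max = max(reps$rhat_max),
      n_nonconverged = sum(!reps$converged),
      n_replicates = n_replicates, seed = seed,
      truth_fingerprint = truth_fingerprint(truth))
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  s <- x$summary
  cat("Parameter-recovery experiment:", s$n_replicates, "replicates\n")
  cat(sprintf("  95%% interval coverage of true coefficients: %.3f\n", s$coverage))
  cat(sprintf("  bias %.4f, RMSE %.4f; max R-hat %.3f; non-converged: %d\n",
              s$bias, s$rmse, s$rhat_max, s$n_nonconverged))
  invisible(x)
}
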