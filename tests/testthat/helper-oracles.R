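# Independent oracles used by the tests. These deliberately share no code
# with the package: the solar oracle uses the low-precision Astronomical
# Almanac sun-position series plus numerical root finding (the package uses
# the NOAA hour-angle equations); the model oracles are naive elementwise
# loops over the model's definitions.

# --- solar position oracle -------------------------------------------------

# Sun altitude (degrees) at POSIXct t; Astronomical Almanac low-precision
# formulas (accuracy ~0.01 deg, minutes-level event times).
oracle_sun_altitude <- function(t, lat, lon) {
  d2r <- pi / 180
  n <- as.numeric(t) / 86400 + 2440587.5 - 2451545.0
  L <- (280.460 + 0.9856474 * n) %% 360
  g <- (357.528 + 0.9856003 * n) %% 360
  lam <- (L + 1.915 * sin(g * d2r) + 0.020 * sin(2 * g * d2r)) * d2r
  eps <- (23.439 - 0.0000004 * n) * d2r
  decl <- asin(sin(eps) * sin(lam))
  ra <- atan2(cos(eps) * sin(lam), cos(lam))
  gmst_h <- (18.697374558 + 24.06570982441908 * n) %% 24
  H <- (gmst_h * 15 + lon) * d2r - ra
  asin(sin(lat * d2r) * sin(decl) + cos(lat * d2r) * cos(decl) * cos(H)) / d2r
}

# Instant of maximum (noon = TRUE) or minimum sun altitude near guess.
oracle_solar_extreme <- function(guess, lat, lon, noon = TRUE) {
  f <- function(s) oracle_sun_altitude(guess + s, lat, lon) * if (noon) 1 else -1
  o <- stats::optimize(f, c(-7200, 7200), maximum = TRUE, tol = 0.5)
  guess + o$maximum
}

# Crossing of altitude `alt` between t_lo and t_hi (altitude must bracket).
oracle_crossing <- function(t_lo, t_hi, lat, lon, alt) {
  f <- function(s) oracle_sun_altitude(as.POSIXct(s, origin = "1970-01-01", tz = "UTC"),
                                       lat, lon) - alt
  r <- stats::uniroot(f, c(as.numeric(t_lo), as.numeric(t_hi)), tol = 0.5)
  as.POSIXct(r$root, origin = "1970-01-01", tz = "UTC")
}

# --- model oracles ---------------------------------------------------------

# Naive elementwise linear predictor: loops, no matrix algebra.
oracle_linpred <- function(data, params) {
  I <- nrow(data$X); K <- ncol(data$log_alpha); J <- ncol(data$X)
  lam <- matrix(NA_real_, I, K)
  for (i in seq_len(I)) {
    lam[i, 1] <- data$log_alpha[i, 1]
    for (k in 2:K) {
      s <- 0
      for (j in seq_len(J)) s <- s + data$X[i, j] * params$beta[j, k - 1]
      lam[i, k] <- s + params$b[data$city[i], k - 1] + data$log_alpha[i, k]
    }
  }
  lam
}

oracle_softmax <- function(lam) {
  out <- lam
  for (i in seq_len(nrow(lam))) out[i, ] <- exp(lam[i, ]) / sum(exp(lam[i, ]))
  out
}

# Brute-force log of the product of per-event categorical masses.
oracle_loglik <- function(data, params) {
  phi <- oracle_softmax(oracle_linpred(data, params))
  ll <- 0
  for (i in seq_len(nrow(phi))) ll <- ll + log(phi[i, data$y[i]])
  ll
}

# Term-by-term log prior with explicit densities.
oracle_logprior <- function(params) {
  if (params$pi < 0.001 || params$pi > 10 || any(params$tau <= 0)) return(-Inf)
  lp <- 0
  for (k in seq_len(ncol(params$beta)))
    for (j in seq_len(nrow(params$beta)))
      lp <- lp + log(params$pi / 2) - params$pi * abs(params$beta[j, k])
  for (k in seq_len(ncol(params$b)))
    for (c in seq_len(nrow(params$b)))
      lp <- lp + 0.5 * log(params$tau[k] / (2 * pi)) -
        0.5 * params$tau[k] * (params$b[c, k] - params$mu[k])^2
  for (k in seq_along(params$mu))
    lp <- lp - 0.5 * log(2 * pi * 10) - params$mu[k]^2 / 20
  for (k in seq_along(params$tau)) lp <- lp - params$tau[k]  # Gamma(1,1) log density
  lp + log(1 / 9.999)
}

# --- small-fixture builders ------------------------------------------------

# Random small model instance (I events, J covariates, C cities).
random_instance <- function(I, J = 2, C = 2, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(I * J), I, J, dimnames = list(NULL, paste0("x", seq_len(J))))
  alpha <- matrix(runif(I * 5, 0.5, 12), I, 5)
  y <- sample.int(5, I, replace = TRUE)
  city <- sample(paste0("c", seq_len(C)), I, replace = TRUE)
  data <- trsf_data(X, y, alpha, city)
  params <- trsf_params(matrix(rnorm(J * 4, 0, 0.7), J, 4),
                        matrix(rnorm(C * 4, 0, 0.5), C, 4),
                        rnorm(4, 0, 0.5), rgamma(4, 2, 1), runif(1, 0.1, 5))
  list(data = data, params = params)
}

# A fitted-model shell with a posterior given by explicit draws, for testing
# the inference layer without running MCMC. `draws` is n x P in the
# sampler's parameter order (beta by category then city intercepts, mu,
# tau, pi).
fake_fit <- function(draws, covariates, city_levels, mean_alpha,
                     categories = diel_categories()) {
  n <- nrow(draws)
  a <- array(draws, c(n, 1, ncol(draws)),
             dimnames = list(NULL, NULL, colnames(draws)))
  structure(list(
    samples = list(draws = a, rhat = rep(1, ncol(draws)), converged = TRUE,
                   control = trsf_control(n_chains = 1, kept_total = n)),
    data = list(city_levels = city_levels),
    mean_alpha = mean_alpha, covariates = covariates,
    categories = categories, call = quote(fake_fit())
  ), class = "trsf")
}

# Point-mass posterior at given parameter values.
point_fit <- function(beta, b, mu = rep(0, 4), tau = rep(1, 4), pi = 1,
                      covariates, city_levels, mean_alpha, ndraw = 50) {
  v <- c(as.vector(beta), as.vector(b), mu, tau, pi)
  draws <- matrix(v, ndraw, length(v), byrow = TRUE)
  colnames(draws) <- dieltrsf:::param_names(covariates, city_levels,
                                           diel_categories())
  fake_fit(draws, covariates, city_levels, mean_alpha)
}

# Study-condition truths shared by tests (chosen once; small desk scale).
recovery_truth <- function() {
  sim_truth(n_cities = 5, sites_per_city = 8,
            start = "2017-05-01", end = "2017-06-19",
            beta = matrix(c(0.4, 0, 0.3, 0.2,
                            -0.3, 0, -0.4, 0), 2, 4, byrow = TRUE,
                          dimnames = list(c("greenspace", "pop_density"), NULL)),
            events_per_site_day = 1, seed = 101)
}

null_truth <- function(events_per_site_day = 2, n_days = 100) {
  sim_truth(n_cities = 5, sites_per_city = 10,
            start = "2017-03-01", end = as.character(as.Date("2017-03-01") + n_days - 1),
            beta = matrix(0, 5, 4), mu = rep(0, 4), tau = rep(1e6, 4),
            events_per_site_day = events_per_site_day, seed = 202)
}
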