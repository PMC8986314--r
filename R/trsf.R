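#' Assemble data for the temporal resource-selection model
#'
#' Validates and bundles the design matrix, category outcomes, availability
#' offsets and city indices. Usually called internally by [trsf()]; exposed
#' for programmatic use (e.g. with the synthetic-data generator's ledger).
#'
#' @param X numeric I x J matrix of scaled covariates (see
#'   [center_and_scale()]); columns must be named.
#' @param y event categories: factor with levels from [diel_categories()]
#'   (or integer codes 1..5 in that order); `day` is the reference.
#' @param alpha I x 5 matrix of availability hours per category, columns in
#'   [diel_categories()] order; all entries must be positive (stored as
#'   `log_alpha`).
#' @param city factor (or coercible) of length I giving each event's city.
#' @return Object of class `trsf_data` with elements `X`, `y` (integer
#'   codes), `log_alpha`, `city` (integer codes), `categories`,
#'   `city_levels`.
#' @export
trsf_data <- function(X, y, alpha, city) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("`X` must have column names")
  cats <- diel_categories()
  if (is.factor(y) || is.character(y)) {
    y <- factor(as.character(y), levels = cats)
    if (anyNA(y)) stop("`y` contains categories outside ", paste(cats, collapse = ", "))
    y <- as.integer(y)
  }
  y <- as.integer(y)
  stopifnot(all(y >= 1 & y <= 5))
  alpha <- as.matrix(alpha)
  stopifnot(nrow(alpha) == nrow(X), ncol(alpha) == 5, length(y) == nrow(X))
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop("availability hours must be positive and finite for every category")
  city <- factor(city)
  stopifnot(length(city) == nrow(X))
  structure(list(
    X = X, y = y, log_alpha = unname(log(alpha)),
    city = as.integer(city), categories = cats,
    city_levels = levels(city)
  ), class = "trsf_data")
}

#' Sampler configuration
#'
#' Defaults reproduce the full-scale fitting protocol: 14 parallel chains,
#' 20,000 burn-in iterations discarded per chain, every 7th subsequent
#' iteration kept, and 75,000 total posterior draws. `kept_total` is split
#' evenly across chains, rounded up (so the total kept is the smallest
#' multiple of `n_chains` at least `kept_total`).
#'
#' @param n_chains number of independent chains.
#' @param burn_in iterations discarded from the start of each chain.
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param kept_total total posterior draws across chains.
#' @param target_accept acceptance rate targeted by step-size adaptation
#'   during burn-in (0.44 is standard for scalar random-walk updates).
#' @param adapt_interval iterations between step-size adjustments.
#' @return Object of class `trsf_control`.
#' @export
trsf_control <- function(n_chains = 14, burn_in = 20000, thin = 7,
                         kept_total = 75000, target_accept = 0.44,
                         adapt_interval = 50) {
  stopifnot(n_chains >= 1, burn_in >= 0, thin >= 1, kept_total >= n_chains)
  structure(list(n_chains = as.integer(n_chains), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), kept_total = as.integer(kept_total),
                 target_accept = target_accept,
                 adapt_interval = as.integer(adapt_interval)),
            class = "trsf_control")
}

param_names <- function(covs, cities, cats) {
  nr <- cats[-1]
  c(as.vector(outer(covs, nr, function(j, k) sprintf("beta[%s,%s]", j, k))),
    as.vector(outer(cities, nr, function(c, k) sprintf("b[%s,%s]", c, k))),
    sprintf("mu[%s]", nr), sprintf("tau[%s]", nr), "pi")
}

#' Draw posterior samples of the selection model by MCMC
#'
#' Runs `n_chains` adaptive Metropolis-within-Gibbs chains from random
#' starting values (per-chain seeds derived deterministically from `seed`)
#' and reports classic Gelman-Rubin and split-half R-hat per parameter.
#' A warning is raised — and the `converged` flag set `FALSE` — if any
#' classic R-hat is 1.1 or above; results are always returned, never
#' silently discarded. A warning also lists diel categories with zero
#' observed events (their parameters are then prior-dominated).
#'
#' @param data a [trsf_data()] object.
#' @param control a [trsf_control()].
#' @param seed master integer seed for reproducibility.
#' @return Object of class `trsf_samples`: `draws` (iterations x chains x
#'   parameters array), `rhat`, `split_rhat`, `accept` (mean acceptance
#'   rates), `control`, `seed`, `converged`.
#' @export
sample_posterior <- function(data, control = trsf_control(), seed = 1L) {
  stopifnot(inherits(data, "trsf_data"), inherits(control, "trsf_control"))
  if (sum(tabulate(data$y, 5) > 0) < 2)
    stop("data are degenerate: fewer than 2 observed categories")
  empty <- which(tabulate(data$y, 5) == 0)
  if (length(empty))
    warning("no events observed in categor", if (length(empty) > 1) "ies: " else "y: ",
            paste(data$categories[empty], collapse = ", "),
            "; their parameters are prior-dominated")
  J <- ncol(data$X); C <- length(data$city_levels); Km <- 4L
  per_chain <- as.integer(ceiling(control$kept_total / control$n_chains))
  set.seed(seed %% .Machine$integer.max)
  chain_seeds <- sample.int(2147483646L, control$n_chains)
  pn <- param_names(colnames(data$X), data$city_levels, data$categories)
  draws <- array(NA_real_, c(per_chain, control$n_chains, length(pn)),
                 dimnames = list(NULL, NULL, pn))
  acc_beta <- acc_b <- NULL
  for (ch in seq_len(control$n_chains)) {
    set.seed(chain_seeds[ch])
    res <- run_trsf_chain(
      data$X, data$y, data$log_alpha, data$city, C,
      matrix(stats::rnorm(J * Km, 0, 0.5), J, Km),
      matrix(stats::rnorm(C * Km, 0, 0.5), C, Km),
      stats::rnorm(Km, 0, 0.5), stats::rgamma(Km, 2, 2),
      stats::runif(1, 0.5, 2),
      control$burn_in, per_chain, control$thin,
      control$target_accept, control$adapt_interval)
    draws[, ch, ] <- res$draws
    acc_beta <- cbind(acc_beta, res$accept_beta)
    acc_b <- cbind(acc_b, res$accept_b)
  }
  rhat <- apply(draws, 3, gelman_rubin)
  srhat <- apply(draws, 3, split_rhat)
  converged <- all(is.na(rhat) | rhat < 1.1)
  if (!converged)
    warning("convergence not reached: max Gelman-Rubin R-hat = ",
            sprintf("%.3f", max(rhat, na.rm = TRUE)), " (criterion < 1.1)")
  structure(list(draws = draws, rhat = rhat, split_rhat = srhat,
                 accept = list(beta = rowMeans(acc_beta), b = rowMeans(acc_b)),
                 control = control, seed = seed, converged = converged),
            class = "trsf_samples")
}

#' Fit a temporal resource-selection model
#'
#' Fits the hierarchical Bayesian multinomial (softmax) model of diel
#' category use: event categories are categorical outcomes whose log-linear
#' predictor combines scaled covariate effects, a city random intercept and
#' a log availability-hours offset, with `day` as the reference category.
#' Selection coefficients carry Laplace (LASSO-type) shrinkage priors whose
#' rate is itself estimated. See [trsf_params()] and the package vignette
#' for the full model statement.
#'
#' @param formula model formula, e.g.
#'   `category ~ greenspace + impervious + vegetation + pop_density + temperature`.
#'   The response is the diel category column; covariates are assumed
#'   already centred/scaled (see [center_and_scale()]). No global intercept
#'   is fitted (city intercepts take its place).
#' @param data data frame of detection events, typically from
#'   [assign_categories()] joined with site covariates.
#' @param city name of the city column in `data` (or a vector/factor).
#' @param alpha availability hours: an I x 5 matrix, or the names of five
#'   columns of `data`; defaults to columns `alpha_day` ...
#'   `alpha_deep_night` as written by [assign_categories()].
#' @param control sampler settings from [trsf_control()].
#' @param seed master seed for the MCMC.
#' @return Object of class `trsf` with components `samples`
#'   (a `trsf_samples`), `data` (the `trsf_data`), `mean_alpha` (study-wide
#'   mean availability hours, the default prediction availability),
#'   `covariates`, `categories`, `call`. Supports `print`, `summary`,
#'   `coef`, `predict`, `plot` and `simulate` methods.
#' @examples
#' \donttest{
#' truth <- sim_truth(n_cities = 3, sites_per_city = 4,
#'                    start = "2017-06-01", end = "2017-06-20",
#'                    events_per_site_day = 1, seed = 1)
#' sim <- simulate_sites(truth)
#' det <- simulate_detections(truth, sim)
#' fit <- trsf(category ~ greenspace + pop_density, data = det$ledger,
#'             city = "city_id",
#'             control = trsf_control(n_chains = 2, burn_in = 500,
#'                                    thin = 1, kept_total = 1000),
#'             seed = 1)
#' print(fit)
#' }
#' @export
trsf <- function(formula, data, city = "city_id", alpha = NULL,
                 control = trsf_control(), seed = 1L) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  tt <- stats::delete.response(stats::terms(formula, data = data))
  X <- stats::model.matrix(tt, data)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (ncol(X) == 0) stop("the model needs at least one covariate")

  if (is.null(alpha)) alpha <- paste0("alpha_", diel_categories())
  if (is.character(alpha)) {
    if (!all(alpha %in% names(data)))
      stop("availability columns not found: ",
           paste(setdiff(alpha, names(data)), collapse = ", "))
    alpha <- as.matrix(data[, alpha])
  }
  cityv <- if (is.character(city) && length(city) == 1) {
    if (!city %in% names(data)) stop("city column `", city, "` not found")
    data[[city]]
  } else city

  d <- trsf_data(X, y, alpha, cityv)
  s <- sample_posterior(d, control, seed)
  structure(list(samples = s, data = d,
                 mean_alpha = stats::setNames(colMeans(alpha), diel_categories()),
                 covariates = colnames(X), categories = diel_categories(),
                 call = match.call()),
            class = "trsf")
}

# Flattened draws (all chains pooled): n_draws x P matrix with parameter names.
pooled_draws <- function(fit) {
  d <- if (inherits(fit, "trsf")) fit$samples$draws else fit$draws
  matrix(d, nrow = dim(d)[1] * dim(d)[2], dimnames = list(NULL, dimnames(d)[[3]]))
}
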