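# Model mathematics for the temporal resource-selection model.
#
# A detection event i falls in diel category y_i in {day, dawn, dusk, night,
# deep_night} (day = reference). With scaled covariates x_i, city c[i], and
# availability hours alpha_{i,k}:
#
#   y_i ~ Categorical(phi_i),  phi_{i,k} = softmax_k(lambda_i),
#   lambda_{i,1} = log(alpha_{i,1}),
#   lambda_{i,k} = x_i' beta_{.,k} + b_{c[i],k} + log(alpha_{i,k}),  k > 1.
#
# Priors: beta_{j,k} ~ Laplace(0, pi) with rate pi (density (pi/2) e^{-pi|x|},
# the JAGS double-exponential convention), pi ~ Uniform(0.001, 10);
# b_{c,k} ~ Normal(mu_k, precision tau_k); mu_k ~ Normal(0, variance 10);
# tau_k ~ Gamma(1, 1). The log offset makes the null model reproduce the
# availability-weighted distribution of a resource selection function with
# an exponential link: with beta = b = 0, phi_k = alpha_k / sum(alpha).

#' Bundle parameters of the temporal resource-selection model
#'
#' @param beta J x (K-1) matrix of selection coefficients for the
#'   non-reference categories (columns ordered dawn, dusk, night,
#'   deep_night); the reference (day) column is pinned at zero and not
#'   stored.
#' @param b C x (K-1) matrix of city random intercepts.
#' @param mu length-(K-1) means of the city intercepts.
#' @param tau length-(K-1) precisions of the city intercepts (> 0).
#' @param pi Laplace rate of the shrinkage prior, in `[0.001, 10]`.
#' @return Object of class `trsf_params`.
#' @export
trsf_params <- function(beta, b, mu, tau, pi) {
  beta <- as.matrix(beta); b <- as.matrix(b)
  stopifnot(ncol(beta) == ncol(b), length(mu) == ncol(b),
            length(tau) == ncol(b), length(pi) == 1)
  structure(list(beta = beta, b = b, mu = as.numeric(mu),
                 tau = as.numeric(tau), pi = as.numeric(pi)),
            class = "trsf_params")
}

#' Log-linear predictor of the selection model
#'
#' Computes the I x K matrix lambda: `log(alpha)` for the day reference
#' column, and covariate effect + city intercept + `log(alpha)` for the
#' other categories.
#'
#' @param data a [trsf_data()] object.
#' @param params a [trsf_params()] object.
#' @return I x K numeric matrix.
#' @export
trsf_linear_predictor <- function(data, params) {
  stopifnot(inherits(data, "trsf_data"), inherits(params, "trsf_params"))
  I <- nrow(data$X); K <- ncol(data$log_alpha)
  lambda <- data$log_alpha
  eff <- data$X %*% params$beta + params$b[data$city, , drop = FALSE]
  lambda[, -1] <- lambda[, -1] + eff
  if (!all(is.finite(lambda))) {
    bad <- which(!apply(is.finite(lambda), 1, all))[1]
    stop("non-finite linear predictor at event ", bad)
  }
  lambda
}

#' Row-wise softmax
#'
#' Numerically stabilized (row-max subtracted) softmax; each row of the
#' result sums to one.
#'
#' @param lambda numeric matrix of scores.
#' @return Matrix of probabilities with the same shape.
#' @export
softmax_rows <- function(lambda) {
  lambda <- as.matrix(lambda)
  m <- apply(lambda, 1, max)
  e <- exp(lambda - m)
  e / rowSums(e)
}

#' Log-likelihood of the selection model
#'
#' `sum_i log phi_{i, y_i}` under the categorical likelihood. If any event
#' has zero probability mass on its observed category, `-Inf` is returned
#' with a warning naming the count of such events.
#'
#' @inheritParams trsf_linear_predictor
#' @return Scalar log-likelihood.
#' @export
trsf_loglik <- function(data, params) {
  phi <- softmax_rows(trsf_linear_predictor(data, params))
  p <- phi[cbind(seq_len(nrow(phi)), data$y)]
  if (any(p == 0)) {
    warning(sum(p == 0), " event(s) with zero category probability; ",
            "log-likelihood is -Inf")
    return(-Inf)
  }
  sum(log(p))
}

#' Log prior density of the selection model
#'
#' Sum of: Laplace(0, rate `pi`) terms for each selection coefficient;
#' Normal(`mu_k`, precision `tau_k`) terms for the city intercepts;
#' Normal(0, variance 10) for each `mu_k`; Gamma(1, 1) for each `tau_k`;
#' and the Uniform(0.001, 10) density for `pi`. Returns `-Inf` outside the
#' support (`pi` outside its bounds or any `tau <= 0`).
#'
#' @param params a [trsf_params()] object.
#' @return Scalar log prior density.
#' @export
trsf_logprior <- function(params) {
  stopifnot(inherits(params, "trsf_params"))
  p <- params
  if (p$pi < 0.001 || p$pi > 10 || any(p$tau <= 0)) return(-Inf)
  lp <- sum(log(p$pi / 2) - p$pi * abs(p$beta))
  for (k in seq_along(p$mu))
    lp <- lp + sum(stats::dnorm(p$b[, k], p$mu[k], 1 / sqrt(p$tau[k]), log = TRUE))
  lp <- lp + sum(stats::dnorm(p$mu, 0, sqrt(10), log = TRUE))
  lp <- lp + sum(stats::dgamma(p$tau, shape = 1, rate = 1, log = TRUE))
  lp + log(1 / (10 - 0.001))
}
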