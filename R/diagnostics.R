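#' Gelman-Rubin convergence diagnostic (classic R-hat)
#'
#' The classic potential scale reduction factor comparing between- and
#' within-chain variance for one parameter:
#' `B = n * var(chain means)`, `W = mean(chain variances)`,
#' `Vhat = (n-1)/n * W + (1 + 1/m) * B / n`, `Rhat = sqrt(Vhat / W)`,
#' for `m` chains of `n` kept iterations. Values below 1.1 are the usual
#' convergence criterion. The split-half variant ([split_rhat()]), which
#' also detects within-chain drift, is reported alongside by the sampler.
#'
#' @param draws numeric matrix with one column per chain (iterations in
#'   rows), or anything coercible to one.
#' @return Scalar R-hat; `NA` (with a warning) when every chain has zero
#'   within-chain variance, where the statistic is undefined.
#' @export
gelman_rubin <- function(draws) {
  draws <- as.matrix(draws)
  m <- ncol(draws); n <- nrow(draws)
  if (m < 2) stop("at least 2 chains are required")
  if (n < 4) stop("at least 4 iterations per chain are required")
  W <- mean(apply(draws, 2, stats::var))
  if (W == 0) {
    warning("zero within-chain variance in all chains; R-hat is undefined")
    return(NA_real_)
  }
  B <- n * stats::var(colMeans(draws))
  Vhat <- (n - 1) / n * W + (1 + 1 / m) * B / n
  sqrt(Vhat / W)
}

#' Split-half R-hat
#'
#' [gelman_rubin()] applied after splitting each chain into halves, so that
#' a trending single chain is also flagged.
#'
#' @inheritParams gelman_rubin
#' @return Scalar split R-hat.
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  h <- n %/% 2
  gelman_rubin(cbind(draws[seq_len(h), , drop = FALSE],
                     draws[seq_len(h) + (n - h), , drop = FALSE]))
}
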