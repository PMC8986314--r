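# S3 methods for fitted temporal resource-selection models.

#' @export
print.trsf <- function(x, ...) {
  d <- x$data
  cat("Temporal resource-selection model (hierarchical multinomial)\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("Events: %d across %d cities; reference category: day\n",
              length(d$y), length(d$city_levels)))
  tab <- table(factor(x$categories[d$y], levels = x$categories))
  cat("Detections by category:\n")
  print(tab)
  rh <- x$samples$rhat
  cat(sprintf("Chains: %d, kept draws: %d; max R-hat = %.3f (%s)\n",
              x$samples$control$n_chains, prod(dim(x$samples$draws)[1:2]),
              max(rh, na.rm = TRUE),
              if (x$samples$converged) "converged, < 1.1" else "NOT converged"))
  cat("Use summary() for coefficient estimates.\n")
  invisible(x)
}

#' Posterior summary of a fitted selection model
#'
#' Posterior medians, central 95% credible intervals and exponentiated
#' medians (odds-scale selection: > 1 means selection for the category
#' relative to day per unit covariate increase) for every selection
#' coefficient, plus hyperparameters and convergence diagnostics.
#'
#' @param object a fitted [trsf()] model.
#' @param ... unused.
#' @return A `summary.trsf` list with `coefficients` (data frame),
#'   `hyper` (data frame for `mu`, `tau`, `pi`), `rhat_max`, `converged`.
#' @export
summary.trsf <- function(object, ...) {
  dr <- pooled_draws(object)
  q <- t(apply(dr, 2, stats::quantile, c(0.025, 0.5, 0.975)))
  tab <- data.frame(parameter = rownames(q), median = q[, 2],
                    lower = q[, 1], upper = q[, 3],
                    rhat = object$samples$rhat[rownames(q)],
                    row.names = NULL)
  is_beta <- grepl("^beta\\[", tab$parameter)
  co <- tab[is_beta, ]
  co$exp_median <- exp(co$median)
  co$excludes_zero <- co$lower > 0 | co$upper < 0
  hy <- tab[grepl("^(mu|tau|pi)", tab$parameter), ]
  structure(list(coefficients = co, hyper = hy,
                 rhat_max = max(object$samples$rhat, na.rm = TRUE),
                 converged = object$samples$converged,
                 call = object$call),
            class = "summary.trsf")
}

#' @export
print.summary.trsf <- function(x, digits = 3, ...) {
  cat("Selection coefficients (posterior median, 95% CrI; exp(median) > 1 =>\n")
  cat("selection for the category relative to day):\n")
  co <- x$coefficients
  co[, c("median", "lower", "upper", "exp_median", "rhat")] <-
    round(co[, c("median", "lower", "upper", "exp_median", "rhat")], digits)
  print(co, row.names = FALSE)
  cat("\nHyperparameters:\n")
  hy <- x$hyper
  hy[, c("median", "lower", "upper", "rhat")] <-
    round(hy[, c("median", "lower", "upper", "rhat")], digits)
  print(hy, row.names = FALSE)
  cat(sprintf("\nMax R-hat: %.3f (%s)\n", x$rhat_max,
              if (x$converged) "all < 1.1" else "convergence NOT reached"))
  invisible(x)
}

#' Posterior-median selection coefficients
#'
#' @param object a fitted [trsf()] model.
#' @param ... unused.
#' @return J x 4 matrix of posterior medians (rows = covariates, columns =
#'   non-reference categories).
#' @export
coef.trsf <- function(object, ...) {
  bl <- draw_blocks(object)
  out <- apply(bl$beta, c(2, 3), stats::median)
  dimnames(out) <- list(object$covariates, object$categories[-1])
  out
}

#' Coefficient interval plot for a fitted selection model
#'
#' Posterior medians and 95% credible intervals of the selection
#' coefficients, one panel row per covariate, grouped by category
#' (dawn, dusk, night, deep night), on the log-odds scale with a reference
#' line at 0 (no selection relative to day).
#'
#' @param x a fitted [trsf()] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.trsf <- function(x, ...) {
  s <- summary(x)$coefficients
  n <- nrow(s)
  old <- graphics::par(mar = c(4, 10, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(s$median, seq_len(n), xlim = range(s$lower, s$upper, 0),
                 ylim = c(0.5, n + 0.5), yaxt = "n", xlab = "coefficient (log odds)",
                 ylab = "", pch = 16, ...)
  graphics::segments(s$lower, seq_len(n), s$upper, seq_len(n))
  graphics::abline(v = 0, lty = 2, col = "grey40")
  graphics::axis(2, at = seq_len(n),
                 labels = sub("^beta\\[(.*)\\]$", "\\1", s$parameter),
                 las = 1, cex.axis = 0.7)
  invisible(x)
}

#' Stacked-bar plot of an activity profile
#'
#' @param x an `activity_profile` from [predict.trsf()].
#' @param ... passed to [graphics::barplot()].
#' @export
plot.activity_profile <- function(x, ...) {
  graphics::barplot(matrix(x$median, dimnames = list(x$category, NULL)),
                    legend.text = as.character(x$category),
                    ylab = "probability of activity", ...)
  invisible(x)
}

#' Posterior-predictive simulation of diel categories
#'
#' Draws new category outcomes for the fitted events: for each simulation a
#' posterior draw is selected at random and each event's category is drawn
#' from its categorical distribution under that parameter draw.
#'
#' @param object a fitted [trsf()] model.
#' @param nsim number of simulated datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return Data frame with `nsim` columns of category factors (one row per
#'   fitted event).
#' @export
simulate.trsf <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  dr <- pooled_draws(object)
  d <- object$data
  J <- length(object$covariates)
  C <- length(d$city_levels)
  pick <- sample.int(nrow(dr), nsim, replace = TRUE)
  out <- lapply(pick, function(r) {
    pars <- trsf_params(matrix(dr[r, seq_len(J * 4)], J, 4),
                        matrix(dr[r, J * 4 + seq_len(C * 4)], C, 4),
                        dr[r, J * 4 + C * 4 + 1:4],
                        dr[r, J * 4 + C * 4 + 4 + 1:4],
                        dr[r, ncol(dr)])
    phi <- softmax_rows(trsf_linear_predictor(d, pars))
    ycat <- apply(phi, 1, function(p) sample.int(5, 1, prob = p))
    factor(object$categories[ycat], levels = object$categories)
  })
  out <- as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
  rownames(out) <- NULL
  out
}
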