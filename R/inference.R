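# Posterior post-processing: activity probabilities, nocturnality, odds
# ratios for SD-shifts in covariates, city and site summaries.

# Split pooled draws into named blocks. Returns list(beta = ndraw x J x 4,
# b = ndraw x C x 4, mu, tau = ndraw x 4, pi = ndraw).
draw_blocks <- function(fit) {
  dr <- pooled_draws(fit)
  J <- length(fit$covariates)
  C <- length(fit$data$city_levels)
  n <- nrow(dr)
  list(beta = array(dr[, seq_len(J * 4)], c(n, J, 4)),
       b = array(dr[, J * 4 + seq_len(C * 4)], c(n, C, 4)),
       mu = dr[, J * 4 + C * 4 + 1:4, drop = FALSE],
       tau = dr[, J * 4 + C * 4 + 4 + 1:4, drop = FALSE],
       pi = dr[, ncol(dr)])
}

# Per-draw category probabilities at one covariate setting.
# level: "population" (mu draws), "new_city" (mu + Normal(0, 1/sqrt(tau))
# draws, the among-city predictive), or a city id (that city's intercepts).
phi_draws <- function(fit, x, alpha, level = "population") {
  bl <- draw_blocks(fit)
  n <- dim(bl$beta)[1]
  x <- as.numeric(x)
  stopifnot(length(x) == length(fit$covariates), length(alpha) == 5, all(alpha > 0))
  int <- if (identical(level, "population")) {
    bl$mu
  } else if (identical(level, "new_city")) {
    bl$mu + matrix(stats::rnorm(n * 4), n, 4) / sqrt(bl$tau)
  } else {
    ci <- match(as.character(level), fit$data$city_levels)
    if (is.na(ci)) stop("unknown city id: ", level)
    bl$b[, ci, ]
  }
  eff <- apply(bl$beta, 3, function(B) B %*% x)  # n x 4
  lam <- cbind(log(alpha[1]),
               eff + int + matrix(log(alpha[-1]), n, 4, byrow = TRUE))
  phi <- softmax_rows(lam)
  colnames(phi) <- fit$categories
  phi
}

summarize_phi <- function(phi, probs = c(0.025, 0.5, 0.975)) {
  q <- apply(phi, 2, stats::quantile, probs = probs)
  structure(data.frame(category = factor(colnames(phi), levels = colnames(phi)),
                       median = q[2, ], lower = q[1, ], upper = q[3, ],
                       row.names = NULL),
            class = c("activity_profile", "data.frame"))
}

#' Predicted diel activity probabilities
#'
#' For each posterior draw, evaluates the category probabilities at a
#' covariate setting via the model's log-linear predictor and softmax link,
#' then summarizes across draws (median and central 95% credible interval).
#' Each draw's five probabilities sum to one exactly.
#'
#' @param object a fitted [trsf()] model.
#' @param newdata named numeric vector (or one-row data frame) of scaled
#'   covariate values; defaults to 0 (city-centred means).
#' @param alpha availability hours for the five categories; defaults to the
#'   study-wide mean availability of the fitted events.
#' @param level `"population"` (city-intercept mean, the default),
#'   `"new_city"` (draws a new city intercept from its hyperdistribution),
#'   or a city id present in the data.
#' @param type `"profile"` for a summary table, `"draws"` for the
#'   draws x categories probability matrix.
#' @param ... unused.
#' @return An `activity_profile` data frame (`category`, `median`, `lower`,
#'   `upper`) or a numeric matrix of per-draw probabilities.
#' @export
predict.trsf <- function(object, newdata = NULL, alpha = NULL,
                         level = "population", type = c("profile", "draws"),
                         ...) {
  type <- match.arg(type)
  x <- stats::setNames(numeric(length(object$covariates)), object$covariates)
  if (!is.null(newdata)) {
    if (is.data.frame(newdata)) newdata <- unlist(newdata[1, , drop = TRUE])
    hit <- intersect(names(newdata), object$covariates)
    if (length(hit) == 0 && length(newdata) == length(x) && is.null(names(newdata))) {
      x[] <- as.numeric(newdata)
    } else x[hit] <- as.numeric(newdata[hit])
  }
  if (is.null(alpha)) alpha <- object$mean_alpha
  phi <- phi_draws(object, x, alpha, level)
  if (type == "draws") phi else summarize_phi(phi)
}

#' Probability of nocturnal activity
#'
#' Nocturnality combines the probability of activity during the night and
#' deep-night categories. Operates per draw, so it can be applied to the
#' `"draws"` output of [predict.trsf()].
#'
#' @param phi matrix (draws x 5) or vector (length 5) of category
#'   probabilities in [diel_categories()] order (or with category names).
#' @return Numeric vector (one value per draw) in `[0, 1]`.
#' @export
nocturnality <- function(phi) {
  if (is.null(dim(phi))) phi <- matrix(phi, 1, dimnames = list(NULL, names(phi)))
  idx <- if (!is.null(colnames(phi))) {
    match(c("night", "deep_night"), colnames(phi))
  } else c(4L, 5L)
  if (anyNA(idx)) stop("`phi` must have night and deep_night columns")
  unname(rowSums(phi[, idx, drop = FALSE]))
}

#' Odds ratios of nocturnality for SD-shifts in a covariate
#'
#' For each posterior draw the nocturnal probability is computed at a
#' reference covariate setting (`p0`) and with covariate `j` increased by
#' `shift` global standard deviations (`p1`, in scaled units a shift of
#' `shift`); the draw's odds ratio is `[p1/(1-p1)] / [p0/(1-p0)]`. Draws
#' where either probability is numerically 0 or 1 are excluded and counted.
#' Other covariates are held at the reference (0 = city means), and
#' availability at the study-wide mean, unless overridden.
#'
#' @param fit a fitted [trsf()] model.
#' @param covariates covariate names to evaluate (default: all).
#' @param shift standard-deviation increases to evaluate (default `c(1, 2)`).
#' @param x_ref reference scaled covariate vector (default all 0).
#' @param alpha availability hours (default: study-wide mean).
#' @param level see [predict.trsf()].
#' @return Data frame of class `odds_ratio_table`: `covariate`, `shift`,
#'   `median`, `lower`, `upper` (central 95% interval), `excludes_one`,
#'   `n_dropped`.
#' @export
odds_ratio <- function(fit, covariates = fit$covariates, shift = c(1, 2),
                       x_ref = NULL, alpha = NULL, level = "population") {
  stopifnot(inherits(fit, "trsf"), all(covariates %in% fit$covariates))
  if (is.null(alpha)) alpha <- fit$mean_alpha
  x0 <- stats::setNames(numeric(length(fit$covariates)), fit$covariates)
  if (!is.null(x_ref)) x0[names(x_ref)] <- as.numeric(x_ref)
  p0 <- nocturnality(phi_draws(fit, x0, alpha, level))
  out <- list()
  for (j in covariates) for (s in shift) {
    x1 <- x0
    x1[j] <- x1[j] + s
    p1 <- nocturnality(phi_draws(fit, x1, alpha, level))
    ok <- p0 > 0 & p0 < 1 & p1 > 0 & p1 < 1
    or <- (p1[ok] / (1 - p1[ok])) / (p0[ok] / (1 - p0[ok]))
    q <- stats::quantile(or, c(0.025, 0.5, 0.975))
    out[[length(out) + 1]] <- data.frame(
      covariate = j, shift = s, median = q[2], lower = q[1], upper = q[3],
      excludes_one = q[1] > 1 || q[3] < 1, n_dropped = sum(!ok))
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("odds_ratio_table", "data.frame")
  out
}

#' City-level and among-city activity summaries
#'
#' Per-city activity profiles at a common covariate setting (each city's
#' own intercept draws) plus the among-city average (`"among-city"` rows,
#' from the intercept-mean draws `mu_k`) whose credible interval reflects
#' the variation among cities through the hyperparameters.
#'
#' @inheritParams odds_ratio
#' @param x named scaled covariate values (default 0).
#' @return Data frame with `level` (city id or `"among-city"`), `category`,
#'   `median`, `lower`, `upper`.
#' @export
city_activity <- function(fit, x = NULL, alpha = NULL) {
  stopifnot(inherits(fit, "trsf"))
  if (is.null(alpha)) alpha <- fit$mean_alpha
  x0 <- stats::setNames(numeric(length(fit$covariates)), fit$covariates)
  if (!is.null(x)) x0[names(x)] <- as.numeric(x)
  rows <- lapply(fit$data$city_levels, function(cc) {
    pr <- summarize_phi(phi_draws(fit, x0, alpha, cc))
    cbind(level = cc, pr)
  })
  pop <- cbind(level = "among-city",
               summarize_phi(phi_draws(fit, x0, alpha, "population")))
  out <- rbind(do.call(rbind, rows), pop)
  rownames(out) <- NULL
  out
}

#' Per-site activity probabilities ordered by nocturnality
#'
#' Evaluates the posterior-median probability of use of each diel category
#' at every site's covariate values, plus the site's nocturnality, and
#' orders sites from least to most nocturnal. Sites with missing covariate
#' values are listed and excluded.
#'
#' @inheritParams odds_ratio
#' @param site_covariates data frame with `site_id` and scaled covariate
#'   columns matching the fitted model (extra columns are ignored).
#' @param level see [predict.trsf()]; a `city_id` column, when present, is
#'   used per site unless `level` is given explicitly.
#' @return Data frame sorted by nocturnality with columns `site_id`,
#'   `phi_<category>` medians, `nocturnality`, `rank`; the attribute
#'   `"range"` holds the min/max nocturnality.
#' @export
site_activity <- function(fit, site_covariates, alpha = NULL, level = NULL) {
  stopifnot(inherits(fit, "trsf"), is.data.frame(site_covariates),
            "site_id" %in% names(site_covariates))
  miss_cols <- setdiff(fit$covariates, names(site_covariates))
  if (length(miss_cols))
    stop("site covariates missing columns: ", paste(miss_cols, collapse = ", "))
  if (is.null(alpha)) alpha <- fit$mean_alpha
  cc <- stats::complete.cases(site_covariates[, fit$covariates, drop = FALSE])
  if (any(!cc))
    message("excluding site(s) with missing covariates: ",
            paste(site_covariates$site_id[!cc], collapse = ", "))
  sc <- site_covariates[cc, , drop = FALSE]
  rows <- lapply(seq_len(nrow(sc)), function(i) {
    lev <- if (!is.null(level)) level
           else if ("city_id" %in% names(sc)) as.character(sc$city_id[i])
           else "population"
    phi <- phi_draws(fit, unlist(sc[i, fit$covariates]), alpha, lev)
    med <- apply(phi, 2, stats::median)
    c(med, nocturnality = stats::median(nocturnality(phi)))
  })
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab)[1:5] <- paste0("phi_", fit$categories)
  tab <- cbind(site_id = sc$site_id, tab)
  tab <- tab[order(tab$nocturnality), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  attr(tab, "range") <- range(tab$nocturnality)
  tab
}
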