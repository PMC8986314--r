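# Posterior post-processing: activity prediction, nocturnality, odds
# ratios, city and site summaries. Uses hand-built posteriors so expected
# values are exact.

covs2 <- c("greenspace", "pop_density")
alpha0 <- c(day = 12, dawn = 1, dusk = 1, night = 8, deep_night = 2)

test_that("null-parameter draws predict availability shares exactly", {
  f <- point_fit(matrix(0, 2, 4), matrix(0, 3, 4), covariates = covs2,
                 city_levels = c("c1", "c2", "c3"), mean_alpha = alpha0)
  phi <- predict(f, alpha = alpha0, type = "draws")
  expect_equal(unname(phi[1, ]), unname(alpha0 / 24), tolerance = 1e-14)
  expect_true(all(abs(rowSums(phi) - 1) < 1e-12))
  prof <- predict(f, alpha = alpha0)
  expect_s3_class(prof, "activity_profile")
  # point-mass posterior: interval width zero
  expect_equal(prof$lower, prof$upper)
  expect_equal(sum(prof$median), 1, tolerance = 1e-12)
})

test_that("nocturnality combines night and deep night", {
  expect_equal(nocturnality(rep(0.2, 5)), 0.4)
  expect_equal(nocturnality(c(day = 0.5, dawn = 0.25, dusk = 0.25,
                              night = 0, deep_night = 0)), 0)
  set.seed(2)
  phi <- softmax_rows(matrix(rnorm(40), 8, 5))
  colnames(phi) <- diel_categories()
  expect_true(all(nocturnality(phi) >= 0 & nocturnality(phi) <= 1))
  expect_equal(nocturnality(phi), phi[, 4] + phi[, 5])
})

test_that("odds ratios are exactly 1 under null effects or zero shift", {
  f <- point_fit(matrix(0, 2, 4), matrix(0, 2, 4), covariates = covs2,
                 city_levels = c("c1", "c2"), mean_alpha = alpha0)
  or <- odds_ratio(f)
  expect_equal(or$median, rep(1, 4), tolerance = 1e-14)
  expect_false(any(or$excludes_one))
  # strong effect, zero shift: still exactly 1 per draw
  bpos <- matrix(0, 2, 4); bpos[2, 3] <- 1.5
  f2 <- point_fit(bpos, matrix(0, 2, 4), covariates = covs2,
                  city_levels = c("c1", "c2"), mean_alpha = alpha0)
  or0 <- odds_ratio(f2, covariates = "pop_density", shift = 0)
  expect_equal(or0$median, 1, tolerance = 1e-14)
  expect_equal(or0$lower, or0$upper)
})

test_that("odds ratios match a brute-force computation over draws", {
  set.seed(77)
  pn <- dieltrsf:::param_names(covs2, c("c1", "c2"), diel_categories())
  draws <- matrix(rnorm(60 * length(pn), 0, 0.4), 60, length(pn),
                  dimnames = list(NULL, pn))
  draws[, "pi"] <- runif(60, 0.5, 5)
  draws[, grep("^tau", pn)] <- rgamma(60 * 4, 2, 1)
  f <- fake_fit(draws, covs2, c("c1", "c2"), alpha0)
  got <- odds_ratio(f, covariates = "greenspace", shift = 1)
  # independent brute force straight from the model equations
  ors <- vapply(seq_len(60), function(r) {
    lam0 <- log(alpha0)
    lam1 <- log(alpha0)
    for (k in 1:4) {
      cat <- diel_categories()[k + 1]
      bg <- draws[r, sprintf("beta[greenspace,%s]", cat)]
      m <- draws[r, sprintf("mu[%s]", cat)]
      lam0[k + 1] <- lam0[k + 1] + m
      lam1[k + 1] <- lam1[k + 1] + m + bg * 1
    }
    p0 <- exp(lam0) / sum(exp(lam0)); p1 <- exp(lam1) / sum(exp(lam1))
    n0 <- p0[4] + p0[5]; n1 <- p1[4] + p1[5]
    (n1 / (1 - n1)) / (n0 / (1 - n0))
  }, 0)
  expect_equal(got$median, unname(quantile(ors, 0.5)), tolerance = 1e-10)
  expect_equal(got$lower, unname(quantile(ors, 0.025)), tolerance = 1e-10)
  expect_equal(got$upper, unname(quantile(ors, 0.975)), tolerance = 1e-10)
})

test_that("strong positive night selection yields OR > 1 excluding 1", {
  bpos <- matrix(0, 2, 4); bpos[2, 3] <- 1.2  # pop_density -> night
  f <- point_fit(bpos, matrix(0, 2, 4), covariates = covs2,
                 city_levels = c("c1", "c2"), mean_alpha = alpha0)
  or <- odds_ratio(f, covariates = "pop_density")
  expect_true(all(or$median > 1))
  expect_true(all(or$excludes_one))
  expect_gt(or$median[or$shift == 2], or$median[or$shift == 1])
})

test_that("nocturnality used in odds ratios equals the prediction path", {
  bpos <- matrix(rnorm(8, 0, 0.3), 2, 4)
  f <- point_fit(bpos, matrix(0.1, 2, 4), covariates = covs2,
                 city_levels = c("c1", "c2"), mean_alpha = alpha0)
  p0 <- nocturnality(predict(f, alpha = alpha0, type = "draws"))[1]
  x1 <- c(greenspace = 1)
  p1 <- nocturnality(predict(f, newdata = x1, alpha = alpha0, type = "draws"))[1]
  manual <- (p1 / (1 - p1)) / (p0 / (1 - p0))
  or <- odds_ratio(f, covariates = "greenspace", shift = 1)
  expect_equal(or$median, manual, tolerance = 1e-12)
})

test_that("city summaries: identical intercepts give identical profiles", {
  b <- matrix(rep(c(0.4, -0.2, 0.9, 0.1), each = 3), 3, 4)  # all cities equal
  f <- point_fit(matrix(0, 2, 4), b, mu = c(0.4, -0.2, 0.9, 0.1),
                 covariates = covs2, city_levels = c("c1", "c2", "c3"),
                 mean_alpha = alpha0)
  ca <- city_activity(f, alpha = alpha0)
  m <- reshape(ca[, c("level", "category", "median")], idvar = "level",
               timevar = "category", direction = "wide")
  for (i in 2:4) expect_equal(unname(unlist(m[1, -1])), unname(unlist(m[i, -1])),
                              tolerance = 1e-12)
  # medians per level sum to ~1
  sums <- tapply(ca$median, ca$level, sum)
  expect_true(all(abs(sums - 1) < 1e-10))
})

test_that("among-city predictive intervals widen as precision drops", {
  set.seed(42)
  pn <- dieltrsf:::param_names(covs2, "c1", diel_categories())
  base <- matrix(0, 500, length(pn), dimnames = list(NULL, pn))
  base[, "pi"] <- 1
  tight <- base; tight[, grep("^tau", pn)] <- 100
  loose <- base; loose[, grep("^tau", pn)] <- 0.25
  f_t <- fake_fit(tight, covs2, "c1", alpha0)
  f_l <- fake_fit(loose, covs2, "c1", alpha0)
  set.seed(1); pt <- predict(f_t, alpha = alpha0, level = "new_city")
  set.seed(1); pl <- predict(f_l, alpha = alpha0, level = "new_city")
  expect_gt(mean(pl$upper - pl$lower), mean(pt$upper - pt$lower))
})

test_that("site tables rank sites by nocturnality with correct sign", {
  bpos <- matrix(0, 2, 4); bpos[2, 3] <- 1  # pop_density selects night
  f <- point_fit(bpos, matrix(0, 1, 4), covariates = covs2,
                 city_levels = "c1", mean_alpha = alpha0)
  one <- site_activity(f, data.frame(site_id = "s1", greenspace = 0,
                                     pop_density = 0))
  expect_identical(nrow(one), 1L)
  expect_identical(one$rank, 1L)
  two <- site_activity(f, data.frame(site_id = c("lo", "hi"),
                                     greenspace = 0, pop_density = c(-1, 1)))
  expect_identical(two$site_id, c("lo", "hi"))
  expect_lt(two$nocturnality[1], two$nocturnality[2])
  expect_equal(attr(two, "range"), range(two$nocturnality))
  # direct sign check on the probabilities themselves
  expect_gt(two$phi_night[2], two$phi_night[1])
  # sites with missing covariates are listed and excluded
  expect_message(
    part <- site_activity(f, data.frame(site_id = c("ok", "bad"),
                                        greenspace = c(0, NA),
                                        pop_density = 0)), "bad")
  expect_identical(part$site_id, "ok")
  expect_error(predict(f, level = "nowhere"), "unknown city")
})

test_that("exponentiated coefficients read as selection on synthetic truth", {
  bpos <- matrix(0, 2, 4)
  bpos[1, 3] <- -0.8  # greenspace avoids night
  bpos[2, 3] <- 0.9   # pop_density selects night
  f <- point_fit(bpos, matrix(0, 1, 4), covariates = covs2,
                 city_levels = "c1", mean_alpha = alpha0)
  co <- coef(f)
  expect_gt(exp(co["pop_density", "night"]), 1)
  expect_lt(exp(co["greenspace", "night"]), 1)
})
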