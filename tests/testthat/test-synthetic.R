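# Synthetic-data generator: design ranges, determinism, agreement between
# the generative code and the model equations, and round-trip processing.

test_that("default truth reproduces the multi-city design ranges", {
  net <- simulate_sites(sim_truth(seed = 4))
  counts <- table(net$sites$city_id)
  expect_identical(length(counts), 10L)
  expect_true(all(counts >= 24 & counts <= 113))
  expect_true(all(net$sites$lat >= 30 & net$sites$lat <= 45))
  expect_true(all(net$covariates$greenspace >= 0 & net$covariates$greenspace <= 1))
  expect_true(all(net$covariates$pop_density > 0))
  # temperature series covers every city and day with a seasonal cycle
  expect_identical(nrow(net$temperature), 10L * 730L)
  by_month <- tapply(net$temperature$tavg_c,
                     format(as.Date(net$temperature$date), "%m"), mean)
  expect_gt(by_month["07"], by_month["01"])
  expect_identical(attr(net$sites, "seed"), 4L)
})

test_that("generation is deterministic under a fixed seed", {
  truth <- recovery_truth()
  n1 <- simulate_sites(truth); n2 <- simulate_sites(truth)
  expect_identical(n1, n2)
  d1 <- simulate_detections(truth, n1)
  d2 <- simulate_detections(truth, n2)
  expect_identical(d1, d2)
  d3 <- simulate_detections(truth, n1, seed = truth$seed + 5L)
  expect_false(identical(d1$ledger$timestamp, d3$ledger$timestamp))
})

test_that("zero covariate spread makes scaling fail as specified", {
  flat <- sim_truth(n_cities = 2, sites_per_city = 3,
                    start = "2017-06-01", end = "2017-06-05",
                    between_city_sd = 0, within_city_sd = 0,
                    events_per_site_day = 1, seed = 9)
  net <- simulate_sites(flat)
  expect_true(all(tapply(net$covariates$greenspace, net$covariates$city_id,
                         function(x) diff(range(x))) == 0))
  expect_error(simulate_detections(flat, net), "zero global standard deviation")
})

test_that("null truth yields availability-proportional category frequencies", {
  truth <- null_truth(events_per_site_day = 2, n_days = 100)
  net <- simulate_sites(truth)
  det <- simulate_detections(truth, net)
  led <- det$ledger
  expect_gt(nrow(led), 8000)
  A <- as.matrix(led[, paste0("alpha_", diel_categories())])
  P <- A / rowSums(A)           # per-event availability shares
  expected <- colSums(P)
  se <- sqrt(colSums(P * (1 - P)))
  observed <- as.numeric(table(led$category))
  expect_true(all(abs(observed - expected) <= 3 * se))
})

test_that("dedupe + categorize round-trips the generator ledger exactly", {
  truth <- recovery_truth()
  net <- simulate_sites(truth)
  det <- simulate_detections(truth, net)
  st <- dedupe_events(det$photos)
  ev <- assign_categories(st, net$sites)
  led <- det$ledger[order(det$ledger$station_id, det$ledger$timestamp), ]
  expect_identical(nrow(ev), nrow(led))
  expect_identical(as.numeric(ev$timestamp), as.numeric(led$timestamp))
  expect_identical(as.character(ev$category), as.character(led$category))
  expect_equal(ev$alpha_night, led$alpha_night, tolerance = 1e-12)
  expect_identical(ev$n_photos, led$n_photos)
})

test_that("strong nocturnal selection shows up along the covariate gradient", {
  bpos <- matrix(0, 2, 4, dimnames = list(c("greenspace", "pop_density"), NULL))
  bpos["pop_density", 3] <- 1
  truth <- sim_truth(n_cities = 5, sites_per_city = 10,
                     start = "2017-04-01", end = "2017-05-20",
                     beta = bpos, tau = rep(25, 4),
                     events_per_site_day = 1, seed = 55)
  det <- simulate_detections(truth, simulate_sites(truth))
  led <- det$ledger
  site_noct <- tapply(led$category %in% c("night", "deep_night"), led$site_id, mean)
  site_pop <- tapply(led$pop_density, led$site_id, mean)
  expect_gt(cor(site_noct, site_pop[names(site_noct)], method = "spearman"), 0)
})

test_that("the generating parameters beat perturbed ones in likelihood", {
  truth <- recovery_truth()
  net <- simulate_sites(truth)
  det <- simulate_detections(truth, net)
  led <- det$ledger
  d <- trsf_data(as.matrix(led[, truth$covariates]), led$category,
                 as.matrix(led[, paste0("alpha_", diel_categories())]),
                 led$city_id)
  tp <- trsf_params(truth$beta, net$b[levels(factor(led$city_id)), ],
                    truth$mu, truth$tau, 1)
  ll0 <- trsf_loglik(d, tp)
  set.seed(31)
  for (r in 1:20) {
    pp <- tp
    idx <- sample.int(length(pp$beta), 1)
    pp$beta[idx] <- pp$beta[idx] + sample(c(-1, 1), 1)
    expect_gt(ll0, trsf_loglik(d, pp))
  }
})

test_that("recovery reports are reproducible and carry convergence records", {
  truth <- sim_truth(n_cities = 3, sites_per_city = 4,
                     start = "2017-06-01", end = "2017-06-20",
                     beta = matrix(c(0.4, 0, 0.3, 0.2), 1, 4,
                                   dimnames = list("pop_density", NULL)),
                     events_per_site_day = 1, seed = 14)
  ctrl <- trsf_control(n_chains = 2, burn_in = 300, thin = 1, kept_total = 400)
  r1 <- recovery_experiment(truth, ctrl, n_replicates = 2, seed = 6)
  r2 <- recovery_experiment(truth, ctrl, n_replicates = 2, seed = 6)
  expect_identical(r1$details, r2$details)
  expect_identical(nrow(r1$replicates), 2L)
  expect_true(all(c("rhat_max", "converged") %in% names(r1$replicates)))
  expect_true(all(r1$details$parameter == rep(
    sprintf("beta[pop_density,%s]", diel_categories()[-1]), 2)))
})
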