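test_that("event times invert the cumulative hazard: null-effect closed form", {
  # with eta = 0 and slope 5, D = sqrt(2E/5) so E[D^2] = 2/5
  scn <- sim_scenario(n = 10000, p = 8, alpha_true = rep(0, 8),
                      beta_true = rep(0, 8), gamma_true = 0,
                      theta_true = c(0, 0), censor_upper = 1e9, seed = 41)
  dat <- simulate_survmed(scn)
  expect_lt(abs(mean(dat$time^2) - 0.4), 0.02)
  expect_equal(attr(dat, "censoring_rate"), 0)    # c -> infinity limit
  # Kolmogorov-Smirnov against the closed-form null survival exp(-2.5 t^2)
  ks <- suppressWarnings(stats::ks.test(dat$time, function(q) 1 - exp(-2.5 * q^2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("mediator marginals match their design moments", {
  scn <- sim_scenario(n = 20000, p = 8, censor_upper = 2, seed = 42)
  dat <- simulate_survmed(scn)
  # E[M_k] = E[c_k] + alpha_k 0.6 + 0.4 (0.3 + 0.5); c_k is one fixed draw
  ck_expect <- 0.25
  for (k in c(1, 5, 7)) {
    mu <- ck_expect + scn$alpha_true[k] * 0.6 + 0.4 * 0.8
    expect_lt(abs(mean(dat$mediators[, k]) - mu), 0.2)
  }
  v1 <- var(dat$mediators[, 1])
  expect_lt(abs(v1 - (1 + 1 * 0.24 + 0.16 * (0.21 + 1 / 12))), 0.1)
})

test_that("equicorrelated mediator errors hit the requested correlation", {
  scn <- sim_scenario(n = 4000, p = 12, alpha_true = rep(0, 12),
                      beta_true = c(1, rep(0, 11)), mediator_correlation = 0.5,
                      censor_upper = 2, seed = 43)
  dat <- simulate_survmed(scn)
  cors <- cor(dat$mediators[, 2:6])
  expect_lt(max(abs(cors[upper.tri(cors)] - 0.5)), 0.06)
})

test_that("censoring calibration reaches its target and is monotone in c", {
  scn <- sim_scenario(n = 500, p = 8, seed = 44)
  c15 <- calibrate_censoring(scn, 0.15)
  c50 <- calibrate_censoring(scn, 0.50)
  expect_lt(c50, c15)                              # heavier censoring, smaller c
  expect_identical(calibrate_censoring(scn, 0.15), c15)  # reproducible
  for (target in c(0.15, 0.50)) {
    cc <- if (target == 0.15) c15 else c50
    rates <- vapply(1:30, function(r) {
      scn2 <- scn; scn2$censor_upper <- cc
      attr(simulate_survmed(scn2, seed = 600 + r), "censoring_rate")
    }, numeric(1))
    expect_lt(abs(mean(rates) - target), 0.015)
  }
})

test_that("realized censoring is monotone non-increasing in the upper bound", {
  scn <- sim_scenario(n = 3000, p = 8, seed = 45)
  rates <- vapply(c(0.3, 0.7, 1.5, 3), function(cc) {
    scn2 <- scn; scn2$censor_upper <- cc
    attr(simulate_survmed(scn2, seed = 45), "censoring_rate")
  }, numeric(1))
  expect_true(all(diff(rates) <= 0))
})

test_that("selection scoring follows the TPR/FP/FDP definitions", {
  expect_equal(score_selection(1:4, 1:4, 100), tibble::tibble(tpr = 1, fp = 0, fdp = 0))
  expect_equal(score_selection(integer(), 1:4, 100),
               tibble::tibble(tpr = 0, fp = 0, fdp = 0))
  expect_equal(score_selection(c(1:4, 9), 1:4, 100),
               tibble::tibble(tpr = 1, fp = 1, fdp = 0.2))
  expect_equal(score_selection(c(7, 8), 1:4, 100)$fdp, 1)
  expect_error(score_selection(1:2, integer(), 100), class = "ahazmed_bad_arg")
  expect_error(score_selection(101, 1:4, 100), "out of")
})

test_that("datasets and studies are deterministic given the seed", {
  scn <- sim_scenario(n = 80, p = 10, censor_upper = 1.5, seed = 46)
  d1 <- simulate_survmed(scn)
  d2 <- simulate_survmed(scn)
  expect_identical(d1$time, d2$time)
  expect_identical(d1$mediators, d2$mediators)
  st1 <- run_sim_study(scn, n_replicates = 3, nlambda = 20)
  st2 <- run_sim_study(scn, n_replicates = 3, nlambda = 20)
  expect_identical(st1$selection, st2$selection)
})

test_that("a single replicate returns its raw scores", {
  scn <- sim_scenario(n = 150, p = 12, censor_upper = 1.5, seed = 47)
  st <- run_sim_study(scn, n_replicates = 1, nlambda = 20)
  bh <- dplyr::filter(st$selection, adjust == "bh")
  expect_equal(bh$n_replicates, 1L)
  expect_true(bh$tpr %in% c(0, 0.25, 0.5, 0.75, 1))
})

test_that("scenario invariants: defaults encode the stated generating design", {
  scn <- sim_scenario(n = 500, p = 10000)
  expect_equal(scn$alpha_true[1:8], c(1, 1, 1, 1, 0.5, 0.5, 0, 0))
  expect_equal(scn$beta_true[1:8], c(1, 1, 1, 1, 0, 0, 0.5, 0.5))
  expect_true(all(scn$alpha_true[9:10000] == 0))
  expect_equal(scn$truth, 1:4)
  expect_equal(scn$gamma_true, 1)
  expect_equal(scn$theta_true, c(0.4, 0.4))
  expect_equal(scn$baseline_slope, 5)
  expect_equal(scn$exposure_prob, 0.6)
  expect_equal(scn$intercept_range, c(0, 0.5))
})
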