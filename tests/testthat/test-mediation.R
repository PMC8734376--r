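test_that("Sobel test reproduces closed-form cases", {
  # null point: ie = 0, se = sqrt(0 + 4*1) = 2, p = 1
  r0 <- sobel_test(2, 0.5, 0, 1)
  expect_equal(r0$ie_hat, 0)
  expect_equal(r0$sobel_se, 2)
  expect_equal(r0$p_raw, 1)
  # symmetric case
  r1 <- sobel_test(1, 0.5, 1, 0.5)
  expect_equal(r1$sobel_se, sqrt(0.5), tolerance = 1e-10)
  expect_equal(r1$statistic, sqrt(2), tolerance = 1e-10)
  expect_equal(r1$p_raw, 2 * (1 - pnorm(sqrt(2))), tolerance = 1e-10)
  expect_equal(round(r1$p_raw, 5), 0.1573)
})

test_that("Sobel p is symmetric in the two paths and monotone in the SEs", {
  a <- sobel_test(1.2, 0.3, -0.7, 0.5)
  b <- sobel_test(-0.7, 0.5, 1.2, 0.3)
  expect_equal(a$p_raw, b$p_raw)
  expect_equal(a$sobel_se, b$sobel_se)
  doubled <- sobel_test(1.2, 0.6, -0.7, 1.0)
  expect_equal(doubled$sobel_se, 2 * a$sobel_se)
  expect_gt(doubled$p_raw, a$p_raw)
})

test_that("degenerate Sobel variance is handled per contract", {
  expect_equal(sobel_test(0, 0, 0, 0)$p_raw, 1)
  expect_error(sobel_test(1, 0, 1, 0), class = "ahazmed_degenerate")
  expect_error(sobel_test(1, -0.1, 1, 0.5), "nonnegative")
})

test_that("BH/BY adjustment matches hand-computed step-up values", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "bh"), c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(0.04, "bh"), 0.04)
  expect_equal(adjust_pvalues(0.04, "by"), 0.04)     # harmonic sum = 1 at m = 1
  p <- c(0.001, 0.01, 0.04, 0.2, 0.9)
  bh <- adjust_pvalues(p, "bh"); by <- adjust_pvalues(p, "by")
  expect_true(all(by >= bh))
  expect_true(all(bh >= p))
  expect_equal(by, pmin(1, bh * sum(1 / seq_along(p))))
  expect_identical(adjust_pvalues(numeric(), "bh"), numeric())
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")
  # adjustment preserves the ordering of the raw p values
  expect_identical(order(bh), order(p))
})

test_that("joint significance test is the maximum of the two path p values", {
  expect_equal(joint_significance_test(0.01, 0.2), 0.2)
  expect_equal(joint_significance_test(0, 0), 0)
  expect_equal(joint_significance_test(c(0.3, 0.5), c(0.4, 0.2)), c(0.4, 0.5))
})

test_that("alpha-path OLS handles exact, noisy and degenerate designs", {
  df <- data.frame(time = rep(1:4, 5), status = rep(1, 20),
                   exposure = rep(c(0, 1), 10))
  df$M1 <- 2 * df$exposure
  df$M2 <- rnorm(20)
  dat <- survmed_data(df, mediator_prefix = "M")
  f <- fit_alpha(dat, 1)
  expect_equal(f$alpha_hat, 2)
  expect_equal(f$alpha_se, 0)
  expect_true(f$degenerate)
  # permutation invariance
  perm <- sample(20)
  dat_p <- survmed_data(df[perm, ], mediator_prefix = "M")
  expect_equal(fit_alpha(dat_p, 2)$alpha_hat, fit_alpha(dat, 2)$alpha_hat)
  # constant exposure is not identified
  df$exposure <- 1
  expect_error(fit_alpha(survmed_data(df, mediator_prefix = "M"), 1), "constant")
})

test_that("alpha estimates recover the truth at the nominal rate", {
  hits <- vapply(1:200, function(r) {
    scn <- sim_scenario(n = 120, p = 2, alpha_true = c(1, 0), beta_true = c(1, 0),
                        censor_upper = 2, seed = 300 + r)
    dat <- simulate_survmed(scn)
    f <- fit_alpha(dat, 1)
    abs(f$alpha_hat - 1) <= 3 * f$alpha_se
  }, logical(1))
  expect_gte(mean(hits), 0.97)
})

test_that("refit_and_test produces coherent mediation records", {
  dat <- toy_data(n = 250, p = 8, seed = 31)
  rec <- refit_and_test(dat, s2 = c(1, 3))
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$ie_hat, rec$alpha_hat * rec$beta_hat)
  expect_equal(rec$sobel_se^2,
               rec$alpha_hat^2 * rec$beta_se^2 + rec$beta_hat^2 * rec$alpha_se^2)
  expect_true(all(rec$p_bh >= rec$p_raw - 1e-15))
  expect_true(all(rec$p_by >= rec$p_bh - 1e-15))
  expect_equal(rec$ci_low, rec$ie_hat - qnorm(0.975) * rec$sobel_se,
               tolerance = 1e-3)
  # the true mediator (alpha = beta = 1) carries a CI covering 1
  expect_lt(rec$ci_low[1], 1); expect_gt(rec$ci_high[1], 1)
})

test_that("empty and oversized selections short-circuit correctly", {
  dat <- toy_data(n = 60, p = 5, seed = 32)
  expect_message(rec <- refit_and_test(dat, integer()), "empty")
  expect_equal(nrow(rec), 0L)
  expect_error(refit_and_test(dat, 1:5, level = 0.05) -> x, NA) # 5 < events
  few_events <- dat
  few_events$status[-(1:4)] <- 0
  expect_error(refit_and_test(few_events, 1:5), class = "ahazmed_overselected")
})

test_that("effect decomposition is exact and behaves under contrast changes", {
  rec <- tibble::tibble(ie_hat = c(1, 1, 1, 1))     # four unit indirect paths
  d <- decompose_effects(gamma_hat = 1, records = rec, x = 0, x_star = 1)
  expect_equal(d$de, 1); expect_equal(d$ie_total, 4); expect_equal(d$te, 5)
  expect_equal(d$te, d$de + d$ie_total)
  expect_warning(d0 <- decompose_effects(1, rec, x = 1, x_star = 1), "coincide")
  expect_equal(c(d0$te, d0$de, d0$ie_total), c(0, 0, 0))
  dflip <- decompose_effects(1, rec, x = 1, x_star = 0)
  expect_equal(c(dflip$te, dflip$de, dflip$ie_total), -c(d$te, d$de, d$ie_total))
})

test_that("single-mediator naive analysis equals refit-and-test on that mediator", {
  dat <- toy_data(n = 200, p = 1, seed = 33)
  naive <- naive_mediate_ahaz(dat)
  joint <- refit_and_test(dat, 1)
  expect_equal(naive$beta_hat, joint$beta_hat)
  expect_equal(naive$alpha_hat, joint$alpha_hat)
  expect_equal(naive$p_raw, joint$p_raw)
  expect_equal(naive$p_bh, joint$p_bh)
})

test_that("all-null mediators yield essentially no BH discoveries", {
  n_disc <- vapply(1:20, function(r) {
    scn <- sim_scenario(n = 150, p = 30, alpha_true = rep(0, 30),
                        beta_true = rep(0, 30), censor_upper = 1, seed = 400 + r)
    dat <- simulate_survmed(scn)
    sum(naive_mediate_ahaz(dat)$significant)
  }, numeric(1))
  expect_lte(mean(n_disc), 0.2)
})

test_that("an outcome-only mediator is rarely declared significant", {
  sig <- vapply(1:30, function(r) {
    scn <- sim_scenario(n = 250, p = 4,
                        alpha_true = c(1, 0, 0, 0), beta_true = c(1, 0.6, 0, 0),
                        censor_upper = 1.5, seed = 500 + r)
    dat <- simulate_survmed(scn)
    rec <- refit_and_test(dat, s2 = c(1, 2))
    rec$significant[rec$index == 2]
  }, logical(1))
  expect_gte(mean(!sig), 0.9)
})
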