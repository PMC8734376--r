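test_that("b, V, D match the hand-worked two-subject example", {
  s <- ahaz_statistics(c(1, 2), c(1, 1), cbind(x = c(0, 1)))
  # risk set at t=1 is both subjects (Qbar 0.5), at t=2 only the second
  expect_equal(s$b, -0.25)
  expect_equal(drop(s$V), 0.25)
  expect_equal(drop(s$D), 0.125)
})

test_that("finite-sum b and V agree with a dense Riemann-grid oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 12 + 2 * seed
    time <- round(rexp(n, 2) + 0.05, 2)
    time[2] <- time[1]                      # force a tie
    status <- rbinom(n, 1, 0.7); status[1] <- 1
    Q <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.5))
    s <- ahaz_statistics(time, status, Q)
    o <- riemann_ahaz_statistics(time, status, Q)
    expect_equal(s$b, o$b, tolerance = 1e-8)
    expect_equal(s$V, o$V, tolerance = 1e-8)
  }
})

test_that("statistics are invariant to subject order and centering kills constants", {
  set.seed(4)
  n <- 25
  time <- rexp(n) + 0.1; status <- rbinom(n, 1, 0.6); status[1] <- 1
  Q <- cbind(x = rnorm(n), const = 1)
  s <- ahaz_statistics(time, status, Q)
  expect_equal(s$b[2], 0)
  expect_equal(s$V[2, ], c(0, 0))
  perm <- sample(n)
  s2 <- ahaz_statistics(time[perm], status[perm], Q[perm, ])
  expect_equal(s2$b, s$b)
  expect_equal(s2$V, s$V)
  expect_equal(s2$D, s$D)
})

test_that("input validation rejects degenerate survival data", {
  expect_error(ahaz_statistics(c(1, 2), c(0, 0), cbind(1:2)),
               class = "ahazmed_no_events")
  expect_error(ahaz_statistics(c(1, NaN), c(1, 1), cbind(1:2)), "NaN")
  expect_error(ahaz_statistics(c(1, -2), c(1, 1), cbind(1:2)), "positive")
})

test_that("unpenalized fit solves VP = b with a small gradient and scales correctly", {
  dat <- toy_data(n = 120, p = 4, seed = 5)
  fit <- ahaz_fit(dat, mediators_idx = 1:2)
  s <- fit$statistics
  expect_lt(max(abs(s$V %*% fit$estimates - s$b)),
            1e-8 * (1 + max(abs(s$b))))
  expect_equal(fit$std_errors, sqrt(diag(fit$covariance)), ignore_attr = TRUE)

  # scale equivariance: multiply mediator 1 by s -> estimate and SE divide by s
  sc <- 7.5
  dat2 <- dat; dat2$mediators[, 1] <- dat2$mediators[, 1] * sc
  fit2 <- ahaz_fit(dat2, mediators_idx = 1:2)
  expect_equal(fit2$estimates[["M1"]], fit$estimates[["M1"]] / sc)
  expect_equal(fit2$std_errors[["M1"]], fit$std_errors[["M1"]] / sc)
})

test_that("zero score offset gives an exactly zero estimate", {
  # two subjects tied at one event time: Qbar absorbs everything, b = 0
  s <- ahaz_statistics(c(1, 1), c(1, 1), cbind(x = c(0, 1)))
  expect_equal(s$b, 0)
  fit <- ahazmed:::fit_from_statistics(s, "mediator")
  expect_equal(unname(fit$estimates), 0)
})

test_that("scalar fit equals b/V and matches a 1-D grid minimizer of the loss", {
  set.seed(6)
  n <- 40
  time <- rexp(n) + 0.05; status <- rbinom(n, 1, 0.8); status[1] <- 1
  Q <- cbind(x = rnorm(n))
  s <- ahaz_statistics(time, status, Q)
  fit <- ahazmed:::fit_from_statistics(s, "mediator")
  expect_equal(unname(fit$estimates), s$b / drop(s$V))
  g <- seq(-5, 5, by = 1e-4)
  loss <- 0.5 * drop(s$V) * g^2 - s$b * g
  expect_equal(unname(fit$estimates), g[which.min(loss)], tolerance = 1e-3)
})

test_that("singular designs are refused with the offending column named", {
  dat <- toy_data(n = 80, p = 3, seed = 7)
  dat$mediators[, 2] <- dat$exposure          # exact collinearity
  err <- expect_error(marginal_ahaz_fit(dat, 2), class = "ahazmed_singular")
  expect_match(conditionMessage(err), "exposure|M2")
  expect_error(marginal_ahaz_fit(dat, 99), "index")
})

test_that("parameter recovery: single-regressor additive hazard, n = 2000", {
  set.seed(8)
  n <- 2000
  X <- rbinom(n, 1, 0.5)
  E <- rexp(n)
  D <- (-X + sqrt(X^2 + 10 * E)) / 5          # hazard 5t + X, gamma = 1
  s <- ahaz_statistics(D, rep(1, n), cbind(x = X))
  est <- s$b / drop(s$V)
  se <- sqrt(drop(solve(s$V) %*% s$D %*% solve(s$V)) / n)
  expect_lt(abs(est - 1), 3 * se)
})

test_that("vectorized marginal fits equal per-mediator joint fits", {
  dat <- toy_data(n = 150, p = 5, seed = 9)
  all_fits <- marginal_ahaz_all(dat)
  for (k in c(1, 3, 5)) {
    single <- marginal_ahaz_fit(dat, k)
    expect_equal(all_fits$beta_hat[k],
                 unname(single$estimates[dat$mediator_names[k]]))
    expect_equal(all_fits$beta_se[k],
                 unname(single$std_errors[dat$mediator_names[k]]))
  }
})

test_that("null mediator marginal estimates cover zero at the nominal rate", {
  # alpha_k = 0 and beta_k = 0 for the tested column; 200 seeded replicates
  hits <- vapply(1:200, function(r) {
    scn <- sim_scenario(n = 80, p = 2, alpha_true = c(1, 0), beta_true = c(1, 0),
                        censor_upper = 2, seed = r)
    dat <- simulate_survmed(scn)
    f <- marginal_ahaz_fit(dat, 2)
    abs(f$estimates[["M2"]]) <= 3 * f$std_errors[["M2"]]
  }, logical(1))
  expect_gte(mean(hits), 0.94)
})
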