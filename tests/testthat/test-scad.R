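test_that("SCAD derivative follows its three branches exactly", {
  expect_equal(scad_deriv(0.5, lambda = 1, a = 3.7), 1)
  expect_equal(scad_deriv(2, lambda = 1, a = 3.7), (3.7 - 2) / 2.7)
  expect_equal(scad_deriv(3.7, lambda = 1, a = 3.7), 0)
  expect_equal(scad_deriv(10, lambda = 1, a = 3.7), 0)
  expect_error(scad_deriv(0.5, lambda = 1, a = 2), "exceed 2")
  expect_error(scad_deriv(0.5, lambda = -1), "positive")
  expect_error(scad_deriv(-0.1, lambda = 1), "nonnegative")
})

test_that("SCAD derivative is the numerical derivative of the penalty primitive", {
  h <- 1e-6
  for (bb in c(0.3, 0.9, 1.5, 3, 4.5)) {
    num <- (scad_penalty(bb + h, 1, 3.7) - scad_penalty(bb - h, 1, 3.7)) / (2 * h)
    expect_equal(scad_deriv(bb, 1, 3.7), num, tolerance = 1e-5)
  }
})

test_that("vanishing penalty recovers the unpenalized solution", {
  set.seed(21)
  V <- crossprod(matrix(rnorm(25), 5)) / 5 + diag(5) * 0.5
  b <- rnorm(5)
  stats <- make_stats(b, V)
  fit <- ahaz_penalized_fit(stats, rep(TRUE, 5), 1e-12)
  expect_equal(drop(fit$beta), solve(V, b), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("lambda above the activation bound zeroes all penalized coefficients", {
  b <- c(0.8, -0.5, 0.3)
  stats <- make_stats(b, diag(3))
  lmax <- max(abs(b))
  fit <- ahaz_penalized_fit(stats, rep(TRUE, 3), lmax * 1.01)
  expect_equal(drop(fit$beta), c(0, 0, 0), ignore_attr = TRUE)
  # and the automatic grid starts exactly at the bound
  grid <- ahazmed:::default_lambda_grid(stats, rep(TRUE, 3))
  expect_equal(grid[1], lmax)
})

test_that("coordinate descent matches dense grid search on 2- and 3-variable problems", {
  V3 <- matrix(c(1, 0.3, 0.2,
                 0.3, 1, 0.1,
                 0.2, 0.1, 1), 3)
  b3 <- c(0.8, 0.3, -0.5)
  stats <- make_stats(b3, V3)
  for (lam in c(0.1, 0.25, 0.6)) {
    fit <- ahaz_penalized_fit(stats, rep(TRUE, 3), lam, check_objective = TRUE)
    oracle <- scad_grid_search(V3, b3, lam, lim = 1.5, step = 2e-3)
    expect_lte(penalized_objective(drop(fit$beta), V3, b3, lam),
               oracle$value + 1e-6)
  }
  V2 <- matrix(c(0.5, -0.2, -0.2, 0.8), 2)
  b2 <- c(-0.6, 0.45)
  stats2 <- make_stats(b2, V2)
  fit2 <- ahaz_penalized_fit(stats2, rep(TRUE, 2), 0.2, check_objective = TRUE)
  oracle2 <- scad_grid_search(V2, b2, 0.2, lim = 2, step = 1e-3)
  expect_lte(penalized_objective(drop(fit2$beta), V2, b2, 0.2),
             oracle2$value + 1e-6)
})

test_that("unpenalized columns are never thresholded", {
  set.seed(22)
  V <- crossprod(matrix(rnorm(16), 4)) / 4 + diag(4) * 0.3
  b <- c(1, 0.05, 0.04, 0.03)
  stats <- make_stats(b, V)
  fit <- ahaz_penalized_fit(stats, c(FALSE, TRUE, TRUE, TRUE), 5)
  expect_equal(unname(fit$beta[1, 1]), solve(V[1, 1, drop = FALSE], b[1])[1],
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(fit$beta[2:4, 1], c(0, 0, 0), ignore_attr = TRUE)
})

test_that("the lasso special case reproduces soft thresholding on a diagonal system", {
  b <- c(0.9, -0.4, 0.1)
  stats <- make_stats(b, diag(3))
  lam <- 0.3
  fit <- ahaz_penalized_fit(stats, rep(TRUE, 3), lam, penalty = "lasso")
  expect_equal(drop(fit$beta), sign(b) * pmax(abs(b) - lam, 0),
               ignore_attr = TRUE)
})

test_that("warm-started paths are continuous away from selection jumps", {
  set.seed(23)
  m <- 8
  V <- crossprod(matrix(rnorm(m * m), m)) / m + diag(m) * 0.4
  b <- rnorm(m) * 0.5
  stats <- make_stats(b, V)
  lam <- exp(seq(log(1), log(0.01), length.out = 30))
  fit <- ahaz_penalized_fit(stats, rep(TRUE, m), lam, check_objective = TRUE)
  jumps <- vapply(2:30, function(k) {
    sqrt(sum((fit$beta[, k] - fit$beta[, k - 1])^2))
  }, numeric(1))
  expect_lt(max(jumps), 1.5)
  expect_true(all(fit$converged))
})

test_that("cross-validation contract: degenerate grid, stratified folds, selection bookkeeping", {
  dat <- toy_data(n = 100, p = 10, seed = 24)
  cv1 <- cv_ahaz_scad(dat, s1 = 1:10, lambda = 0.05, seed = 3)
  expect_equal(nrow(cv1$cv_curve), 1L)
  expect_equal(cv1$lambda_star, 0.05)
  expect_true(all(cv1$selected$coefficient != 0))
  expect_setequal(cv1$selected$index,
                  cv1$screened_indices[which(cv1$coefficients != 0)])

  folds <- ahazmed:::draw_folds(dat$status, 5, seed = 9)
  expect_true(all(vapply(1:5, function(f) sum(dat$status[folds == f]) >= 1, logical(1))))
  expect_identical(folds, ahazmed:::draw_folds(dat$status, 5, seed = 9))
})

test_that("per-subject averaging makes CV invariant to duplicating the dataset", {
  dat <- toy_data(n = 60, p = 6, seed = 25)
  dup <- new_survmed_data(
    time = rep(dat$time, 2), status = rep(dat$status, 2),
    exposure = rep(dat$exposure, 2),
    covariates = dat$covariates[rep(1:60, 2), ],
    mediators = dat$mediators[rep(1:60, 2), ],
    mediator_names = dat$mediator_names
  )
  s1 <- ahaz_statistics(dat$time, dat$status, dat$mediators)
  s2 <- ahaz_statistics(dup$time, dup$status, dup$mediators)
  expect_equal(s1$b, s2$b)
  expect_equal(s1$V, s2$V)
})

test_that("CV selects the signal mediator under a modest design", {
  dat <- toy_data(n = 200, p = 15, seed = 26)
  cv <- cv_ahaz_scad(dat, sis_screen(dat, d = 8), seed = 26)
  expect_true(1L %in% cv$selected$index)
  expect_equal(cv$cv_curve$lambda[which.min(cv$cv_curve$cv_loss)],
               cv$lambda_star)
})
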