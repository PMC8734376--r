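# Independent brute-force oracles used across test files.  These deliberately
# avoid the package's telescoping/crossprod shortcuts.

# Riemann-sum evaluation of b, V over a dense time grid refined to include
# every observed time as a breakpoint (the integrand is piecewise constant
# between observed times, so midpoint evaluation on the refined grid is
# exact up to floating-point accumulation).
riemann_ahaz_statistics <- function(time, status, Q, subdivisions = 50) {
  Q <- as.matrix(Q)
  n <- length(time)
  m <- ncol(Q)
  breaks <- sort(unique(c(0, time)))
  V <- matrix(0, m, m)
  for (j in seq_len(length(breaks) - 1)) {
    lo <- breaks[j]; hi <- breaks[j + 1]
    step <- (hi - lo) / subdivisions
    mids <- lo + (seq_len(subdivisions) - 0.5) * step
    for (t in mids) {
      at_risk <- time >= t
      qbar <- colMeans(Q[at_risk, , drop = FALSE])
      for (i in which(at_risk)) {
        d <- Q[i, ] - qbar
        V <- V + step * (d %o% d)
      }
    }
  }
  b <- rep(0, m)
  for (i in which(status == 1)) {
    at_risk <- time >= time[i]
    qbar <- colMeans(Q[at_risk, , drop = FALSE])
    b <- b + (Q[i, ] - qbar)
  }
  list(b = unname(b) / n, V = unname(V) / n)
}

# Dense grid search over the penalized quadratic objective (up to 3 penalized
# coordinates).  A coarse global pass is refined around the incumbent until
# the step reaches `step`, so the final objective is resolved as finely as a
# single dense grid at that step without its memory cost.
scad_grid_search <- function(V, b, lambda, a = 3.7, lim = 3, step = 1e-3) {
  m <- length(b)
  eval_grid <- function(axes) {
    X <- as.matrix(do.call(expand.grid, axes))
    vals <- 0.5 * rowSums((X %*% V) * X) - drop(X %*% b) +
      rowSums(matrix(ahazmed::scad_penalty(abs(X), lambda, a), nrow(X)))
    k <- which.min(vals)
    list(x = unname(unlist(X[k, ])), value = vals[k])
  }
  cur_step <- (2 * lim) / 60
  best <- eval_grid(rep(list(seq(-lim, lim, by = cur_step)), m))
  while (cur_step > step) {
    cur_step <- max(step, cur_step / 10)
    axes <- lapply(best$x, function(c0) seq(c0 - 12 * cur_step, c0 + 12 * cur_step,
                                            by = cur_step))
    best <- eval_grid(axes)
  }
  best
}

penalized_objective <- function(beta, V, b, lambda, a = 3.7, penalized = rep(TRUE, length(beta))) {
  0.5 * drop(t(beta) %*% V %*% beta) - sum(b * beta) +
    sum(ahazmed::scad_penalty(abs(beta[penalized]), lambda, a))
}

make_stats <- function(b, V, terms = paste0("q", seq_along(b))) {
  structure(list(b = b, V = as.matrix(V), D = diag(length(b)),
                 n = 100L, n_events = 50L, terms = terms),
            class = "ahaz_statistics")
}

# Small dataset with fully controlled fields.
toy_data <- function(n = 60, p = 6, seed = 1, censor_upper = 2) {
  scn <- ahazmed::sim_scenario(
    n = n, p = p,
    alpha_true = c(1, rep(0, p - 1)), beta_true = c(1, rep(0, p - 1)),
    censor_upper = censor_upper, seed = seed
  )
  ahazmed::simulate_survmed(scn)
}
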