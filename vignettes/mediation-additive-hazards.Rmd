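---
title: "High-dimensional mediation analysis under the additive hazards model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{High-dimensional mediation analysis under the additive hazards model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ahazmed)
```

## The problem

Exposures such as tobacco smoking leave a broad molecular footprint — for
example on DNA methylation — and part of their effect on a survival outcome
may be transmitted through those molecular changes.  With methylation arrays
the number of candidate mediators p (CpG sites, often 10^5) vastly exceeds
the cohort size n, so the classical mediation toolkit (fit every mediator
jointly, test each product of path coefficients) is unusable as stated.
`ahazmed` implements a complete procedure for this setting built on the
*additive* hazards model, where covariate effects are hazard-rate
*differences* rather than the rate ratios of the Cox model — the natural
scale on which indirect effects decompose additively.

## Models

For subject $i$ with observed time $T_i = \min(D_i, C_i)$, event indicator
$\delta_i$, exposure $X_i$, covariates $Z_i$ and mediators $M_{ki}$:

$$\lambda_i(t) = \lambda_0(t) + \gamma X_i + \theta^T Z_i +
  \sum_{k=1}^{p} \beta_k M_{ki}, \qquad
  M_{ki} = c_k + \alpha_k X_i + \vartheta^T Z_i + e_{ki}.$$

The per-mediator indirect effect of a unit exposure contrast is
$\alpha_k \beta_k$, and the counterfactual hazard difference decomposes
exactly as
$$TE = \underbrace{\gamma(x^*-x)}_{DE} +
  \underbrace{\textstyle\sum_k \alpha_k\beta_k (x^*-x)}_{IE}.$$

Estimation of $(\gamma, \theta, \beta)$ uses the Lin–Ying least-squares-type
estimating equation: with counting process $N_i(t)$ and at-risk indicator
$Y_i(t)$, the score is $U(P) = b - VP$ with
$b = n^{-1}\sum_i \int (Q_i - \bar Q(t))\,dN_i(t)$ and
$V = n^{-1}\sum_i \int Y_i(t) (Q_i - \bar Q(t))^{\otimes 2}\,dt$, so
$\hat P$ solves the linear system $V\hat P = b$, equivalently minimises the
quadratic loss $L(P) = \tfrac12 P^TVP - b^TP$.  Both integrals are evaluated
*exactly* as finite sums over the ordered distinct observed times: the
integrands are piecewise constant between observed times, subjects tied at
a time all belong to its risk set, and integrating beyond the largest
observed time contributes nothing because every $Y_i$ is zero there.
Coefficient covariance is the sandwich $V^{-1} D V^{-1} / n$ with $D$ the
average outer product of the centered score increments at event times — the
standard variance estimator for this model.  The model itself never states
how the $\beta$-path variances should be obtained, and this choice is the
single most likely source of small numeric differences from other
implementations.

## The three-step procedure

1. **Screening** (`sis_screen()`).  Sure independence screening keeps the
   $d = [2n/\log n]$ mediators with the largest absolute Pearson
   correlation with the exposure (rounding half up; this is the only
   convention that gives $d = 248$ at $n = 833$).  The doubled subset size
   relative to the classical $[n/\log n]$ reflects that a mediator must
   carry signal on two sides at once.  An outcome-side utility — the
   standardized marginal additive-hazards coefficient — is available via
   `statistic = "marginal_hazard"` for sensitivity analysis; the
   exposure-correlation utility is the default because it is the one
   described for the real-data application, and because the appearance
   pattern of exposure-null mediators in the reference simulations is only
   consistent with it.

2. **SCAD selection** (`cv_ahaz_scad()`).  On the screened set the
   penalized quadratic loss
   $Q(\beta) = \tfrac12\beta^TV\beta - b^T\beta + \sum_j p_\lambda(|\beta_j|)$
   is minimised by cyclic coordinate descent, each coordinate solved in
   closed form by three-branch SCAD thresholding against its partial
   residual; the objective is non-increasing across sweeps (assertable via
   `check_objective = TRUE`).  $\lambda$ is chosen by 5-fold
   cross-validation (folds stratified by event status) of the
   Verweij–van Houwelingen held-out loss — full-sample loss minus
   training-fold loss on the subject-sum scale — which evaluates the
   held-out subjects inside the full sample's risk sets instead of forming
   tiny fold-only risk sets.  The grid is 50 log-spaced values from the
   activation bound $\lambda_{\max}$ (the smallest $\lambda$ zeroing every
   penalized coefficient) down to $10^{-3}\lambda_{\max}$.  $a = 3.7$ is
   the standard SCAD concavity default.  SCAD is non-convex, so the solver
   fixes the sweep order (screening-rank order) and uses a zero warm start
   at $\lambda_{\max}$ with warm-started descent, making the local solution
   reproducible.

   **Which columns are penalized.**  By default the Step-2 design contains
   the screened mediators *only* (`design = "mediators"`), each column
   penalized.  This is a deliberate choice: with the exposure held
   unpenalized in the model, the exposure coefficient absorbs the entire
   mediated signal (it tracks $\gamma + \sum_k \alpha_k\beta_k$ over the
   omitted mediators), so every true mediator competes only on the small
   residual part of its signal that is orthogonal to the exposure — and
   after correlation screening the retained null columns jointly span the
   exposure in-sample, destabilising the fit.  Measured on the built-in
   generator, that variant's true-positive rate plateaus far below what a
   working procedure should achieve.  Penalizing the mediators alone lets
   each candidate compete on its full marginal hazard signal — including
   the component transmitted from the exposure, which is precisely what
   makes a mediator worth keeping — and reproduces the selection behaviour
   the procedure is known for.  The adjusted variant remains available
   (`design = "adjusted"`, optionally `penalize_all = TRUE`) for
   sensitivity analysis.

3. **Testing and decomposition** (`refit_and_test()`,
   `decompose_effects()`).  The selected set $S_2$ is refit *unpenalized*
   jointly with exposure and covariates — penalized estimates are biased
   and carry no tractable standard error, so the refit is the
   post-selection estimate — giving $\hat\beta_k$ with sandwich SEs;
   ordinary least squares of each $M_k$ on $(1, X, Z)$ gives
   $\hat\alpha_k$.  The Sobel statistic
   $\hat\alpha_k\hat\beta_k / \sqrt{\hat\alpha_k^2\hat\sigma_{\beta_k}^2 +
   \hat\beta_k^2\hat\sigma_{\alpha_k}^2}$ is referred to the standard
   normal; p values are adjusted across the $|S_2|$ hypotheses (not all p)
   by Benjamini–Hochberg, with Benjamini–Yekutieli reported alongside for
   dependence-robust control, and mediators with adjusted p below 0.05 are
   declared significant.  Wald intervals $\hat\alpha_k\hat\beta_k \pm
   1.96\,\hat\sigma_{\alpha_k\beta_k}$ accompany each record.  TE is
   reported both as $DE + IE$ and from the mediator-free fit of the
   exposure; the two differ in finite samples and comparing them is a
   useful diagnostic.  The default exposure contrast is $x = 0 \to x^* = 1$.

Two baselines support method comparison: the *naive* method
(`naive_mediate_ahaz()`) estimates each indirect effect from its marginal
additive-hazards fit and adjusts across all p hypotheses with no selection;
the *joint-significance* variant (`test = "joint"`) replaces the Sobel p by
$\max(p_\alpha, p_\beta)$.

## The simulator

`sim_scenario()` / `simulate_survmed()` generate data from exactly the
design used to validate the procedure: $X \sim B(1, 0.6)$,
$Z_1 \sim B(1, 0.3)$, $Z_2 \sim U(0,1)$, mediator intercepts
$c_k \sim U(0, 0.5)$, errors $e_{ki} \sim N(0,1)$ (optionally
equicorrelated), hazard $\lambda(t) = 5t + X + 0.4Z_1 + 0.4Z_2 + \beta^TM$,
and effect vectors $\alpha = (1,1,1,1,0.5,0.5,0,\dots)$,
$\beta = (1,1,1,1,0,0,0.5,0.5,0,\dots)$ — so mediators 1–4 are true
(both paths nonzero), 5–6 are exposure-only, 7–8 outcome-only.  Event times
invert the cumulative hazard $\Lambda(t) = 2.5t^2 + \eta t$ at an Exp(1)
draw through the positive quadratic root; censoring is $U(0, c)$ with $c$
calibrated by root-finding on a fixed 20,000-subject Monte-Carlo batch to
hit a target rate within 0.5%.  The linear predictor $\eta$ is negative for
a vanishing fraction of subjects (the hazard is then negative near $t = 0$);
the generator accepts the inversion whenever the cumulative hazard at the
solution is nonnegative — which holds by construction — and counts redraws
otherwise, so the stated marginal structure is preserved and the redraw
rate is effectively zero at these parameter magnitudes.

`run_sim_study()` repeats generation and analysis with per-replicate seeds
derived deterministically from the master seed, scoring selection (TPR, FP
count, FDP per replicate, averaged; FDP is 0 when nothing is selected) and
per-mediator estimation (mean estimate, 95% CI coverage, empirical SE, mean
estimated SE) over the replicates in which the mediator entered $S_2$.

What the generator does *not* emulate about real methylation data: beta
values live in $[0,1]$ with heteroskedastic, non-Gaussian noise; CpG sites
are correlated in blocks rather than equicorrelated; exposure effects on
methylation are far smaller than $\alpha = 1$; and confounding is absent by
construction.  Passing tests therefore demonstrate the procedure's
operating characteristics under its stated design, not performance
guarantees on array data.

## Numerical choices

* Linear systems are solved after a reciprocal-condition-number guard at
  $10^{-12}$; failure names the offending columns.  There is no
  pseudo-inverse fallback — silent rank deficiency would corrupt every
  downstream Sobel standard error.
* Coordinate-descent convergence is the maximum absolute coefficient change,
  default `tol = 1e-7` with a 10,000-sweep budget; non-convergence warns
  and flags.  Screening ties break by ascending mediator index for
  cross-platform determinism.
* A mediator column with zero variance screens with score 0 (warning); a
  zero-curvature penalized column keeps coefficient 0.
* Degenerate Sobel variance (zero SE with nonzero estimate) is an error;
  the 0/0 null point yields p = 1.
* Folds are re-drawn (up to 10 times) until every held-out fold contains an
  event.

## Problem sizes used in the shipped studies

The packaged acceptance studies run 100 replicates per scenario at
p = 10,000 with n = 500 and n = 1,000 — the reference design at a fifth of
its original replicate count, which leaves Monte-Carlo standard errors of
roughly 0.01–0.03 on the reported proportions.  Unit and property tests use
much smaller configurations (n ≤ 600, p ≤ 1,500) chosen to exercise the same
code paths.

## Known limitations

* The procedure assumes no unmeasured confounding on any of the four
  standard identification conditions; no propensity-score adjustment is
  provided.
* Baseline hazard estimation, time-varying coefficients and time-dependent
  mediators are out of scope; so are MCP/SICA penalties, adaptive-weight or
  one-step SCAD variants, and bootstrap confidence intervals for indirect
  effects.  On the built-in generator, the exact SCAD minimiser selects
  slightly more sparsely than one-step variants with marginal initial
  estimates would, which shows up as a modestly lower true-positive rate
  and false-positive count than those variants report under identical
  conditions.
* The Sobel normal approximation is conservative near the null; with very
  few events or $|S_2|$ approaching the event count the refit is refused
  rather than regularised.
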