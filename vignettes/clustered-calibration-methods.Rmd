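---
title: "Clustered flexible calibration: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustered flexible calibration: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4.5)
library(clustercal)
```

## The problem

A clinical prediction model outputs a risk $\hat p \in (0,1)$ for a binary
outcome $y$. Calibration asks whether patients given risk $\hat p$ actually
experience the event with probability $\hat p$; a flexible calibration curve
estimates the observed proportion $P(y = 1 \mid \hat p)$ as a smooth function
of $\hat p$, and a perfectly calibrated model tracks the diagonal. In
multicenter or multi-study validation the data are clustered: event rates and
calibration differ between centers, so a single pooled curve both
misrepresents the "typical" center and hides between-center heterogeneity.

`clustercal` estimates the calibration curve of the *cluster with the average
effect* together with a confidence interval (uncertainty about that average
curve) and a prediction interval (the range in which the curve of a *new*
cluster may fall), plus cluster-specific curves. Three estimators are
provided, alongside the conventional cluster-ignorant curve (`cal_ignore()`,
a pooled logistic model with a restricted cubic spline on
$\mathrm{logit}(\hat p)$).

## The three estimators

**CG-C (`cal_cgc()`).** Grouped calibration extended to clusters. Within each
cluster the predictions are split into $Q$ groups, either per-cluster
quantiles or fixed intervals of the probability space. Each cluster-group is
summarised by its mean logit predicted risk and its logit observed
proportion with their sampling variances, and for each group the pairs are
pooled across clusters with a bivariate random-effects meta-analysis
(unstructured $2\times2$ between-cluster covariance, REML via
`metafor::rma.mv()`). The $Q$ pooled points form the curve. The within-cluster
correlation between the two summaries is not identified from the summaries
themselves; it defaults to 0 and is exposed as `rho_w`. Groups with a single
contributing cluster admit no pooling and are dropped with a warning.
Continuity corrections of 0.5 are applied only to boundary event counts
(0 or all), the smallest perturbation that keeps logits finite.

**2MA-C (`cal_2mac()`).** Two stages. Stage 1 fits a flexible curve per
cluster: either a logistic model on a restricted cubic spline of
$\mathrm{logit}(\hat p)$ with 3–5 knots chosen by sequential deviance tests
at $\alpha = 0.05$ (the smallest number of knots no larger candidate improves
upon), or a LOESS smoother of the raw 0/1 outcome with the span chosen by
bias-corrected AIC over the grid $\{0.3, 0.4, \ldots, 1.0\}$. Stage 2
evaluates every cluster curve on a fixed grid of 100 evenly spaced risks from
0.01 to 0.99 and pools the logit-scale estimates pointwise with a univariate
random-effects meta-analysis (REML $\tau^2$, DerSimonian–Laird fallback),
weighting clusters by the inverse of their delta-method variance plus
$\tau^2$. Each grid point is pooled independently — the curve is a sequence of
pointwise estimates, not a joint model — which is the approach's known
structural limitation. By default every cluster is extrapolated over the full
grid; `restrict_range = TRUE` limits each cluster to its observed risk range,
because tail extrapolation is exactly where pointwise pooling is weakest.

**MIX-C (`cal_mixc()`).** A one-stage logistic mixed model: the outcome is
regressed on a restricted cubic spline (3 knots, placed on the pooled logit
risks) of $\mathrm{logit}(\hat p)$, with a correlated random intercept and
random spline coefficients per cluster (unstructured $3\times3$ covariance
$\Sigma_u$, Laplace approximation via `lme4::glmer()`; a diagonal random
effects structure is the fallback when the unstructured fit fails). Sharing
the fixed-effect knots with the random effects keeps the cluster deviations
identified. The average-cluster curve sets the random effects to zero;
cluster curves use the empirical-Bayes modes and therefore shrink
small-cluster curves toward the average.

### Intervals

Confidence intervals are z-based on the logit scale and back-transformed.
Prediction intervals for the meta-analytic methods use the t-based form with
$k-2$ degrees of freedom, $\hat\mu \pm t_{0.975,k-2}\sqrt{\hat\tau^2 +
\widehat{se}^2}$, the standard choice for random-effects meta-analysis; with
fewer than 3 clusters the PI is reported missing rather than fabricated. For
MIX-C no closed form exists for the quantiles of an expit-transformed normal
mixture, so the PI is simulated: `n_draws` random-effect vectors from
$N(0, \hat\Sigma_u)$ (projected to the nearest positive semi-definite matrix
if necessary) plus fixed-effect draws from their asymptotic normal, with
pointwise 2.5/97.5 percentiles. Whether fixed-effect uncertainty belongs in
a PI is debatable; we include it so the PI can never undercut the CI, and we
additionally clip the PI to contain the CI. When $\hat\Sigma_u$ is
numerically zero the PI equals the CI by construction. At the default 10,000
draws the percentile noise is below ±0.005 on the probability scale.

```{r example}
d <- make_fixture("heterogeneous", n_clusters = 10, n_per = 300, seed = 1)
curve <- suppressWarnings(cal_2mac(d, smoother = "rcs", grid_size = 50))
glance(curve)
```

```{r plot, eval = requireNamespace("ggplot2", quietly = TRUE)}
autoplot(curve, show_clusters = TRUE)
```

## The synthetic-data generator

Real multicenter validation data are rarely shareable, so the package ships
the data-generating machinery used to study the methods end to end. The
generator draws a *superpopulation*: 200 clusters of 10,000 individuals by
default, a single standard-normal linear predictor $x$ (standing in for a
combination of predictors), normal random intercepts $u_j$ per cluster, and
outcomes $y \sim \mathrm{Bernoulli}(\mathrm{expit}(\beta_0 + \beta_1 x +
u_j))$. Three targets pin the parameters down:

* **ICC** (5% or 20% in the study design): on the logit scale the residual
  variance is $\pi^2/3$, so $\sigma_u^2 = \frac{\mathrm{ICC}}{1 -
  \mathrm{ICC}}\,\pi^2/3$ in closed form (`icc_to_variance()`).
* **AUC** (0.75 or 0.9): $\beta_1$ is found by bracketed root-finding on a
  Monte-Carlo estimate of the c-statistic of the true probabilities against
  simulated outcomes, with common random numbers so the objective is smooth
  (`calibrate_slope_for_auc()`).
* **Event rate** (30% overall): $\beta_0$ by root-finding on the Monte-Carlo
  mean of the true probabilities (`calibrate_intercept_for_rate()`).

Because the marginal AUC depends weakly on the intercept, the two
root-finds are alternated for two passes, which brings both targets inside
their tolerances (±0.005 on the calibration sample). Deterministic
root-finding replaces manual trial-and-error tuning so every superpopulation
is reproducible from its seed. Validation/development scenarios are drawn by
sampling clusters and then $n_j = \lceil \mathrm{EPC} \times 1.15 /
\mathrm{prev}_j \rceil$ rows per cluster, where $\mathrm{prev}_j$ is the
cluster's realised prevalence — the ceiling guarantees at least the intended
events per cluster in expectation. A non-linear variant
(`make_nonlinear_superpopulation()`) adds a quadratic or smoothed-step term
to the true logit risk, recalibrating the intercept, to exercise smoother
flexibility beyond the logistic-linear truth.

What the generator does *not* emulate: multiple correlated predictors,
random slopes in the outcome model, non-normal cluster effects, informative
cluster sizes, or measurement error in $\hat p$. Passing tests under this
generator therefore show the estimators recover a known truth under the
stated clustered logistic designs, not that they are robust to everything
real validation data can do.

## Evaluation metrics

`msce()` is the mean squared difference between the estimated and true
observed proportions over the fixed 100-point grid (10 points for grouped
curves, which are scored at their own pooled locations), on the probability
scale. The truth is obtained by numerically inverting the (monotone)
prediction model to the predictor scale and evaluating the data-generating
model with $u = 0$ (average cluster) or $u = u_j$ (cluster-specific); if a
fitted predictor is not monotone on the probed lattice, a large-sample
empirical window estimate over the superpopulation is used instead.
`pi_coverage()` is, per grid point, the proportion of clusters whose true
cluster-specific value falls inside the PI. `run_experiment()` wires these
together for replicated scenarios and reports the conventional
median (IQR) × 100 summaries.

## Numerical choices

* Predicted risks are clipped to $[10^{-5}, 1 - 10^{-5}]$ before any logit;
  the data model is silent on exact 0/1 risks and finite logits are
  non-negotiable.
* Knot placement uses the standard quantile defaults: (0.10, 0.50, 0.90) for
  3 knots, (0.05, 0.35, 0.65, 0.95) for 4, (0.05, 0.275, 0.50, 0.725, 0.95)
  for 5.
* The 3/4/5-knot spline models are not strictly nested, so the "fewest knots
  that no larger model beats" rule is applied as deviance-difference tests
  with degrees of freedom equal to the parameter-count difference; all three
  pairwise comparisons (3–4, 3–5, 4–5) are consulted.
* LOESS uses local degree 2, tricube weights, Gaussian (least-squares) local
  fits on the raw outcome, and
  $\mathrm{AICc} = n\log\hat\sigma^2 + n(n + \mathrm{tr}L)/(n -
  \mathrm{tr}L - 2)$ with the exact smoother-matrix trace for $n \le 1500$.
* Logistic fits flag possible separation (non-convergence or a coefficient
  beyond 20) and refit with a ridge penalty of $10^{-4}$ on non-intercept
  terms so sparse clusters keep two-stage pipelines alive.
* Interval grouping is right-closed, $((g-1)/Q,\, g/Q]$ with the first
  interval including 0 — an arbitrary but documented tie-break that makes
  group membership reproducible from $\hat p$ alone.
* MIX-C defaults to the Laplace approximation (`nAGQ = 1`). Replicated
  simulation studies (`run_experiment()`) use the pure-PIRLS approximation
  (`nAGQ = 0`), which on our fixtures changes the average-cluster curve by
  well under 0.02 anywhere while cutting the fit time several-fold; the test
  suite checks this agreement directly.
* Problem sizes used by the heavier checks in the test suite: the
  superpopulation-target checks run two full-size cells (200 × 10,000); the
  diagonal-recovery study uses 50 replicates of 30 clusters × 500; the
  method-comparison study 25 replicates of the strong-clustering,
  low-discrimination, EPC 200, 30-cluster validation scenario. These match
  the scale at which the qualitative conclusions stabilise.

## Known limitations

* CG-C and 2MA-C pool grid points (or groups) independently; nothing
  enforces smoothness or even monotonicity of the pooled curve, and
  simultaneous coverage over the whole curve is not controlled.
* PI coverage is imperfect for all three estimators, especially in the tails
  of the risk distribution and with few events per cluster; between-cluster
  heterogeneity tends to be underestimated there, making PIs too narrow.
  The MIX-C PI inherits any misestimation of $\Sigma_u$.
* The empirical-window truth fallback estimates the *marginal* curve, which
  differs from the average-cluster curve when the ICC is large (Jensen gap);
  it is only used when a fitted predictor is non-monotone.
* Outcomes are binary only; survival, competing-risk and multinomial
  calibration are out of scope, as are monotonicity-constrained or penalised
  smoothers.
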