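---
title: "Panel network models for symptom dynamics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Panel network models for symptom dynamics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Adolescent internalizing symptoms (depressive problems, somatic complaints,
several anxiety subtypes) and externalizing symptoms (attention/hyperactivity,
oppositional and conduct problems) are highly comorbid and predict each other
over time. Panel studies measure such symptom scales on a few widely spaced
waves (here: three assessments roughly at ages 11, 13 and 16). `panelnets`
implements the two panel network approaches used to study these dynamics, the
centrality and stability machinery around them, and the prospective
regressions linking wave-1 executive functioning (EF) to later broadband
symptom levels — together with a synthetic cohort generator so every stage is
testable without access to a restricted cohort.

# Models

## Cross-lagged panel network (CLPN)

For a consecutive wave pair $(s, t)$ and $p$ standardized node scores, each
node $k$ at wave $t$ is regressed on *all* $p$ nodes at wave $s$ with an
$\ell_1$ penalty:

$$\hat\beta^{(k)} = \arg\min_\beta \tfrac{1}{2n}\lVert y_k - \beta_0 -
X\beta\rVert^2 + \lambda_k \lVert\beta\rVert_1 .$$

The weight matrix collects these coefficients (`weights[j, k]` = effect of
node $j$ on node $k$); its diagonal carries the autoregressive effects, and
weak coefficients are shrunk *exactly* to zero. Each outcome gets its own
penalty from seeded 10-fold cross-validation. The CLPN deliberately conflates
within- and between-person variance — it answers a prediction question, not a
within-person mechanism question.

**Penalty selection rule.** The default is the one-standard-error rule
(sparsest penalty within one SE of the minimum cross-validated MSE), with the
minimum-MSE rule available via `rule = "min"`. This was an empirical design
decision: with pure-noise outcomes, the minimum rule — ours and
`cv.glmnet`'s alike — retains at least one spurious coefficient in roughly
40–60% of regressions, which contradicts the estimator's purpose of keeping
the false-positive edge rate near zero. The 1-SE rule achieves exact sparsity
under the null at the cost of a known shrinkage bias of roughly the selected
penalty (≈0.1–0.2 on standardized data at $n = 1000$). When edge *magnitudes*
matter more than support recovery, use `rule = "min"`; when the network
topology matters, use the default.

CLPN estimation uses complete cases per wave pair; full-information maximum
likelihood (FIML) is applied only in the GVAR and the regressions, the
convention in this workflow.

## Cross-sectional Gaussian graphical models

Per wave, a partial-correlation network is selected by the extended Bayesian
information criterion over a graphical-lasso path: 100 log-spaced penalties
from the smallest penalty giving an empty graph down to 1% of it, each fitted
by block coordinate descent maximizing
$\log\det K - \mathrm{tr}(SK) - \lambda \lVert K\rVert_{1,\text{off}}$
(duality gap below $10^{-6}$ certifies each solve), and scored by

$$\mathrm{EBIC}_\gamma = -n\,(\log\det K - \mathrm{tr}(SK)) + E\log n +
4E\gamma\log p,$$

with $E$ the number of edges and $\gamma = 0.5$ by default (ties broken
toward the sparser graph). By default the distinct sparsity patterns found
along the path are refit by constrained maximum likelihood before scoring
(`refit = TRUE`): scoring the penalized estimates instead biases selection
toward denser path members whose shrinkage happens to be mild, and makes it
disagree with exhaustive enumeration of candidate supports — the refit
variant provably coincides with that enumeration whenever the true pattern
appears on the path. Input moments are Pearson correlations on complete
cases (Spearman and pairwise options exist).

## Panel GVAR with random intercepts

The within/between decomposition writes person $i$'s stacked observations as

$$y_{it} = \mu_t + b_i + w_{it}, \qquad
w_{i,t+1} = B\, w_{it} + \zeta_{it},$$

with trait intercepts $b_i \sim N(0, \Sigma_B)$, innovations
$\zeta \sim N(0, K_\zeta^{-1})$, and a stationary within-process covariance
$\Sigma_W$ solving the discrete Lyapunov equation
$\Sigma_W = B\Sigma_W B^\top + K_\zeta^{-1}$. The implied covariance between
waves $t$ and $t+d$ is $\Sigma_B + B^d \Sigma_W$. Three networks result: the
**temporal** network ($B$, lag-1 Granger-type effects), the
**contemporaneous** network (partial correlations of $K_\zeta$), and the
**between-person** network (partial correlations of $K_B = \Sigma_B^{-1}$).

Estimation is pattern-wise FIML: persons are grouped by identical
observed-cell masks, each group contributes a Gaussian log-density on its
observed cells only, and sufficient statistics per pattern make an evaluation
cost independent of $n$. The optimizer works on an unconstrained vector:
means per wave-variable cell, free entries of $B$ (spectral radius rescaled
below 0.99 inside the map rather than rejected — a smoother surface), and
each precision as log-diagonal plus free off-diagonals (indefinite proposals
are repelled by a large penalty value). Convergence requires the max-norm of
the per-person score below $10^{-5}$; a moment-based start (between
covariance from person means, $B$ from pooled OLS on within deviations) plus
seeded perturbed restarts guard against local optima.

**Prune and step-up search.** After the saturated fit, every network
parameter (entries of $B$, off-diagonals of both precisions) with a Wald $p
\ge \alpha$ (observed-information SEs) is fixed to zero and the model refitted;
then the fixed parameter with the largest significant score test
(modification index, computed from the full-parameterization gradient and
information at the restricted optimum) is freed and refitted, repeatedly,
until no candidate reaches $\alpha = .05$; a final Wald pass then removes
parameters that lost significance during the search (one round of recursive
pruning, which keeps the per-parameter false-retention rate near the nominal
level). Ties break by statistic then lexicographic name; a parameter pruned
and re-added twice terminates the search with a warning. Every decision is
recorded in a trace table.

**Fit indices.** $\chi^2 = 2(\ell_{\text{sat}} - \ell_{\text{model}})$
against the saturated reference (unstructured mean and covariance, fitted by
an EM algorithm under missingness), with the independence baseline (free
means, diagonal covariance — closed form, since the likelihood factorizes per
cell). RMSEA uses $\sqrt{\max(0, (\chi^2 - df)/(df\,n))}$ with $n$ the number
of persons; CFI and TLI are capped at 1.

## Preprocessing

`detrend_standardize()` removes, per variable, a pooled regression on wave
time and its square across all person-wave observations and divides the
residuals by their pooled (maximum-likelihood, i.e. $1/n$) standard
deviation, so every variable has pooled mean exactly 0 and pooled SD exactly
1 across waves. Detrending is dataset-level, not per person: the model itself
separates within- and between-person variance, and the transform only serves
stationarity of the mean structure. It is idempotent to $10^{-10}$. Wave
index (1, 2, 3) is the default time code — waves are the lag unit — with mean
assessment ages available via `wave_times`.

## Centrality and stability

In-/out-strength sum absolute incoming/outgoing weights (self-loops excluded
by default); bridge strength sums a node's absolute edges to other
communities. Absolute values are the default because substantively negative
edges (e.g. social phobia–conduct) would otherwise cancel; signed variants
sit behind a flag. The case-dropping bootstrap re-estimates the metric on
seeded subsamples at drop proportions 0.05–0.75 and reports the
correlation-stability (CS) coefficient: the largest proportion at which at
least 95% of bootstraps correlate ≥ 0.7 with the full-sample metric. We read
"largest" cumulatively (all smaller proportions must also pass), the
convention that makes CS monotone in the threshold; zero-variance metric
vectors count as correlation 1 when identical to the full-sample vector.

## EF scores and hierarchical regressions

`derive_ef_scores()` computes the eight task measures: fluctuation in tempo
(SD over the 50 per-series mean reaction times, $n-1$ convention) and overall
error percentage from the sustained-attention task; part 2 − part 1 (response
inhibition) and part 3 − part 1 (cognitive flexibility) differences from the
set-shifting task; part 3 − part 1 (working memory) from the memory-search
task; RT in ms and errors in %, higher always worse. Outliers are screened
per measure with a single-pass between-person $|z| \ge 4$ rule.

`hierarchical_compare()` fits the two-step models by FIML: step 1 regresses
the broadband aggregate at wave $t$ on sex and both aggregates at wave
$t-1$; step 2 adds all eight EF measures in the documented order. Estimates
come from the implied joint covariance (equal to least squares on complete
data to $10^{-8}$); standard errors use the observed information of the
joint Gaussian model via the delta method. Standardized and raw estimates
are both reported (sex stays raw, coded 0/1 with 1 = female).

# The synthetic cohort generator

The generator emulates the design the estimators target: $N = 2170$ persons,
three waves, ten symptom scales in two communities (seven
internalizing-like, three externalizing-like), monotone attrition with 96%
and 76% participation at waves 2 and 3, and weak EF–symptom effects
($|\beta| \le .07$, largest on fluctuation in tempo). The `trails_like`
template anchors means and linear/quadratic trends by fitting the quadratic
time curve exactly through published three-wave descriptive means per scale,
and scales total variance to the published SDs with a 40% between / 60%
within split — a conventional trait share for symptom scales in adolescence.
Network magnitudes are calibration choices (the source tables print no edge
weights): within-community contemporaneous partials 0.12–0.15, a depressive
hub with temporal out-edges of 0.2 to the other internalizing nodes,
reciprocal Panic–Somatic and AttHyper–Oppositional pairs of 0.15, a negative
Conduct→SocPhob edge, spectral radius rescaled below 0.9. Attrition is
wave-level (whole assessments go missing) with dropout odds increasing in
the standardized baseline symptom mean (log-odds slope 0.5 by default; the
intercept is calibrated so realized participation matches the target).

What it does **not** emulate: ordinal item-level measurement (scores are
Gaussian; optional clipping to the 0–2 scale exists to study robustness but
is off by default, since the estimators assume multivariate normality),
measurement error, informative missingness beyond the baseline-severity
mechanism, and non-stationary or nonlinear dynamics. Passing recovery tests
on this generator therefore demonstrates correctness of the estimators under
their own assumptions, not robustness to their violation.

# Numerical choices

- Lyapunov equations are solved by a doubling iteration
  ($\Sigma \leftarrow \Sigma + A\Sigma A^\top$, $A \leftarrow A^2$),
  quadratically convergent under the enforced spectral-radius guard;
  residuals are verified below $10^{-10}$.
- The FIML kernel is compiled (RcppArmadillo) and checked against a
  plain-R per-person reference implementation to $10^{-9}$.
- LASSO solving delegates to glmnet (path member read exactly, not
  interpolated; entries below $10^{-12}$ stored as exact zeros);
  $\lambda = 0$ uses exact least squares. Closed-form soft-thresholding and
  an independent coordinate-descent loop serve as test oracles.
- Graphical-lasso convergence is certified by the duality gap
  ($< 10^{-6}$); EBIC ties break toward sparsity.
- Observed information matrices use central finite differences; singular
  information falls back to a pseudo-inverse.
- Degenerate inputs error early and specifically: zero residual variance in
  detrending, singular observed submatrices in FIML (naming the pattern),
  collinear predictors in regression, unassigned community labels.

# Problem sizes

The test suite exercises the full stack at the sizes the estimators are
meant for while staying lightweight: unit tests use $p = 2$–6 and $n =$
100–1000; recovery, selection-error and fit-calibration studies use $p = 4$,
$T = 3$, $n = 2000$ with 20 replicates; the end-to-end pipeline check runs
the default $N = 2170$, $p = 10$ cohort. `scripts/acceptance.R` reruns the
same computations from scratch under a caller-supplied seed.

# Known limitations

- Lag-1 linear dynamics and approximate stationarity are assumed; processes
  on other time scales are invisible to the model.
- Wald/score inference in the prune–step-up search is asymptotic; at small
  $n$ relative to $p(p+1)$ the selection error rates degrade.
- The saturated-reference EM and the GVAR optimizer assume missingness at
  random given the observed cells.
- Scale scores are treated as continuous and error-free; latent-variable
  measurement models are out of scope.
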