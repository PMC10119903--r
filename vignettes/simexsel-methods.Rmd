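---
title: "Methods: SIMEX-corrected, selection-aware ATE estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SIMEX-corrected, selection-aware ATE estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

`simexsel` estimates the average treatment effect
$\tau_0 = E\{Y(1)\} - E\{Y(0)\}$ from observational data under three
standard causal assumptions — consistency
($Y = TY(1) + (1-T)Y(0)$), no unmeasured confounding given the covariate
vector $W = (X^\top, Z^\top)^\top$, and positivity ($0 < \pi < 1$) — plus
two complications that the package exists to handle:

* **Classical additive measurement error.** The error-prone covariates $X$
  are observed only through surrogates $X^* = X + e$ with
  $e \sim N(0, \Sigma_e)$ independent of everything else. $\Sigma_e$ is
  treated as known at estimation time; it can be supplied, estimated from
  external replicate measurements, or posited through a reliability ratio.
* **Unknown active set.** Only a subvector $W_I$ of $W$ drives treatment
  assignment: $P(T = 1 \mid W) = P(T = 1 \mid W_I)$. Which components
  belong to $W_I$ is unknown and must be learned.

The propensity is modelled parametrically,
$\pi_i = g(\gamma_0 + X_i^\top \gamma_x + Z_i^\top \gamma_z)$, with the
logistic, probit, or complementary log–log link. The estimator of $\tau_0$
is the stabilized IPW contrast, whose ratio-of-weighted-sums form keeps the
weights summing to one in each arm and is the variant the whole pipeline is
built around. The unstabilized form is available for comparison; the two
agree when the fitted propensity equals the treated fraction for everyone.

## The five-step procedure

1. **Simulation.** Draw $e_{ik} \sim N(0, \Sigma_e)$ once per subject and
   replicate ($k = 1..K$) and form
   $X^*_i(k,\psi) = X^*_i + \sqrt{\psi}\, e_{ik}$ for each level $\psi$ in
   the grid $C$. The draws are a deterministic function of (seed, subject,
   replicate) only: every $\psi$ level reuses them, and so does step 5.
   This sharing is a contract, not an optimization — it makes the
   coefficient-level and effect-level extrapolations consistent with each
   other.
2. **Estimation.** For each $(k, \psi)$, solve the likelihood score
   equation of the full treatment model with $X^*(k,\psi)$ in place of the
   covariates, and average over $k$:
   $\hat\gamma(\psi) = K^{-1}\sum_k \hat\gamma(k,\psi)$.
3. **Extrapolation.** Componentwise, fit a working extrapolant to
   $\{(\psi, \hat\gamma_j(\psi))\}$ and evaluate at $\psi = -1$, where the
   cumulative error variance $(1+\psi)\Sigma_e$ vanishes. The result is the
   corrected pilot $\tilde\gamma$.
4. **Selection.** Minimize the penalized quadratic loss
   $\tfrac{n}{2}(\gamma-\tilde\gamma)^\top V_n(\gamma-\tilde\gamma)
   + n\sum_{j\ge 1} p'_\lambda(|\tilde\gamma_j|)\,|\gamma_j|$ over a grid of
   $\lambda$, scoring each solution with
   $\mathrm{BIC}(\lambda) = n(\hat\gamma(\lambda)-\tilde\gamma)^\top V_n
   (\hat\gamma(\lambda)-\tilde\gamma) + 2\log(n)\,\mathrm{df}_\lambda$.
   The intercept is never penalized; covariates that must stay in the model
   get penalty weight zero.
5. **Effect estimation.** Holding the selected (shrunken) coefficients
   fixed — no refit, so the near-unbiasedness of the SCAD weights carries
   through — recompute the stabilized IPW estimate on each $X^*(k,\psi)$,
   average over $k$, and extrapolate $\{(\psi, \hat\tau(\psi))\}$ to
   $\psi = -1$.

Setting $\Sigma_e = 0$ collapses steps 1–3 and 5 to the uncorrected
analysis exactly (to solver tolerance); this collapse is asserted in the
test suite.

## Tunable parameters

| Parameter | Default | Rationale |
|---|---|---|
| $C$ (levels) | $\{0, 0.25, \dots, 2\}$ | nine levels spanning twice the nominal error variance give the extrapolant curvature to work with; the first level must be 0 |
| $K$ | 500 | replicate-averaging noise in $\hat\gamma(\psi)$ is $O(1/\sqrt{K})$; 500 makes it negligible at study sizes. Benchmarks use $K = 50$, which leaves the replicate-mean metrics essentially unchanged while cutting cost tenfold |
| extrapolant | quadratic | exact for locally quadratic attenuation trends and the most stable of the three families; rational-linear is exact for the attenuation curve of a linear model and available when that shape is expected |
| penalty | SCAD, $a = 3.7$ | derivative weights vanish beyond $a\lambda$, leaving strong pilots unshrunk (oracle behaviour); LASSO provided for comparison |
| $\Lambda$ | 50 log-spaced values on $[10^{-4}\max_j\lvert\tilde\gamma_j\rvert,\ \max_j\lvert\tilde\gamma_j\rvert]$ | the one-step threshold for component $j$ is $p'_\lambda(\lvert\tilde\gamma_j\rvert)$, so this grid runs from shrinking essentially nothing to shrinking every covariate |
| $V_n$ | identity | the easy-to-implement choice; any positive definite matrix is accepted and handled by coordinate descent |
| bootstrap $B$ | 200 | standard errors of a bootstrap SD stabilize around $B \approx 200$; the minimum accepted is 50 |

## Scaling of the selection loss

The quadratic loss in step 4 carries an explicit factor $n$. This is the
natural calibration: $(\gamma - \tilde\gamma)^\top V_n (\gamma -
\tilde\gamma)$ stands in for twice the log-likelihood drop around the
pilot, whose curvature grows like $n$, and the BIC's $2\log(n)\,
\mathrm{df}$ term is sized against exactly that scale. Without the factor
$n$ the information criterion would always prefer the empty model (a
coefficient distortion of typical size $1/\sqrt{n}$ could never pay for a
$2\log n$ df charge), and the SCAD weight $p'_\lambda(|\tilde\gamma_j|)$
would be identically zero for any $\lambda$ small enough to matter. With
it, the identity-weight solution is the soft threshold
$\hat\gamma_j = \mathrm{sign}(\tilde\gamma_j)(|\tilde\gamma_j| -
p'_\lambda(|\tilde\gamma_j|))_+$, and BIC zeroes a pilot component of
magnitude $u$ roughly when $nu^2 < 2\log n$ — the usual
$\sqrt{\log n / n}$ boundary.

Similarly, the pseudo-error scale in step 1 is $\sqrt{\psi}$, so that the
*variance* added at level $\psi$ is $\psi\Sigma_e$ and the extrapolation
target $\psi = -1$ corresponds to zero total error variance. A
`scaling = "linear"` switch (adding $\psi\,e_{ik}$) is provided for users
who want the variance scale to be $\psi^2\Sigma_e$ instead; the default is
the convention under which extrapolation to $-1$ removes the error.

## Numerical choices

* **Solver.** Fisher scoring from a zero start with step-halving on the
  log-likelihood, declared converged when
  $\lVert\text{score}\rVert_\infty < 10^{-8}$ (at most 100 iterations).
  Deterministic given the data; the zero start keeps refits across
  $(k,\psi)$ cells exchangeable.
* **Probability clipping.** Link probabilities are clipped to
  $(10^{-10}, 1-10^{-10})$ so scores and inverse weights stay finite at
  extreme linear predictors; at realistic predictors the clipping is
  inactive. Exact 0/1 propensities supplied by a user are an error, with
  the offending subject named.
* **Separation.** Diverging coefficient paths are capped at
  $\lvert\gamma_j\rvert \le 30$ with a warning. Non-converged $(k,\psi)$
  fits are dropped from the K-average; more than 10% dropped raises a
  warning, a fully failed level is an error naming $\psi$.
* **Rational-linear fits.** $f(\psi) = a + b/(c+\psi)$ is initialized from
  the exact solution through three spread points and refined by
  Levenberg–Marquardt. A fitted pole inside $[-1, \psi_{\max}]$ makes the
  extrapolation meaningless, so the fit falls back to quadratic with a
  warning; a constant trajectory short-circuits to the constant.
* **Ties and zeros.** BIC ties resolve to the larger $\lambda$ (sparser
  model); estimates below $10^{-10}$ in magnitude count as excluded for
  df, #S, and the active set. An intercept-only selection proceeds with a
  constant propensity and says so.
* **Reproducibility.** Every stochastic component (pseudo-errors, synthetic
  data, bootstrap, benchmark replicates) derives from explicit seeds;
  per-replicate seeds are drawn up front so benchmark results are invariant
  to execution order. Seeded helpers restore the caller's RNG stream.

## The synthetic-data generator

`simulation_design()` emulates a covariate-rich observational study:
$(X, Z) \sim N(0, \Sigma_w)$ with unit variances, AR(0.5) correlation
within the error-prone and error-free blocks, and weak cross-block
covariances $0.4^{2+|j-k|}$ (read as a power; a multiplicative reading
would produce covariances above 1 and an indefinite matrix). The default
truth has 16 of 30 covariates active in treatment assignment with
coefficients $\pm 1$ and intercept 1, linear or logistic outcome models
whose coefficient on treatment is 1, and diagonal measurement error with
common variance $\sigma_e^2 \in \{0.15, 0.5, 0.75\}$. Under the linear
outcome model the true ATE is exactly 1; under the logistic outcome model
it is computed by Monte Carlo (default 5000 draws).

Two properties of the default design deserve emphasis, because they govern
what the benchmark numbers look like:

* With 16 coefficients of magnitude 1 on correlated unit-variance
  covariates, the treatment linear predictor has a standard deviation
  around 5. Treatment assignment is therefore nearly deterministic for
  most subjects, practical positivity is weak, and inverse weights are
  heavy-tailed: at $n = 400$ the replicate spread of any IPW-type estimate
  of $\tau_0$ is large (its Monte-Carlo standard error dominates small
  differences between methods), and unpenalized logistic coefficients
  carry per-component sampling errors of a few tenths, which puts a floor
  of several units under the summed L1 loss of any 31-parameter fit. The
  acceptance script reports exactly these honestly computed quantities.
* The generator draws covariates already standardized (mean 0, variance 1),
  so the pipeline's standardization step is off for synthetic data and on
  by recommendation for real data (`standardize_covariates()`).

What the generator does *not* emulate: non-normal or skewed covariates,
heteroscedastic or differential measurement error, misclassified discrete
covariates, and treatment models outside the three links. Passing tests on
this generator therefore demonstrates internal correctness of the
machinery under the stated design, not robustness to those violations.

## Measurement-error covariance inputs

* **Replicates.** With external replicate measurements, $\Sigma_e$ is the
  pooled within-subject covariance
  $\sum_i\sum_k (x_{ik}-\bar x_i)(x_{ik}-\bar x_i)^\top / \sum_i (n_i-1)$,
  assembled block-diagonally across variable groups. Subjects with fewer
  than two replicates are dropped with a warning.
* **Reliability.** Given $R_{ij} = \sigma_{X,ij}/\sigma_{X^*,ij}$, the
  entries are $\sigma_{e,ij} = (R_{ij}^{-1}-1)\sigma_{X,ij}$; when only the
  surrogate covariance is observable, $\Sigma_X$ is taken as a shrunken
  copy of it (default factor 0.9 — a parameter, not a constant, since
  true-score covariances are smaller than surrogate ones by an unknown
  amount). The sweep interface scans a set of plausible $R$ values;
  $R = 1$ reproduces the naive analysis, which is a useful anchor row.
* Either route ends in a symmetry/PSD check with eigenvalue clipping at
  zero (warned) as the repair.

## Design decisions on open points

* Only likelihood scores are implemented as the estimating function of the
  treatment model; the machinery would accept any unbiased estimating
  function, but none is exposed.
* The number of selected covariates `#S` counts non-intercept components
  (the true active count of the default design is 16); conventions that
  count the intercept read one higher.
* Coverage rates use bootstrap intervals. Re-running a five-step pipeline
  inside every bootstrap replicate of every benchmark replicate is
  expensive, so interval computation is off by default in
  `run_benchmark()` and coverage is a reported, demonstration-scale
  quantity rather than an asserted one.
* Step 5 reuses the shrunken step-4 coefficients as printed; `refit = TRUE`
  refits the unpenalized model on the active set first, and is off by
  default.
* No propensity trimming by default — the stabilized estimator is the
  guard against extreme weights; `[0.01, 0.99]` flags are logged so users
  can judge practical positivity.

## Known limitations

* The asymptotic variance of the five-step estimator is not implemented;
  uncertainty is bootstrap-only, and bootstrap intervals inherit the
  heavy-tailed behaviour of IPW under weak overlap.
* The extrapolation families are working approximations; when the true
  attenuation trend is none of the three, the corrected estimator is only
  approximately consistent, and the choice of family matters more as
  $\Sigma_e$ grows.
* Discrete error-prone covariates (misclassification) and
  machine-learning propensity models are out of scope.
* Under designs with near-deterministic assignment (see above), IPW-type
  estimates are intrinsically unstable at moderate n regardless of the
  correction; diagnosing overlap before trusting any ATE estimate is the
  user's responsibility.
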