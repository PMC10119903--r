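# simexsel

Estimation of the average treatment effect (ATE) from observational data
when two practical problems strike at once:

1. some pre-treatment confounders are **measured with error** — only
   surrogates `X* = X + e`, `e ~ N(0, Σe)`, are observed — and
2. it is unknown **which covariates actually drive treatment assignment**,
   so the propensity model must be selected, not assumed.

Ignoring either feature biases the usual inverse-probability-weighted (IPW)
estimator: measurement error attenuates the propensity coefficients, and
irrelevant covariates inflate the variability of the weights. `simexsel` is
aimed at biostatisticians and epidemiologists who need both corrections in
one coherent procedure, with simulation tooling to study its finite-sample
behaviour.

## The estimator

For subject *i* with binary treatment `T_i`, outcome `Y_i`, error-prone
covariates `X_i` (observed as `X_i*`) and error-free covariates `Z_i`, the
propensity score is modelled parametrically,
`π_i = g(γ0 + X_iᵀγx + Z_iᵀγz)` with a logistic, probit, or complementary
log–log link `g`. The target is `τ0 = E{Y(1)} − E{Y(0)}`, estimated by the
stabilized IPW contrast

```
τ̂ = (Σ T_i/π̂_i)⁻¹ Σ T_i Y_i/π̂_i − (Σ (1−T_i)/(1−π̂_i))⁻¹ Σ (1−T_i) Y_i/(1−π̂_i).
```

Five steps produce a measurement-error-corrected, confounder-selected τ̂:

1. **Simulation.** For levels `ψ ∈ C = {0, 0.25, …, 2}` and replicates
   `k = 1..K`, build pseudo-contaminated surrogates
   `X*(k,ψ) = X* + √ψ · e_ik`, `e_ik ~ N(0, Σe)`, so the cumulative error
   variance is `(1+ψ)Σe`.
2. **Estimation.** Refit the full treatment model on each `X*(k,ψ)` by
   solving the likelihood score equation; average the coefficients over k
   to get `γ̂(ψ)`.
3. **Extrapolation.** Fit a working extrapolant (quadratic, linear, or
   rational-linear) to each coefficient trajectory `{(ψ, γ̂_j(ψ))}` and
   evaluate it at `ψ = −1` (zero error variance), giving the corrected
   pilot `γ̃` (the SIMEX idea of Cook & Stefanski).
4. **Selection.** Shrink `γ̃` with a one-step weighted-L1 penalty — weights
   `p'_λ(|γ̃_j|)` from the LASSO or SCAD penalty derivative — and pick λ by
   `BIC(λ) = n(γ̂(λ)−γ̃)ᵀVn(γ̂(λ)−γ̃) + 2 log(n)·df_λ`. Active covariates
   form the final treatment model.
5. **Effect estimation.** With the selected coefficients held fixed,
   recompute the stabilized IPW estimate on each `X*(k,ψ)` (same
   pseudo-errors as step 1), average over k, and extrapolate the curve
   `{(ψ, τ̂(ψ))}` to `ψ = −1`.

Uncertainty comes from a nonparametric bootstrap over subjects that re-runs
all five steps per resample. `Σe` can be supplied directly, estimated from
external replicate measurements (method of moments), or derived from an
assumed reliability ratio `R = σ_X/σ_X*` for sensitivity analysis.

## Worked example

A synthetic observational study with 8 candidate confounders (4 error-prone,
4 error-free), of which only 4 matter, measurement-error variance 0.5
(reliability 2/3), and true ATE 1:

```r
library(simexsel)

design <- simulation_design(
  n = 400, px = 4, pz = 4, sigma_e2 = 0.5,
  gamma0 = 0.3, gamma_x = c(0.8, -0.8, 0, 0), gamma_z = c(0.8, -0.8, 0, 0),
  beta_x = c(0.6, 0.6, 0, 0), beta_z = c(0.6, 0.6, 0, 0))
data <- generate_dataset(design, seed = 1)

fit <- simexsel_fit(data$sample, sigma_e = 0.5, K = 50, seed = 2,
                    boot = 100, boot_seed = 3)
fit
#> SIMEX + scad selection
#> Active covariates (4): X1, X2, Z1, Z2
#> ATE estimate: tau_hat = 1.1558
#>   bootstrap S.E. = 0.2235  95% CI = [ 0.7177 , 1.594 ]  p = 2.34e-07
#>   note: 6 propensity score(s) outside (0.01, 0.99)
```

The procedure recovers exactly the four truly active confounders and an ATE
estimate whose CI covers the truth. The correction is doing real work: the
naive analysis (`simexsel_fit(..., correct = FALSE)`) estimates the first
error-prone coefficient at 0.527 where the corrected pilot gives 0.794
(truth 0.8):

```r
naive <- simexsel_fit(data$sample, correct = FALSE)
round(c(corrected = fit$gamma_tilde[["X1"]],
        naive = naive$gamma_tilde[["X1"]], truth = 0.8), 3)
#> corrected     naive     truth
#>     0.794     0.527     0.800
```

`run_benchmark()` repeats such pipelines over replicates and tabulates
selection metrics (L1/L2 loss, #S, #FN) and estimation metrics (Bias, S.E.,
RMSE, optional bootstrap coverage) for the proposed, naive, full-model, and
true-covariate analyses. A command-line wrapper for simulation, fitting,
and benchmarking lives in `inst/cli/simexsel.R`.

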