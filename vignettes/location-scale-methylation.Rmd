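---
title: "Location-scale models for DNA methylation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Location-scale models for DNA methylation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the statistical machinery it
implements: the model family, the inference procedures, the synthetic data
the tests run on, and the numerical and design decisions that were genuinely
open. It states no empirical numbers beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The response and its transformations

Methylation at a CpG site is measured as a β-value, the proportion of
methylated signal, `max(M,0)/(max(M,0)+max(U,0)+α_β)` with a stabilising
offset `α_β = 100` (`signals_to_beta()`). β-values live in (0,1), are skewed
toward their boundary, and are heteroscedastic: their variance is largest at
intermediate methylation and shrinks toward 0 and 1. Three standard response
scales are supported (`transform_beta()`):

* **raw**: the β-value itself;
* **logit2**: `log2(y/(1-y))`, the M-value scale (`signals_to_m()` computes
  the intensity-based M-value directly; with zero offsets the two coincide);
* **arcsine**: `asin(sqrt(y))`, the classical variance-stabilising transform
  for proportions, mapping (0,1) to (0, π/2).

Exact zeros or ones (absent after standard preprocessing, but possible in
user data) are rejected by the transforms; `clamp_unit()` moves them into
(0,1) by an explicit, counted amount (default ε = 1e-6). Clamping is opt-in
by design — silent modification of a response is worse than an error.

## The eight models

Each model has two linear submodels, `g1(μ) = X1 γ1` and `g2(σ) = X2 γ2`.
Gaussian models (on any of the three response scales) use identity and log
links; beta regression uses the mean–dispersion parametrisation
`E(Y) = μ`, `Var(Y) = μ(1−μ)σ²` — equivalently shapes
`a = μ(1/σ²−1)`, `b = (1−μ)(1/σ²−1)` — with logit links for both parameters,
which keeps σ in (0,1) without constraints. "Fixed scale" means `X2` is an
intercept column only; "variable scale" regresses σ on covariates as well.
The codes `ra, lo, ar, be, ra+, lo+, ar+, be+` name the eight combinations
(`model_spec()`).

### Fitting

`methlss_fit()` maximises the joint likelihood by alternating scoring
between the submodels followed by a joint BFGS polish with analytic
gradients:

* Gaussian: γ1 by weighted least squares given σ, γ2 by a damped Newton
  step with expected information `2 X2'X2`; for fixed scale this converges in
  two sweeps and reproduces OLS with `σ̂ = sqrt(RSS/n)` exactly.
* Beta: γ1 initialised by OLS on the empirical logits, γ2 from a
  method-of-moments dispersion; two alternating quasi-Newton sweeps, then the
  joint polish.

Standard errors come from the inverse observed information at the optimum
(analytic for the Gaussian family, finite-differenced analytic gradients for
the beta family). Convergence is declared on the **Newton decrement** — the
expected log-likelihood gain of one further Newton step — below
`1e-6 · (1 + |loglik|)`. The decrement is invariant to the scale of the
covariates and the sample size, unlike a raw gradient norm, which grows with
both and would misclassify numerically converged fits. Fitting is
deterministic; there is no randomness anywhere in the optimiser.

### Inference

Wald tests (`wald_test()`, `summary()`) use the t reference with
`n − p1 − p2` degrees of freedom. At EWAS-scale n this is indistinguishable
from the normal reference; at small n it is mildly conservative, which is the
safer default.

### Diagnostics and model comparison

`residuals()` returns normalized quantile residuals
`Φ⁻¹(F(y_i; μ̂_i, σ̂_i))`, exactly the standardized residuals for Gaussian
fits; the response is continuous so no randomisation is involved. CDF values
that underflow are mapped to ±8 with a warning. `residual_normality()` wraps
the Shapiro–Wilk test.

`pseudo_r2()` implements the Cox–Snell form
`1 − exp(−2(ℓ_fit − ℓ_null)/m)` against the intercept-only model of the same
family and response scale. This likelihood-ratio form was chosen because it
accounts for the fit of the scale submodel (a correlation- or deviance-based
R² would not) and applies identically to both families; a
Nagelkerke-rescaled variant is available via `type = "nagelkerke"`. Held-out
evaluation (`split_performance()`, default 50/50 split) plugs the
training-fitted coefficients into the test-half likelihood; held-out values
can be negative.

One caveat worth knowing when comparing *across* response scales
(`benchmark_models()`): the likelihood gain `ℓ_fit − ℓ_null` is free of the
transform's Jacobian (it cancels between fit and null), so cross-scale
comparison is coherent — but a strong location effect at a boundary-near
site *induces* a scale effect on the raw scale (see the delta-method section
below), which the raw-scale variable model can legitimately absorb as extra
likelihood gain. With dominant location effects at extreme sites, `ra+` can
therefore out-tally the generating model; the benchmark's self-consistency
test uses a scale-dominant generating configuration for this reason.

## Why scale tests leak: the delta-method picture

If Y is beta with mean μ and dispersion σ, the residual scale a Gaussian
model sees on each response scale is approximately (`delta_sd()`):

| scale   | implied sd                  | depends on μ? |
|---------|-----------------------------|----------------|
| raw     | `σ √(μ(1−μ))`               | strongly       |
| logit2  | `σ / (ln2 · √(μ(1−μ)))`     | strongly       |
| arcsine | `σ / 2`                     | no             |

A covariate that shifts only μ therefore shifts the *apparent* scale on the
raw and logit2 scales — inflating the type-I error of σ-tests in `ra+` and
`lo+` — while the arcsine scale is protected. Conversely, a covariate that
shifts only σ moves the *mean* of the logit2- and arcsine-transformed
response through the distribution's skewness, inflating μ-tests most severely
for the logit-type models (`lo`, `lo+`, `be`), less for the arcsine models,
and least for raw-scale models. The simulation engine reproduces both
effects quantitatively; the acceptance suite pins them at n = 1763.

These closed forms are first-order approximations. Direct comparison with
the exact sd (trigamma identities / Monte Carlo) shows they are accurate to
~3% for raw and arcsine across μ ∈ [0.1, 0.9] and σ ≤ 0.2, and for logit2 up
to σ = 0.1; at σ = 0.2 near the boundary the logit2 form is only a ~12%
guide. The tests encode exactly these bands.

## The simulation engine

`run_error_rate_experiment()` crosses simulation settings (tested parameter;
manipulated-covariate effects `γ_μ`, `γ_σ` on the logit scale of each
parameter, per covariate unit — the study grid uses 0, 0.005 and 0.05) with
model codes. Per site it draws baselines (μ0, σ0), simulates
`Y ~ Beta(μ_i, σ_i)` with
`logit μ_i = logit μ0 + γ_μ c_i`, `logit σ_i = logit σ0 + γ_σ c_i`
(`simulate_beta_site()`), fits each model with intercept + centered
manipulated covariate in the active submodels, and tabulates the Wald
rejection proportion with its binomial Monte-Carlo SE. The "real-data"
variant reassigns caller-supplied observed responses onto the simulated
draws by rank (`rank_reassign()`), preserving the empirical marginal while
imposing the simulated dependence.

### Synthetic calibration

Real cohort-fitted per-site parameters are not shipped; the generator's
defaults are a documented calibration chosen once:

* `logit(μ0)` ~ equal mixture of N(−2.2, 0.6²) and N(+2.2, 0.6²) — a bimodal
  baseline with most sites near 10% or 90% methylation;
* `logit(σ0)` ~ N(−1.6, 0.3²) — dispersions around 0.17;
* manipulated covariate ~ N(28, 5²), BMI-like, used centered;
* non-manipulated covariates in `generate_study()` (age-like, binary
  sex-like) carry effects within the grid's moderate range.

What this emulates: bounded bimodal responses, the mean–variance coupling of
proportions, covariate effects of realistic size, SNP-driven multimodality
(additive genotype effect on logit μ under Hardy–Weinberg draws), and
one-sided outlier patterns (displacement on the logit scale, so boundary-near
sites throw outliers inward). What it does not emulate: probe-type
(Infinium I/II) artifacts, batch and cell-mixture structure, between-site
correlation, and the exact boundary-concentration of real 450K baselines.
Consequently, passing simulation tests demonstrate correctness of the
machinery and the direction and rough size of the misspecification effects,
not cohort-exact rates. One known consequence: the arcsine-scale μ-test
inflation under a strong scale nuisance sits near 50% under this calibration
at n = 1763 — clearly inflated and correctly ordered between the logit-type
and raw models, but smaller than on real boundary-heavy data, where the
arcsine second-order bias `dE[asin √Y]/dσ` is larger. The variable-scale
Gaussian model on M-values also sits essentially *at* the severe-inflation
boundary (~88%) rather than clearly above it.

## Resampling inference

`resample_pvalue()` implements the bootstrap for location-scale models:

1. fit the full model, record the Wald statistic `t_obs`;
2. refit with the tested coefficient constrained to zero (its design column
   removed) — the *constrained-refit* reading; zeroing the coefficient inside
   the full fit was the alternative, but the constrained refit is the one
   whose fitted surfaces are an actual null MLE;
3. B times (default 100): draw a parametric sample from the fitted null,
   **rank-reassign** the originally observed responses to subjects along the
   draw's ranks, refit the full model, record `t*_b`;
4. `p = (1 + #{|t*_b| ≥ |t_obs|})/(B + 1)` — the +1 convention; p-values live
   on {1/(B+1), …, 1} and are never zero.

Every bootstrap replicate is an exact permutation of the observed data, so
the null distribution of `t*` inherits outliers, mixture components and any
other marginal misbehaviour — which is precisely what makes the test robust
where the asymptotic σ-test is not. Non-converged replicates are redrawn up
to three times, then dropped with B decremented; fewer than B/2 effective
replicates aborts. When both the μ- and σ-coefficients of a covariate are
tested, two independent null constructions are run. Genetic covariates
(`select_correlated_covariates()`: greedy forward selection on the running
least-squares residual, deterministic, ties to the lowest index) are chosen
once per site and held fixed across bootstrap replicates; re-selecting inside
each replicate would mix selection noise into the null distribution. The
±5 Mb windowing helper (`window_candidates()`) is separated from the
selection so the module stays free of genome-coordinate conventions.

## Screening

`run_ewas()` flags DMCs (location term) and DVCs (scale term) at an explicit
threshold — typically `0.05 / <number of genome-wide tests>`; the threshold is
never inferred from the input dimensions, because the matrix at hand is
usually a slice of the genome-wide set. Resampling confirmation runs only
for flagged sites. Per-site failures are logged and never abort a screen.
`validate_associations()` joins a discovery and a replication screen and
tests enrichment of replicated associations among the resampling-significant
ones with Fisher's exact test; `bartlett_median_split()` provides the
simpler two-group variance test as a contrast.

## Numerical choices and degenerate inputs

* Induced parameters outside (0,1) during simulation are clamped to
  (1e-6, 1−1e-6) with a warning counter; boundary random draws are redrawn
  once, then clamped to 1e-12.
* Ties in `rank_reassign()` break by input order (`ties = "stable"`); a
  seeded random tie-break is available for heavily tied real data.
* Rank-deficient designs error naming the offending columns; a rank-deficient
  training half in split evaluation errors so the caller can flag the site.
* Beta-family likelihood evaluations clamp link inverses to
  [1e-12, 1−1e-12]; non-finite likelihoods are treated as −∞ by the
  optimiser.
* `residual_normality()` requires 3–5000 finite, non-constant values (the
  Shapiro–Wilk domain).

## Problem sizes

The acceptance computations use 500 sites (null level, residual normality)
and 300 sites (nuisance-inflation cells) at n = 1763 subjects, with B = 100
(or 99) bootstrap replicates — sizes chosen so each quantity's binomial
Monte-Carlo error is a few percent while a full run stays in the minutes
range on one core. Parameter-recovery properties run at n = 2000–5000 with
50–200 replicates. These are the package's own test sizings; the underlying
functions take arbitrary sizes.

## Known limitations

* The eight models cover linear covariate effects only; no smooth terms,
  no distributions beyond Gaussian and beta, no regularisation.
* Asymptotic and resampling inference both assume independent subjects.
* The resampling test separates effects on location and scale only when the
  true coupling between the two is moderate; with strong effects on the
  other parameter no permutation-marginal method can fully decouple them.
* Cross-scale pseudo-R² comparison inherits the transform-leakage caveat
  described above.
* IDAT parsing, probe-level QC, normalisation and cell-type deconvolution
  are out of scope; inputs are assumed preprocessed.
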