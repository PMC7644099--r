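---
title: "Hierarchical Gaussian-process models of microbial growth curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical Gaussian-process models of microbial growth curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpgrowth)
```

## The problem

High-throughput plate readers measure optical density (OD) of hundreds of
microbial cultures every few minutes for one or two days.  The scientific
quantity of interest is usually not a single curve but a *functional
contrast*: how does growth under a stress treatment differ from the control,
over the whole time course?  Two features of real phenomics data make this
hard:

1. **Growth curves are not sigmoid under stress.**  Classical logistic or
   Gompertz fits summarize a curve by carrying capacity, maximum growth rate
   and lag time, but severe perturbations produce shapes (diauxie, partial
   lysis, growth arrest) that no three-parameter family captures.
2. **Random effects are large.**  Each run of the instrument (a *batch*)
   and each well (a *replicate*) adds its own smooth, correlated deviation.
   In the regime where batch variation is comparable to the treatment
   effect, analyses that ignore it are confidently wrong: each batch alone
   yields a narrow posterior that contradicts the other batches.

`gpgrowth` addresses both problems with a functional mixed-effects model in
which every term — fixed or random — is an unknown smooth function with a
Gaussian-process prior.

## The model

All modelling is done on log OD, so time-zero inoculation offsets act
additively and are absorbed by the batch terms rather than subtracted in
preprocessing.  Write $y_{k,r}(t)$ for the log-OD of replicate $r$ in batch
$k$ at time $t$.  For a single treatment factor, the three nested
hierarchies are

* $M_{null}$: $y_r(t) = m(t) + \delta_{c(r)}(t) + \varepsilon_r(t)$, with
  $m$ the control mean curve, $\delta_c$ the deviation of treatment level
  $c$ (zero for the control, by the corner constraint), and
  $\varepsilon_r(t) \sim N(0, \sigma_y^2)$ white noise;
* $M_{batch}$: adds a batch-indexed GP twin of every fixed term,
  $m^{(k)}(t)$ and $\delta^{(k)}_c(t)$, drawn from shared group-level
  kernels;
* $M_{full}$: additionally gives every well its own replicate GP, so the
  residual is a smooth curve plus white noise rather than white noise
  alone.

With two crossed factors (e.g. pH and acid concentration) the fixed part
becomes a functional ANOVA
$m(t) + \alpha_p(t) + \beta_c(t) + (\alpha\beta)_{p,c}(t)$, each term with
its own kernel and batch twin.

Every latent function in a group shares an RBF kernel
$\kappa(t,t') = \sigma^2 \exp(-|t-t'|^2/\ell)$.  The lengthscale appears
*un-squared* in the denominator; this non-standard convention is the
package default (`kernel_dialect = "as_printed"`) and a
`"squared_lengthscale"` switch is provided for the field's more common
parameterization.  The kernel variances $\sigma^2$ are the model's
*variance components*: the mean, treatment, batch, replicate
("biological") and noise rows of `variance_components()` quantify how much
each source contributes to what the plate reader sees.

## Inference strategy

Given the hyperparameters, every latent function is Gaussian and can be
integrated out exactly: the observation vector is multivariate normal with
a covariance assembled from masked kernel blocks
(`assemble_covariance()`).  The sampler therefore explores only the 5–23
dimensional hyperparameter space, not thousands of latent function values
— the single most important design choice in the package, both for mixing
and for testability.  Sampling uses our own No-U-Turn HMC implementation
on log-transformed hyperparameters (positivity by construction, Jacobian
included), with dual-averaging step-size adaptation (target acceptance
0.8), a diagonal mass matrix re-estimated in warmup windows, and
divergence reporting.  Split-$\hat R$ (non-rank-normalized, matching the
era of the < 1.1 recommendation) and an autocorrelation-based effective
sample size are computed per parameter; 4 chains × 1000 warmup × 1000
draws are the defaults.

Two exact computational devices keep this fast:

* **Exchangeability reduction.**  Replicate curves that share a
  (condition, batch) cell and a time grid are exchangeable, so an
  orthonormal Helmert rotation splits them into the scaled cell mean
  (which keeps the full cross-cell covariance) and iid contrasts whose
  likelihood needs only a per-grid scatter matrix.  This is a change of
  basis, not an approximation; the test suite asserts equality with the
  dense path to 13 digits.  Cells with ragged grids simply stay dense.
* **Analytic gradients in C++.**  The marginal likelihood and its gradient
  in the log-hyperparameters are computed in RcppArmadillo;
  `tr(W \partial\Sigma)` trace identities give every gradient in one
  Cholesky plus elementwise products.

Numerical choices: a jitter of $10^{-8}\sigma_y^2$ is always added to the
diagonal, escalating tenfold on Cholesky failure up to $10^{-4}\sigma_y^2$
before the proposal is rejected as divergent; conditional covariance draws
use an eigendecomposition with negative eigenvalues clipped at zero.

## Priors and their scales

Time is standardized to $[0,1]$ before modelling (the map is stored and
all output is reported back in hours), which makes the lengthscale priors
scale-appropriate.  Defaults follow the shape–rate convention:
Gamma(10, 10) for fixed-effect variances (mean 1 on the squared log-OD
scale), Gamma(7, 10) for random-effect variances, inverse-Gamma
lengthscale presets per organism class (`halobacterium`: inv-Gamma(6, 1)
everywhere; `pseudomonas`: inv-Gamma(2, 3) fixed / inv-Gamma(10, 1)
random).  The noise variance prior is not pinned down by any analysis we
reproduce, so a weakly informative Gamma(1, 10) (mean 0.1) is the default;
it is exposed in configuration and echoed in all output metadata.
Lengthscale priors are stored per group (sharing a preset default), so
per-group overrides need no structural change.

## Reporting

`predict()` returns the posterior of any latent function — an effect, a
batch deviation, or the fitted curve of a condition — as a mixture over
(thinned, at most 500) hyperparameter draws of its conditional Gaussian
given the data.  Derivative posteriors (instantaneous growth rate,
d log OD/dt per hour) use the analytic RBF derivative cross-kernels, exact
under the model; a finite-difference cross-check lives in the test suite.
`credible_band()` gives pointwise central bands (the package makes no
simultaneous-band claim), and `significant_intervals()` scans a band for
maximal grid runs excluding zero — the default grid is 100 equally spaced
points, and interval endpoints snap to grid points rather than
interpolating.  Batch-effect posteriors use the same selector mechanism
(`effect = "treatment_batch", batch = ...`).

## The simulator and what passing tests mean

`simulate_growth()` is the generative model run forwards: latent functions
drawn from their kernels on the design grid, summed through the design
incidence, plus replicate GPs and white noise.  Its defaults put the batch
variance (0.3) in the same regime as the treatment variance (0.4) —
exactly the regime where ignoring batch effects misleads — and several
-fold above replicate (0.06) and instrument noise (0.01) variances, with a
mean-curve variance of 1 and lengthscales 0.15–0.25 on standardized time.
Two presets mirror realistic designs: `halo_like` (3 stress levels, 9
batches, 12 replicates, 48 h at 30-minute reads — the balanced
idealization of a large archaeal oxidative-stress screen) and `pa_like`
(3 pH × 3 acid concentrations, 2 batches, 3 replicates, 24 h at 15-minute
reads); `halo_reduced` is a desk-scale version used throughout the tests.

The simulator draws iid Gaussian noise and perfectly balanced designs; it
does not emulate instrument drift, heteroscedastic low-OD noise, plate
edge effects or missing wells.  Passing recovery tests therefore
demonstrate that the *inference machinery is calibrated for the model's
own data-generating process* — coverage of prior-drawn truths, uniform
simulation-based-calibration ranks, covariance agreement between simulator
and likelihood — not that the model is correct for any particular
instrument.

Problem sizes used by the test suite were chosen to keep each experiment
at desk scale while preserving the studied regime: the convergence check
fits 2 conditions × 3 batches × 3 replicates × 25 time points (450
observations) with 4 × (500 + 500) NUTS iterations; the calibration
experiment runs 50 replications of a 2 × 2 × 3 × 12 full-hierarchy design
at 2 × (250 + 250) iterations; the batch-overconfidence experiment runs
ten seeds of a 2 × 3 × 4 × 15 design.  All master seeds fan out through
R's RNG, so every experiment is reproducible bit for bit.

## Design decisions that were genuinely open

* **What "noise" means under the full hierarchy.**  The replicate GP could
  replace white noise entirely (leaving only a numerical floor).  We keep
  an estimated white-noise component alongside the replicate GP, because
  instrument error and smooth replicate deviation are scientifically
  distinct variance components and the decomposition reports both.
* **Identifiability of effects.**  Corner constraints (reference level
  carries zero effect) rather than sum-to-zero: the control condition is a
  natural zero in growth experiments, and it keeps every latent function
  interpretable as "difference from control".  The reference level is the
  first in sort order unless specified.
* **Baseline parameterization.**  The logistic baseline
  $y(t) = A/(1+\exp(4\mu_{max}(\lambda-t)/A + 2))$ follows the classical
  grofit convention so that $\mu_{max}$ *is* the maximum slope and
  $\lambda$ the tangent-intercept lag; Welch's unequal-variance one-sided
  t-test compares $\mu_{max}$ between groups, since growth-rate variances
  visibly differ across conditions.  The KDE used for rate distributions
  is a direct Gaussian sum with Scott's-rule bandwidth
  $n^{-1/5}\,\mathrm{sd}(x)$.
* **Blank correction** is exposed as a preprocessing option but off by
  default: whether raw OD was blank-corrected upstream varies by
  instrument, and the log-scale batch terms absorb constant offsets.

## Known limitations

Dense covariance algebra scales as $O(n^3)$ in the number of cell-mean
rows; hundreds of curves on a shared grid are comfortable, but designs
with thousands of distinct ragged grids are not.  Bands are pointwise, so
scanning them for significant intervals carries the usual
multiple-look caveat.  Only RBF kernels and at most two crossed factors
are supported, and model comparison (information criteria, Bayes factors)
is out of scope.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_growth("halo_reduced", seed = 1)
fit <- gpgrowth(~condition, sim$data, model = "batch",
                chains = 4, iter = 500, warmup = 500, seed = 1)
summary(fit)
delta <- predict(fit, "treatment", level = "stress")
plot(delta)
significant_intervals(credible_band(delta))
variance_components(fit)
```
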