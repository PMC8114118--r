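---
title: "Models and methods behind protarray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind protarray}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protarray)
```

`protarray` pre-processes single-channel (forward-phase) protein
microarray data. This vignette explains the statistical models behind
each stage, the parameters that matter and why their defaults are what
they are, what the synthetic-data generator does and does not emulate,
and the numerical choices made where the methods left room for
interpretation.

## Data model and indexing

A slide is divided into mini-arrays (blocks), each allocated to one
serum sample; every feature (antigen, control protein, purification tag
or printing buffer) is printed several times — triplicate in the
default geometry — inside a block. Quantification software reports a
foreground and a local-background statistic per spot; we use the
medians, which are insensitive to single bright pixels (mean columns
can be selected through the parser dialect). The long-format spot table
indexes each intensity by slide, block, grid position, feature and
replicate, and the layout attaches sample, feature class, tag and batch.
Coordinates are 1-based and block-within-slide order is row-major, the
GenePix convention. Parsing is strict: column roles are resolved once
through an explicit dialect (never sniffed), every data row must yield a
record, and unmapped blocks or duplicated coordinates are hard errors.
Because a sample may in principle span several blocks, the layout maps
blocks to samples explicitly rather than assuming one block per sample.

## Background correction

Six strategies are available because the right choice depends on where
the background signal lives, which the `background_diagnostics()`
output (foreground/background correlation per slide, per-block
background summaries, buffer-spot summaries) is designed to reveal:

* **local** — `fg - bg` per spot. Unbiased when the local background
  estimate is trustworthy; can go negative, so negatives are *flagged*,
  never silently replaced — replacement is an explicit downstream
  policy.
* **global** — `fg` minus the slide-wide median of the local
  backgrounds; appropriate when the local estimates are noisy but the
  slide-level background is homogeneous.
* **moving minimum** — `fg` minus the *minimum* background of the
  spot's block. When an artefact (smear, scratch) contaminates most
  local background annuli in a block, the block minimum is still taken
  from an unaffected spot; the median would not be.
* **half moving minimum** — moving minimum, then every corrected value
  ≤ 0 is replaced by half the minimum *positive* corrected value. The
  replacement scope is the block by default — the unit the method
  targets — and can be widened to the slide. Note this is a data-driven
  floor, not the fixed 0.5 floor some packages use. We read the method
  as "moving minimum followed by half-minimum replacement": the
  alternative reading (a separate subtraction rule) has no coherent
  definition, and this is the only reading under which the method's
  output is strictly positive as intended.
* **normexp** — the observed foreground is modelled as `X = B + S`
  with `B ~ Normal(mu, sigma^2)` and `S ~ Exponential(theta)`; the
  corrected intensity is the posterior mean
  `E[S | X = x] = m + sigma * phi(m/sigma) / Phi(m/sigma)`,
  `m = x - mu - sigma^2/theta`. This map is smooth, strictly
  increasing and strictly positive, so one parameter set per slide sends
  all net-negative spots to a common positive scale. The estimator is
  ours to define: `mu` and `sigma` come from the median and MAD of the
  slide's local backgrounds, `theta = max(mean(fg) - mu, 1)`, optionally
  refined by direct maximisation of the marginal convolution likelihood
  (`normexp_loglik()`). The moment step makes the fit cheap and robust;
  the ML step removes its bias and is verified by parameter recovery in
  the tests.
* **log-linear** — plain subtraction above a slide-specific threshold
  `delta`, and the smooth interpolant
  `delta * exp(1 - (bg + delta)/fg)` below it. `delta` is the smallest
  positive `fg - bg` on the slide, floored at 1 intensity unit, which
  anchors the interpolant at the observed positive range. The
  interpolant is continuous at the knot (`fg - bg = delta` maps to
  `delta`), strictly positive and monotone in `fg`; continuity and
  monotonicity are asserted in the tests.

## Replicate quality control

`CV% = 100 * sd/mean` with the *sample* standard deviation (n − 1): at
n = 2–3 replicates the denominator choice changes the CV by double-digit
percentages, so it is fixed and documented. A CV with non-positive mean
carries no information and is reported as undefined ("out of range" in
the per-sample summary) rather than coerced.

The filtering policy per (sample, feature) set: pass if the full-set CV
is at or below the cutoff (default 20%); otherwise exempt the set if its
mean lies below the low-intensity threshold — near the detection floor
small absolute differences produce large CVs that should not reject a
spot; otherwise search all subsets of size ≥ `min_keep` (default 2)
exhaustively for the minimal-CV subset and keep it if it meets the
cutoff; otherwise fail (a status, not an error). The best-subset rule is
the only deterministic reading of "keep 2 of 3 and exclude the
outlier"; ties are broken by the larger subset mean (prefer retaining
signal), then the lexicographically smallest index set. The search is
exact and is tested against an independent bit-mask enumeration.
Raising the cutoff or the exemption threshold can only retain more sets
(monotonicity, also tested).

Retained replicates are averaged; failed sets become missing cells.
Tag subtraction then removes the replicate-averaged signal of each
antigen's purification tag in the same sample, flooring at 0 — the tag
itself attracts antibodies, and that reactivity is not antigen-specific.
The stage is optional because untagged designs exist.

## Normalisation

**log2** with offset `alpha_hat` (an estimate of the median background
level; 0 for background-corrected data). Values at or below the offset
are undefined and become missing, with a count attached — log transforms
inflate variance near zero and cannot represent non-positive values,
which is the motivation for VSN below.

**Cyclic loess.** For each distinct pair of arrays, a loess curve is
fitted to the MA scatter and half of the centred correction
`M - Mhat(A)` is applied to each array, sweeping all pairs `n_cycles`
times (default 3). The smoother is a native local *linear* regression
with tricube weights over a span of 0.7 and 3 bisquare robustness
iterations — the classical LOWESS scheme, cross-checked against
`stats::loess` in the tests; span and degree are exposed because no
single setting suits every bow shape. Identical arrays are an exact
fixed point (the pairwise `M` is identically zero and the sweep skips).
The pairwise-cyclic variant matches the MA equations directly; a fast
"average-array" variant would converge faster on many arrays but is not
needed at the problem sizes targeted here. The method assumes most
features do *not* differ between arrays — exactly the assumption that
fails for serology panels with genuine between-sample variation, which
is why the method is provided for comparison but VSN is the default
pipeline choice.

**Robust linear model on controls.** Control proteins (e.g. human IgG
and IgM) are expected to bind constantly everywhere; the model
`log2 y = intercept + slide_i + block_j + protein_k + error`
is fitted to control spots by IRLS with Huber weights (tuning constant
1.345, scale re-estimated by MAD each iteration, at most 50 iterations,
tolerance 1e-6) under sum-to-zero constraints per factor — the standard
identifiable parameterisation; the robust loss caps the influence of a
contaminated control spot at a bounded multiple of the clean fit's
change (tested against OLS and against an independent robust-regression
implementation). Only `slide_i + block_j` is subtracted from the data:
the protein effect `tau_k` absorbs printing amount and affinity of the
control proteins themselves and is not a technical artefact of the
samples, so removing it would distort nothing useful and is not done.
Subtracting a per-(slide, block) constant leaves every within-block
feature contrast exactly unchanged. Constant (saturated) controls are
rejected with advice, since saturation hides exactly the variation the
controls are meant to measure. Negative values must be made positive
before logging; the pipeline applies the half-minimum policy explicitly
and counts the replacements in the audit record.

**VSN.** The two-component error model
`y = mu * e^eta + eps`, `eta ~ N(0, sigma_eta^2)`,
`eps ~ N(0, sigma_eps^2)` produces variance
`~ mu^2 sigma_eta^2 + sigma_eps^2`: proportional at high signal,
additive near zero. The transformation
`h(y) = glog2((y - a_i)/b_i)`, with
`glog2(u) = log2(u + sqrt(u^2+1)) = arsinh(u)/ln 2`, stabilises this
variance; it is defined for negative values, odd, strictly increasing
and asymptotically `log2(2u)`. Each array gets its own offset `a_i`
(fixed at 0 for background-corrected input) and scale `b_i > 0`,
enforced by optimising `log b_i`.

Estimation maximises the profiled likelihood in which `h`-transformed
values are normal per feature with a common variance, per-feature means
are profiled out, and the Jacobian of `h` enters per observation; cells
may be missing (the criterion runs over observed cells; a feature needs
at least two). Robustness (default `trim = 0.1`) is by *concentration
steps*: fit on all features, set aside the 10% with the largest mean
squared residual, re-maximise on the rest, and iterate until the
retained set is stable (at most 5 rounds), with two optimiser starts
guarding against local minima. Trimming *inside* a single joint
objective — selecting the kept subset during optimisation — was tried
and rejected: it couples the subset choice to the scale estimate and
inflates the `b_i` by tens of percent even on data simulated exactly
from the model, whereas the concentration scheme recovers them closely.

One identifiability caveat, quantified during development and worth
knowing when reading fitted parameters: the *relative* scales
`b_i / b_j` are determined by the whole intensity range and recover
within a few percent at 50 features × 6 arrays, but the *common* level
of the `b_i` is informed only by features near the additive-noise
regime (intensities of order `b`), so with few such features it carries
sampling error of tens of percent. The transformation's
variance-stabilising behaviour depends almost entirely on the relative
scales.

## Mean–variance diagnostics

`mean_sd_profile()` computes per-feature means and sds across samples,
orders features by mean rank and reports a running median of the sd over
a centred window of `ceiling(0.1 * K)` features. `spearman_mvd()` is the
headline statistic: the Spearman correlation between feature means and
sds (invariant to monotone transforms of the means; constant inputs are
reported as undefined with a tie flag). The trend tests are applied to
the running-sd sequence of the mean-ordered profile — the natural
reading of "is the smoothed meanSd profile trending?" — with the window
fraction exposed:

* **Cox–Stuart**: pair `x_t` with `x_(t + ceiling(n/2))`, drop ties,
  test the sign counts against Binomial(n, ½) with an exact two-sided
  binomial test.
* **Mann–Kendall**: `S = sum_(i<j) sign(x_j - x_i)`, tie-corrected
  variance, normal approximation with continuity correction, two-sided.
  The exact null enumeration is used only as a test oracle.

Both default to two-sided alternatives (a normalisation could in
principle overshoot into a decreasing trend; one-sided options are
exposed). Calibration is verified empirically: on iid Gaussian
sequences of length 50, both tests reject at a rate inside [0.03, 0.07]
at nominal 5% over 2 000 replicates. Note the tests are calibrated for
exchangeable input; the running-window smoothing introduces
autocorrelation, so p-values on smoothed profiles are interpreted as a
ranking device rather than exact error rates.

## Batch correction

The location/scale model
`Y_wsk = alpha_k + X beta_k + gamma_wk + delta_wk eps_wsk` is fitted in
four steps: feature-wise least squares on batch indicators plus
covariates to preserve; standardisation by the batch-size-weighted grand
mean and pooled residual sd; empirical-Bayes shrinkage of the per-batch
means and variances of the standardised data — parametric mode places a
normal prior on locations and an inverse-gamma prior on squared scales,
estimates hyperparameters by method of moments across features, and
iterates the coupled posterior updates to a relative tolerance of 1e-4
(at most 200 iterations); nonparametric mode replaces the posteriors by
likelihood-weighted averages over the other features' estimates — and
finally the adjustment
`sigma_k/delta*_wk * (Z - gamma*_wk) + alpha_k + X beta_k`. The
standardising scale used in the re-scaling step is the pooled
feature-level sd `sigma_k`: re-scaling by anything batch-specific on
both sides would cancel the correction, so this is the only internally
consistent choice. A single batch returns the input unchanged; a
singleton batch is allowed only with `mean_only = TRUE` (its scale is
not estimable); confounding between batch and preserved covariates is a
hard error; features with missing cells or zero pooled variance pass
through unadjusted with a warning. The implementation is cross-checked
against an independent empirical-Bayes implementation to 1e-3 on a
shared fixture, and shrinkage, covariate preservation and
identity-on-one-batch are asserted directly.

`batch_diagnostics()` provides PC scores with variance explained, the
sample distance matrix for hierarchical clustering, and per-batch
feature means; `pc_batch_ratio()` condenses separation into a
between/within batch variance ratio of a chosen component.

## The synthetic generator

`synthetic_config()` / `generate_experiment()` emulate a mini-array
design: by default 21 blocks per slide (one sample each), 100 antigens
printed in triplicate, IgG/IgM controls, GST/MBP/His6 tag spots,
buffer spots, and a block grid auto-sized at 20 columns. The foreground
of a spot is

```
bg + (mu_feature + tag carry-through) * exp(eta_bio + eta_tech)
   * 2^(slide + block + batch effects) + eps
```

with the spot's own background reading `bg ~ N(300, 40)` written to the
background column, `mu` lognormal across antigens
(`meanlog log(1000)`, `sdlog 1`) to create realistic mean–variance
dependence, constant control signal (5 000, deliberately below
saturation) and zero buffer signal. The proportional error is split into
a sample-level component `sigma_eta = 0.2` drawn once per
(feature, sample) and shared by its technical replicates — the
serological spread across sera that these arrays are designed to
detect — and a spot-level technical component `sigma_rep = 0.08`,
a tight-triplicate CV of about 8%; the additive error is
`sigma_eps = 50` intensity units. This separation matters: replicate
filtering sees only the technical noise, normalisation sees the full
between-sample spread, and collapsing the two would park every
replicate set at the CV cutoff. Tagged antigens receive their tag's
signal additively (carry-through), which is what tag subtraction is
meant to remove. All effects, true signals and noise draws are recorded
as ground truth; generation is deterministic given the seed and
restores the caller's RNG state.

`inject_artefact()` inflates the recorded background of the first 80%
of spots (row-major) in chosen blocks — deterministic, so tests do not
depend on which spots are hit — leaving foregrounds untouched: the
scenario in which local subtraction over-corrects but block-minimum
methods survive, because the minimum still comes from an unaffected
spot.

Two focused simulators back the recovery tests:
`simulate_two_component()` (matrix-level two-component model with known
per-array gains, hence known `b_i = gain * sigma_eps/sigma_eta`) and
`simulate_batch_matrix()` (additive scale, known batch shift/scale and
an optional preserved group effect; within-batch residual sd 0.25 on
the log2 scale, the spread plausibly left after averaging tight
triplicates).

What the generator does **not** emulate: pixel-level images and
spatially structured artefacts (gradients, ring effects), scanner
saturation and flagged spots, carry-over between adjacent spots,
non-Gaussian background outliers, and correlated antibody responses
across antigens. Passing tests therefore demonstrate correctness of the
algorithms under the stated error model, not robustness to every
failure mode of real slides — which is precisely why the diagnostic
outputs (background plots data, CV tables, meanSd reports, PCA) exist.

## Problem sizes and runtime choices

The test suite and the acceptance script run at desk scale, chosen so
the full suite completes in well under a minute: experiments of 1–2
slides with 2–21 blocks and 10–220 features, recovery fixtures of
50–400 features × 2–8 arrays, 1 000 brute-force CV cases, and 2 000
trend-test null replicates. All simulation-based checks fix their seeds;
stochastic bounds (type-I error bands, null rho bands) were sized to
hold with margin at those seeds.

## Known limitations

* The VSN absolute scale is weakly identified when few features sit
  near the additive-noise regime (see above).
* The trend-test p-values on running-sd sequences inherit smoothing
  autocorrelation (see above).
* The normexp maximum-likelihood refinement assumes the convolution
  model globally; heavy right tails beyond exponential (e.g. saturated
  spots) should be flagged upstream.
* `filter_replicates()` enumerates subsets exhaustively — exact and
  fast for the 2–6 replicates of printed designs, not meant for dozens
  of replicates.
* Batch correction preserves only covariates supplied in the design;
  latent structure discovery (surrogate variables) is out of scope.
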