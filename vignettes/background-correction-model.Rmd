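---
title: "An exponential-normal mixture model for methylation array background"
author: "methylbgc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An exponential-normal mixture model for methylation array background}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylbgc)
```

## The problem

Infinium-style methylation BeadChips report, for every CpG, a methylated
(M) and an unmethylated (U) fluorescence intensity, summarized as the
beta value `M / (M + U + 100)`. Both intensities carry additive optical
and chemistry background. Because the background level varies from array
to array and is large relative to the signal of whichever allele is *not*
present at a CpG, it biases betas toward 0.5 — most visibly at the fully
unmethylated and fully methylated extremes — and it differs systematically
between the two probe chemistries (Infinium I and II), contributing to the
well-known probe-design bias. Subtraction rules (a percentile or median of
the negative controls) remove a constant but clip low intensities at zero,
destroying information in exactly the range where background matters most.

## The model

Each observed intensity is modeled as `S = X + Y`:

* `X`, the true signal, follows a two-component mixture
  `p1 * Exp(lambda) + p2 * N+(nu, tau^2)` with `p1 + p2 = 1`, where
  `N+` denotes a normal distribution left-truncated at zero. The
  exponential component captures the absent/weak allele (a CpG that is
  unmethylated contributes essentially no methylated signal, and vice
  versa), the truncated-normal component the present allele.
* `Y`, the background, follows `N+(mu, sigma^2)`.

Intensities are split into six parts that are modeled separately, per
sample: type I red M, type I red U, type I green M, type I green U,
type II M (green channel) and type II U (red channel). The mixture shape
differs across these parts (different chemistry, dye and allele
composition), which is why one set of parameters per part is fitted.

The corrected intensity is the conditional expectation `E(X | S = s)`.
Because `X > 0` and `Y > 0` force `X` into `(0, s)`, each component's
conditional law is a normal restricted to `(0, s)`:

* exponential component: completing the square in
  `exp(-lambda * x) * phi((s - x - mu) / sigma)` gives a normal with
  location `s - mu - sigma^2 * lambda` and scale `sigma`;
* normal component: the product of the signal and background kernels is a
  normal with precision `1/tau^2 + 1/sigma^2` and precision-weighted
  location `((s - mu)/sigma^2 + nu/tau^2) / (1/sigma^2 + 1/tau^2)`.

The correction is the posterior-weighted average of the two restricted
means, with the posterior weight of the exponential component computed
from the two closed-form convolution densities. Three properties follow
directly and are enforced by tests: `0 < E(X|S=s) < s`, strict
monotonicity in `s` (ranks within a part are preserved), and no
truncation (corrected values are never clipped).

When `p1 = 1` and the truncations are immaterial, the correction reduces
to the classic normal-exponential ("normexp") adjustment used for
expression arrays; the test suite checks this limit against an
independent implementation. The closed forms themselves are validated
against adaptive quadrature of the defining integrals (tolerances
`rel 1e-10 / abs 1e-12`, roughly four orders tighter than the `1e-6`
agreement asserted), so any algebra slip would surface immediately.

## Numerical choices

Scanner intensities reach `2^16` while background scales are of order
`10^2`, so standardized arguments of several hundred occur routinely and
naive ratios of normal CDFs underflow. Every tail-sensitive quantity is
computed from log-space primitives: `pnorm(log.p = TRUE)`,
`dnorm(log = TRUE)`, a stable `log(exp(a) - exp(b))`, and a truncated
normal mean that switches to the representable tail by reflection. Means
of near-degenerate intervals (width `< 1e-8` standard deviations) fall
back to the midpoint. The correction is finite and NaN-free over the
whole scanner range by construction, and tests sweep `s` up to 65535.

## Estimating the background

Three routes, chosen by data availability:

* **neg** — robust location/scale of the per-channel negative control
  intensities (613 per channel on the 450K design): median and
  `1.4826 * MAD`, followed by one truncation-aware refinement step that
  matches the observed median and IQR to those implied by a zero-truncated
  normal (the raw order statistics are biased when `mu / sigma` is small).
  When the MAD degenerates on coarse or heavily tied values, the IQR-based
  scale is used instead. The scale is floored at 1 intensity unit, and
  fewer than 20 values (or constant input) is an error.
* **oob** — the same estimator applied to the out-of-band intensities of
  type I probes (the readings on the channel a probe is *not* assigned
  to, which contain no target signal). The green-channel background uses
  the out-of-band readings of red-assigned probes and vice versa. With
  ~10^5 values instead of 613, the estimate is markedly more precise;
  a test verifies the smaller RMSE directly.
* **est** — a full maximum-likelihood fit of the convolution model with
  `(mu, sigma)` free alongside the signal parameters, on the pooled M and
  U intensities of one probe class x channel. Unlike the control-probe
  routes, this one is run separately for Infinium I and II probes and can
  therefore capture the elevated type II background.

## Fitting by EM

With the background fixed, the only latent variable is the component
label. The E-step is the component posterior; the M-step updates `p1` in
closed form and the remaining parameters by warm-started numerical
maximization of the expected complete-data log-likelihood (the
truncated-normal M-step has no closed form): a one-dimensional search on
`log(lambda)` and a Nelder-Mead step on `(nu, log tau)`. Every update is
accepted only if it improves its objective, so the observed-data
log-likelihood trace is non-decreasing (a generalized EM); the trace is
checked in tests on every run. Convergence is declared when the relative
log-likelihood change drops below `1e-6` (at most 1000 iterations).

Initialization is deterministic and scale-aware — `p1 = 0.5`,
`lambda = 1/median`, `nu` at the 75th percentile, `tau` from the MAD of
the upper half — so fits are reproducible without any RNG.

Two degeneracies need care. First, mixtures whose true weight sits on the
boundary (`p1` near 0 or 1): EM from an interior start can stall at a
local optimum in which the spare component fits a slice of the other
component's tail. After convergence the fit is therefore compared against
both single-component fits and the likelihood winner is returned, with
`p1` clamped to `[1e-4, 1 - 1e-4]` and flagged. Second, under the joint
(`est`) route the signal-normal and the background can swap roles; the
constraint `nu >= mu + 2 * sigma` (enforced by reparameterization)
removes the swapped branch. The joint route uses conditional
maximizations per M-step and, because those approach diagonal ridges of
the `(lambda, mu, sigma)` surface slowly, finishes with a joint
Nelder-Mead polish of the observed-data likelihood from the EM solution;
its convergence tolerance is `1e-5` with the polish supplying the final
precision. Fits subsample to at most 5e4 points (caller-seeded):
estimation accuracy saturates well below full-array sizes.

## Detection p-values and QC

The detection p-value compares `M + U` with an empirical distribution of
summed negative-control intensities matched to the probe chemistry: for a
type I probe, all pairwise sums `c_i + c_j` (i != j) of its assigned
channel's negative controls; for a type II probe, the row-wise
`red + green` sums of the control table. The convention
`p = (#sums >= observed + 1) / (n + 1)` avoids exact zeros and gives
`p = 1` at zero signal. Whether type II channels should be combined by
sum or by maximum is not settled usage; the sum is used here and isolated
in one function.

The QC mask excludes a measurement when either allele's bead count is
below 3 or the detection p-value exceeds 0.05 — both strict inequalities,
so bead count 3 and p = 0.05 are retained. Probe exclusion lists
(cross-reactive probes, SNPs, sex chromosomes) are accepted as plain id
vectors from the user; no annotation databases are shipped.

Multimodal CpGs are flagged by `nmode()`: counts of local maxima of a
20-bin histogram on `[0, 1]` whose mass exceeds 5% of samples, merging
peaks whose separating valley stays above half the smaller peak. The bin
count, mass and valley thresholds are package choices, exposed as
arguments.

## The surrounding pipeline

* **Dye bias.** Per sample, the medians of the red-target and
  green-target non-polymorphic controls (on their target channels) define
  factors `(R+G)/(2R)` and `(R+G)/(2G)` applied to all red- and
  green-channel measurements respectively — the simplest control-anchored
  scaling that equalizes the channels at their common mean. The reference
  dye-correction literature does not pin down a formula; this choice is
  deliberately minimal.
* **Quantile normalization** is applied across samples separately within
  four strata — (M, type I), (U, type I), (M, type II), (U, type II) —
  via `limma::normalizeQuantiles` with tie-averaging. Normalizing M and U
  (not betas) and keeping the chemistries apart avoids forcing the two
  probe designs onto a common intensity distribution.
* **Baselines.** `q5`, `lumi1` and `lumi2` are one-line subtraction rules
  (5th percentile of negative controls, their median, and the
  kernel-density mode of the methylated intensities, per channel); they
  are included as comparators and report the fraction of values they
  truncate at zero.
* The pipeline runs any ordered subset of
  `background correction -> dye bias -> quantile normalization`, then
  computes betas with the standard offset of 100 (retained after
  correction; the beta definition is unconditional). An empty step list
  is the identity. BMIQ-style probe-design rescaling and batch correction
  are deliberate hook points for user-supplied functions, not
  implementations.

## What the simulator emulates — and what it does not

`simulate_array()` draws each part exactly from the stated model: labels
`Bernoulli(p1)`, signals from `Exp(lambda)` or `N+(nu, tau^2)`,
backgrounds from `N+(mu, sigma^2)`, and emits `S = X + Y` together with
the full ground truth (the reconstruction identity is exact). Bimodal
methylation arises from a per-CpG state that swaps which allele is
exponential. A Kolmogorov-Smirnov check at `n = 1e5` confirms the emitted
parts follow the intended convolution density.

Structural realism choices, each fixed once and documented here:

* **Probe composition** 28% type I / 72% type II; 613 negative and 186
  non-polymorphic controls per sample, as on the 450K design.
* **Background scales** `mu = 1000/1200` (red/green) with within-array
  spread 15% of the level (`sigma = 150/180`), type II levels elevated
  1.5-fold — magnitudes typical of scanner output, set at the middle of
  the plausible range.
* **Array-level background variation**: every array draws a per-channel
  level factor (lognormal, 0.3 log-SD) applied consistently to probe
  backgrounds, out-of-band readings and negative controls. Independently
  processed arrays differ in background level, and this shared, removable
  component — not the iid per-probe noise — is what per-sample background
  estimation targets; duplicates would be nearly uncorrectable without it.
* **Duplicates**: a per-CpG population template with lognormal
  person-level scatter (0.2 log-SD; methylation at a CpG varies little
  between individuals in blood) and member-level technical noise
  (0.05 log-SD, multiplicative for positivity and scale invariance).
  This reproduces the motivating contrast: raw-beta Pearson correlations
  above 0.99 between duplicates while mean-centered correlations are far
  lower.
* **Titration standards**: at level `m`, each CpG's shared magnitude `A`
  splits as `m * A` (methylated) and `(1-m) * A` (unmethylated); default
  levels 0/5/10/20/40/50/60/80/100% with 10,3,2,3,3,2,3,3,10 replicates
  (39 arrays).
* **Dye imbalance** multiplies red-channel components before summation so
  the reconstruction identity survives; the pre-imbalance beta is kept as
  the accuracy truth. Scanner rounding to the integer grid is available
  but off by default so oracle comparisons stay exact.

Not emulated: bead-level replicate structure, spatial chip artifacts,
bisulfite-conversion chemistry, probe-affinity (sequence) effects and
cross-hybridization. Passing tests therefore demonstrate correct and
well-behaved inference *under the stated generative model* and realistic
magnitudes — they do not certify performance on any particular real
cohort, where these unmodeled effects are present.

## Evaluation metrics

Raw beta correlations between any two blood samples are near 1 because
the between-CpG methylation pattern dominates; subtracting each CpG's
across-sample mean before correlating (the mean-centered correlation)
removes that pattern and makes duplicate agreement informative. At least
three samples are required — with exactly two, centering produces mirror
images and the correlation degenerates to -1. The companion metric is the
mean absolute beta difference in percentage points. Titration accuracy is
summarized as the signed per-level median of `beta - expected` (signed,
because background pushes the two extremes in opposite directions); the
absolute version is also reported. Method comparisons use one-sided
paired t-tests against raw across duplicate pairs.

## Problem sizes used by the tests

Unit tests run on arrays of 1.5-8k probes and parts of 2e4-5e4 draws;
the end-to-end checks use the default study scale: 20 duplicate pairs and
the 39-array titration design at 10^4 probes each, with the out-of-band
route. Parameter recovery is checked on 25 seeded models at `n = 5e4`
via the joint route, asserting median absolute relative errors (<= 5% for
`mu`, `nu`, `lambda`; <= 15% for `sigma`, `tau`; `p1` within 0.02).
`scripts/acceptance.R` reruns the same computations from scratch under a
caller-supplied seed.

## Known limitations

* The joint (`est`) route's likelihood surface is flat along a
  `(lambda, mu, sigma)` ridge for some parameter combinations; individual
  `sigma` estimates can then be off by tens of percent even though median
  recovery is well within tolerance. The control-probe routes are immune.
* Per-sample, per-part fits assume each part holds at least 1000 probes
  (5000 for the joint route); arrays far smaller than 10^4 probes with
  the standard type I fraction will not support the four type I parts.
* The dye-bias scaling and the lumi2 mode rule are minimal stand-ins for
  external methods whose published descriptions leave details open; both
  are isolated behind single functions so they can be swapped.
* Corrected intensities remain estimates of `E(X|S)`; downstream
  variance-based analyses should expect the correction to be a smooth,
  rank-preserving shrinkage, not a noise remover.
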