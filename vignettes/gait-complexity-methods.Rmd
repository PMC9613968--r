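---
title: "Measuring gait complexity: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring gait complexity: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitcomplexity)
```

## The problem

"Complexity" in human movement analysis is not one quantity. Three
families of measures are in common use, and they quantify genuinely
different properties of multi-joint kinematics:

* **Dimensionality** — how many independent directions of joint-space
  variation the movement uses. The standard operationalization is the
  number of principal components needed to explain 95% of the variance
  of the joint-angle time series (here called N95).
* **Variability** — how large the excursions are. For multivariate
  angles the generalized variance (GV), the determinant of the
  covariance matrix, measures the volume of the configuration cloud;
  GaitSD measures stride-to-stride deviation of time-normalized gait
  waveforms.
* **Nonlinear dynamics** — how predictable the movement is over time.
  The largest Lyapunov exponent (LyE) of the delay-embedded signal
  measures trajectory divergence; composite multiscale sample entropy
  (CMSE) and its Complexity Index (CI) measure irregularity across time
  scales.

Because these measure different things, they can and do rank the same
set of activities differently. This package implements all of them as
one tested pipeline and provides synthetic generators with known ground
truth, so the disagreement itself becomes a reproducible, testable
phenomenon rather than an anecdote.

## Data model

A **trial** is a frames × channels matrix of joint angles in degrees at
a fixed sampling rate (60 Hz by default in the generator, matching
wearable motion-capture practice). The canonical lower-limb channel set
is 18 degrees of freedom: {hip, knee, ankle} × {left, right} ×
{sagittal, frontal, transverse}. **Foot contacts** are frame indices of
initial contact for one foot; a stride (gait cycle) is the half-open
interval between successive initial contacts of the same foot —
non-overlapping, single-foot, which keeps "N gait cycles" well defined.
Each stride is linearly interpolated onto 101 phase points (0–100% of
the cycle in 1% steps, endpoints preserved exactly).

## The measures

### N95 dimensionality

Columns are mean-centred; the eigenvalues of the sample covariance
(divisor n − 1) are computed from the p × p covariance matrix
(equivalent to, and at p = 18 cheaper than, an SVD of the data). N95 is
the smallest k whose cumulative percent variance reaches 95% (a ≥
comparison). Covariance PCA is used rather than correlation PCA: the
channels share units, and the absolute-variance spectrum is itself of
interest — the package deliberately exposes both the percent and the
absolute view, because trailing components with small *relative*
variance can still carry large *absolute* variance, and the rank
`highvar` vs `highdim` activities in `generate_discordant_activities()`
demonstrate exactly that reversal. Per-trial PCA is the default;
pooling frames across trials is available in `activity_n95(pooled =
TRUE)` since both conventions exist in practice.

### Generalized variance and GaitSD

GV is the determinant of the sample covariance, computed as the product
of its eigenvalues in log space: an 18-channel determinant in degrees²
per axis spans hundreds of orders of magnitude, so `log_gv` and the
geometric-mean form `normalized_gv = gv^(1/p)` (degrees²) are the
recommended reporting scales, with the raw determinant retained as the
canonical definition. If the smallest eigenvalue falls below 1e-10 of
the largest the covariance is flagged rank-deficient and GV is reported
as 0 rather than as numerical noise.

GaitSD works on the N × 101 × p cycle tensor. For joint k:

$$\mathrm{GVSD}^2_k \;=\; \frac{\sum_{j=1}^{T}\sum_{i=1}^{N}
  (X_{ij} - \bar X_j)^2}{T\,(N-1)}, \qquad T = 101 .$$

The per-joint values are combined into one scalar either as the mean of
per-joint SDs (default) or as the square root of the mean of per-joint
variances. The published construction is typographically ambiguous
between the two; both are implemented and tested. They coincide for
homogeneous variability and diverge (mean-of-SDs being smaller, by
Jensen's inequality) when joints differ — a property the test suite
asserts rather than hides. GV is computed on raw trial frames; GaitSD
only ever on time-normalized cycles.

One numerical note: linear interpolation onto the phase grid averages
adjacent frames, so white per-frame noise of SD σ appears in GaitSD
attenuated by roughly √(2/3) when cycles pass through resampling.
Noise injected directly on the phase grid is recovered without bias
(the recovery test does exactly that); this is a property of
interpolation, not an estimator defect.

### Delay embedding and the largest Lyapunov exponent

The scalar series (per convention, the sagittal hip, knee and ankle
angles) is embedded by Takens' construction. The delay is the first
local minimum of the histogram-based average mutual information (equal
width bins, B = max(16, n^{1/3})); because binning superimposes small
wiggles on the MI curve, the minimum is located on a 5-point moving
average and then refined to the raw-curve argmin within ±2 lags. Flat
curves without a local minimum (white noise) fall back to the global
argmin with an explicit flag. The embedding dimension comes from global
false nearest neighbours with the standard Kennel tests (R_tol = 15,
A_tol = 2, attractor size = SD of the series) and a 10% acceptance
threshold; temporal neighbours within one delay are excluded from the
search, pairs identical to machine precision are never counted false,
and for long series the reference set is an evenly spaced subsample
(cap 2000) searched against all vectors. Saturation (noise that never
de-aliases) is reported, not truncated.

On a clean Lorenz x-series the false-neighbour fraction at dimension 2
is a few percent — consistent with the original Kennel results — so the
10% criterion can already stop at 2, while a 1% criterion requires the
full dimension 3. The tests assert both facts; users comparing
embedding dimensions across conditions should fix the threshold and
treat it as part of the measure.

The Lyapunov exponent follows the Rosenstein construction: each
point's nearest neighbour outside a Theiler window of one mean period,
mean ln distance tracked forward, least-squares slope × sampling rate.
The mean period is the reciprocal of the power-weighted mean frequency
of the periodogram — robust for broadband signals where the single
tallest periodogram peak is erratic. The default fit window spans half
to two mean periods: the first half period is dominated by a transient
in which imperfectly aligned neighbour pairs rotate into the most
expanding direction (which inflates the slope), and beyond a few
periods the curve saturates at attractor size. With these defaults the
estimator reproduces ln 2 on the r = 4 logistic map to well under 5%,
gives |LyE| < 5% of that value for a sinusoid, and lands within 15% of
an independent two-trajectory perturbation-growth (Benettin) oracle on
the Lorenz system — all recomputed in the test suite and acceptance
script, not quoted.

### CMSE and the Complexity Index

Sample entropy uses the Richman–Moorman convention (N − m templates at
both lengths, Chebyshev distance, self-matches excluded), with m = 2
and r = 0.2 × SD. When no templates match, the value is an explicitly
flagged `NA` — never a silent infinity. At scale τ the composite
variant averages sample entropy over all τ coarse-graining offsets,
with r held fixed at 0.2 × SD of the *original* series across scales
(the standard multiscale convention; it keeps scales comparable). The
Complexity Index is the sum over scales 1..20. Undefined offsets are
dropped from a scale's mean; a scale with no defined offset poisons the
CI into a flagged `NA`. The implementation satisfies the standard
sanity signatures: CMSE at τ = 1 equals plain SampEn exactly, white
noise is monotonically decreasing across scales, and 1/f noise is
flatter with a higher CI at matched length.

## The synthetic generator

`generate_gait()` emulates the statistical structure the measures
respond to, not biomechanical detail. Per stride, each channel is a
fixed linear combination (loading matrix, default 25° × orthonormal
columns) of `latent_rank` periodic basis waveforms (distinct stride
harmonics, hence mutually orthogonal with equal variance — this makes
rank recovery by the 95% rule exact when residual noise is small), plus
per-stride latent amplitude jitter, white stride-level and sensor
noise, and stride durations with a chosen coefficient of variation.
Waveforms are defined on cycle phase [0, 1), so stride boundaries join
continuously and add no artificial discontinuity spikes to the entropy
estimates. Setting `chaos_mod` modulates stride durations with a
logistic map at r = 4, injecting genuinely aperiodic timing — the
designed contrast for the Lyapunov measure. Every generator is a pure
function of (config, seed): identical configurations are bitwise
reproducible and the caller's RNG stream is left untouched. A
`latent_rank` of zero is rejected as degenerate (it would produce a
constant, zero-entropy trial); the deterministic-periodic case is
instead any rank with all noise terms and the duration CV set to zero.

What the generator does **not** emulate: realistic joint coordination
and waveform shapes beyond low harmonics, soft-tissue and sensor
artifacts, turns, asymmetry between feet, non-stationarity across a
session. Tests passing on this generator therefore validate the
estimators and the pipeline plumbing — they do not certify conclusions
about any particular clinical population.

`generate_toy_clouds()` produces the two-dimensional Gaussian
illustration of the variance/dimensionality dissociation (equal-shape
clouds at 4× scale: GV ratio 16, same N95; near-rank-1 vs isotropic:
N95 1 vs 2), and `generate_benchmark()` provides the canonical
validation signals (sine, white, 1/f pink via spectral shaping,
logistic map, Lorenz via fixed-step RK4 integration).

## The designed discordance suite

`generate_discordant_activities()` fixes four activity archetypes: a
periodic low-rank low-noise *walk*; *highdim* (eight latent directions,
small amplitude); *highvar* (three directions, large amplitude, strong
sensor noise); and *irregular* (chaotic stride timing, broadband
noise). By construction, the most complex activity is `highdim` under
N95, `highvar` under generalized variance, and `irregular` under the
Complexity Index, while `walk` is simplest under all three at once;
Kendall's W across the five measure rankings is well below 1. The suite
is the package's quantitative stand-in for the qualitative observation
that reasonable complexity measures contradict each other, and the
concordance statistic is the minimal quantitative summary of a ranking
table that is otherwise compared only by eye.

## Problem sizes and tolerances

The test suite and acceptance script use sizes at which each oracle is
tight but cheap: 10,000 samples for the logistic map and iid-Gaussian
sample entropy (5% tolerances), 20,000 Lorenz samples at dt = 0.01
(15% against the perturbation oracle), 4,000 samples for the
CMSE noise signatures, 200 cycles for GaitSD recovery (5%), 50 strides
per synthetic trial and 2 trials per activity for the pipeline suite.
Cross-module identities (GV = product of eigenvalues) are held to 1e-8
relative; exact identities (micro-case GaitSD = √2, CMSE τ=1 = SampEn,
brute-force pair counts) are asserted with no tolerance at all.

## Known limitations

* The Lyapunov estimator inherits all the caveats of its family: it
  assumes an autonomous, time-invariant system, needs long stationary
  records, and its value depends on the fit window. The default window
  is principled, but comparisons should only ever be made with
  identical settings; treat the absolute number with caution.
* Entropy at coarse scales becomes undefined on short series; the flags
  make this visible rather than fatal, but CI values from trials much
  shorter than ~1,000 samples should not be compared.
* N95 is an integer statistic: it jumps. Aggregating across trials
  (mean ± SD) softens but does not remove this.
* Activity labels are metadata supplied by the user; the package never
  infers activity boundaries from the signal.
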