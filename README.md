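# gaitcomplexity

Complexity measures for multi-joint gait kinematics, in one tested R
pipeline.

Human-movement researchers quantify the "complexity" of locomotion in
three distinct ways, and the three can contradict each other on the
same data:

* **Dimensionality** — N95, the number of principal components needed
  to explain 95% of the variance of the joint-angle time series
  (covariance PCA over frames × channels, cumulative ≥ 95% rule);
* **Variability** — the generalized variance GV = det(Σ), the volume of
  the joint-configuration cloud (reported also as log GV and the
  geometric-mean form GV^(1/p)), and GaitSD, the stride-to-stride
  waveform deviation on 101-point time-normalized gait cycles:

  GVSD²ₖ = Σⱼ Σᵢ (Xᵢⱼ − X̄ⱼ)² / (T(N−1)),  GaitSD = (1/p) Σₖ √GVSD²ₖ ;

* **Nonlinear dynamics** — the largest Lyapunov exponent of the
  delay-embedded sagittal joint angles (delay from the first local
  minimum of average mutual information, dimension from global false
  nearest neighbours at the 10% Kennel criterion, divergence slope by
  the Rosenstein method), and composite multiscale sample entropy
  (m = 2, r = 0.2 × SD, scales τ = 1..20) with its Complexity Index
  CI = Σ_τ CMSE(x, τ, m, r).

The package implements the full pipeline — loading wide-CSV trials,
segmenting strides at foot contacts, time-normalizing cycles, every
measure above, per-activity aggregation, and a cross-measure ranking
table with Kendall's W — plus synthetic generators (multi-joint gait
with controllable latent rank, variance scale, stride noise and timing
chaos; 2-D Gaussian toy clouds; sine / white / pink / logistic / Lorenz
benchmarks) so that every estimator is validated against analytic or
ground-truth values without any external data.

## Worked example

```r
library(gaitcomplexity)

# a synthetic 18-channel trial: 50 strides at 60 Hz, latent rank 3
g <- generate_gait(gait_gen_config(latent_rank = 3, n_strides = 50,
                                   seed = 42),
                   trial_id = "demo", activity_label = "walk")
g$trial
#> <kin_trial> demo [walk]
#>   3303 frames x 18 channels at 60 Hz (55.0 s)

report <- analyze_activity(list(g$trial), list(g$contacts),
                           activity_label = "walk")
report
#> <activity_report> walk: 1 trial(s), 49 cycle(s)
#>   N95 3.00 +/- 0.00 | GV^(1/p) 0.931 deg^2 | GaitSD 0.546 deg | LyE 0.449 /s | CI 9.26

report$per_trial[[1]]$nld
#> <nld_summary> 6 channel(s)
#>   hip_L_sagittal: dim 4, delay 10, LyE 0.585 /s, CI 11.6
#>   hip_R_sagittal: dim 3, delay 8, LyE 0.608 /s, CI 8.33
#>   knee_L_sagittal: dim 3, delay 10, LyE 0.231 /s, CI 8.19
#>   knee_R_sagittal: dim 3, delay 16, LyE 0.315 /s, CI 6.96
#>   ankle_L_sagittal: dim 3, delay 10, LyE 0.581 /s, CI 10.3
#>   ankle_R_sagittal: dim 3, delay 10, LyE 0.374 /s, CI 10.1
```

Reading this: the PCA needed exactly the 3 latent directions the
generator injected (N95 = 3); the configuration cloud is small
(GV^(1/p) ≈ 0.93 deg² per axis); strides deviate from the mean waveform
by ~0.55° RMS; the per-joint Lyapunov exponents are small and positive
(a near-periodic signal with stride-level noise) and the Complexity
Index sits near the low end typical of regular motion.

The designed cross-measure disagreement, end to end:

```r
suite <- generate_discordant_activities(seed = 1)
reports <- lapply(names(suite), function(a)
  analyze_activity(lapply(suite[[a]], `[[`, "trial"),
                   lapply(suite[[a]], `[[`, "contacts"),
                   activity_label = a))
rank_activities(reports)
#> <ranking_table> rank 1 = most complex
#>               walk highdim highvar irregular
#> n95              4       1     2.5       2.5
#> normalized_gv    4       3     1.0       2.0
#> gait_sd          4       3     1.0       2.0
#> lye              3       1     4.0       2.0
#> ci               4       3     2.0       1.0
#> Kendall's W = 0.469
```

Three different activities are "most complex" depending on the measure
(dimensionality → `highdim`, generalized variance → `highvar`, entropy
→ `irregular`), while the periodic low-noise walking analogue is
simplest under all of N95, GV and CI at once.

## Input formats

* Trial CSV: one row per frame; column 1 `time` (s), remaining columns
  named `<joint>_<side>_<plane>`, e.g. `knee_L_sagittal`, angles in
  degrees. `load_trial()` / `write_trial()` round-trip losslessly.
* Contacts CSV: columns `frame_index` (1-based) and `foot` (`L`/`R`).
* Normalized cycle sets serialize as `<stem>.csv` (long format: cycle,
  phase, channel, value) plus `<stem>.json` (dimensions, channel
  labels, source trials) via `write_cycle_set()` / `read_cycle_set()`.
* Activity reports are deterministic JSON (`write_activity_report()`),
  ranking tables CSV (`write_ranking()`).

A thin command-line wrapper with `simulate`, `analyze` and `rank`
subcommands is installed at `inst/cli/gaitcomplexity.R`.

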