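---
title: "Methods: estimating subjective pain from wearable sensor segments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating subjective pain from wearable sensor segments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painwear)
```

## The problem

During treatment of an acute sickle-cell pain crisis, patients rate their
pain on a 0–10 visual-analog scale — occasionally, subjectively, and at
minute-resolution timestamps — while a wrist-worn device records physiology
and movement roughly once per second. `painwear` implements a
between-subject pipeline that estimates those sparse subjective scores from
the dense objective signals: eight channels (heart rate, R-R interval,
galvanic skin response, skin temperature, Z-axis acceleration, Y/Z angular
velocity, and a cumulative step count), pooled across patients into a single
model.

The pipeline has four stages, each exposed as ordinary functions:

1. **Alignment** — each pain report is matched to the one-minute sensor
   segment recorded at the same hour and minute; when no same-minute
   segment exists, the nearest segment within a tolerance (default 10
   minutes, inclusive) is used, on the assumption that pain changes slowly
   relative to the reporting cadence. Equidistant ties break toward the
   *earlier* segment, preferring physiology that precedes the report.
   Records with no admissible segment are returned as unmatched rather than
   erroring: matched plus unmatched always partition the input.
2. **Feature extraction** — each matched segment is denoised with a
   centered, edge-truncated moving average and summarised by eight
   statistics per channel (mean, population SD, mean derivative, RMS,
   peak-to-peak, peak-to-RMS, peak count, power), giving up to
   8 × 8 = 64 features per record.
3. **Wrapper feature selection** — greedy forward selection or backward
   elimination scored by the out-of-fold RMSE of a chosen regression
   family, because the value of a feature subset is defined by the learner
   that will use it.
4. **Modelling and evaluation** — ridge, lasso, Gaussian-process and
   support-vector regression under 10-fold cross-validation (RMSE, Pearson
   r, residual tables), plus a four-level classification route: scores are
   binned as none (0), mild (1–3), moderate (4–6), severe (7–10), and a
   native SVM is compared against the regressor's binned predictions via
   per-class F1 and support-weighted F1.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `tolerance_min` | 10 | minutes | inclusive reading of the "under ten minutes" matching rule; at minute resolution the open/closed distinction is a one-minute edge case, so it is config-exposed |
| `min_coverage` | 0.8 | fraction | a channel enters a segment only with ≥ 80% of its nominal 60 samples; guards statistics against near-empty windows |
| `window` | 5 | samples | moving-average length; 5 s at 1 Hz suppresses sample noise while preserving minute-scale structure |
| `steps_as_increments` | `TRUE` | — | statistics on a monotone counter are degenerate (peak count identically 0); differencing makes them describe walking activity |
| `lambda` | 1.0 | — | ridge/lasso strength on standardized features |
| `cost`, `epsilon` | 1.0, 0.1 | — | SVR/SVM parameters, fixed per run (no nested tuning: one model per family is reported) |
| `k` | 10 | folds | cross-validation |
| `tol` | 1e-4 | RMSE | minimum improvement for the wrapper to continue |

Kernel methods use the RBF kernel with the scale set by the median
pairwise-distance heuristic *on the training folds only*; SVR and SVM use
the same kernel so the regression-vs-classification comparison is fair.
Standardization parameters are likewise fit per training fold.

## Numerical and convention choices

* **Population SD** (the 1/n form) everywhere, matching the RMS/power
  family; the mean-only baseline RMSE then equals the target's population
  SD exactly.
* **RMS is `sqrt(power)` by construction**, so the identity `rms² = power`
  holds to machine precision.
* **Peaks** are interior runs of equal values strictly greater than both
  neighbours; a plateau counts once, endpoints never count. Counting
  happens after filtering.
* **Derivative** is the mean first difference divided by the sampling
  interval taken from the channel's actual timestamps (units per second).
* **Degenerate inputs** raise errors naming the statistic (too-short
  input; peak-to-RMS of an all-zero signal); inside `extract_features()`
  such entries are flagged `NA`, never silently zeroed, and rows carrying
  them are dropped (and counted) before modelling.
* **Fractional scores** use half-open category bins anchored at the
  integer bounds (none < 1 ≤ mild < 4 ≤ moderate < 7 ≤ severe), so an
  app-logged 0.41 is "none". Predictions are clamped to [0, 10] before
  binning. Zero-support classes are excluded from the weighted F1 (not
  counted as 0).
* **Ties** in the wrapper break toward the lexicographically smallest
  feature name; the fold assignment is drawn once per run so every
  candidate subset is scored on identical splits.
* **Zero-variance features** are dropped before selection: a constant
  column leaves every model's predictions unchanged, so it can only pad
  greedy rankings with no-ops.
* All statistics are computed on the *filtered* signal, including those
  insensitive to noise — one convention for all eight rather than a
  per-statistic mix.

## The synthetic cohort generator

No public dataset with this structure exists, so `sim_config()` /
`generate_cohort()` emulate one: 20 sessions of mean duration 3.79 h (SD
2.23, truncated at 0.5 h) at 1 Hz — about 5,800 sensor values per channel
per patient — with 2 app-logged and 3–4 nurse-charted pain reports per
session, which after matching pools to roughly 107 records.

Each session has a latent pain trajectory `p(t)`: piecewise constant with
downward jumps at 2–4 simulated medication times (treatment-driven relief,
not a smooth ramp), with the jump sizes summing to a total in-stay decrease
drawn from N(2.75, 2.34) truncated at zero. The severity mix of reported
scores is controlled by four class weights (defaults 2/4/34/67 for
none/mild/moderate/severe). A session draws a severity anchor from those
weights, uniform within the level's score interval; the anchor is the level
the stay *settles at* after treatment, and presentation pain sits the total
decrease above it (capped at 10). This anchoring was chosen over anchoring
the trajectory's start or midpoint because only the end-of-stay reading
keeps the pooled reports severe-dominated once the in-stay decrease and the
10-point ceiling interact: patients present near the top of the scale and
are treated down toward their settle level.

Channels are `baseline + coupling · p(t) + AR(1) noise` (coefficient 0.9 —
autocorrelated noise gives the moving-average filter realistic work).
Defaults couple heart rate (+2 bpm per pain point) and skin conductance
(+15 kΩ per point) positively and the step *rate* negatively
(Poisson increments with rate `max(0, -c·(10 - p))`, so the counter freezes
at maximal pain and a zero coefficient freezes it entirely). Baselines
(e.g. 85 bpm, 33 °C) and noise SDs are placeholders for plausible resting
physiology, not estimates of any dataset. Reports are the latent value at
the report minute plus N(0, 0.5) reporting noise, clamped to [0, 10];
nurse scores are rounded to integers, app scores keep two decimals, and a
config flag can bias nurse reports to probe the assumption that the two
sources are interchangeable. Session `i` is seeded `seed + i`, so cohorts
are bit-reproducible and individual sessions regenerable in isolation.

**What the generator does not emulate** — and therefore what passing tests
do *not* establish about clinical data: medication pharmacokinetics,
movement artefacts and device dropout, circadian structure, inter-patient
baseline heterogeneity, or any nonlinear pain–physiology link beyond the
rate floor. The linear coupling with modest noise makes synthetic
regression performance (RMSE well below the score SD, r > 0.9) far better
than is plausible clinically; the simulation checks are about *mechanism*
(the right features get selected, regression beats the native classifier
under severe-skewed class imbalance, every family beats the mean-only
baseline), not about attainable accuracy.

## Design choices where the design was open

* **Matching** uses nearest-in-time among admissible segments (an
  any-within-tolerance mode would also be defensible; nearest is
  implemented and the tolerance is config-exposed). App and nurse scores
  follow the same rule, and both are kept when they share a minute.
* **The wrapper's learner** defaults to the family later evaluated (SVR),
  since subset value is learner-relative; the objective is out-of-fold
  RMSE in both directions.
* **Cross-validation pools rows from all sessions** (a between-subject
  model); `cv_predict(folds = session_labels)` provides a grouped mode for
  leakage-aware sensitivity analysis.
* **Selected feature sets are data-dependent outputs**, not constants of
  the artifact: on synthetic cohorts the selected names follow the
  configured couplings, not any fixed published list.
* **Evaluation is out-of-fold throughout**, including the classification
  metrics.

## Problem sizes used in the test-suite

Unit and property tests run on sequences of length 2–120, tables of 2–6
features, and cohorts of 2–6 short sessions; the simulation-based checks
(feature recovery, regression-vs-classification) use ten 20-session
cohorts at the default configuration — the study-scale condition — which
keeps the whole suite within a few minutes on one CPU.

## Limitations

Pooled cross-validation shares patients between folds, which flatters
between-subject generalisation; sub-minute alignment, frequency-domain and
HRV features, per-patient normalisation and personalised models are out of
scope; and the weighted F1 under extreme imbalance remains dominated by the
majority class even when minority classes are never predicted correctly —
the per-class F1 vector should always be read alongside it.
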