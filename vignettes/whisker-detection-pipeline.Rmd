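---
title: "Analyzing whisker detection learning: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing whisker detection learning: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whiskerlfp)
```

## The experiment this package models

Head-fixed, water-restricted mice learn a go/no-go detection task: a brief
deflection of a single whisker predicts that licking a spout within a 1 s
response window will be rewarded. Stimulus and catch trials are interleaved
with 50% probability at random 6–12 s inter-trial intervals; a lick during
the 3–4 s no-lick window preceding a scheduled trial aborts it. Performance
is summarized by the hit rate (licks on stimulus trials), the false-alarm
rate (licks on catch trials) and the signal-detection sensitivity

$$d' = Z(\text{hit rate}) - Z(\text{FA rate}),$$

with $Z$ the inverse standard-normal CDF. While mice learn, local field
potentials (LFP) are recorded at 2 kHz from six cortical areas — wS1, wS2,
wM1, PtA, dCA1 and mPFC — and, in separate cohorts, single units are
recorded in mPFC with silicon probes. The scientific pattern the pipeline
is built to quantify: sensory areas respond to the whisker deflection from
the first day, whereas short-latency (< 50 ms) evoked responses in dCA1 and
mPFC *emerge with learning*, track daily performance, are larger on hit
than miss trials, and are absent when the same stimulus is presented
without reward contingency (neutral exposure).

## Package shape

The package has three layers:

1. **Data model** (`trial_table`, `continuous_recording`, `unit_data`,
   `session_meta`): validated containers plus an HDF5 session file
   (`write_session()`/`read_session()`) with a CSV trial-table mirror.
2. **Analyses**: behavior (`dprime()`, `session_performance()`,
   `select_trained_sessions()`), evoked potentials (`preprocess_lfp()`,
   `extract_epochs()`, `average_sep()`, `find_first_peak()`,
   `onset_latency()`, `windowed_paired_test()`,
   `peak_vs_dprime_correlation()`), ROC decoding (`sp_curve()`), spikes
   (`psth()`, `modulation_test()`, `hit_miss_unit_test()`), inactivation
   (`opto_compare()`, `muscimol_compare()`), and a nonparametric toolkit
   (`wilcoxon_signed_rank()`, `mann_whitney()`, `holm_adjust()`,
   `dunn_holland_wolfe()`).
3. **Synthetic cohorts** (`cohort_scenario()`, `simulate_session()`,
   `make_cohort()`): generators that emulate the statistical structure the
   analyses assume, so that every stage can be validated by parameter
   recovery without recorded data.

Because the package is a multi-stage pipeline rather than a single
estimator, it is organized as a family of stage functions returning small
S3 result objects (`sep_result`, `sp_curve`, `modulation_result`,
`pairwise_result`) rather than one `fit()`-style entry point.

## Behavioral conventions

* All within-trial times are seconds relative to trial onset; catch trials
  carry a scheduled "virtual" onset so they can be epoched identically.
  Every window in the package is half-open $[a, b)$.
* A stimulus trial with a lick in $[0, 1)$ s is a hit; a catch trial with a
  lick there is a false alarm. Hits whose first lick precedes 0.1 s are
  flagged *premature*: they may be chance licks rather than detections.
  Premature hits **count toward the hit rate** (nothing suggests they went
  unrewarded) but are **excluded from hit-trial evoked-response averages**,
  where response specificity matters. This asymmetry is deliberate and
  surfaced in `trial_mask()`.
* The loglinear correction, $(n_\text{hit}+0.5)/(n_\text{stim}+1)$ and
  likewise for false alarms, is applied to every session rather than only
  to extreme ones, so that $d'$ is finite everywhere and no session is
  treated specially.
* "Trained" sessions for evoked-response analysis are the first three days
  with day index > 4 and $d' > 1$; neutral-exposure analyses use the last
  three exposure days.

## LFP processing

* **Artifact removal.** The 1 ms electromagnetic stimulation artifact is
  blanked by linear interpolation over $[0, 2)$ ms after each delivered
  stimulus, *before* filtering, so that filter ringing cannot smear it.
* **Filtering.** 0.1–100 Hz band-pass, 4th-order Butterworth applied
  forward–backward (zero phase). The coefficients come from
  `signal::butter()`; the forward–backward application runs in compiled
  code with odd-reflection padding because cohort-scale traces (millions
  of samples per channel) make an R-level loop the bottleneck. Equivalence
  with `signal::filtfilt()` away from the edges is asserted in the tests.
* **Epoching.** Windows of $[-50, 300)$ ms around onsets, each trial
  corrected by its own 50 ms pre-onset baseline mean.
* **First-peak measurement.** The first peak is the earliest local
  extremum of the area's polarity (positive in mPFC, negative elsewhere)
  inside 3–100 ms whose magnitude exceeds `k_sd` baseline SDs of the
  waveform. The default gate is 2 SD, appropriate for single-session
  averages; for grand averages pooling thousands of trials the baseline SD
  is so small that pre-latency noise wiggles can cross 2 SD, and a 4 SD
  gate is used instead. Condition contrasts (D1 vs Trained, Hit vs Miss)
  measure the waveform at the *same* reference time — the peak time of the
  reference condition — via `measure_at()` (nearest sample).
* **Onset latency** is the first post-onset time at which the absolute
  waveform exceeds 2 baseline SDs for at least 5 ms. The underlying
  experiments report latencies without defining an estimator; this
  threshold-crossing rule is this package's documented convention, so
  absolute latency values are comparable *within* analyses run by this
  package but not necessarily to values obtained with other estimators.
* **Windowed condition comparison** runs a paired Wilcoxon signed-rank
  test across mice on consecutive 5 ms windows and reports *uncorrected*
  per-window p-values, mirroring the color-coded significance bars of the
  original displays. No correction across windows is applied; treat the
  map as descriptive, not confirmatory.

## ROC "stimulus probability"

Single-trial mean LFP amplitudes in 10 ms windows slid by 2.5 ms are
compared between stimulus and catch trials; the area under the ROC curve
is the stimulus probability (SP) for that window. Ties count one half
(`roc_auc()` is exactly the Mann–Whitney U divided by $n_s n_c$; the tests
assert this identity against `wilcox.test` and brute-force pair counting).
Chance bands come from 100 within-session label permutations (mean ± SD),
seeded explicitly for reproducibility. Curves are computed per session and
averaged across mice; whether the original analysis pooled sessions per
mouse before the ROC is not documented, so per-session-then-average is
this package's stated choice.

## Spike analyses

Units are classified by waveform trough-to-peak duration: regular-spiking
(RSU, putative excitatory) at ≥ 0.35 ms, fast-spiking (FSU) below. The
0.35 ms boundary is a field-standard default and a parameter, since the
exact boundary used in the source experiments is not published. The
bootstrap modulation test compares each unit's firing rate in the 1 s
windows before and after onset across hit trials: trials are resampled
1000 times, and the unit is called positively (negatively) modulated when
fewer than $\alpha/2$ of bootstrap mean differences fall at or below
(at or above) zero, giving a two-sided level of $\alpha = 0.05$. Hit–miss
differences per unit use a 1000-fold label permutation, a convention
adopted here because the original test is unnamed.

## Nonparametric toolkit

`wilcoxon_signed_rank()` and `mann_whitney()` wrap R's `wilcox.test`
(exact small-sample enumeration without ties, continuity-corrected normal
approximation otherwise); zero differences are dropped, and an all-zero
comparison returns p = 1 by documented convention. `holm_adjust()` wraps
`p.adjust`. The Dunn–Holland–Wolfe procedure — joint ranking of all
observations, pairwise mean-rank differences against a critical value at
family level α with tie correction and a Bonferroni split across the
$k(k-1)/2$ pairs — is implemented here because no installed package
provides it; its decisions are checked in the tests against a
permutation-based max-statistic oracle on small instances. With complete
separation and $k = 3$ groups, adjacent-group comparisons only become
significant from about $n = 10$ per group; this is a property of the
procedure, not a bug.

## The synthetic generator: what it emulates, and what it does not

The generator's defaults are the study conditions the analyses assume:

* **Trial schedule**: 6–12 s uniform inter-trial intervals, 50% catch
  trials, 1 s response window, an abort probability of 0.05 (the real
  abort rate is unreported; this is a free parameter), 4% premature hits.
* **Learning**: hit probability follows a logistic in training day rising
  from the false-alarm rate (0.16) to an asymptote of 0.80, with
  half-maximum at day 3 and a slope of 0.8 days. These values place the
  trained-selected sessions (day > 4, $d' > 1$) at hit ≈ 0.76–0.79 and
  $d' \approx 1.7$–1.9, the regime the task is learned to in 5–12 days.
  Neutral exposure replaces the lick model by a stimulus-independent
  per-trial lick probability (0.2).
* **Evoked kernels**: per area, a difference-of-exponentials kernel (the
  published waveforms have no stated functional form) with onset latencies
  ordered wS1 (5 ms) < wS2 < wM1 < PtA < dCA1 (16 ms) < mPFC (18 ms), all
  peaks < 50 ms, negative polarity except mPFC. Amplitude is
  `base + gain × d'`: wS1/wS2 have large bases and zero gain (stable with
  learning); dCA1/mPFC have near-zero bases (15/10 µV) and gains of
  40/35 µV per $d'$ unit (they emerge with learning). Hit trials scale the
  kernel by a per-area `hit_gain` (1.0 in wS1 up to 1.3 in dCA1/mPFC). In
  the neutral paradigm every gain is forced to zero. A 1 ms, 1500 µV
  artifact impulse is injected at each delivered stimulus so the blanking
  step is genuinely exercised.
* **Noise**: stationary AR(1) with marginal SD 60 µV and coefficient 0.95
  at 2 kHz (≈ 10 ms correlation time), a realistic smoothness/amplitude
  regime for cortical LFP relative to the 10–250 µV signals.
* **Spikes**: inhomogeneous Poisson units at 5 Hz baseline; one third
  positively and one third negatively modulated (±50% of baseline over the
  1 s post-onset window on hits, half that on misses; no modulation under
  neutral exposure); trough-to-peak durations from an RSU/FSU Gaussian
  mixture (0.60 ± 0.08 ms vs 0.25 ± 0.04 ms, 20% FSU).
* **Inactivation**: photo-inhibition on 30% of trials multiplies the hit
  probability by a per-area factor (0.3 in wS1/wS2/dCA1/mPFC scenarios,
  1.0 in wM1/PtA); muscimol scenarios apply the factor session-wide.
* **Determinism**: every (mouse, day) session draws from a substream
  derived from the master seed by fixed offsets (`derive_seed()`), so
  cohorts are reproducible and any single session can be regenerated in
  isolation.

What the generator does **not** emulate — and therefore what passing tests
do not establish about recorded data: 1/f and oscillatory LFP structure,
movement and lick artifacts, electrode drift, correlated noise across
areas, spike-waveform shape beyond duration, history-dependent behavior
(impulsivity, satiety, lapses), and any trial-to-trial coupling between
neural amplitude and single-trial choice beyond the fixed hit/miss gain.
Parameter recovery on this generator validates the *pipeline arithmetic*,
not the biology.

## Validation strategy and problem sizes

The test suite validates each stage against independent oracles: a
rational-approximation inverse normal (Acklam + Newton) for $d'$;
brute-force pair counting and the Mann–Whitney identity for the ROC area;
permutation oracles for the rank procedures; and null-calibration runs
(zero-coupling cohorts, homogeneous Poisson units) that check empirical
false-positive rates against nominal levels. Parameter recovery runs a
14-mouse × 8-day × 200-trial detection cohort through the full LFP
pipeline and requires grand-average peak times within ±2 ms and amplitudes
within ±10% of the programmed kernels, a significant positive
amplitude–$d'$ Pearson correlation in mPFC/dCA1 and none in wS1; the
neutral-exposure counterpart (12 mice) must show no evoked-response growth
anywhere and chance-level decoding in mPFC/dCA1; the opto analysis (8 mice,
10 cohort seeds) must flag hit-rate reductions exactly in the areas where
they were programmed. These cohort sizes were chosen to match the scale of
the modeled experiments while keeping a full validation run in minutes on
one core.

## Known limitations

* The latency estimator and peak gate are conventions; absolute latencies
  and near-threshold peaks are estimator-dependent.
* The per-window Wilcoxon map is uncorrected by design; its "significant"
  windows are descriptive.
* `read_trials_csv()` reconstructs only the first lick per trial; the
  full lick sequence lives in the HDF5 container.
* The Dunn–Holland–Wolfe critical values are asymptotic; for very small
  groups the permutation oracle in the tests is the better reference.
* Muscimol comparisons use absolute post-injection block rates (pre/post
  deltas are available to the caller); whether the original analysis used
  deltas is not documented.
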