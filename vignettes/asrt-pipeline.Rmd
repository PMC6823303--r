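---
title: "Simulating and analysing the alternating serial reaction time task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing the alternating serial reaction time task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asrtlab)
```

## The task and its probability structure

In the alternating serial reaction time (ASRT) task, participants respond to
arrows pointing in one of four directions (1 = left, 2 = up, 3 = down,
4 = right). Unbeknownst to them, an eight-element sequence alternates
predetermined ("pattern") and random elements — for instance 2–r–1–r–3–r–4–r,
where each `r` is drawn uniformly. A standard session has 30 blocks of 85
trials (5 random warm-up trials, then ten repetitions of the eight-element
cycle), 2,550 trials in all.

Because presentation is cyclic and continuous, the 24 permutations of the
four directions collapse to 6 sequence equivalence classes
(`enumerate_unique_sequences()`); one is assigned per participant
(`select_sequence()`).

The alternation induces second-order transitional probabilities: of three
consecutive trials (a *triplet*; the window moves trial by trial, so every
trial is the final element of one triplet), the first predicts the third.
If the third direction is the sequence's cyclic successor of the first, the
triplet is *high-probability*; there are 16 such types among the 64, and in
the steady state each occurs with per-trial probability

$$P(\text{high type}) = \tfrac12\cdot\tfrac1{16} + \tfrac12\cdot\tfrac1{64}
 = \tfrac5{128}, \qquad
P(\text{low type}) = \tfrac12\cdot\tfrac1{64} = \tfrac1{128},$$

the five-fold frequency ratio of the task. The transitional probability that
direction $d$ is followed two trials later by its successor is
$0.5 + 0.5 \times 0.25 = 62.5\%$ (12.5% for each other direction), because
trials two apart are both pattern or both random, each with probability 1/2.
`enumerate_triplets()` and `transitional_probability()` return these values
analytically; `classify_stream()` labels generated streams empirically, and
the test suite checks the two routes against each other.

Trial categories follow the field's convention: pattern trials are always
`pattern_high` (they instantiate the sequential regularity even at the block
boundary, where the moving window reaches into the warm-up trials and the
literal successor rule would occasionally fail); random trials split into
`random_high` and `random_low` by the successor rule. Trills (1–2–1) and
repetitions (1–1–1) — necessarily low-probability — are excluded from RT and
ERP analyses because of preexisting response tendencies
(`filter_analysis_triplets()`). Warm-up-final triplets are labeled but
excluded by default (`include_warmup_triplets = FALSE`): the standard
analysis protocol does not specify them, and excluding them keeps per-block
category counts aligned with the alternation design.

## What the synthetic cohort emulates

No public data exist for this paradigm at the trial level, so the package
ships a generator whose defaults encode the study conditions:

* **Layout** — 32 subjects × 30 blocks × 85 trials; six epoch bins of five
  blocks each.
* **Reaction times** — `RT = baseline + category effect + epoch effect +
  noise`, with baseline 365 ms, category offsets −5 / −2 / +5 ms for
  random-high / pattern / random-low (the observed ordering: fastest on
  random high-probability triplets), a shallow practice curve across bins,
  and additive mean-zero lognormal noise (SD 60 ms, fixed log-scale shape
  0.5). The noise family is a design choice: RTs are positive and
  right-skewed, and since the downstream statistic is the cell *median*, the
  exact family is non-critical. RTs are truncated at the 700 ms response
  deadline (200 ms stimulus + 500 ms blank; the task never states an RT
  ceiling, so the deadline is adopted as one).
* **Accuracy** — ~93% correct per category (93.2 / 94.0 / 91.9), misses at
  0.5%; misses count as incorrect in accuracy tables because the task's
  feedback treats them as failures.
* **EEG** — per-trial multichannel segments on a stimulus-anchored axis
  [−700, 1300) ms so both lockings can be cut from the same array. The P3 is
  two Gaussian components (peak at 330 ms, SD 40 ms; late bump at 470 ms,
  SD 80 ms) whose amplitudes are solved per trial so that the stimulus-locked
  peak-window (280–380 ms) and late-window (380–600 ms) means equal the
  configured per-category values exactly in the noiseless case — 3.74 /
  3.61 / 3.67 µV at the peak for pattern / random-high / random-low, and a
  category × epoch late-P3 surface around 0.6–1.4 µV that declines after the
  second bin, most steeply for random high-probability triplets. The
  component rides on the centroparietal pool (CP1, CPz, CP2, P1, Pz, P2) at
  unit gain and on other channels attenuated, plus white noise (SD 10 µV).
  Sampling is 250 Hz by default (configurable) — a desk-scale choice; the
  original recording used 1000 Hz, which only changes discretization error.
* **Artifacts** — with probability 0.5% per trial, a 20-ms ±150 µV excursion
  on one channel inside the stimulus-locked span, so the downstream ±100 µV
  rejection recovers the configured rate.
* **Generation task** — inclusion/exclusion runs of 24 presses (4 runs per
  condition). At each press the high-probability continuation of the press
  two back is chosen with probability `bias`, else uniformly among the other
  three keys; `bias = 0.25` is exactly uniform pressing, anchoring the 25%
  chance level. Default biases 0.315 / 0.281 emulate the reported production
  rates.
* **Between-subject structure** — subject shifts on baseline RT (SD 20 ms)
  and on the P3 amplitude applied to *all* categories (SD 1 µV; amplitudes
  correlate strongly within subject, so the shift preserves category
  differences), small jitter on category effects (2 ms RT, 0.05 µV P3) and
  on the generation biases (0.05). The jitter SDs are set so that the
  injected category differences are detectable at n = 32 with test
  statistics of the reported order of magnitude.

What the generator does **not** emulate: biophysical EEG (no 1/f spectrum,
dipole topography, or ocular/cardiac artifact morphology), upstream
preprocessing (filtering, ICA, interpolation, re-referencing — synthetic
segments are generated at that stage of cleanliness), RT–ERP single-trial
coupling, and sequence-wide autocorrelation of attention. Passing tests
therefore certify the *pipeline arithmetic* and its statistical behaviour
under the stated model, not the neuroscience of real recordings.

## Measurement pipelines

**Behaviour.** For each subject × epoch bin × category cell, the median RT
over analyzable, correct, RT > 0 trials (`compute_rt_table()`); the
`random_combined` category pools random-high and random-low *trials* before
taking the median — it is not the mean of the two medians. Accuracy tables
(`compute_accuracy_table()`) use all analyzable trials. Empty cells warn and
flag the subject for exclusion from the ANOVA.

**ERP.** `segment_trials()` cuts stimulus-locked ([−200, 600) ms) or
response-locked ([−700, 700) ms) epochs for correct, RT > 0, analyzable
trials; response-locked cuts are snapped to the sample grid at
stimulus + RT, and trials whose window exceeds the stored array (RT >
600 ms) are dropped with a count. `baseline_correct()` subtracts the
per-channel mean over [−200, 0) (stimulus) or [500, 700) (response, the end
of the response-to-stimulus interval). `reject_artifacts()` removes a
segment iff any sample at any channel strictly exceeds ±100 µV.
`average_and_pool()` averages within cells, then across the centroparietal
pool; `measure_component()` takes the arithmetic mean over the component
window. All windows are half-open `[start, end)` in ms, converted to samples
by inclusion of sample times with `start <= t < end` — 380 ms belongs to the
late P3 only, and shared boundaries are never double-counted.

**Generation scoring.** `score_generation()` applies the moving window
within runs (never across them) and counts *all* triplets, trills and
repetitions included: the 25% chance level (16 of 64 types) presumes their
inclusion, which is why this scoring deliberately diverges from the RT/ERP
trial filter.

## Statistics

`rm_anova()` implements the balanced within-subject factorial partition for
up to three factors: each effect's sum of squares comes from
inclusion–exclusion over marginal means, and its error term is the
effect × subject interaction. Reported per effect: *F*, uncorrected degrees
of freedom, the Greenhouse–Geisser ε (classical sample estimator: the cell
covariance projected onto an orthonormal contrast basis,
$\varepsilon = \mathrm{tr}(E)^2 / (d\,\mathrm{tr}(E^2))$, clipped to
$[1/d, 1]$), the corrected *p* (applied when the effect has more than one
numerator df and ε < 1), and partial eta-squared
$\eta_p^2 = SS_{\text{effect}} / (SS_{\text{effect}} + SS_{\text{error}})$.
Two numerical conventions are worth stating: the corrected *p* is never
reported below the uncorrected one (with *F* < 1 the df-shrunken tail
probability can cross over; the correction is meant to be conservative), and
constant data raise an explicit undefined-*F* error rather than propagating
NaN. `lsd_pairwise()` runs uncorrected paired *t*-tests per level pair
(Fisher's LSD convention; a pooled-error variant is behind a flag), and
`one_sample_t()` / `paired_t()` provide the generation-task tests.

Which ε estimator produced any published statistic is generally unknowable;
the test suite therefore validates the engine against `stats::aov`
Error-strata decompositions and first-principles identities (F = t² for two
levels, ε = 1 under compound symmetry, the 1/(k−1) lower bound) rather than
against printed group statistics.

## End-to-end run and problem sizes

`run_full_pipeline(pipeline_config(...))` ties everything together:
simulate → classify → measure → ANOVAs (Type × Epoch on RT; Locking ×
Type × Epoch on P3 peak and late P3) → generation-task tests → a structural
verification report that recomputes the analytic constants. Every output
file carries version, master seed, and a config hash; the full configuration
is echoed to the output directory, and identical configs reproduce identical
bundles.

The packaged tests and the acceptance script use desk-scale problem sizes
chosen as the smallest that leave the Monte-Carlo error well under each
tolerance: ~1.2 × 10⁵-trial streams for distributional checks, 10⁴
generation runs for the chance level, 32-subject cohorts for parameter
recovery, and 500 replicate 10-subject cohorts for the type-I calibration.

## Known limitations

* Unbalanced or missing-cell designs are rejected, not estimated; subjects
  with empty cells must be excluded upstream (the configurable 35% maximum
  rejection fraction mirrors common practice).
* The ANOVA engine is within-subject only — no between-subject factors or
  mixed models.
* Response-locked averages of the synthetic P3 inherit RT variability
  (the template is stimulus-locked), so response-locked amplitudes are
  slightly smeared relative to stimulus-locked ones; real data behave the
  same way, but the degree is not calibrated.
* Peak latency is deliberately not measured (mean amplitudes only).
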