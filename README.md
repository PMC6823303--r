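# asrtlab

Simulation and analysis toolkit for the **alternating serial reaction time
(ASRT) task**, the four-choice paradigm used to study implicit statistical
learning with reaction times and event-related potentials (ERPs).

In the ASRT task an eight-element sequence alternates predetermined
("pattern") and random elements — e.g. 2–r–1–r–3–r–4–r over the four
directions 1 = left, 2 = up, 3 = down, 4 = right. The alternation hides a
second-order transitional probability structure: of any three consecutive
trials (a *triplet*, taken as a moving window so every trial ends one), the
third direction equals the cyclic successor of the first with probability

P(d<sub>t+2</sub> = succ(d<sub>t</sub>)) = ½·1 + ½·¼ = **62.5%**
(12.5% for each other direction),

because trials two apart are either both pattern or both random. Of the 64
triplet types, 16 are *high-probability* (per-trial probability 5/128 each)
and 48 *low-probability* (1/128 each) — a five-fold frequency ratio. Learning
shows up as faster responses and larger centroparietal P3 amplitudes on
high- than low-probability triplets.

The package provides, for researchers who work with this paradigm or need a
fully synthetic testbed for ERP pipelines:

* **Sequence model** — the six unique sequences (24 permutations modulo
  rotation), per-participant selection, block/session stream generation
  (`enumerate_unique_sequences`, `select_sequence`, `generate_session`);
* **Triplet engine** — moving-window classification
  (pattern-high / random-high / random-low, trill and repetition flags) and
  the exact analytic probability structure (`classify_stream`,
  `enumerate_triplets`, `transitional_probability`,
  `filter_analysis_triplets`);
* **Synthetic cohorts** — reaction times with category/practice effects and
  lognormal noise, multichannel EEG segments carrying a parameterised P3
  (peak and late components), >±100 µV artifacts, and inclusion/exclusion
  generation runs (`simulate_subject`, `simulate_cohort`, `map_cohort`);
* **Behavioral pipeline** — per-epoch-bin median RTs and accuracy by triplet
  type, process-dissociation scoring against the 25% chance level
  (`compute_rt_table`, `compute_accuracy_table`, `score_generation`);
* **ERP pipeline** — stimulus-/response-locked segmentation, baseline
  correction, ±100 µV rejection, centroparietal pooling, and P3-peak
  (280–380 ms) / late-P3 (380–600 ms) mean amplitudes (`segment_trials`,
  `baseline_correct`, `reject_artifacts`, `average_and_pool`,
  `measure_component`, `erp_measure_table`);
* **Stats engine** — within-subject factorial ANOVA with Greenhouse–Geisser
  ε, partial η², LSD pairwise follow-ups, one-sample/paired *t*-tests
  (`rm_anova`, `gg_epsilon`, `lsd_pairwise`, `one_sample_t`, `paired_t`);
* **Orchestration** — `pipeline_config()` + `run_full_pipeline()` for the
  whole simulate → classify → measure → test chain with reproducible seeds,
  config hashing, and CSV/JSON outputs.

## Worked example

```r
library(asrtlab)

sq <- select_sequence(seed = 2026)
sq
#> ASRT sequence: 1-r-4-r-2-r-3-r (cyclic)

# the defining transition: an element is followed two trials later by its
# cyclic successor with probability 62.5%
transitional_probability(sq, 4, sequence_successor(sq, 4))
#> [1] 0.625

# a small synthetic cohort, behavioral arm only
rep <- run_full_pipeline(pipeline_config(master_seed = 7, n_subjects = 8,
                                         n_blocks = 12, include_eeg = FALSE))
rep$rt_anova_three
#> Repeated-measures ANOVA (Greenhouse-Geisser corrected)
#>          effect df1 df2    F epsilon     p   p_gg eta_p2
#>        category   2  14 6.02   0.984 0.013 0.0135  0.462
#>           epoch   5  35 1.90   0.578 0.120 0.1640  0.213
#>  category:epoch  10  70 0.71   0.358 0.711 0.7110  0.092
```

The `category` main effect says the injected triplet-type RT differences
(−5 / −2 / +5 ms for random-high / pattern / random-low) are detected even in
this reduced 8-subject, 12-block cohort: F(2, 14) = 6.02, corrected
p = .013, η²ₚ = .46. `epoch` tracks general practice effects (not reliable at
this size), and their interaction is null, as injected. The generation-task
scores are tested against the 25% chance level the same way:

```r
rep$pdp$tests$exclusion_vs_chance
#> t(7) = 1.392, p = 0.2065, mean difference = 3.267
```

(the exclusion-condition bias is injected at ~3% above chance; with 8
subjects the test is underpowered, as expected — the default 32-subject
cohort detects it).

A full-size run with the ERP arm is
`run_full_pipeline(pipeline_config(master_seed = 1), out_dir = "out")`; it
writes tidy measure tables (`rt_table.csv`, `erp_table.csv`), ANOVA JSONs,
process-dissociation scores, and a structural verification report, all
stamped with the seed and a config hash.

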