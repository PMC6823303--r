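test_that("degenerate behavior generator returns the baseline everywhere", {
  st <- generate_session(canonical_sequence(), 6, rng_seed = 1)
  lab <- classify_stream(st)
  p <- behavior_params(baseline_rt = 400,
                       category_effects = c(pattern_high = 0,
                                            random_high = 0, random_low = 0),
                       epoch_effects = rep(0, 6), rt_noise_sd = 0,
                       accuracy = c(pattern_high = 1, random_high = 1,
                                    random_low = 1),
                       accuracy_other = 1, miss_rate = 0)
  beh <- simulate_behavior(st, lab, p, rng_seed = 2)
  expect_true(all(beh$rt == 400))
  expect_true(all(beh$correct))
})

test_that("accuracy parameter is recovered binomially", {
  st <- generate_session(canonical_sequence(), 120, rng_seed = 3)  # ~1e4 trials
  lab <- classify_stream(st)
  p <- behavior_params(accuracy = c(pattern_high = 0.93, random_high = 0.93,
                                    random_low = 0.93),
                       accuracy_other = 0.93, miss_rate = 0)
  beh <- simulate_behavior(st, lab, p, rng_seed = 4)
  n <- nrow(st)
  se <- sqrt(0.93 * 0.07 / n)
  expect_lt(abs(mean(beh$correct) - 0.93), 3 * se)
})

test_that("injected category effects order the empirical RT means", {
  st <- generate_session(canonical_sequence(), 60, rng_seed = 5)
  lab <- classify_stream(st)
  p <- behavior_params(category_effects = c(pattern_high = -2,
                                            random_high = -5,
                                            random_low = 5),
                       rt_noise_sd = 30)
  beh <- simulate_behavior(st, lab, p, rng_seed = 6)
  m <- tapply(beh$rt, lab$category, mean, na.rm = TRUE)
  expect_lt(m[["random_high"]], m[["pattern_high"]])
  expect_lt(m[["pattern_high"]], m[["random_low"]])
})

test_that("RT noise is right-skewed, mean-zero, with the requested sd", {
  x <- asrtlab:::with_seed(9, asrtlab:::rt_noise(2e5, 60))
  expect_lt(abs(mean(x)), 1)          # mean 0 +- MC error
  expect_lt(abs(sd(x) - 60), 1.5)
  expect_gt(mean((x / sd(x))^3), 0.5) # positive skew
  expect_true(all(simulate_behavior(
    generate_session(canonical_sequence(), 6, 1),
    classify_stream(generate_session(canonical_sequence(), 6, 1)),
    behavior_params(), 1)$rt <= 700, na.rm = TRUE))
})

test_that("noiseless EEG reproduces the configured window amplitudes", {
  rec <- tiny_subject(7, n_blocks = 6, include_eeg = TRUE,
                      erp = quick_erp_params(noise_sd = 0,
                                             artifact_rate = 0))
  et <- erp_measure_table(rec)
  stim <- et[et$locking == "stimulus" & et$category != "random_combined", ]
  amp <- rec$params$erp$p3_amp
  late <- rec$params$erp$late_p3_amp
  for (i in seq_len(nrow(stim))) {
    target <- if (stim$component[i] == "p3_peak") amp[[stim$category[i]]]
      else late[stim$category[i], stim$epoch[i]]
    expect_equal(stim$amplitude[i], target, tolerance = 1e-6)
  }
})

test_that("injected artifacts are rejected at the configured rate", {
  st <- generate_session(canonical_sequence(), 30, rng_seed = 10)
  lab <- classify_stream(st)
  p <- behavior_params(miss_rate = 0,
                       accuracy = c(pattern_high = 1, random_high = 1,
                                    random_low = 1), accuracy_other = 1)
  beh <- simulate_behavior(st, lab, p, rng_seed = 11)
  ep <- quick_erp_params(artifact_rate = 0.05)
  eeg <- simulate_eeg(st, lab, beh, ep, rng_seed = 12)
  rec <- list(id = 1, stream = st, labels = lab, behavior = beh, eeg = eeg)
  seg <- reject_artifacts(baseline_correct(segment_trials(rec, "stimulus")))
  n <- sum(seg$rejection$n)
  frac <- seg$n_rejected / n
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("uniform generation scores at the 25% chance level", {
  sq <- canonical_sequence()
  scores <- vapply(1:400, function(s) {
    runs <- simulate_generation_task(
      sq, generation_params(bias_inclusion = 0.25, bias_exclusion = 0.25),
      rng_seed = s)
    score_generation(runs$inclusion, sq)$pct_high
  }, numeric(1))
  se <- sd(scores) / sqrt(length(scores))
  expect_lt(abs(mean(scores) - 25), 3 * se)
})

test_that("high-probability production is monotone in the generation bias", {
  sq <- canonical_sequence()
  mean_score <- vapply(c(0.25, 0.5, 0.75), function(b) {
    mean(vapply(1:150, function(s) {
      runs <- simulate_generation_task(
        sq, generation_params(bias_inclusion = b, bias_exclusion = b),
        rng_seed = 1000 + s)
      score_generation(runs$inclusion, sq)$pct_high
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_score) > 0))
})

test_that("a constant-key run produces 0% high-probability triplets", {
  sc <- score_generation(list(rep(2L, 24L)), canonical_sequence())
  expect_equal(sc$pct_high, 0)
  expect_equal(sc$n_triplets, 22L)
})

test_that("cohorts are reproducible and collapse when sd = 0", {
  pop <- population_params(sd_baseline_rt = 0, sd_rt_category = 0,
                           sd_p3_shift = 0, sd_p3_category = 0, sd_bias = 0)
  c1 <- simulate_cohort(3, pop, rng_seed = 5, n_blocks = 6)
  c2 <- simulate_cohort(3, pop, rng_seed = 5, n_blocks = 6)
  expect_identical(c1[[2]]$behavior, c2[[2]]$behavior)
  expect_identical(c1[[3]]$stream, c2[[3]]$stream)
  # zero between-subject sd: all subjects share parameters
  m <- attr(c1, "manifest")
  expect_identical(m$params[[1]], m$params[[3]])
  expect_error(simulate_cohort(1), ">= 2")
})

test_that("map_cohort streams the same subjects simulate_cohort builds", {
  pop <- population_params()
  via_map <- map_cohort(function(r) r$behavior$rt[1:5], n_subjects = 3,
                        population = pop, rng_seed = 9, n_blocks = 6)
  full <- simulate_cohort(3, pop, rng_seed = 9, n_blocks = 6)
  expect_identical(via_map[[2]], full[[2]]$behavior$rt[1:5])
})
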