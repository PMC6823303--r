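noiseless_record <- function(seed = 7L, n_blocks = 6L, rt = NULL, ...) {
  st <- generate_session(canonical_sequence(), n_blocks, rng_seed = seed)
  lab <- classify_stream(st)
  p <- behavior_params(miss_rate = 0, rt_noise_sd = 0,
                       category_effects = c(pattern_high = 0,
                                            random_high = 0, random_low = 0),
                       epoch_effects = rep(0, 6),
                       baseline_rt = if (is.null(rt)) 365 else rt,
                       accuracy = c(pattern_high = 1, random_high = 1,
                                    random_low = 1), accuracy_other = 1)
  beh <- simulate_behavior(st, lab, p, rng_seed = seed + 1L)
  ep <- quick_erp_params(noise_sd = 0, artifact_rate = 0, ...)
  eeg <- simulate_eeg(st, lab, beh, ep, rng_seed = seed + 2L)
  list(id = 1L, stream = st, labels = lab, behavior = beh, eeg = eeg,
       params = list(erp = ep))
}

test_that("response-locked cuts align with the stimulus-locked axis", {
  rec <- noiseless_record(rt = 400)
  stim <- segment_trials(rec, "stimulus")
  resp <- segment_trials(rec, "response")
  tr <- stim$info$trial[1]
  k_resp <- which(resp$info$trial == tr)
  # sample at t = 0 response-locked equals sample at t = RT stimulus-locked
  v_resp <- resp$data[1, which(resp$times == 0), k_resp]
  v_stim <- stim$data[1, which(stim$times == 400), 1]
  expect_equal(v_resp, v_stim)
})

test_that("only analyzable correct trials yield segments; counts add up", {
  rec <- noiseless_record()
  flipped <- which(rec$labels$analyzable)[1:10]
  rec$behavior$correct[flipped] <- FALSE
  seg <- segment_trials(rec, "stimulus")
  qualifying <- sum(rec$labels$analyzable & rec$behavior$correct &
                      rec$behavior$rt > 0)
  expect_equal(dim(seg$data)[3] + seg$n_dropped, qualifying)
  expect_false(any(seg$info$trial %in% flipped))

  # perfect accuracy, 30 blocks: 200 pattern segments per epoch bin
  # (40 pattern trials x 5 blocks)
  rec30 <- noiseless_record(seed = 3, n_blocks = 30)
  seg30 <- segment_trials(rec30, "stimulus")
  pat <- table(seg30$info$epoch[seg30$info$category == "pattern_high"])
  expect_true(all(pat == 200L))
})

test_that("baseline correction zeroes the baseline window and is idempotent", {
  rec <- noiseless_record()
  seg <- segment_trials(rec, "stimulus")
  seg$data[] <- seg$data + 5  # constant offset
  bc <- baseline_correct(seg)
  win <- asrtlab:::window_index(bc$times, component_windows()$baseline$stimulus)
  expect_lt(max(abs(apply(bc$data[, win, , drop = FALSE], c(1, 3), mean))),
            1e-10)
  bc2 <- baseline_correct(bc)
  expect_equal(bc2$data, bc$data, tolerance = 1e-12)

  # a constant segment becomes all-zero
  segc <- seg; segc$data[] <- 7
  expect_true(all(abs(baseline_correct(segc)$data) < 1e-12))
})

test_that("rejection uses strict exceedance of the +/-100 uV threshold", {
  rec <- noiseless_record()
  seg <- segment_trials(rec, "stimulus")
  n <- dim(seg$data)[3]
  seg$data[2, 10, 1] <- 101       # one sample, one channel: rejected
  seg$data[3, 12, 2] <- 100       # exactly at threshold: retained
  out <- reject_artifacts(seg, threshold = 100)
  expect_equal(dim(out$data)[3], n - 1L)
  expect_false(seg$info$trial[1] %in% out$info$trial)
  expect_true(seg$info$trial[2] %in% out$info$trial)

  clean <- segment_trials(rec, "stimulus")
  kept <- reject_artifacts(clean, threshold = 100)
  expect_equal(kept$n_rejected, 0L)
  expect_equal(sum(kept$rejection$rejected), 0L)
})

test_that("pooling averages the CP pool and is order-invariant", {
  rec <- noiseless_record()
  seg <- baseline_correct(segment_trials(rec, "stimulus"))
  avg1 <- average_and_pool(seg)
  avg2 <- average_and_pool(seg, rev(asrtlab:::CP_POOL))
  expect_equal(avg1$waveforms, avg2$waveforms)
  expect_error(average_and_pool(seg, c("CP1", "Nope")), "missing pool")

  # single segment: pooled waveform equals its channel-pool mean
  one <- seg
  one$data <- seg$data[, , 1, drop = FALSE]
  one$info <- seg$info[1, , drop = FALSE]
  a <- average_and_pool(one)
  row <- which(a$cells$category == one$info$category &
                 a$cells$epoch == one$info$epoch)
  pool_idx <- match(asrtlab:::CP_POOL, dimnames(seg$data)[[1]])
  expect_equal(a$waveforms[row, ], colMeans(seg$data[pool_idx, , 1]))
})

test_that("window means match the analytic Gaussian integral", {
  fs <- 250
  times <- seq(-200, 600 - 1000 / fs, by = 1000 / fs)
  bump <- exp(-((times - 330)^2) / (2 * 40^2))
  got <- measure_component(bump, times, which = "p3_peak",
                           locking = "stimulus")
  analytic <- integrate(function(t) exp(-((t - 330)^2) / (2 * 40^2)),
                        280, 380)$value / 100
  expect_equal(got, analytic, tolerance = 1e-3)
  expect_equal(measure_component(rep(2.5, length(times)), times,
                                 which = "late_p3", locking = "stimulus"),
               2.5)
  expect_error(measure_component(bump, times + 1000, which = "p3_peak",
                                 locking = "stimulus"), "outside")
})

test_that("the noiseless template survives the full pipeline unchanged", {
  rec <- noiseless_record(rt = 330)
  et <- erp_measure_table(rec)
  stim_peak <- et[et$locking == "stimulus" & et$component == "p3_peak" &
                    et$category == "pattern_high", ]
  expect_equal(stim_peak$amplitude, rep(3.74, 6), tolerance = 1e-6)

  # with RT = 330 ms the template peak sits in both peak windows:
  # response-locked peak-window mean is near its stimulus-locked value
  resp_peak <- et[et$locking == "response" & et$component == "p3_peak" &
                    et$category == "pattern_high", ]
  expect_true(all(resp_peak$amplitude > 0.8 * stim_peak$amplitude))
})

test_that("measure table bookkeeping: retained + rejected = qualifying", {
  rec <- tiny_subject(13, n_blocks = 6, include_eeg = TRUE,
                      erp = quick_erp_params(artifact_rate = 0.05))
  et <- erp_measure_table(rec)
  rej <- attr(et, "rejection")$stimulus
  seg <- segment_trials(rec, "stimulus")
  expect_equal(sum(rej$n), dim(seg$data)[3])
  stim <- et[et$locking == "stimulus" &
               et$category %in% c("pattern_high", "random_high",
                                  "random_low"), ]
  expect_equal(sum(stim$n_segments[stim$component == "p3_peak"]),
               sum(rej$n) - sum(rej$rejected))
})
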