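# Synthetic multichannel EEG segments with a parameterised centroparietal
# P3 component.
#
# Each trial carries a stimulus-anchored array spanning -700..+1300 ms so
# that both stimulus-locked (-200..600 ms) and response-locked
# (-700..700 ms around the key press) epochs can be cut from it. The P3 is
# modelled as two Gaussian components on the stimulus axis: a peak bump
# (~330 ms) and a late slow bump (~470 ms) realizing the descending flank.
# Their amplitudes are solved per trial so that the *measured* mean
# amplitudes over the stimulus-locked P3-peak (280-380 ms) and late-P3
# (380-600 ms) windows equal the configured per-category values exactly in
# the noiseless case.

CP_POOL <- c("CP1", "CPz", "CP2", "P1", "Pz", "P2")

#' ERP generator parameters
#'
#' Defaults follow the study's structure: centroparietal pool channels plus
#' two attenuated non-pool channels, 250 Hz sampling (configurable; chosen
#' for desk-scale speed), P3 peaking at 330 ms, peak-window amplitudes of
#' 3.74 / 3.61 / 3.67 uV for pattern / random-high / random-low triplets,
#' and late-window amplitudes per category x epoch bin that decline after
#' the second bin, most steeply for random high-probability triplets.
#' White noise per sample and channel; occasional large-amplitude
#' excursions (> 100 uV) emulate residual artifacts.
#'
#' @param sampling_rate Hz.
#' @param channel_names channel labels; must include the CP pool
#'   (CP1, CPz, CP2, P1, Pz, P2).
#' @param nonpool_gain attenuation of the component on non-pool channels.
#' @param p3_latency peak latency, ms post-stimulus.
#' @param p3_width Gaussian SD of the peak bump, ms.
#' @param late_latency,late_width centre and SD of the late bump, ms.
#' @param p3_amp named per-category peak-window mean amplitude, uV.
#' @param late_p3_amp 3 x 6 matrix (category x epoch bin) of late-window
#'   mean amplitudes, uV; rows named by category.
#' @param noise_sd white-noise SD per sample, uV.
#' @param artifact_rate per-trial probability of an injected artifact.
#' @param artifact_amp artifact excursion, uV (must exceed 100 so injected
#'   artifacts are rejectable).
#' @return list of class `erp_params`.
#' @export
erp_params <- function(sampling_rate = 250,
                       channel_names = c(CP_POOL, "Fz", "Oz"),
                       nonpool_gain = 0.3,
                       p3_latency = 330, p3_width = 40,
                       late_latency = 470, late_width = 80,
                       p3_amp = c(pattern_high = 3.74,
                                  random_high = 3.61,
                                  random_low = 3.67),
                       late_p3_amp = default_late_p3_amp(),
                       noise_sd = 10,
                       artifact_rate = 0.005, artifact_amp = 150) {
  stopifnot(sampling_rate > 0, all(CP_POOL %in% channel_names),
            artifact_amp > 100, artifact_rate >= 0, artifact_rate <= 1)
  structure(list(sampling_rate = sampling_rate,
                 channel_names = channel_names, nonpool_gain = nonpool_gain,
                 p3_latency = p3_latency, p3_width = p3_width,
                 late_latency = late_latency, late_width = late_width,
                 p3_amp = p3_amp, late_p3_amp = late_p3_amp,
                 noise_sd = noise_sd, artifact_rate = artifact_rate,
                 artifact_amp = artifact_amp),
            class = "erp_params")
}

#' Default late-P3 amplitude calibration (category x epoch bin, uV)
#'
#' Amplitudes around 0.6-1.4 uV that decline after epoch bin 2, with the
#' steepest decline for random high-probability triplets, mirroring the
#' acquisition trajectory the late P3 is meant to express.
#'
#' @return 3 x 6 numeric matrix with rows pattern_high, random_high,
#'   random_low.
#' @export
default_late_p3_amp <- function() {
  m <- rbind(pattern_high = c(1.40, 1.44, 0.86, 1.17, 0.89, 1.14),
             random_high  = c(1.41, 1.30, 0.61, 0.86, 0.85, 0.80),
             random_low   = c(1.32, 1.30, 0.91, 1.22, 1.00, 1.23))
  colnames(m) <- paste0("epoch", 1:6)
  m
}

# stimulus-anchored time axis in ms: [-700, 1300), one sample per 1000/fs
eeg_times <- function(sampling_rate) {
  step <- 1000 / sampling_rate
  seq(-700, 1300 - step, by = step)
}

gauss_bump <- function(times, center, width) {
  exp(-((times - center)^2) / (2 * width^2))
}

# window means of both unit bumps over the stimulus-locked peak and late
# windows; inverted to map target window means to bump amplitudes
template_mix <- function(times, params, windows) {
  g1 <- gauss_bump(times, params$p3_latency, params$p3_width)
  g2 <- gauss_bump(times, params$late_latency, params$late_width)
  w_peak <- times >= windows$p3_peak$stimulus[1] &
    times < windows$p3_peak$stimulus[2]
  w_late <- times >= windows$late_p3$stimulus[1] &
    times < windows$late_p3$stimulus[2]
  M <- rbind(c(mean(g1[w_peak]), mean(g2[w_peak])),
             c(mean(g1[w_late]), mean(g2[w_late])))
  list(g1 = g1, g2 = g2, Minv = solve(M))
}

#' Simulate per-trial EEG segments
#'
#' One channels x samples x trials array on the stimulus-anchored axis
#' [-700, 1300) ms. Per trial, the two-bump P3 template is scaled so the
#' stimulus-locked peak- and late-window means equal `p3_amp[category]` and
#' `late_p3_amp[category, epoch]`; warm-up/unclassified trials carry the
#' across-category mean amplitudes. CP-pool channels carry the component at
#' unit gain, other channels attenuated; white noise is added everywhere,
#' and with probability `artifact_rate` a 20-ms excursion of
#' `+/-artifact_amp` uV is injected on one random channel inside the
#' stimulus-locked span, so the downstream rejection fraction recovers the
#' configured rate.
#'
#' @param stream an `asrt_stream`.
#' @param labels matching [classify_stream()] output.
#' @param responses [simulate_behavior()] output (stored alongside; the
#'   signal itself is stimulus-locked).
#' @param params an [erp_params()] object.
#' @param rng_seed integer seed.
#' @param windows measurement windows used to calibrate the template
#'   (defaults to [component_windows()]).
#' @return numeric array `[channel, sample, trial]` with dimnames on the
#'   channel axis and attributes `times` (ms) and `sampling_rate`.
#' @export
simulate_eeg <- function(stream, labels, responses, params = erp_params(),
                         rng_seed = 1L, windows = component_windows()) {
  n <- nrow(stream)
  times <- eeg_times(params$sampling_rate)
  S <- length(times)
  chans <- params$channel_names
  C <- length(chans)
  n_blocks <- attr(stream, "n_blocks") %||% max(stream$block)
  epoch <- epoch_of_block(stream$block, n_blocks, n_bins = min(6L, n_blocks))

  mix <- template_mix(times, params, windows)
  cat <- labels$category
  peak_target <- params$p3_amp[cat]
  peak_target[is.na(peak_target)] <- mean(params$p3_amp)
  late_target <- params$late_p3_amp[cbind(match(cat, rownames(params$late_p3_amp)),
                                          pmin(epoch, ncol(params$late_p3_amp)))]
  late_target[is.na(late_target)] <- mean(params$late_p3_amp)

  amps <- mix$Minv %*% rbind(as.numeric(peak_target), as.numeric(late_target))
  signal <- outer(mix$g1, amps[1L, ]) + outer(mix$g2, amps[2L, ])  # S x n

  gain <- ifelse(chans %in% CP_POOL, 1, params$nonpool_gain)

  with_seed(rng_seed, {
    arr <- array(stats::rnorm(C * S * n, sd = params$noise_sd),
                 dim = c(C, S, n), dimnames = list(chans, NULL, NULL))
    for (ch in seq_len(C))
      arr[ch, , ] <- arr[ch, , ] + gain[ch] * signal
    hit <- which(stats::runif(n) < params$artifact_rate)
    if (length(hit)) {
      burst <- max(1L, round(params$sampling_rate * 0.02))  # ~20 ms
      # place the burst inside the stimulus-locked span so the injected
      # rate is what downstream rejection sees
      at_ok <- which(times >= -200 & times < 600 - burst * 1000 /
                       params$sampling_rate)
      for (tr in hit) {
        ch <- sample.int(C, 1L)
        at <- at_ok[sample.int(length(at_ok), 1L)]
        arr[ch, at:(at + burst - 1L), tr] <-
          arr[ch, at:(at + burst - 1L), tr] +
          sample(c(-1, 1), 1L) * params$artifact_amp
      }
    }
    attr(arr, "times") <- times
    attr(arr, "sampling_rate") <- params$sampling_rate
    arr
  })
}
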