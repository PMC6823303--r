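# Synthetic behavior: per-trial responses and reaction times with
# triplet-type and practice (epoch) effects plus right-skewed noise.

#' Behavioral generator parameters
#'
#' Defaults emulate a healthy young-adult cohort on the task: grand-mean RT
#' around 365 ms, faster responses on random high-probability triplets than
#' on pattern triplets than on random low-probability ones (-5 / -2 / +5 ms
#' offsets), a shallow practice curve across the six epoch bins, ~93%
#' accuracy, and additive mean-zero lognormal RT noise (right-skewed,
#' bounded below) whose standard deviation on the ms axis is `rt_noise_sd`.
#'
#' @param baseline_rt grand-mean RT in ms.
#' @param category_effects named ms offsets per triplet category.
#' @param epoch_effects ms offsets per epoch bin (length 6).
#' @param rt_noise_sd standard deviation of the additive noise, ms.
#' @param accuracy named per-category probability of a correct response.
#' @param accuracy_other correct probability for warm-up/unclassified trials.
#' @param miss_rate probability of no response on a trial.
#' @param rt_ceiling response deadline, ms; generated RTs are truncated here
#'   (stimulus 200 ms + response window 500 ms).
#' @return list of class `behavior_params`.
#' @export
behavior_params <- function(baseline_rt = 365,
                            category_effects = c(pattern_high = -2,
                                                 random_high = -5,
                                                 random_low = 5),
                            epoch_effects = c(2, 2, -3, 1, -4, 0),
                            rt_noise_sd = 60,
                            accuracy = c(pattern_high = 0.932,
                                         random_high = 0.940,
                                         random_low = 0.919),
                            accuracy_other = 0.93,
                            miss_rate = 0.005,
                            rt_ceiling = 700) {
  stopifnot(baseline_rt > 0, rt_noise_sd >= 0,
            all(accuracy >= 0 & accuracy <= 1),
            miss_rate >= 0, miss_rate <= 1)
  structure(list(baseline_rt = baseline_rt,
                 category_effects = category_effects,
                 epoch_effects = epoch_effects,
                 rt_noise_sd = rt_noise_sd,
                 accuracy = accuracy, accuracy_other = accuracy_other,
                 miss_rate = miss_rate, rt_ceiling = rt_ceiling),
            class = "behavior_params")
}

# mean-zero additive lognormal noise with sd `sd_ms` on the ms axis;
# fixed shape sdlog = 0.5 gives a realistic right skew
rt_noise <- function(n, sd_ms) {
  if (sd_ms == 0 || n == 0L) return(numeric(n))
  s <- 0.5
  m <- sd_ms / sqrt(exp(s^2) - 1)          # mean of the lognormal part
  stats::rlnorm(n, meanlog = log(m) - s^2 / 2, sdlog = s) - m
}

#' Map block numbers to epoch bins
#'
#' The session is cut into six equally long bins of consecutive blocks
#' (five blocks per bin in the standard 30-block session).
#'
#' @param block block numbers.
#' @param n_blocks total blocks in the session (must be divisible by
#'   `n_bins`).
#' @param n_bins number of bins (default 6).
#' @return integer epoch-bin indices.
#' @export
epoch_of_block <- function(block, n_blocks, n_bins = 6L) {
  if (n_blocks %% n_bins != 0L)
    stop("`n_blocks` (", n_blocks, ") must be divisible by the number of ",
         "epoch bins (", n_bins, ")", call. = FALSE)
  per <- n_blocks %/% n_bins
  as.integer(ceiling(block / per))
}

#' Simulate per-trial responses and reaction times
#'
#' RT = baseline + category effect + epoch effect + mean-zero lognormal
#' noise, truncated at the response deadline; a response occurs with
#' probability `1 - miss_rate` and is correct with the category's accuracy
#' probability. Misses have no RT.
#'
#' @param stream an `asrt_stream`.
#' @param labels matching [classify_stream()] output.
#' @param params a [behavior_params()] object.
#' @param rng_seed integer seed.
#' @return `data.frame` with columns `responded`, `correct`, `rt` (ms,
#'   `NA` for misses), aligned with the stream rows.
#' @export
simulate_behavior <- function(stream, labels, params = behavior_params(),
                              rng_seed = 1L) {
  if (nrow(labels) != nrow(stream))
    stop("`labels` must be aligned with `stream`", call. = FALSE)
  n <- nrow(stream)
  n_blocks <- attr(stream, "n_blocks") %||% max(stream$block)
  epoch <- epoch_of_block(stream$block, n_blocks,
                          n_bins = min(6L, n_blocks))

  cat_eff <- params$category_effects[labels$category]
  cat_eff[is.na(cat_eff)] <- 0
  ep_eff <- params$epoch_effects[epoch]
  ep_eff[is.na(ep_eff)] <- 0
  acc <- params$accuracy[labels$category]
  acc[is.na(acc)] <- params$accuracy_other

  with_seed(rng_seed, {
    rt <- params$baseline_rt + as.numeric(cat_eff) + as.numeric(ep_eff) +
      rt_noise(n, params$rt_noise_sd)
    rt <- pmin(rt, params$rt_ceiling)
    responded <- stats::runif(n) >= params$miss_rate
    correct <- responded & (stats::runif(n) < acc)
    rt[!responded] <- NA_real_
    data.frame(responded = responded, correct = correct, rt = rt)
  })
}

#' Generation-task (inclusion/exclusion) parameters
#'
#' At every key press after the first two, the simulated participant
#' presses the high-probability continuation of the press two back with
#' probability `bias`, otherwise uniformly one of the other three keys.
#' `bias = 0.25` therefore reproduces fully uniform pressing (the 25%
#' chance level). Defaults emulate the reported production rates: ~31.5%
#' high-probability triplets under inclusion and ~28.1% under exclusion.
#'
#' @param bias_inclusion,bias_exclusion probability of choosing the
#'   high-probability continuation in each condition.
#' @param runs runs per condition.
#' @param presses_per_run key presses per run (each run ends after 24).
#' @return list of class `generation_params`.
#' @export
generation_params <- function(bias_inclusion = 0.315, bias_exclusion = 0.281,
                              runs = 4L, presses_per_run = 24L) {
  stopifnot(bias_inclusion >= 0, bias_inclusion <= 1,
            bias_exclusion >= 0, bias_exclusion <= 1,
            runs >= 1, presses_per_run >= 1)
  structure(list(bias_inclusion = bias_inclusion,
                 bias_exclusion = bias_exclusion,
                 runs = as.integer(runs),
                 presses_per_run = as.integer(presses_per_run)),
            class = "generation_params")
}

simulate_generation_runs <- function(sequence, bias, runs, presses) {
  succ <- sequence_successor(sequence, DIRECTIONS)
  mat <- matrix(NA_integer_, nrow = presses, ncol = runs)
  if (presses >= 1L) mat[1L, ] <- sample(DIRECTIONS, runs, replace = TRUE)
  if (presses >= 2L) mat[2L, ] <- sample(DIRECTIONS, runs, replace = TRUE)
  if (presses >= 3L) for (t in 3:presses) {
    high <- succ[mat[t - 2L, ]]
    take_high <- stats::runif(runs) < bias
    alt <- vapply(high, function(h)
      sample(DIRECTIONS[DIRECTIONS != h], 1L), integer(1))
    mat[t, ] <- ifelse(take_high, high, alt)
  }
  lapply(seq_len(runs), function(j) mat[, j])
}

#' Simulate inclusion/exclusion key-press runs
#'
#' @param sequence an [asrt_sequence()].
#' @param params a [generation_params()] object.
#' @param rng_seed integer seed.
#' @return named list with elements `inclusion` and `exclusion`, each a
#'   list of integer key-press vectors (one per run).
#' @export
simulate_generation_task <- function(sequence, params = generation_params(),
                                     rng_seed = 1L) {
  sequence <- asrt_sequence(sequence)
  with_seed(rng_seed, list(
    inclusion = simulate_generation_runs(sequence, params$bias_inclusion,
                                         params$runs, params$presses_per_run),
    exclusion = simulate_generation_runs(sequence, params$bias_exclusion,
                                         params$runs, params$presses_per_run)
  ))
}
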