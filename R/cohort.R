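# Synthetic cohorts: per-subject parameter draws from population
# distributions and deterministic per-subject seeds.

#' Population (between-subject) distribution of generator parameters
#'
#' Subject-level parameters are drawn around the fixed within-subject
#' structure of [behavior_params()] / [erp_params()]:
#' a subject shift on baseline RT, small jitter on the per-category RT
#' offsets, a subject shift on the P3 amplitude applied to all categories
#' (amplitudes correlate strongly within subject, so the shift preserves
#' category differences), small jitter on the per-category amplitudes, and
#' jitter on the generation-task biases. Between-subject SDs default to
#' values consistent with group effects detectable at n = 32: baseline RT
#' SD 20 ms, RT category-effect SD 2 ms, P3 subject-shift SD 1 uV,
#' amplitude category-effect SD 0.05 uV, bias SD 0.05.
#'
#' @param behavior a [behavior_params()] object of population means.
#' @param erp an [erp_params()] object of population means.
#' @param generation a [generation_params()] object of population means.
#' @param sd_baseline_rt,sd_rt_category,sd_p3_shift,sd_p3_category,sd_bias
#'   between-subject standard deviations (0 collapses the population onto
#'   its means).
#' @return list of class `population_params`.
#' @export
population_params <- function(behavior = behavior_params(),
                              erp = erp_params(),
                              generation = generation_params(),
                              sd_baseline_rt = 20, sd_rt_category = 2,
                              sd_p3_shift = 1, sd_p3_category = 0.05,
                              sd_bias = 0.05) {
  structure(list(behavior = behavior, erp = erp, generation = generation,
                 sd_baseline_rt = sd_baseline_rt,
                 sd_rt_category = sd_rt_category,
                 sd_p3_shift = sd_p3_shift,
                 sd_p3_category = sd_p3_category,
                 sd_bias = sd_bias),
            class = "population_params")
}

draw_subject_params <- function(population) {
  # caller provides the RNG context
  beh <- population$behavior
  beh$baseline_rt <- beh$baseline_rt +
    stats::rnorm(1, sd = population$sd_baseline_rt)
  beh$category_effects <- beh$category_effects +
    stats::rnorm(length(beh$category_effects),
                 sd = population$sd_rt_category)
  erp <- population$erp
  shift <- stats::rnorm(1, sd = population$sd_p3_shift)
  erp$p3_amp <- erp$p3_amp + shift +
    stats::rnorm(length(erp$p3_amp), sd = population$sd_p3_category)
  erp$late_p3_amp <- erp$late_p3_amp + shift
  gen <- population$generation
  gen$bias_inclusion <- min(1, max(0, gen$bias_inclusion +
    stats::rnorm(1, sd = population$sd_bias)))
  gen$bias_exclusion <- min(1, max(0, gen$bias_exclusion +
    stats::rnorm(1, sd = population$sd_bias)))
  list(behavior = beh, erp = erp, generation = gen)
}

#' Simulate one synthetic subject
#'
#' Generates the subject's trial stream (sequence selected pseudorandomly
#' from the six unique ones), triplet labels, responses/RTs, optionally the
#' per-trial EEG array, and the inclusion/exclusion generation runs. All
#' stage seeds are derived deterministically from `seed` and recorded in
#' the output.
#'
#' @param seed integer subject seed.
#' @param params list with elements `behavior`, `erp`, `generation` (as
#'   from [behavior_params()] etc.).
#' @param n_blocks blocks in the session.
#' @param include_eeg generate the EEG array (sizeable: ~80 MB per subject
#'   at 250 Hz and 30 blocks); set `FALSE` for behavior-only cohorts.
#' @param id subject identifier carried into measure tables.
#' @return list of class `subject_record` with elements `id`, `sequence`,
#'   `stream`, `labels`, `behavior`, `eeg` (or `NULL`), `generation`,
#'   `params`, `seeds`.
#' @export
simulate_subject <- function(seed, params = list(behavior = behavior_params(),
                                                 erp = erp_params(),
                                                 generation = generation_params()),
                             n_blocks = 30L, include_eeg = TRUE, id = 1L) {
  seeds <- derive_seeds(seed, 4L)
  sequence <- select_sequence(seeds[1L])
  stream <- generate_session(sequence, n_blocks, rng_seed = seeds[2L])
  labels <- classify_stream(stream)
  behavior <- simulate_behavior(stream, labels, params$behavior, seeds[3L])
  eeg <- if (include_eeg)
    simulate_eeg(stream, labels, behavior, params$erp, seeds[4L]) else NULL
  generation <- simulate_generation_task(sequence, params$generation,
                                         seeds[4L] + 1L)
  structure(list(id = id, sequence = sequence, stream = stream,
                 labels = labels, behavior = behavior, eeg = eeg,
                 generation = generation, params = params,
                 seeds = c(subject = as.integer(seed), sequence = seeds[1L],
                           stream = seeds[2L], behavior = seeds[3L],
                           eeg = seeds[4L])),
            class = "subject_record")
}

#' Simulate a cohort of synthetic subjects
#'
#' Per-subject parameters are drawn from the population distributions and
#' per-subject seeds derived deterministically from the master seed, so the
#' whole cohort is reproducible from `(population, n_subjects, rng_seed)`.
#'
#' @param n_subjects cohort size (default 32).
#' @param population a [population_params()] object.
#' @param rng_seed master seed.
#' @param n_blocks blocks per subject.
#' @param include_eeg generate EEG arrays (memory-heavy for full cohorts;
#'   prefer [map_cohort()] to stream subjects through an analysis).
#' @return list of class `cohort` of `subject_record`s, with the manifest
#'   (seeds and drawn parameters) as attribute `manifest`.
#' @export
simulate_cohort <- function(n_subjects = 32L,
                            population = population_params(),
                            rng_seed = 1L, n_blocks = 30L,
                            include_eeg = FALSE) {
  manifest <- cohort_manifest(n_subjects, population, rng_seed)
  subjects <- lapply(seq_len(n_subjects), function(i)
    simulate_subject(manifest$seed[i], manifest$params[[i]], n_blocks,
                     include_eeg, id = i))
  structure(subjects, manifest = manifest, class = "cohort")
}

cohort_manifest <- function(n_subjects, population, rng_seed) {
  if (n_subjects < 2L) stop("a cohort needs >= 2 subjects", call. = FALSE)
  seeds <- derive_seeds(rng_seed, n_subjects + 1L)
  params <- with_seed(seeds[n_subjects + 1L],
                      lapply(seq_len(n_subjects),
                             function(i) draw_subject_params(population)))
  list(seed = seeds[seq_len(n_subjects)], params = params,
       master_seed = as.integer(rng_seed), n_subjects = n_subjects)
}

#' Stream a cohort through a per-subject analysis
#'
#' Generates each subject in turn (optionally with EEG), applies `fun`,
#' and discards the raw record, keeping memory flat for full-size EEG
#' cohorts.
#'
#' @param fun function of one `subject_record`.
#' @inheritParams simulate_cohort
#' @return list of `fun` results, one per subject.
#' @export
map_cohort <- function(fun, n_subjects = 32L,
                       population = population_params(), rng_seed = 1L,
                       n_blocks = 30L, include_eeg = FALSE) {
  manifest <- cohort_manifest(n_subjects, population, rng_seed)
  lapply(seq_len(n_subjects), function(i) {
    rec <- simulate_subject(manifest$seed[i], manifest$params[[i]], n_blocks,
                            include_eeg, id = i)
    fun(rec)
  })
}
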