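# End-to-end orchestration: configuration, the full simulate -> classify ->
# measure -> test pipeline, and structural self-verification.

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run. Defaults reproduce the
#' task's standard layout: 30 blocks cut into 6 epoch bins, 32 subjects,
#' the canonical measurement windows, and the +/-100 uV rejection
#' threshold.
#'
#' @param master_seed integer master seed for the whole run.
#' @param n_subjects cohort size.
#' @param n_blocks blocks per session.
#' @param n_bins epoch bins (`n_blocks` must be divisible by it).
#' @param population a [population_params()] object.
#' @param windows a [component_windows()] object.
#' @param rejection_threshold artifact-rejection threshold, uV.
#' @param max_rejection_fraction subjects whose per-category rejection
#'   fraction exceeds this are excluded from the ERP ANOVA.
#' @param include_eeg run the ERP arm (memory- and time-heavy).
#' @param include_warmup_triplets keep warm-up-final triplets in analyses.
#' @param phase_continuous continue the pattern cycle across blocks.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(master_seed = 1L, n_subjects = 32L,
                            n_blocks = 30L, n_bins = 6L,
                            population = population_params(),
                            windows = component_windows(),
                            rejection_threshold = 100,
                            max_rejection_fraction = 0.35,
                            include_eeg = TRUE,
                            include_warmup_triplets = FALSE,
                            phase_continuous = FALSE) {
  cfg <- list(master_seed = as.integer(master_seed),
              n_subjects = as.integer(n_subjects),
              n_blocks = as.integer(n_blocks), n_bins = as.integer(n_bins),
              population = population, windows = windows,
              rejection_threshold = rejection_threshold,
              max_rejection_fraction = max_rejection_fraction,
              include_eeg = include_eeg,
              include_warmup_triplets = include_warmup_triplets,
              phase_continuous = phase_continuous)
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param config object to validate.
#' @export
validate_config <- function(config) {
  if (config$n_subjects < 2L)
    stop("configuration error: n_subjects must be >= 2", call. = FALSE)
  if (config$n_blocks %% config$n_bins != 0L)
    stop("configuration error: n_blocks (", config$n_blocks,
         ") not divisible by n_bins (", config$n_bins, ")", call. = FALSE)
  if (config$rejection_threshold <= 0)
    stop("configuration error: rejection threshold must be positive",
         call. = FALSE)
  invisible(config)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass_deep(config), tmp, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}

write_table_with_meta <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, meta[[nm]]), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Verify the task's structural constants
#'
#' Recomputes the analytic constants of the probability structure (unique
#' sequences, triplet counts, frequency ratio, transitional probabilities,
#' trial counts) from the package's own generators and compares them with
#' their closed-form values.
#'
#' @param sequence sequence used for the checks.
#' @return `data.frame` `quantity, value, expected, ok`.
#' @export
verify_structure <- function(sequence = asrt_sequence(c(2, 1, 3, 4))) {
  seqs <- enumerate_unique_sequences()
  rot <- unique(do.call(rbind, lapply(seqs, function(s)
    do.call(rbind, sequence_rotations(s)))))
  tt <- enumerate_triplets(sequence)
  stream <- generate_session(sequence, n_blocks = 30L, rng_seed = 1L)
  p_high <- mean(tt$probability[tt$frequency_class == "high"])
  p_low <- mean(tt$probability[tt$frequency_class == "low"])
  checks <- data.frame(
    quantity = c("unique_sequences", "permutations", "triplet_types",
                 "high_probability_triplets", "frequency_ratio",
                 "transition_successor_pct", "transition_other_pct",
                 "trials_per_block", "trials_per_session",
                 "pattern_fraction_nonwarmup"),
    value = c(length(seqs), nrow(rot), nrow(tt),
              sum(tt$frequency_class == "high"), p_high / p_low,
              100 * transitional_probability(sequence, 3, 4),
              100 * transitional_probability(sequence, 3, 1),
              sum(stream$block == 1L), nrow(stream),
              mean(stream$trial_class[stream$trial_class != "warmup"] ==
                     "pattern")),
    expected = c(6, 24, 64, 16, 5, 62.5, 12.5, 85, 2550, 0.5))
  checks$ok <- abs(checks$value - checks$expected) < 1e-9
  checks
}

#' Run the full simulation and analysis pipeline
#'
#' Simulates a cohort, classifies trial streams, computes the behavioral
#' and (optionally) ERP measure tables, runs the factorial ANOVAs
#' (Type x Epoch on median RTs; Locking x Type x Epoch on P3 peak and late
#' P3), scores the inclusion/exclusion runs with one-sample and paired
#' t-tests, and recomputes the structural constants. With `out_dir` set,
#' writes tidy CSVs and JSON results, each stamped with version, seed and
#' config hash.
#'
#' @param config a [pipeline_config()] object.
#' @param out_dir optional output directory (created if needed).
#' @return list of class `asrt_report`: `config_hash`, `structure`,
#'   `rt_table`, `accuracy_table`, `erp_table` (or `NULL`),
#'   `rt_anova`, `rt_anova_three`, `erp_anova` (per component),
#'   `pdp` (scores + tests), `log` (per-stage counts).
#' @export
run_full_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  validate_config(config)
  hash <- config_hash(config)
  log <- list()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  structure_report <- stage("verify_structure", verify_structure())

  per_subject <- stage("simulate+measure", map_cohort(function(rec) {
    list(rt = compute_rt_table(rec, config$n_bins),
         acc = compute_accuracy_table(rec, config$n_bins),
         erp = if (config$include_eeg)
           erp_measure_table(rec, config$windows,
                             config$rejection_threshold) else NULL,
         pdp = compute_pdp_scores(rec),
         n_trials = nrow(rec$stream))
  }, n_subjects = config$n_subjects, population = config$population,
     rng_seed = config$master_seed, n_blocks = config$n_blocks,
     include_eeg = config$include_eeg))

  rt_table <- do.call(rbind, lapply(per_subject, `[[`, "rt"))
  acc_table <- do.call(rbind, lapply(per_subject, `[[`, "acc"))
  pdp_table <- do.call(rbind, lapply(per_subject, `[[`, "pdp"))
  erp_table <- if (config$include_eeg)
    do.call(rbind, lapply(per_subject, `[[`, "erp")) else NULL
  log$n_subjects <- length(per_subject)
  log$trials_per_subject <- per_subject[[1L]]$n_trials

  # Type x Epoch ANOVA on median RT, three triplet types
  rt3 <- rt_table[rt_table$category %in% TRIPLET_CATEGORIES, ]
  rt_anova_three <- stage("rt_anova",
    rm_anova(rt3, "value", c("category", "epoch")))
  # pattern vs combined-random contrast
  rt2 <- rt_table[rt_table$category %in%
                    c("pattern_high", "random_combined"), ]
  rt_anova <- stage("rt_anova", rm_anova(rt2, "value",
                                         c("category", "epoch")))
  rt_lsd <- stage("rt_lsd", lsd_pairwise(
    stats::aggregate(value ~ subject + category, data = rt3, FUN = mean),
    "value", "category"))

  erp_anova <- NULL
  if (config$include_eeg) {
    erp_anova <- list()
    for (comp in c("p3_peak", "late_p3")) {
      d <- erp_table[erp_table$component == comp &
                       erp_table$category %in% TRIPLET_CATEGORIES, ]
      erp_anova[[comp]] <- stage(paste0("erp_anova_", comp),
        rm_anova(d, "amplitude", c("locking", "category", "epoch")))
    }
  }

  pdp_tests <- stage("pdp_tests", {
    inc <- pdp_table$pct_high[pdp_table$condition == "inclusion"]
    exc <- pdp_table$pct_high[pdp_table$condition == "exclusion"]
    list(inclusion_vs_chance = one_sample_t(inc, 25),
         exclusion_vs_chance = one_sample_t(exc, 25),
         inclusion_vs_exclusion = paired_t(inc, exc))
  })

  report <- structure(list(config = config, config_hash = hash,
                           structure = structure_report,
                           rt_table = rt_table, accuracy_table = acc_table,
                           erp_table = erp_table, rt_anova = rt_anova,
                           rt_anova_three = rt_anova_three, rt_lsd = rt_lsd,
                           erp_anova = erp_anova,
                           pdp = list(scores = pdp_table, tests = pdp_tests),
                           log = log),
                      class = "asrt_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    meta <- list(package = "asrtlab",
                 version = as.character(utils::packageVersion("asrtlab")),
                 seed = config$master_seed, config_hash = hash)
    write_table_with_meta(rt_table, file.path(out_dir, "rt_table.csv"), meta)
    write_table_with_meta(acc_table,
                          file.path(out_dir, "accuracy_table.csv"), meta)
    if (!is.null(erp_table))
      write_table_with_meta(erp_table,
                            file.path(out_dir, "erp_table.csv"), meta)
    write_table_with_meta(pdp_table, file.path(out_dir, "pdp_scores.csv"),
                          meta)
    write_table_with_meta(structure_report,
                          file.path(out_dir, "structure_report.csv"), meta)
    anovas <- list(rt_pattern_vs_random = as.data.frame(rt_anova),
                   rt_three_types = as.data.frame(rt_anova_three))
    if (!is.null(erp_anova))
      for (comp in names(erp_anova))
        anovas[[paste0("erp_", comp)]] <- as.data.frame(erp_anova[[comp]])
    jsonlite::write_json(c(list(meta = meta), anovas),
                         file.path(out_dir, "anova_results.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    jsonlite::write_json(unclass_deep(config),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

#' @export
print.asrt_report <- function(x, ...) {
  cat("ASRT pipeline report (seed ", x$config$master_seed, ", ",
      x$config$n_subjects, " subjects, ", x$config$n_blocks, " blocks)\n",
      sep = "")
  cat("\nStructural checks:", sum(x$structure$ok), "of",
      nrow(x$structure), "within tolerance\n")
  cat("\nRT ANOVA (pattern vs random, Type x Epoch):\n")
  print(x$rt_anova)
  cat("\nRT ANOVA (three triplet types):\n")
  print(x$rt_anova_three)
  if (!is.null(x$erp_anova)) {
    for (comp in names(x$erp_anova)) {
      cat("\nERP ANOVA (", comp, ", Locking x Type x Epoch):\n", sep = "")
      print(x$erp_anova[[comp]])
    }
  }
  cat("\nGeneration task, % high-probability triplets vs 25% chance:\n")
  cat("  inclusion: "); print(x$pdp$tests$inclusion_vs_chance)
  cat("  exclusion: "); print(x$pdp$tests$exclusion_vs_chance)
  invisible(x)
}
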