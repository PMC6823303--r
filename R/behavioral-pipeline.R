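# Behavioral pipeline: per-epoch-bin median RTs and accuracy by triplet
# type, and inclusion/exclusion (process-dissociation) scoring.

MEASURE_CATEGORIES <- c("pattern_high", "random_high", "random_low",
                        "random_combined")

category_members <- function(category) {
  switch(category,
         random_combined = c("random_high", "random_low"),
         category)
}

#' Per-epoch-bin median RTs by triplet type
#'
#' For each epoch bin and category (pattern_high, random_high, random_low,
#' and random_combined — the *pooled* random trials, not the mean of the
#' two medians), the median RT over analyzable, correctly responded trials
#' with RT > 0. Empty cells are flagged missing with a warning.
#'
#' @param record a `subject_record` (or list with `stream`, `labels`,
#'   `behavior`, `id`).
#' @param n_bins epoch bins (block count must be divisible by it).
#' @return `data.frame` `subject, epoch, category, measure, value, n`;
#'   attribute `complete` is `FALSE` if any cell is empty.
#' @export
compute_rt_table <- function(record, n_bins = 6L) {
  measure_table(record, n_bins, measure = "median_rt")
}

#' Per-epoch-bin response accuracy by triplet type
#'
#' Percentage of correct responses over analyzable trials; missing
#' responses count as incorrect (the task treats them as failures).
#'
#' @inheritParams compute_rt_table
#' @return `data.frame` as in [compute_rt_table()] with
#'   `measure = "accuracy"` (percent).
#' @export
compute_accuracy_table <- function(record, n_bins = 6L) {
  measure_table(record, n_bins, measure = "accuracy")
}

measure_table <- function(record, n_bins, measure) {
  labels <- record$labels
  beh <- record$behavior
  n_blocks <- attr(record$stream, "n_blocks") %||% max(record$stream$block)
  epoch <- epoch_of_block(labels$block, n_blocks, n_bins)

  analyzable <- labels$analyzable
  cells <- expand.grid(epoch = seq_len(n_bins),
                       category = MEASURE_CATEGORIES,
                       stringsAsFactors = FALSE)
  value <- numeric(nrow(cells)); n_tr <- integer(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    in_cell <- analyzable & epoch == cells$epoch[i] &
      labels$category %in% category_members(cells$category[i])
    if (measure == "median_rt") {
      sel <- in_cell & beh$correct & !is.na(beh$rt) & beh$rt > 0
      n_tr[i] <- sum(sel)
      value[i] <- if (n_tr[i]) stats::median(beh$rt[sel]) else NA_real_
    } else {
      n_tr[i] <- sum(in_cell)
      value[i] <- if (n_tr[i])
        100 * sum(beh$correct[in_cell]) / n_tr[i] else NA_real_
    }
  }
  out <- data.frame(subject = record$id %||% NA_integer_,
                    epoch = cells$epoch, category = cells$category,
                    measure = measure, value = value, n = n_tr)
  if (anyNA(out$value)) {
    miss <- out[is.na(out$value), c("epoch", "category")]
    warning("subject ", out$subject[1L], ": empty cell(s): ",
            paste(miss$category, miss$epoch, sep = "/", collapse = ", "),
            "; subject should be excluded from the ANOVA", call. = FALSE)
    attr(out, "complete") <- FALSE
  } else attr(out, "complete") <- TRUE
  out
}

#' Score a generation (inclusion/exclusion) condition
#'
#' Moving-window triplets within each run (windows never span runs); the
#' score is the percentage of produced triplets that are high-probability
#' under the participant's sequence. All triplets count, including trills
#' and repetitions — 16 of the 64 types are high, so uniform pressing
#' scores at the 25% chance level.
#'
#' @param runs list of integer key-press vectors (one per run).
#' @param sequence the participant's [asrt_sequence()].
#' @return list of class `pdp_score`: `pct_high`, `n_triplets`, `n_high`.
#' @export
score_generation <- function(runs, sequence) {
  sequence <- asrt_sequence(sequence)
  succ <- sequence_successor(sequence, DIRECTIONS)
  n_high <- 0L; n_total <- 0L
  for (run in runs) {
    if (length(run) < 3L) {
      warning("run shorter than 3 presses skipped", call. = FALSE)
      next
    }
    first <- run[seq_len(length(run) - 2L)]
    third <- run[3:length(run)]
    n_total <- n_total + length(third)
    n_high <- n_high + sum(third == succ[first])
  }
  structure(list(pct_high = if (n_total) 100 * n_high / n_total else
                   NA_real_,
                 n_triplets = n_total, n_high = n_high),
            class = "pdp_score")
}

#' Process-dissociation scores for a subject
#'
#' @param record a `subject_record` with a `generation` element.
#' @return `data.frame` `subject, condition, pct_high, n_triplets`.
#' @export
compute_pdp_scores <- function(record) {
  rows <- lapply(names(record$generation), function(cond) {
    sc <- score_generation(record$generation[[cond]], record$sequence)
    data.frame(subject = record$id %||% NA_integer_, condition = cond,
               pct_high = sc$pct_high, n_triplets = sc$n_triplets)
  })
  do.call(rbind, rows)
}
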