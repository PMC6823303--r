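# Triplet engine: moving-window classification of trials by second-order
# transitional probability, plus the exact analytic probability structure.
#
# Every trial is the final element of one triplet (trial t with the trials
# at t-2 and t-1). A triplet is high-probability when its final direction is
# the sequence's cyclic successor of its first direction; such triplets can
# arise as P-r-P or r-P-r and therefore occur five times more often than
# the remaining (low-probability, necessarily random-final) ones.

TRIPLET_CATEGORIES <- c("pattern_high", "random_high", "random_low")

#' Classify every trial of a stream by its moving-window triplet
#'
#' Trial `t` is labeled from the directions at positions `t - 2`, `t - 1`,
#' `t` of the same block (windows never span block boundaries; the warm-up
#' trials re-establish context at each block start). The first two trials
#' of a block are `unclassified`. Pattern-class trials are always
#' `pattern_high`; random and warm-up trials are `random_high` when the
#' final direction is the cyclic successor of the first, otherwise
#' `random_low`. Trills (first = last, e.g. 1-2-1) and repetitions (all
#' three equal) are flagged; together with warm-up-final and unclassified
#' trials they are excluded from analysis by [filter_analysis_triplets()].
#'
#' @param stream an `asrt_stream` from [generate_session()] or
#'   [read_trial_log()].
#' @param sequence the generating [asrt_sequence()]; defaults to the one
#'   attached to `stream`. A stream spanning several sequences is invalid.
#' @return a `data.frame` with the stream columns plus `t1,t2,t3`
#'   (triplet directions), `category`, `is_trill`, `is_repetition`,
#'   `epoch` (set by downstream binning, `NA` here), and `analyzable`.
#' @export
classify_stream <- function(stream, sequence = attr(stream, "sequence")) {
  if (is.null(sequence))
    stop("no sequence attached to the stream; pass `sequence`", call. = FALSE)
  sequence <- asrt_sequence(sequence)
  if (is.unsorted(order(stream$block, stream$pos)) )
    stream <- stream[order(stream$block, stream$pos), ]

  n <- nrow(stream)
  idx <- seq_len(n)
  dir <- stream$direction
  t1 <- ifelse(stream$pos > 2L, dir[pmax(idx - 2L, 1L)], NA_integer_)
  t2 <- ifelse(stream$pos > 1L, dir[pmax(idx - 1L, 1L)], NA_integer_)
  t3 <- dir

  succ <- sequence_successor(sequence, DIRECTIONS)
  is_high <- !is.na(t1) & t3 == succ[t1]

  category <- rep(NA_character_, n)
  classified <- !is.na(t1)
  is_pattern <- stream$trial_class == "pattern"
  category[classified & is_pattern] <- "pattern_high"
  category[classified & !is_pattern & is_high] <- "random_high"
  category[classified & !is_pattern & !is_high] <- "random_low"
  category[!classified] <- "unclassified"

  # trills/repetitions are low-probability (random-final) types by
  # definition; a block-initial pattern trial whose window reaches into the
  # warm-ups is never flagged
  is_repetition <- classified & !is_pattern & t1 == t2 & t2 == t3
  is_trill <- classified & !is_pattern & t1 == t3 & !is_repetition

  analyzable <- classified & !is_trill & !is_repetition &
    stream$trial_class != "warmup"

  out <- cbind(as.data.frame(stream),
               data.frame(t1 = t1, t2 = t2, t3 = t3, category = category,
                          is_trill = is_trill, is_repetition = is_repetition,
                          analyzable = analyzable))
  attr(out, "sequence") <- sequence
  attr(out, "n_blocks") <- attr(stream, "n_blocks") %||%
    length(unique(stream$block))
  class(out) <- c("asrt_labels", "data.frame")
  out
}

#' Enumerate the 64 triplet types and their steady-state probabilities
#'
#' All ordered direction combinations (d1, d2, d3) with their frequency
#' class (high iff d3 is the cyclic successor of d1 — 16 high, 48 low) and
#' the per-trial steady-state probability of observing that triplet under
#' the 50/50 pattern/random alternation: a pattern-final triplet fixes
#' d3 = successor(d1) with d1 uniform over the pattern cycle and d2 random,
#' a random-final triplet is uniform over all 64, so each high triplet has
#' probability 1/32 + 1/128 = 5/128 and each low triplet 1/128 — the
#' five-fold frequency ratio of the task.
#'
#' @param sequence an [asrt_sequence()].
#' @return `data.frame` with columns `d1,d2,d3`, `frequency_class`
#'   (`"high"`/`"low"`), `probability`, `is_trill`, `is_repetition`.
#' @export
enumerate_triplets <- function(sequence) {
  sequence <- asrt_sequence(sequence)
  g <- expand.grid(d1 = DIRECTIONS, d2 = DIRECTIONS, d3 = DIRECTIONS)
  succ <- sequence_successor(sequence, DIRECTIONS)
  high <- g$d3 == succ[g$d1]
  # mixture: P(pattern-final) = 1/2 -> (d1 uniform over cycle, d2 uniform,
  # d3 forced); P(random-final) = 1/2 -> uniform over the 64 types
  prob <- ifelse(high, 0.5 * (1 / 4) * (1 / 4), 0) + 0.5 / 64
  data.frame(d1 = g$d1, d2 = g$d2, d3 = g$d3,
             frequency_class = ifelse(high, "high", "low"),
             probability = prob,
             is_repetition = g$d1 == g$d2 & g$d2 == g$d3,
             is_trill = g$d1 == g$d3 & !(g$d1 == g$d2 & g$d2 == g$d3))
}

#' Second-order transitional probability between trials two apart
#'
#' P(direction at t + 2 = `d_third` | direction at t = `d_first`) in the
#' steady state of the alternating stream. Trials two apart are either
#' both pattern (the successor is certain) or both random (uniform), each
#' with probability 1/2, giving 0.5 + 0.125 = 62.5% for the successor and
#' 12.5% for each other direction.
#'
#' @param sequence an [asrt_sequence()].
#' @param d_first,d_third direction codes in 1:4.
#' @return probability in `[0, 1]`.
#' @examples
#' sq <- asrt_sequence(c(2, 1, 3, 4))
#' transitional_probability(sq, 3, 4)  # 0.625
#' @export
transitional_probability <- function(sequence, d_first, d_third) {
  sequence <- asrt_sequence(sequence)
  if (!all(c(d_first, d_third) %in% DIRECTIONS))
    stop("direction codes must be in 1:4", call. = FALSE)
  0.5 * as.numeric(d_third == sequence_successor(sequence, d_first)) +
    0.5 * 0.25
}

#' Keep only the trials that enter RT / ERP analyses
#'
#' Removes unclassified trials, warm-up-final triplets, and the two
#' low-probability triplet types with preexisting response tendencies —
#' repetitions (1-1-1) and trills (1-2-1). The surviving categories are
#' exactly pattern_high, random_high and random_low.
#'
#' @param labels output of [classify_stream()].
#' @param include_warmup keep warm-up-final triplets (default `FALSE`).
#' @return the filtered label `data.frame`.
#' @export
filter_analysis_triplets <- function(labels, include_warmup = FALSE) {
  keep <- labels$category %in% TRIPLET_CATEGORIES &
    !labels$is_trill & !labels$is_repetition
  if (!include_warmup) keep <- keep & labels$trial_class != "warmup"
  out <- labels[keep, , drop = FALSE]
  attr(out, "sequence") <- attr(labels, "sequence")
  attr(out, "n_blocks") <- attr(labels, "n_blocks")
  out
}
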