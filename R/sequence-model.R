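# ASRT sequence model: the eight-element alternating pattern/random stream.
#
# Direction codes: 1 = left, 2 = up, 3 = down, 4 = right. A sequence is a
# permutation of the four directions; pattern trials cycle through it while
# every second trial is random, giving the P-r-P-r-P-r-P-r eight-element
# cycle. Because presentation is continuous, sequences equal up to cyclic
# rotation are the same task: 24 permutations collapse to 6 equivalence
# classes.

TRIALS_PER_BLOCK <- 85L
WARMUP_PER_BLOCK <- 5L
DIRECTIONS <- 1:4

#' Construct (and validate) an ASRT sequence
#'
#' @param elements integer vector of length 4; a permutation of 1:4 giving
#'   the order of the four predetermined spatial directions
#'   (1 = left, 2 = up, 3 = down, 4 = right).
#' @return an object of class `asrt_sequence` (integer vector).
#' @examples
#' asrt_sequence(c(2, 1, 3, 4))
#' @export
asrt_sequence <- function(elements) {
  elements <- as.integer(elements)
  if (length(elements) != 4L || !setequal(elements, DIRECTIONS))
    stop("an ASRT sequence must be a permutation of directions 1:4",
         call. = FALSE)
  structure(elements, class = "asrt_sequence")
}

#' @export
print.asrt_sequence <- function(x, ...) {
  cat("ASRT sequence: ",
      paste0(paste(unclass(x), collapse = "-r-"), "-r"), " (cyclic)\n",
      sep = "")
  invisible(x)
}

#' Cyclic successor of a direction under a sequence
#'
#' The element that follows `d` in the repeating pattern cycle (the element
#' after the fourth is the first).
#'
#' @param sequence an [asrt_sequence()].
#' @param d direction code(s) in 1:4.
#' @return direction code(s) of the same length as `d`.
#' @export
sequence_successor <- function(sequence, d) {
  sequence <- asrt_sequence(sequence)
  pos <- match(d, unclass(sequence))
  if (anyNA(pos)) stop("direction codes must be in 1:4", call. = FALSE)
  unclass(sequence)[pos %% 4L + 1L]
}

canonical_rotation <- function(elements) {
  # rotate so the sequence starts with direction 1
  i <- match(1L, elements)
  as.integer(elements[((seq_len(4L) + i - 2L) %% 4L) + 1L])
}

#' Enumerate the unique ASRT sequences
#'
#' There are 24 permutations of the four directions, but continuous cyclic
#' presentation makes rotations equivalent, leaving 6 unique sequences.
#' Returns one canonical representative per class (starting with direction
#' 1), in lexicographic order.
#'
#' @return list of 6 [asrt_sequence()] objects.
#' @examples
#' length(enumerate_unique_sequences())  # 6
#' @export
enumerate_unique_sequences <- function() {
  perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  perms <- perms[apply(perms, 1L, function(r) length(unique(r)) == 4L), ]
  canon <- unique(t(apply(as.matrix(perms), 1L, canonical_rotation)))
  canon <- canon[order(canon[, 2L], canon[, 3L], canon[, 4L]), , drop = FALSE]
  lapply(seq_len(nrow(canon)), function(i) asrt_sequence(canon[i, ]))
}

#' All cyclic rotations of a sequence
#' @param sequence an [asrt_sequence()].
#' @return list of 4 integer vectors.
#' @keywords internal
sequence_rotations <- function(sequence) {
  e <- unclass(asrt_sequence(sequence))
  lapply(0:3, function(k) as.integer(e[((seq_len(4L) + k - 1L) %% 4L) + 1L]))
}

#' Pseudorandomly select a sequence for a participant
#'
#' Uniform draw over the six unique sequences, reproducible under `seed`.
#'
#' @param seed non-negative integer seed.
#' @return an [asrt_sequence()].
#' @export
select_sequence <- function(seed) {
  seqs <- enumerate_unique_sequences()
  seqs[[with_seed(seed, sample.int(length(seqs), 1L))]]
}

#' Generate a session of ASRT trials
#'
#' Each 85-trial block starts with 5 random warm-up trials followed by 10
#' repetitions of the eight-element P-r-P-r cycle: even within-block
#' positions (6, 8, ..., 84) are pattern trials following the sequence,
#' odd positions (7, 9, ..., 85) are i.i.d. uniform random. By default the
#' pattern phase restarts at the sequence's first element in every block;
#' `phase_continuous = TRUE` carries the phase across block boundaries.
#'
#' @param sequence an [asrt_sequence()] (or a permutation of 1:4).
#' @param n_blocks number of blocks (default 30, i.e. 2550 trials).
#' @param rng_seed integer seed for the random trials.
#' @param phase_continuous logical; continue the pattern cycle across
#'   blocks instead of restarting it.
#' @return a `data.frame` of class `asrt_stream` with columns
#'   `block`, `pos` (1..85 within block), `trial_class`
#'   (`"warmup"`/`"pattern"`/`"random"`), `direction`; the sequence, seed
#'   and timing constants are attached as attributes.
#' @examples
#' s <- generate_session(asrt_sequence(c(2, 1, 3, 4)), n_blocks = 1,
#'                       rng_seed = 1)
#' table(s$trial_class)
#' @export
generate_session <- function(sequence, n_blocks = 30L, rng_seed = 1L,
                             phase_continuous = FALSE) {
  sequence <- asrt_sequence(sequence)
  n_blocks <- as.integer(n_blocks)
  if (is.na(n_blocks) || n_blocks < 1L)
    stop("`n_blocks` must be >= 1", call. = FALSE)

  pos <- rep(seq_len(TRIALS_PER_BLOCK), times = n_blocks)
  block <- rep(seq_len(n_blocks), each = TRIALS_PER_BLOCK)
  trial_class <- ifelse(pos <= WARMUP_PER_BLOCK, "warmup",
                        ifelse(pos %% 2L == 0L, "pattern", "random"))
  n <- length(pos)
  direction <- integer(n)

  is_pattern <- trial_class == "pattern"
  n_pat <- sum(is_pattern)
  if (phase_continuous) {
    phase <- (seq_len(n_pat) - 1L) %% 4L + 1L
  } else {
    phase <- rep(rep(1:4, times = 10L), times = n_blocks)
  }
  direction[is_pattern] <- unclass(sequence)[phase]

  n_rand <- sum(!is_pattern)
  direction[!is_pattern] <- with_seed(rng_seed,
    sample(DIRECTIONS, n_rand, replace = TRUE))

  out <- data.frame(block = block, pos = pos, trial_class = trial_class,
                    direction = direction)
  attr(out, "sequence") <- sequence
  attr(out, "n_blocks") <- n_blocks
  attr(out, "rng_seed") <- as.integer(rng_seed)
  attr(out, "phase_continuous") <- phase_continuous
  attr(out, "timing") <- asrt_timing()
  class(out) <- c("asrt_stream", "data.frame")
  out
}

#' Write / read a trial-log CSV
#'
#' Plain CSV with columns `subject,block,pos,trial_class,direction,seed`.
#'
#' @param stream an `asrt_stream`.
#' @param path output file.
#' @param subject subject identifier stored in the log.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(stream, path, subject = 1L) {
  df <- data.frame(subject = subject, block = stream$block, pos = stream$pos,
                   trial_class = stream$trial_class,
                   direction = stream$direction,
                   seed = attr(stream, "rng_seed") %||% NA_integer_)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @param sequence the sequence the log was generated under (not stored in
#'   the CSV itself).
#' @export
read_trial_log <- function(path, sequence = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("block", "pos", "trial_class", "direction")
  if (!all(need %in% names(df)))
    stop("trial log must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- df[need]
  if (!is.null(sequence)) attr(out, "sequence") <- asrt_sequence(sequence)
  attr(out, "n_blocks") <- length(unique(out$block))
  class(out) <- c("asrt_stream", "data.frame")
  out
}
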