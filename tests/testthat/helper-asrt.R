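# Shared fixtures: all built in code at test time.

canonical_sequence <- function() asrt_sequence(c(2, 1, 3, 4))

# tiny deterministic subject for fast pipeline tests
tiny_subject <- function(seed = 11L, n_blocks = 6L, include_eeg = FALSE,
                         erp = quick_erp_params(), ...) {
  simulate_subject(seed,
                   params = list(behavior = behavior_params(...),
                                 erp = erp,
                                 generation = generation_params()),
                   n_blocks = n_blocks, include_eeg = include_eeg, id = 1L)
}

# low sampling rate keeps EEG fixtures small in unit tests
quick_erp_params <- function(...) erp_params(sampling_rate = 100, ...)

# hand-built stream: one block with prescribed directions
manual_stream <- function(directions, sequence = canonical_sequence()) {
  n <- length(directions)
  stopifnot(n <= 85)
  pos <- seq_len(n)
  trial_class <- ifelse(pos <= 5L, "warmup",
                        ifelse(pos %% 2L == 0L, "pattern", "random"))
  out <- data.frame(block = 1L, pos = pos, trial_class = trial_class,
                    direction = as.integer(directions))
  attr(out, "sequence") <- sequence
  attr(out, "n_blocks") <- 1L
  class(out) <- c("asrt_stream", "data.frame")
  out
}
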