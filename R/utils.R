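#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the Mersenne-Twister generator, and
#' restores the previous state on exit, so seeded generators never disturb
#' the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0)
    stop("`seed` must be a single non-negative integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max), kind = "Mersenne-Twister")
  expr
}

#' Derive child seeds from a master seed
#'
#' Deterministic expansion of one master seed into `n` distinct 31-bit
#' child seeds (one per subject / per stage), so every stochastic stage is
#' independently reproducible.
#'
#' @param master integer master seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @keywords internal
derive_seeds <- function(master, n) {
  with_seed(master, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trial timing constants of the task
#'
#' Fixed presentation constants carried as metadata: 200 ms stimulus,
#' up to 500 ms response window after stimulus offset, and a 700 ms
#' response-to-stimulus interval (RSI). Used only for event-time
#' bookkeeping by the EEG simulator.
#'
#' @return named list of durations in ms.
#' @export
asrt_timing <- function() {
  list(stimulus_ms = 200, max_blank_ms = 500, rsi_ms = 700,
       response_window_ms = 700)
}
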