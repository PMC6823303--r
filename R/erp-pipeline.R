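# ERP pipeline: segmentation into stimulus- and response-locked epochs,
# baseline correction, +/-100 uV artifact rejection, category x epoch-bin
# averaging over a centroparietal pool, and mean-amplitude component
# measurement.
#
# Window convention: half-open [start, end) in ms; a sample at time t
# belongs to the window iff start <= t < end, so the 380 ms boundary
# belongs to the late P3 only.

#' Measurement and baseline windows, ms
#'
#' Stimulus-locked: segments span [-200, 600), P3 peak [280, 380), late P3
#' [380, 600), baseline [-200, 0). Response-locked: segments span
#' [-700, 700), P3 peak [-50, 50), late P3 [50, 250), baseline [500, 700)
#' (the final 200 ms of the response-to-stimulus interval).
#'
#' @param p3_peak,late_p3,baseline,span named lists with `stimulus` and
#'   `response` two-element `c(start, end)` vectors.
#' @return list of class `component_windows`.
#' @export
component_windows <- function(
    span     = list(stimulus = c(-200, 600), response = c(-700, 700)),
    p3_peak  = list(stimulus = c(280, 380),  response = c(-50, 50)),
    late_p3  = list(stimulus = c(380, 600),  response = c(50, 250)),
    baseline = list(stimulus = c(-200, 0),   response = c(500, 700))) {
  w <- list(span = span, p3_peak = p3_peak, late_p3 = late_p3,
            baseline = baseline)
  for (lock in c("stimulus", "response")) {
    sp <- span[[lock]]
    for (nm in c("p3_peak", "late_p3", "baseline")) {
      win <- w[[nm]][[lock]]
      if (win[1] < sp[1] || win[2] > sp[2])
        stop(nm, " window lies outside the ", lock, "-locked span",
             call. = FALSE)
    }
  }
  class(w) <- "component_windows"
  w
}

window_index <- function(times, window) {
  which(times >= window[1] & times < window[2])
}

#' Cut per-trial EEG into stimulus- or response-locked segments
#'
#' One segment per analyzable, correctly responded trial with RT > 0.
#' Stimulus-locked segments span [-200, 600) ms around stimulus onset;
#' response-locked segments span [-700, 700) ms around the key press (cut
#' at stimulus time + RT on the stimulus-anchored array, snapped to the
#' sample grid). Trials whose response-locked span exceeds the available
#' data are dropped and counted.
#'
#' @param record a subject record from [simulate_subject()], or any list
#'   with elements `stream`, `labels`, `behavior`, `eeg`.
#' @param locking `"stimulus"` or `"response"`.
#' @param windows a [component_windows()] object.
#' @return list of class `erp_segments` with elements `data` (array
#'   channel x sample x segment), `info` (`data.frame` of trial row,
#'   category, epoch), `times` (segment axis, ms), `locking`, and
#'   `n_dropped` (qualifying trials whose window fell outside the data).
#' @export
segment_trials <- function(record, locking = c("stimulus", "response"),
                           windows = component_windows()) {
  locking <- match.arg(locking)
  eeg <- record$eeg
  if (is.null(eeg)) stop("record carries no EEG array", call. = FALSE)
  times <- attr(eeg, "times")
  fs <- attr(eeg, "sampling_rate")
  step <- 1000 / fs
  labels <- record$labels
  beh <- record$behavior
  n_blocks <- attr(record$stream, "n_blocks") %||% max(record$stream$block)
  epoch <- epoch_of_block(record$stream$block, n_blocks,
                          n_bins = min(6L, n_blocks))

  qual <- which(labels$analyzable & beh$correct & !is.na(beh$rt) & beh$rt > 0)
  span <- windows$span[[locking]]
  n_samp <- as.integer(round((span[2] - span[1]) / step))

  # start sample of each segment on the stimulus-anchored axis
  anchor <- if (locking == "stimulus") rep(0, length(qual)) else
    floor(beh$rt[qual] / step) * step   # snap response time to the grid
  start_t <- anchor + span[1]
  start_idx <- as.integer(round((start_t - times[1]) / step)) + 1L
  ok <- start_idx >= 1L & (start_idx + n_samp - 1L) <= length(times)
  dropped <- sum(!ok)
  qual <- qual[ok]
  start_idx <- start_idx[ok]

  C <- dim(eeg)[1L]
  data <- array(NA_real_, dim = c(C, n_samp, length(qual)),
                dimnames = list(dimnames(eeg)[[1L]], NULL, NULL))
  for (k in seq_along(qual))
    data[, , k] <- eeg[, start_idx[k]:(start_idx[k] + n_samp - 1L), qual[k]]

  structure(list(
    data = data,
    info = data.frame(trial = qual, category = labels$category[qual],
                      epoch = epoch[qual]),
    times = span[1] + (seq_len(n_samp) - 1L) * step,
    locking = locking, n_dropped = dropped, windows = windows),
    class = "erp_segments")
}

#' Baseline-correct segments
#'
#' Subtracts, per channel and segment, the mean over the locking-
#' appropriate baseline window ([-200, 0) ms stimulus-locked, [500, 700) ms
#' response-locked). Idempotent.
#'
#' @param segments an `erp_segments` object.
#' @return the corrected `erp_segments`.
#' @export
baseline_correct <- function(segments) {
  win <- window_index(segments$times,
                      segments$windows$baseline[[segments$locking]])
  if (!length(win)) stop("baseline window contains no samples", call. = FALSE)
  m <- segments$data[, win, , drop = FALSE]
  # channel x segment means over the baseline samples
  bl <- colMeans(aperm(m, c(2L, 1L, 3L)), dims = 1L)
  if (is.null(dim(bl))) bl <- matrix(bl, nrow = dim(m)[1L])
  segments$data <- sweep_baseline(segments$data, bl)
  segments
}

sweep_baseline <- function(data, bl) {
  d <- dim(data)
  data - aperm(array(bl, dim = c(d[1L], d[3L], d[2L])), c(1L, 3L, 2L))
}

#' Reject segments with activity beyond a threshold
#'
#' A segment is removed iff any sample at any channel exceeds the
#' threshold in absolute value (strictly: |amplitude| > threshold, so a
#' sample at exactly +/-100 uV is retained).
#'
#' @param segments an `erp_segments` object.
#' @param threshold uV (default 100).
#' @return the retained `erp_segments`, with a `rejection` element giving
#'   overall and per-category rejection counts and percentages.
#' @export
reject_artifacts <- function(segments, threshold = 100) {
  n_seg <- dim(segments$data)[3L]
  bad <- if (n_seg) apply(abs(segments$data), 3L, max) > threshold else
    logical(0)
  cats <- unique(segments$info$category)
  rejection <- data.frame(
    category = cats,
    n = vapply(cats, function(cc) sum(segments$info$category == cc),
               integer(1)),
    rejected = vapply(cats, function(cc)
      sum(bad[segments$info$category == cc]), integer(1)))
  rejection$pct <- ifelse(rejection$n > 0,
                          100 * rejection$rejected / rejection$n, NA_real_)
  segments$data <- segments$data[, , !bad, drop = FALSE]
  segments$info <- segments$info[!bad, , drop = FALSE]
  segments$rejection <- rejection
  segments$n_rejected <- sum(bad)
  segments
}

#' Average segments within cells and pool centroparietal channels
#'
#' For each triplet category x epoch-bin cell (plus the pooled
#' `random_combined` category), averages the retained segments and then the
#' channels of the centroparietal pool, yielding one pooled waveform per
#' cell. Cells with zero segments are flagged missing.
#'
#' @param segments an `erp_segments` object (baseline-corrected and
#'   artifact-rejected).
#' @param channel_pool channel labels to pool (all must be present).
#' @return list of class `erp_averages`: `waveforms` (cell x sample
#'   matrix), `cells` (`data.frame` of category, epoch, n_segments),
#'   `times`, `locking`, `windows`.
#' @export
average_and_pool <- function(segments, channel_pool = CP_POOL) {
  chans <- dimnames(segments$data)[[1L]]
  if (!all(channel_pool %in% chans))
    stop("missing pool channel(s): ",
         paste(setdiff(channel_pool, chans), collapse = ", "), call. = FALSE)
  pool_idx <- match(channel_pool, chans)

  info <- segments$info
  epochs <- sort(unique(info$epoch))
  cats <- c(TRIPLET_CATEGORIES, "random_combined")
  members <- list(pattern_high = "pattern_high",
                  random_high = "random_high",
                  random_low = "random_low",
                  random_combined = c("random_high", "random_low"))

  cells <- expand.grid(category = cats, epoch = epochs,
                       stringsAsFactors = FALSE)
  n_samp <- dim(segments$data)[2L]
  wf <- matrix(NA_real_, nrow = nrow(cells), ncol = n_samp)
  nseg <- integer(nrow(cells))
  # pooled channel mean once per segment: samples x segments
  pooled <- colMeans(segments$data[pool_idx, , , drop = FALSE])
  for (i in seq_len(nrow(cells))) {
    sel <- info$category %in% members[[cells$category[i]]] &
      info$epoch == cells$epoch[i]
    nseg[i] <- sum(sel)
    if (nseg[i] > 0L)
      wf[i, ] <- rowMeans(pooled[, sel, drop = FALSE])
  }
  cells$n_segments <- nseg
  structure(list(waveforms = wf, cells = cells, times = segments$times,
                 locking = segments$locking, windows = segments$windows),
            class = "erp_averages")
}

#' Mean amplitude of a component window
#'
#' Arithmetic mean of the waveform samples in the half-open window
#' (start inclusive, end exclusive) appropriate to the locking.
#'
#' @param waveform numeric vector of pooled amplitudes.
#' @param times time axis, ms.
#' @param windows a [component_windows()] object.
#' @param which `"p3_peak"` or `"late_p3"`.
#' @param locking `"stimulus"` or `"response"`.
#' @return mean amplitude, uV.
#' @export
measure_component <- function(waveform, times, windows = component_windows(),
                              which = c("p3_peak", "late_p3"),
                              locking = c("stimulus", "response")) {
  which <- match.arg(which)
  locking <- match.arg(locking)
  win <- windows[[which]][[locking]]
  if (win[1] < times[1] || win[2] > times[length(times)] + diff(times[1:2]))
    stop("component window lies outside the waveform span", call. = FALSE)
  idx <- window_index(times, win)
  mean(waveform[idx])
}

#' Full ERP measurement table for one subject
#'
#' Runs segmentation, baseline correction, artifact rejection, pooling and
#' component measurement for both lockings, returning tidy rows per
#' locking x category x epoch bin x component.
#'
#' @param record a subject record with EEG.
#' @param windows a [component_windows()] object.
#' @param threshold artifact-rejection threshold, uV.
#' @param channel_pool channels to pool.
#' @return `data.frame` with columns `subject, locking, category, epoch,
#'   component, amplitude, n_segments`, plus attribute `rejection` (list of
#'   per-locking rejection tables).
#' @export
erp_measure_table <- function(record, windows = component_windows(),
                              threshold = 100, channel_pool = CP_POOL) {
  out <- list(); rej <- list()
  for (locking in c("stimulus", "response")) {
    seg <- segment_trials(record, locking, windows)
    seg <- baseline_correct(seg)
    seg <- reject_artifacts(seg, threshold)
    rej[[locking]] <- seg$rejection
    avg <- average_and_pool(seg, channel_pool)
    for (comp in c("p3_peak", "late_p3")) {
      amp <- apply(avg$waveforms, 1L, function(w)
        if (all(is.na(w))) NA_real_ else
          measure_component(w, avg$times, windows, comp, locking))
      out[[paste(locking, comp)]] <- data.frame(
        subject = record$id %||% NA_integer_, locking = locking,
        category = avg$cells$category, epoch = avg$cells$epoch,
        component = comp, amplitude = amp,
        n_segments = avg$cells$n_segments)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "rejection") <- rej
  res
}
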