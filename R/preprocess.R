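#' Band-pass filter and downsample a raw recording
#'
#' Restricts the recording to the slow ERP band and brings it to the working
#' sampling rate.  The band is realized as a zero-phase (forward-backward)
#' 4th-order Butterworth low-pass at `high` applied at the native rate,
#' integer decimation to `fs_out`, then a zero-phase 4th-order Butterworth
#' high-pass at `low` at the reduced rate; staging the high-pass after
#' decimation keeps the very low normalized cutoff well conditioned while
#' realizing the same pass band.  Zero-phase filtering preserves ERP latency.
#'
#' @param rec A `raw_recording`.
#' @param low,high Band edges in Hz (`low < high < fs/2`).
#' @param fs_out Output sampling rate in Hz; `fs(rec)` must be an integer
#'   multiple of it.
#' @return The recording, filtered and resampled (`fs` updated; event times
#'   are in seconds and unchanged).
#' @export
bandpass_downsample <- function(rec, low = 0.1, high = 10, fs_out = 100) {
  fs <- rec$fs
  if (!(low > 0 && low < high && high < fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2")
  dec <- fs / fs_out
  if (abs(dec - round(dec)) > 1e-9)
    stop("fs (", fs, ") must be an integer multiple of fs_out (", fs_out, ")")
  dec <- as.integer(round(dec))
  xt <- t(rec$samples)               # column-major per channel
  lp <- signal::butter(4, high / (fs / 2), type = "low")
  for (ch in seq_len(ncol(xt))) xt[, ch] <- signal::filtfilt(lp, xt[, ch])
  if (dec > 1L) xt <- xt[seq(1, nrow(xt), by = dec), , drop = FALSE]
  hp <- signal::butter(4, low / (fs_out / 2), type = "high")
  for (ch in seq_len(ncol(xt))) xt[, ch] <- signal::filtfilt(hp, xt[, ch])
  rec$samples <- t(xt)
  rec$fs <- fs_out
  rec
}

#' Remove ocular artifacts (placeholder hook)
#'
#' Identity transform reserved for an ICA-based electrooculogram removal
#' stage.  The synthetic data contain no ocular activity, so no ICA is
#' implemented; enabling the hook only emits a warning.
#'
#' @param rec A `raw_recording`.
#' @param enable If `TRUE`, warn that no EOG removal is performed.
#' @return `rec`, unchanged.
#' @export
remove_eog <- function(rec, enable = FALSE) {
  if (enable)
    warning("EOG removal hook enabled but no ICA stage is implemented; ",
            "returning data unchanged")
  rec
}

#' Epoch a preprocessed recording into single trials
#'
#' Target videos contribute exactly one epoch starting at the target onset;
#' nontarget videos are tiled into non-overlapping epochs from video onset,
#' discarding the partial tail.  Epochs are `trial_len` seconds (150 samples
#' at 100 Hz) by 16 channels.  `trial_index` follows stimulus order and is
#' identical across the subjects of one synchronized group.
#'
#' @param rec A `raw_recording` at the working rate (100 Hz).
#' @param trial_len Epoch length in seconds.
#' @return A `trial_set`: `trials` (n x 16 x samples array, microvolts),
#'   `labels` (1 target / 0 nontarget), `validity` (all `TRUE` until
#'   [screen_validity()]), `trial_index`, plus subject/channel metadata.
#' @export
epoch_trials <- function(rec, trial_len = 1.5) {
  ev <- rec$events
  if (is.null(ev) || nrow(ev) == 0) stop("recording has no events")
  bad <- ev$class == "target" & !is.finite(ev$target_onset)
  if (any(bad))
    stop("target video(s) without target onset marker: ",
         paste(ev$video_id[bad], collapse = ", "))
  fs <- rec$fs
  nsamp <- as.integer(round(trial_len * fs))
  layout <- trial_layout(ev, trial_len)
  n <- nrow(layout)
  nch <- nrow(rec$samples)
  trials <- array(NA_real_, c(n, nch, nsamp))
  for (i in seq_len(n)) {
    i0 <- as.integer(round(layout$start[i] * fs)) + 1L
    if (i0 + nsamp - 1L > ncol(rec$samples))
      stop("epoch ", i, " extends past the end of the recording")
    trials[i, , ] <- rec$samples[, i0:(i0 + nsamp - 1L)]
  }
  ts <- list(subject_id = rec$subject_id,
             trials = trials,
             labels = layout$class,
             validity = rep(TRUE, n),
             trial_index = layout$trial_index,
             video_id = layout$video_id,
             fs = fs,
             channels = rec$channels)
  class(ts) <- "trial_set"
  ts
}

#' Flag trials exceeding the amplitude validity threshold
#'
#' A trial is valid iff its maximum absolute amplitude over all channels and
#' samples is within the threshold (inclusive: a peak of exactly
#' `threshold` microvolts is still valid).  Trials are flagged, never removed.
#'
#' @param ts A `trial_set`.
#' @param threshold Amplitude threshold in microvolts (> 0).
#' @return `ts` with its `validity` flags replaced.
#' @export
screen_validity <- function(ts, threshold = 120) {
  if (threshold <= 0) stop("threshold must be positive")
  peak <- apply(abs(ts$trials), 1, max)
  ts$validity <- peak <= threshold
  ts
}
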