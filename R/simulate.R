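#' Configuration for the synthetic multi-subject EEG simulator
#'
#' Defines one simulated recording session: a randomized stream of short
#' target videos (each containing exactly one visual target) and nontarget
#' videos, watched simultaneously by `n_subjects` observers whose EEG is
#' recorded on a 16-channel 10-20 montage.  Each target elicits a P3-like
#' positive deflection over parieto-occipital electrodes with trial-to-trial
#' latency jitter; background activity is pink noise plus a weak 10 Hz
#' rhythm; a configurable fraction of trials carries a large-amplitude
#' artifact so downstream validity screening has something to reject.
#'
#' @param n_subjects Number of synchronized observers (>= 1).
#' @param n_target_videos,n_nontarget_videos Number of videos per class.
#' @param video_length_range Video duration range in seconds, within [4, 10].
#' @param channels Montage labels (16).
#' @param fs_raw Raw sampling rate in Hz.
#' @param p3_amplitude Peak P3 amplitude in microvolts, one value per subject
#'   (recycled).  Scales a fixed posterior-dominant scalp pattern.
#' @param p3_latency_jitter Range (s) of the P3 peak delay after target onset.
#' @param target_onset_min Earliest target onset, seconds after video start.
#'   The target never appears in the first second of a video; its onset is
#'   drawn uniformly between `target_onset_min` and `length - trial_len` so a
#'   full epoch fits inside the video.
#' @param noise_sd Standard deviation (microvolts) of the pink background noise.
#' @param alpha_amplitude Amplitude (microvolts) of the 10 Hz background rhythm.
#' @param artifact_rate Fraction of trials driven beyond the +/-120 microvolt
#'   validity threshold.
#' @param artifact_amplitude Peak amplitude (microvolts) of injected artifacts.
#' @param p3_width Full width (s) of the raised-cosine P3 bump.
#' @param gap Inter-video fixation gap in seconds.
#' @param trial_len Epoch length in seconds.
#' @param seed Integer seed; the whole simulation is reproducible from it.
#'
#' @return An object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 3, n_target_videos = 10,
#'                   n_nontarget_videos = 10, seed = 1)
sim_config <- function(n_subjects = 3,
                       n_target_videos = 100,
                       n_nontarget_videos = 100,
                       video_length_range = c(4, 10),
                       channels = default_montage(),
                       fs_raw = 600,
                       p3_amplitude = 8,
                       p3_latency_jitter = c(0.3, 0.7),
                       target_onset_min = 1,
                       noise_sd = 4,
                       alpha_amplitude = 1,
                       artifact_rate = 0.05,
                       artifact_amplitude = 150,
                       p3_width = 0.3,
                       gap = 2,
                       trial_len = 1.5,
                       seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_target_videos = as.integer(n_target_videos),
              n_nontarget_videos = as.integer(n_nontarget_videos),
              video_length_range = as.numeric(video_length_range),
              channels = as.character(channels),
              fs_raw = as.numeric(fs_raw),
              p3_amplitude = as.numeric(p3_amplitude),
              p3_latency_jitter = as.numeric(p3_latency_jitter),
              target_onset_min = as.numeric(target_onset_min),
              noise_sd = as.numeric(noise_sd),
              alpha_amplitude = as.numeric(alpha_amplitude),
              artifact_rate = as.numeric(artifact_rate),
              artifact_amplitude = as.numeric(artifact_amplitude),
              p3_width = as.numeric(p3_width),
              gap = as.numeric(gap),
              trial_len = as.numeric(trial_len),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  r <- cfg$video_length_range
  if (length(r) != 2 || r[1] > r[2] || r[1] < 4 || r[2] > 10)
    stop("video_length_range must lie within [4, 10] seconds")
  if (cfg$n_subjects < 1) stop("n_subjects must be >= 1")
  if (cfg$artifact_rate < 0 || cfg$artifact_rate > 1)
    stop("artifact_rate must be in [0, 1]")
  if (length(cfg$channels) != 16) stop("montage must have 16 channels")
  jt <- cfg$p3_latency_jitter
  if (length(jt) != 2 || jt[1] > jt[2] || jt[1] < 0)
    stop("p3_latency_jitter must be a nonnegative (min, max) range")
  if (cfg$target_onset_min < 1)
    stop("target_onset_min must be >= 1 s: targets never appear in the first second")
  if (cfg$target_onset_min + cfg$trial_len > r[1])
    stop("shortest video cannot hold a full epoch after target_onset_min")
  if (cfg$noise_sd < 0 || any(cfg$p3_amplitude < 0))
    stop("noise_sd and p3_amplitude must be nonnegative")
  invisible(cfg)
}

# Pink (1/f) noise, unit variance per channel, via spectral shaping.
# Computed at a 2-3-5-smooth length >= n so the FFT stays O(n log n); the
# real and imaginary parts of one random-phase complex spectrum give two
# independent channels per inverse FFT.
pink_noise <- function(n, k = 1L) {
  n2 <- stats::nextn(n, c(2, 3, 5))
  fidx <- pmin(1:(n2 - 1), n2 - (1:(n2 - 1)))   # symmetric frequency index
  amp <- c(0, 1 / sqrt(fidx))
  out <- matrix(NA_real_, k, n)
  for (j in seq_len(ceiling(k / 2))) {
    spec <- amp * exp(2i * pi * runif(n2))
    z <- fft(spec, inverse = TRUE) / n2
    x1 <- Re(z)[seq_len(n)]
    x2 <- Im(z)[seq_len(n)]
    out[2L * j - 1L, ] <- x1 / sd(x1)
    if (2L * j <= k) out[2L * j, ] <- x2 / sd(x2)
  }
  if (k == 1L) out[1, ] else out
}

# Shared stimulus stream: presentation order, lengths, onsets, target onsets.
draw_event_stream <- function(cfg) {
  nv <- cfg$n_target_videos + cfg$n_nontarget_videos
  cls <- sample(rep(c("target", "nontarget"),
                    c(cfg$n_target_videos, cfg$n_nontarget_videos)))
  len <- runif(nv, cfg$video_length_range[1], cfg$video_length_range[2])
  onset <- cfg$gap + c(0, cumsum(len[-nv] + cfg$gap))
  target_onset <- rep(NA_real_, nv)
  is_t <- cls == "target"
  target_onset[is_t] <- onset[is_t] +
    runif(sum(is_t), cfg$target_onset_min, len[is_t] - cfg$trial_len)
  data.frame(onset = onset, duration = len,
             video_id = seq_len(nv), class = cls,
             target_onset = target_onset, stringsAsFactors = FALSE)
}

# Prospective epoch layout implied by the event stream: one epoch per target
# video starting at target onset, nontarget videos tiled without overlap from
# video onset.  trial_index is shared across all subjects of a group.
trial_layout <- function(events, trial_len = 1.5) {
  rows <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    if (ev$class == "target") {
      rows[[i]] <- data.frame(video_id = ev$video_id, class = 1L,
                              start = ev$target_onset)
    } else {
      k <- floor(ev$duration / trial_len)
      if (k > 0)
        rows[[i]] <- data.frame(video_id = ev$video_id, class = 0L,
                                start = ev$onset + trial_len * (seq_len(k) - 1))
    }
  }
  out <- do.call(rbind, rows)
  out$trial_index <- seq_len(nrow(out))
  out
}

simulate_one_subject <- function(cfg, events, subject_id, amplitude) {
  fs <- cfg$fs_raw
  total <- max(events$onset + events$duration) + cfg$gap
  n <- ceiling(total * fs)
  nch <- length(cfg$channels)
  samples <- if (cfg$noise_sd > 0)
    cfg$noise_sd * pink_noise(n, nch) else matrix(0, nch, n)
  if (cfg$alpha_amplitude > 0) {
    base <- 2 * pi * 10 * (seq_len(n) - 1) / fs
    phase <- runif(nch, 0, 2 * pi)
    for (ch in seq_len(nch))
      samples[ch, ] <- samples[ch, ] +
        cfg$alpha_amplitude * sin(base + phase[ch])
  }

  # P3 bumps: raised-cosine of width p3_width, peaking `latency` after target
  # onset, scaled by the posterior scalp pattern and the subject's amplitude.
  pattern <- p3_scalp_pattern(cfg$channels)
  tg <- events[events$class == "target", ]
  lat <- runif(nrow(tg), cfg$p3_latency_jitter[1], cfg$p3_latency_jitter[2])
  for (j in seq_len(nrow(tg))) {
    peak <- tg$target_onset[j] + lat[j]
    i0 <- max(1L, floor((peak - cfg$p3_width / 2) * fs) + 1L)
    i1 <- min(n, ceiling((peak + cfg$p3_width / 2) * fs) + 1L)
    tt <- (seq(i0, i1) - 1) / fs
    bump <- amplitude * 0.5 * (1 + cos(2 * pi * (tt - peak) / cfg$p3_width))
    bump[abs(tt - peak) > cfg$p3_width / 2] <- 0
    samples[, i0:i1] <- samples[, i0:i1] + pattern %o% bump
  }

  # Artifacts: an in-band ~1 Hz sinusoid burst on one channel, peak amplitude
  # beyond the screening threshold, spanning most of the affected epoch so it
  # survives the zero-phase 0.1-10 Hz filter.
  layout <- trial_layout(events, cfg$trial_len)
  flagged <- rbinom(nrow(layout), 1, cfg$artifact_rate) == 1
  for (j in which(flagged)) {
    st <- layout$start[j] + 0.2
    i0 <- floor(st * fs) + 1L
    i1 <- min(n, i0 + fs - 1L)   # one 1 s cycle
    tt <- seq_along(i0:i1) / fs
    ch <- sample.int(nch, 1)
    sgn <- sample(c(-1, 1), 1)
    samples[ch, i0:i1] <- samples[ch, i0:i1] +
      sgn * cfg$artifact_amplitude * sin(2 * pi * tt)
  }

  rec <- list(subject_id = subject_id,
              samples = samples,
              fs = fs,
              channels = cfg$channels,
              events = events)
  class(rec) <- "raw_recording"
  list(rec = rec,
       topography = amplitude * pattern,
       latencies = lat,
       artifact = flagged)
}

#' Simulate one synchronized multi-subject recording session
#'
#' All subjects of a group watch the identical stimulus stream (bit-identical
#' event tables); their EEG differs in noise, P3 amplitude, latency jitter and
#' artifact placement.  Ground truth (true topographies, per-trial P3
#' latencies, artifact flags and the prospective epoch layout) is returned
#' alongside the recordings for validation of downstream stages.
#'
#' @param config A [sim_config()].
#' @return A list with elements `recordings` (list of `raw_recording`: 16 x T
#'   sample matrix in microvolts, sampling rate, channel labels, event table)
#'   and `truth` (list with `topography`, `latencies`, `artifact`, `layout`,
#'   `amplitudes`).
#' @export
#' @examples
#' sim <- simulate_group(sim_config(n_subjects = 2, n_target_videos = 3,
#'                                  n_nontarget_videos = 3, seed = 7))
#' sapply(sim$recordings, function(r) dim(r$samples)[1])
simulate_group <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  events <- draw_event_stream(config)
  amps <- rep(config$p3_amplitude, length.out = config$n_subjects)
  recs <- vector("list", config$n_subjects)
  topo <- matrix(NA_real_, config$n_subjects, length(config$channels),
                 dimnames = list(NULL, config$channels))
  lat <- matrix(NA_real_, config$n_subjects, config$n_target_videos)
  layout <- trial_layout(events, config$trial_len)
  art <- matrix(FALSE, config$n_subjects, nrow(layout))
  for (s in seq_len(config$n_subjects)) {
    one <- simulate_one_subject(config, events, paste0("sub", s), amps[s])
    recs[[s]] <- one$rec
    topo[s, ] <- one$topography
    lat[s, ] <- one$latencies
    art[s, ] <- one$artifact
  }
  list(recordings = recs,
       truth = list(topography = topo, latencies = lat, artifact = art,
                    layout = layout, amplitudes = amps))
}

#' Simulate a pool of independent single-mind subjects
#'
#' Generates `n_strong + n_weak` subjects recorded separately (independent
#' stimulus streams), with strong subjects drawn at a high P3 amplitude and
#' weak subjects at a low one.  Used to exercise P3-map clustering and
#' source-domain selection.
#'
#' @param config A [sim_config()]; its `seed` seeds the whole pool.
#' @param n_strong,n_weak Pool composition (`n_strong + n_weak >= 2`).
#' @param strong_amplitude,weak_amplitude Peak P3 amplitudes in microvolts.
#' @return List with `recordings` (one `raw_recording` per subject),
#'   `truth` (data frame: subject_id, group, amplitude) and per-subject
#'   ground-truth details in `details`.
#' @export
simulate_subject_pool <- function(config, n_strong, n_weak,
                                  strong_amplitude = 9, weak_amplitude = 3) {
  if (n_strong + n_weak < 2) stop("pool needs at least two subjects")
  n <- n_strong + n_weak
  amps <- c(rep(strong_amplitude, n_strong), rep(weak_amplitude, n_weak))
  grp <- rep(c("strong", "weak"), c(n_strong, n_weak))
  recs <- vector("list", n)
  details <- vector("list", n)
  for (s in seq_len(n)) {
    cfg_s <- config
    cfg_s$n_subjects <- 1L
    cfg_s$p3_amplitude <- amps[s]
    cfg_s$seed <- config$seed + s * 131L
    sim <- simulate_group(cfg_s)
    sim$recordings[[1]]$subject_id <- paste0("sub", s)
    recs[[s]] <- sim$recordings[[1]]
    details[[s]] <- sim$truth
  }
  list(recordings = recs,
       truth = data.frame(subject_id = paste0("sub", seq_len(n)),
                          group = grp, amplitude = amps,
                          stringsAsFactors = FALSE),
       details = details)
}
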