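#' Write a raw recording to the plain-text array container
#'
#' The container is a directory holding `samples.tsv` (channels x time,
#' microvolts, one row per channel with a leading `channel` column),
#' `events.tsv` (onset, duration, video_id, class, target_onset; seconds),
#' and `meta.json` (subject_id, fs, channels).  See the package's
#' `FORMATS.md` (in `inst/`) for the full description.
#'
#' @param rec A `raw_recording`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_recording <- function(rec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  smp <- data.frame(channel = rec$channels, rec$samples,
                    check.names = FALSE)
  write.table(smp, file.path(dir, "samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(rec$events, file.path(dir, "events.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(subject_id = rec$subject_id, fs = rec$fs,
                            channels = rec$channels),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a raw recording from the array container
#'
#' @param dir Directory written by [write_recording()].
#' @return A `raw_recording`.
#' @export
read_recording <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  smp <- read.table(file.path(dir, "samples.tsv"), sep = "\t",
                    stringsAsFactors = FALSE)
  samples <- as.matrix(smp[, -1, drop = FALSE])
  dimnames(samples) <- NULL
  events <- read.table(file.path(dir, "events.tsv"), sep = "\t",
                       header = TRUE, stringsAsFactors = FALSE)
  rec <- list(subject_id = meta$subject_id, samples = samples,
              fs = meta$fs, channels = meta$channels, events = events)
  class(rec) <- "raw_recording"
  rec
}

#' Write a trial set to the array container
#'
#' `trials.tsv` holds one row per (trial, channel) pair: `trial`, `channel`,
#' then the sample values; `trials_meta.tsv` holds per-trial label,
#' validity and trial index; `meta.json` the subject/rate/montage.
#'
#' @param ts A `trial_set` or `aligned_trial_set`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_trial_set <- function(ts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(ts$trials)
  flat <- matrix(aperm(ts$trials, c(2, 1, 3)), d[1] * d[2], d[3])
  idx <- data.frame(trial = rep(seq_len(d[1]), each = d[2]),
                    channel = rep(ts$channels, d[1]))
  write.table(cbind(idx, flat), file.path(dir, "trials.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  meta_df <- data.frame(trial = seq_len(d[1]), label = ts$labels,
                        validity = ts$validity,
                        trial_index = ts$trial_index)
  if (!is.null(ts$offsets)) meta_df$offset <- ts$offsets
  write.table(meta_df, file.path(dir, "trials_meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(subject_id = ts$subject_id, fs = ts$fs,
                            channels = ts$channels, n_trials = d[1],
                            n_samples = d[3],
                            aligned = inherits(ts, "aligned_trial_set")),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a trial set from the array container
#'
#' @param dir Directory written by [write_trial_set()].
#' @return A `trial_set` or `aligned_trial_set` (per the stored metadata).
#' @export
read_trial_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  flat <- as.matrix(read.table(file.path(dir, "trials.tsv"), sep = "\t",
                               stringsAsFactors = FALSE)[, -(1:2)])
  dimnames(flat) <- NULL
  nch <- length(meta$channels)
  trials <- aperm(array(flat, c(nch, meta$n_trials, meta$n_samples)),
                  c(2, 1, 3))
  md <- read.table(file.path(dir, "trials_meta.tsv"), sep = "\t",
                   header = TRUE, stringsAsFactors = FALSE)
  ts <- list(subject_id = meta$subject_id, trials = trials,
             labels = md$label, validity = md$validity,
             trial_index = md$trial_index, fs = meta$fs,
             channels = meta$channels)
  if (isTRUE(meta$aligned)) {
    ts$offsets <- md$offset
    class(ts) <- "aligned_trial_set"
  } else class(ts) <- "trial_set"
  ts
}

#' Write an ERP template (series + spatial filter) to TSV/JSON
#'
#' @param template An `erp_template`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_template <- function(template, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(data.frame(sample = seq_along(template$series),
                         value = template$series),
              file.path(dir, "template.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(weights = template$filter$weights,
                            eigenvalue = template$filter$eigenvalue,
                            crop_start = template$crop_start),
                       file.path(dir, "filter.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read an ERP template written by [write_template()]
#'
#' @param dir Directory holding `template.tsv` and `filter.json`.
#' @return An `erp_template`.
#' @export
read_template <- function(dir) {
  tpl <- read.table(file.path(dir, "template.tsv"), sep = "\t",
                    header = TRUE)
  flt <- jsonlite::read_json(file.path(dir, "filter.json"),
                             simplifyVector = TRUE)
  sf <- list(weights = flt$weights, eigenvalue = flt$eigenvalue)
  class(sf) <- "spatial_filter"
  out <- list(series = tpl$value, filter = sf, crop_start = flt$crop_start)
  class(out) <- "erp_template"
  out
}

#' Export P3 maps as a TSV table
#'
#' One row per subject: subject_id, peak latency (ms), then the 16 channel
#' values at the P3 peak.
#'
#' @param maps List of `p3_map`.
#' @param path Output TSV path.
#' @return Invisibly, the exported data frame.
#' @export
write_p3_maps <- function(maps, path) {
  df <- do.call(rbind, lapply(maps, function(m)
    data.frame(subject_id = m$subject_id,
               peak_latency_ms = m$peak_latency_ms,
               t(m$topography), check.names = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Save a network unit to a JSON checkpoint
#'
#' Stores the architecture and all parameter arrays at full double precision
#' (one file per subject network).  Optimizer state is not persisted; a
#' reloaded network is ready for evaluation or fresh fine-tuning.
#'
#' @param net A `network_unit`.
#' @param path Output file (conventionally `.json`).
#' @return Invisibly, `path`.
#' @export
save_network <- function(net, path) {
  payload <- list(
    arch = unclass(net$arch),
    par = lapply(net$par, function(p)
      if (is.matrix(p)) list(dim = dim(p), data = as.vector(p))
      else list(dim = length(p), data = as.vector(p))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a network unit from a JSON checkpoint
#'
#' @param path File written by [save_network()].
#' @return A `network_unit` (with a fresh, zeroed optimizer state).
#' @export
load_network <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  arch <- do.call(net_arch, payload$arch[c("n_filters", "kernel_t", "pool",
                                           "embed", "hidden", "n_channels",
                                           "n_samples")])
  par <- lapply(payload$par, function(p) {
    if (length(p$dim) == 2) matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  net <- list(arch = arch, par = par,
              adam = list(m = lapply(par, function(p) p * 0),
                          v = lapply(par, function(p) p * 0),
                          t = 0L))
  class(net) <- "network_unit"
  net
}
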