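#' Fit a one-component CSP spatial filter
#'
#' Common spatial patterns for the target vs nontarget contrast: the filter is
#' the generalized eigenvector maximizing the ratio of target-class variance
#' to pooled variance.  Class covariances are averages of trace-normalized
#' per-trial covariances, shrunk by `lambda * trace/16 * I` for small-sample
#' stability.  Solved by whitening the pooled covariance and taking the
#' leading eigenvector of the whitened target covariance (eigenvalues
#' descending, ties resolved by index).  The returned weight vector has unit
#' norm; its sign is fixed so the projected mean target response peaks
#' positive.
#'
#' @param target_trials,nontarget_trials Arrays `n x channels x samples`.
#' @param lambda Shrinkage factor for covariance regularization.
#' @return A `spatial_filter`: `weights` (unit 16-vector), `eigenvalue`.
#' @export
fit_csp <- function(target_trials, nontarget_trials, lambda = 1e-6) {
  ct <- class_covariance(target_trials, lambda)
  cn <- class_covariance(nontarget_trials, lambda)
  cc <- ct + cn
  ec <- eigen(cc, symmetric = TRUE)
  if (min(ec$values) <= max(ec$values) * 1e-12)
    stop("pooled covariance is rank deficient even after regularization")
  wh <- ec$vectors %*% (t(ec$vectors) / sqrt(ec$values))
  k <- t(wh) %*% ct %*% wh
  ek <- eigen((k + t(k)) / 2, symmetric = TRUE)
  w <- wh %*% ek$vectors[, 1]
  w <- w / sqrt(sum(w^2))

  # sign convention: mean target projection peaks positive
  avg <- apply(target_trials, c(2, 3), mean)
  p <- drop(crossprod(w, avg))
  if (p[which.max(abs(p))] < 0) w <- -w
  sf <- list(weights = drop(w), eigenvalue = ek$values[1])
  class(sf) <- "spatial_filter"
  sf
}

class_covariance <- function(trials, lambda) {
  if (length(dim(trials)) != 3 || dim(trials)[1] < 2)
    stop("need at least two trials per class")
  nch <- dim(trials)[2]
  acc <- matrix(0, nch, nch)
  for (i in seq_len(dim(trials)[1])) {
    x <- trials[i, , ]
    c_i <- tcrossprod(x)
    tr <- sum(diag(c_i))
    if (tr > 0) acc <- acc + c_i / tr
  }
  cv <- acc / dim(trials)[1]
  cv + diag(lambda * sum(diag(cv)) / nch, nch)
}

#' Build the one-dimensional target ERP template
#'
#' Projects every target trial through the CSP filter, averages the
#' projections, and crops the average to a contiguous window (default 100
#' samples = 1000 ms at 100 Hz).  The window is anchored on the average P3
#' peak: it starts `peak_anchor` samples before the peak (clamped to the
#' trial frame), which leaves most of the window after the peak.  Anchoring
#' the peak early keeps the whole latency-jitter range recoverable when
#' single trials are slid against the template — a peak-centered window
#' would push half the candidate offsets out of the admissible range.
#'
#' @param filter A `spatial_filter` from [fit_csp()].
#' @param target_trials Array `n x channels x samples` (samples >= `length`).
#' @param length Template length in samples.
#' @param peak_anchor Position (samples into the window) where the average
#'   peak is placed, frame permitting.
#' @return An `erp_template`: `series` (length-`length` numeric),
#'   `filter`, `crop_start` (0-based offset of the window).
#' @export
build_template <- function(filter, target_trials, length = 100L,
                           peak_anchor = 25L) {
  avg <- apply(target_trials, c(2, 3), mean)
  p <- drop(crossprod(filter$weights, avg))
  ns <- base::length(p)
  if (ns < length) stop("trials shorter than the template length")
  peak <- which.max(p)               # first maximum; sign fixed by fit_csp
  o <- min(max(peak - peak_anchor - 1L, 0L), ns - length)
  tpl <- list(series = p[(o + 1):(o + length)], filter = filter,
              crop_start = as.integer(o))
  class(tpl) <- "erp_template"
  tpl
}

#' Align latency-jittered trials to the ERP template
#'
#' Each trial's CSP projection (150 samples) is compared to the template at
#' every admissible window offset (0..50 for a 100-sample template); the
#' offset with the highest Pearson correlation wins, ties (and degenerate
#' zero-variance windows) resolved toward the smallest offset.  The full
#' 16-channel data at the chosen window is returned, so aligned trials are
#' `16 x 100`.
#'
#' @param ts A `trial_set` (or an object with `trials`, `labels`, `validity`,
#'   `trial_index`).
#' @param template An `erp_template`.
#' @return An `aligned_trial_set`: `trials` (n x 16 x 100), `offsets`
#'   (0-based, per trial), and the parent metadata (labels, validity,
#'   trial_index, subject_id, channels, fs).
#' @export
align_trials <- function(ts, template) {
  w <- template$filter$weights
  tl <- length(template$series)
  dims <- dim(ts$trials)
  n <- dims[1]; nch <- dims[2]; ns <- dims[3]
  if (ns < tl) stop("trials shorter than the template")
  noff <- ns - tl + 1L
  tplc <- template$series - mean(template$series)
  tpl_ss <- sum(tplc^2)
  out <- array(NA_real_, c(n, nch, tl))
  offsets <- integer(n)
  for (i in seq_len(n)) {
    x <- ts$trials[i, , ]
    p <- drop(crossprod(w, x))
    best <- -Inf; besto <- 0L
    if (tpl_ss > 0) {
      for (o in 0:(noff - 1L)) {
        seg <- p[(o + 1):(o + tl)]
        segc <- seg - mean(seg)
        ss <- sum(segc^2)
        if (ss == 0) next
        r <- sum(segc * tplc) / sqrt(ss * tpl_ss)
        if (r > best + 1e-12) { best <- r; besto <- o }
      }
    }
    offsets[i] <- besto
    out[i, , ] <- x[, (besto + 1):(besto + tl)]
  }
  al <- list(subject_id = ts$subject_id,
             trials = out,
             offsets = offsets,
             labels = ts$labels,
             validity = ts$validity,
             trial_index = ts$trial_index,
             fs = ts$fs,
             channels = ts$channels)
  class(al) <- "aligned_trial_set"
  al
}
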