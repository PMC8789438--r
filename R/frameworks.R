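#' Specification of a detection framework
#'
#' The four frameworks compared in this package differ only in how many
#' networks they train and how observer information is merged:
#'
#' * `sbci` — single-mind: one network, one observer, no fusion.
#' * `sc-cbci` — single-classifier collaborative: the group's aligned
#'   signals are averaged trialwise into one pseudo-subject (signal-level
#'   fusion), then one network is trained on it.
#' * `mc-cbci` — multi-classifier collaborative: one network per observer
#'   trained independently (`beta = 0`), probabilities fused by weighted
#'   average at evaluation only (decision-level fusion).
#' * `ml-cbci` — mutual-learning collaborative: decision-level fusion whose
#'   binarized collaborative decision is also fed back as a pseudo-label
#'   loss during training (`beta > 0`).
#'
#' @param name One of `"sbci"`, `"sc-cbci"`, `"mc-cbci"`, `"ml-cbci"`.
#' @param n_subjects Group size (used by the multi-network frameworks).
#' @return A `framework_spec`: `name`, `n_networks`, `fusion`
#'   (none/signal/decision), `mutual_learning`, `alpha` default.
#' @export
framework_spec <- function(name, n_subjects = 3L) {
  name <- match.arg(name, c("sbci", "sc-cbci", "mc-cbci", "ml-cbci"))
  spec <- switch(name,
    "sbci" = list(n_networks = 1L, fusion = "none",
                  mutual_learning = FALSE, alpha = 0.2),
    "sc-cbci" = list(n_networks = 1L, fusion = "signal",
                     mutual_learning = FALSE, alpha = 0.2),
    "mc-cbci" = list(n_networks = as.integer(n_subjects),
                     fusion = "decision", mutual_learning = FALSE,
                     alpha = 0.2),
    "ml-cbci" = list(n_networks = as.integer(n_subjects),
                     fusion = "decision", mutual_learning = TRUE,
                     alpha = 0.4))
  spec$name <- name
  class(spec) <- "framework_spec"
  spec
}

framework_cfg <- function(spec, cfg) {
  cfg$alpha <- spec$alpha
  if (!spec$mutual_learning) cfg$beta <- 0
  cfg
}

#' Single-mind framework
#'
#' One observer, one adversarial domain-adaptation network, no fusion:
#' [train_group()] with `N = 1` and the pseudo-label term off.
#'
#' @param source A `source_domain`.
#' @param target One `aligned_trial_set`.
#' @param cfg A [train_config()]; `alpha`/`beta` are overridden to the
#'   framework's operating point (0.2 / 0).
#' @return List: `fit` (the [train_group()] result), `prediction`,
#'   `metrics` (fused == individual here), `spec`.
#' @export
run_sbci <- function(source, target, cfg = train_config()) {
  spec <- framework_spec("sbci")
  cfg <- framework_cfg(spec, cfg)
  fit <- train_group(source, list(target), cfg)
  pred <- predict_group(fit$nets, list(target), cfg$weights %||% 1)
  list(fit = fit, prediction = pred, metrics = pred$fused_metrics,
       spec = spec)
}

#' Average a synchronized group's signals into one pseudo-subject
#'
#' Signal-level fusion: the trialwise mean of the subjects' aligned trials
#' (per channel and sample) at identical stimulus positions.  Validity is the
#' logical AND of the members' validity; labels and trial indices are shared.
#'
#' @param targets List of `aligned_trial_set` with identical `trial_index`.
#' @return One `aligned_trial_set` for the averaged pseudo-subject.
#' @export
average_group_signals <- function(targets) {
  ti <- targets[[1]]$trial_index
  for (tg in targets)
    if (!identical(tg$trial_index, ti))
      stop("cannot average desynchronized subjects")
  avg <- targets[[1]]$trials
  for (tg in targets[-1]) avg <- avg + tg$trials
  avg <- avg / length(targets)
  out <- targets[[1]]
  out$subject_id <- paste0("avg(",
                           paste(vapply(targets, function(tg) tg$subject_id,
                                        character(1)), collapse = "+"), ")")
  out$trials <- avg
  out$validity <- Reduce(`&`, lapply(targets, function(tg) tg$validity))
  out$offsets <- NULL
  out
}

#' Single-classifier collaborative framework (signal-level fusion)
#'
#' Averages the group's aligned trials into one pseudo-subject
#' ([average_group_signals()]) and trains a single network on it.
#'
#' @param source A `source_domain`.
#' @param targets List of `aligned_trial_set` for the group.
#' @param cfg A [train_config()].
#' @return As [run_sbci()], plus the averaged pseudo-subject in `averaged`.
#' @export
run_sc_cbci <- function(source, targets, cfg = train_config()) {
  spec <- framework_spec("sc-cbci", length(targets))
  cfg <- framework_cfg(spec, cfg)
  avg <- average_group_signals(targets)
  fit <- train_group(source, list(avg), cfg)
  pred <- predict_group(fit$nets, list(avg), cfg$weights %||% 1)
  list(fit = fit, prediction = pred, metrics = pred$fused_metrics,
       averaged = avg, spec = spec)
}

#' Multi-classifier collaborative framework (decision-level fusion)
#'
#' One network per observer, trained independently (`beta = 0`); decisions
#' are fused by weighted average and binarized at evaluation only.
#'
#' @param source A `source_domain`.
#' @param targets List of `aligned_trial_set` for the group.
#' @param cfg A [train_config()].
#' @return List: `fit`, `prediction`, `metrics` (fused),
#'   `per_network_metrics`, `spec`.
#' @export
run_mc_cbci <- function(source, targets, cfg = train_config()) {
  spec <- framework_spec("mc-cbci", length(targets))
  cfg <- framework_cfg(spec, cfg)
  fit <- train_group(source, targets, cfg)
  pred <- predict_group(fit$nets, targets,
                        cfg$weights %||% rep(1, length(targets)))
  list(fit = fit, prediction = pred, metrics = pred$fused_metrics,
       per_network_metrics = pred$per_network_metrics, spec = spec)
}

#' Mutual-learning collaborative framework
#'
#' Decision-level fusion with the collaborative pseudo-label fed back to
#' every network during training (`beta > 0`, `alpha = 0.4`).
#'
#' @param source A `source_domain`.
#' @param targets List of `aligned_trial_set` for the group.
#' @param cfg A [train_config()].
#' @return As [run_mc_cbci()].
#' @export
run_ml_cbci <- function(source, targets, cfg = train_config()) {
  spec <- framework_spec("ml-cbci", length(targets))
  cfg <- framework_cfg(spec, cfg)
  fit <- train_group(source, targets, cfg)
  pred <- predict_group(fit$nets, targets,
                        cfg$weights %||% rep(1, length(targets)))
  list(fit = fit, prediction = pred, metrics = pred$fused_metrics,
       per_network_metrics = pred$per_network_metrics, spec = spec)
}
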