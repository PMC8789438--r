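#' Training configuration for the group trainer
#'
#' Defaults mirror the published operating point of the mutual-learning
#' configuration: batch size 40, Adam at learning rate 3e-4, 100 epochs,
#' loss weights `alpha` (adversarial) 0.4, `gamma` (source category) 0.8,
#' `beta` (target category / mutual learning) 0.2, equal fusion weights.
#' The decision-fusion baseline without mutual learning uses `beta = 0` and
#' `alpha = 0.2`; see [framework_spec()].
#'
#' @param batch_size Samples per domain per iteration (`m`).
#' @param learning_rate Adam learning rate.
#' @param epochs Training epochs.
#' @param alpha,gamma,beta Loss weights for the adversarial, source-category
#'   and target-category (pseudo-label) terms; all nonnegative.
#' @param weights Fusion weights across the group's networks.
#' @param seed Integer seed covering initialization and batch sampling.
#' @param warmup_frac Fraction of epochs trained with the pseudo-label term
#'   off before target-sample selection and mutual learning engage.
#' @param select_fraction Fraction of valid target trials kept by the
#'   target-domain sample selector.
#' @param arch A [net_arch()].
#' @param eval_each_epoch Record fused/per-network F1 each epoch (uses the
#'   held-back evaluation labels; they never influence training).
#' @return A `train_config`.
#' @export
train_config <- function(batch_size = 40L, learning_rate = 3e-4,
                         epochs = 100L, alpha = 0.4, gamma = 0.8,
                         beta = 0.2, weights = NULL, seed = 1L,
                         warmup_frac = 0.1, select_fraction = 0.8,
                         arch = net_arch(), eval_each_epoch = TRUE) {
  if (any(c(alpha, gamma, beta) < 0)) stop("loss weights must be >= 0")
  cfg <- list(batch_size = as.integer(batch_size),
              learning_rate = learning_rate, epochs = as.integer(epochs),
              alpha = alpha, gamma = gamma, beta = beta, weights = weights,
              seed = as.integer(seed), warmup_frac = warmup_frac,
              select_fraction = select_fraction, arch = arch,
              eval_each_epoch = isTRUE(eval_each_epoch))
  class(cfg) <- "train_config"
  cfg
}

#' Fuse per-network target probabilities into shared pseudo-labels
#'
#' The collaborative decision: a weighted average of the networks'
#' target-class probabilities per trial, binarized at 0.5 (a tie maps to the
#' target class).  With one network this reduces to self-training on the
#' network's own binarized prediction.
#'
#' @param probs `N x m` matrix of target-class probabilities (one row per
#'   network) or a vector (`N = 1`).
#' @param weights Nonnegative fusion weights, not all zero; default equal.
#' @return A `pseudo_labels` list: `prob` (fused mean), `labels` (binary).
#' @export
fuse_and_binarize <- function(probs, weights = NULL) {
  if (!is.matrix(probs)) probs <- matrix(probs, nrow = 1)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  n <- nrow(probs)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) == 0)
    stop("weights must be nonnegative, length N, not all zero")
  fused <- drop(crossprod(probs, weights)) / sum(weights)
  out <- list(prob = fused, labels = as.integer(fused >= 0.5))
  class(out) <- "pseudo_labels"
  out
}

# Shared candidate pool for one synchronized group: the trials valid for
# every subject, in trial_index order, as one m x 16 x 100 array per subject.
group_candidates <- function(targets) {
  ti <- targets[[1]]$trial_index
  for (tg in targets)
    if (!identical(tg$trial_index, ti))
      stop("target subjects are not stimulus-synchronized ",
           "(trial_index streams differ)")
  valid <- Reduce(`&`, lapply(targets, function(tg) tg$validity))
  pos <- which(valid)
  pos <- pos[order(ti[pos])]
  list(trial_index = ti[pos],
       labels = targets[[1]]$labels[pos],
       trials = lapply(targets, function(tg) tg$trials[pos, , , drop = FALSE]))
}

#' Train a group of individual networks with mutual learning
#'
#' Couples `N` adversarial domain-adaptation units — one per observer —
#' through shared pseudo-labels.  Every iteration each network sees the same
#' labeled source batch plus its own subject's target batch drawn at
#' identical stimulus positions; per-network target-class probabilities are
#' fused ([fuse_and_binarize()]) and the binarized collaborative label is
#' fed back to all networks as their target-category loss.  The total
#' objective per iteration is
#' `sum_n alpha * L_adv(n) + gamma * L_s(n) + beta * L_t(n)`,
#' stepped with Adam.  The first `warmup_frac` of epochs run with the
#' pseudo-label term off; at the end of warm-up the shared target-domain
#' sample selection (top `select_fraction` by group-averaged target
#' probability) is made and frozen.  With `beta = 0` the networks train
#' independently (decision-fusion baseline); with `N = 1` and `beta = 0` the
#' trainer is exactly single-subject adversarial domain adaptation.
#'
#' @param source A `source_domain`.
#' @param targets List of `aligned_trial_set`, one per group subject, with
#'   identical `trial_index` streams.
#' @param cfg A [train_config()].
#' @return List: `nets`, `history` (per-iteration data frame: epoch, iter,
#'   net, loss_adv, loss_s, loss_t, alpha/gamma/beta in force, group
#'   `total`), `epoch_history` (per-epoch fused and per-network F1 if
#'   enabled), `selection` (selected trial_index set), `cfg`.
#' @export
train_group <- function(source, targets, cfg = train_config()) {
  n_nets <- length(targets)
  if (n_nets < 1) stop("need at least one target subject")
  weights <- cfg$weights %||% rep(1, n_nets)
  if (length(weights) != n_nets)
    stop("fusion weights must match the number of networks")
  set.seed(cfg$seed)
  cand <- group_candidates(targets)
  n_cand <- length(cand$trial_index)
  m <- cfg$batch_size
  n_src <- dim(source$trials)[1]
  nets <- lapply(seq_len(n_nets), function(i) new_network(cfg$arch))

  warmup_epochs <- if (cfg$warmup_frac > 0)
    min(cfg$epochs, max(1L, ceiling(cfg$warmup_frac * cfg$epochs))) else 0L
  pool <- seq_len(n_cand)          # warm-up: all shared valid trials
  selection_made <- warmup_epochs == 0L
  sel_index <- NULL
  onehot <- function(lab) cbind(1 - lab, lab)
  hist_rows <- vector("list", cfg$epochs * 4L)
  hr <- 0L
  epoch_rows <- list()

  if (selection_made) {
    sel <- shared_selection(nets, cand, weights, cfg$select_fraction)
    pool <- sel$pos; sel_index <- sel$trial_index
  }

  for (epoch in seq_len(cfg$epochs)) {
    beta_eff <- if (epoch <= warmup_epochs) 0 else cfg$beta
    perm <- sample(pool)
    iters <- max(1L, length(pool) %/% m)
    for (it in seq_len(iters)) {
      bpos <- if (length(pool) >= m)
        perm[((it - 1L) * m + 1L):(it * m)] else perm
      bm <- length(bpos)
      sidx <- sample.int(n_src, bm, replace = n_src < bm)
      xs <- source$trials[sidx, , , drop = FALSE]
      ys <- source$labels[sidx]
      fwd_s <- vector("list", n_nets); fwd_t <- vector("list", n_nets)
      for (nn in seq_len(n_nets)) {
        fwd_s[[nn]] <- net_forward(nets[[nn]], xs, keep_cache = TRUE)
        fwd_t[[nn]] <- net_forward(nets[[nn]],
                                   cand$trials[[nn]][bpos, , , drop = FALSE],
                                   keep_cache = TRUE)
      }
      pt <- do.call(rbind,
                    lapply(fwd_t, function(fw) fw$class_probs[, 2]))
      pseudo <- fuse_and_binarize(pt, weights)
      total <- 0
      for (nn in seq_len(n_nets)) {
        ls <- source_class_loss(fwd_s[[nn]]$class_probs, ys)
        ladv <- domain_adv_loss(fwd_s[[nn]]$domain_probs,
                                fwd_t[[nn]]$domain_probs)
        lt <- target_class_loss(fwd_t[[nn]]$class_probs, pseudo)
        total <- total + cfg$alpha * ladv + cfg$gamma * ls + beta_eff * lt
        dlc_s <- cfg$gamma * (fwd_s[[nn]]$class_probs - onehot(ys))
        dld_s <- cfg$alpha *
          (fwd_s[[nn]]$domain_probs - cbind(rep(1, bm), rep(0, bm)))
        dld_t <- cfg$alpha *
          (fwd_t[[nn]]$domain_probs - cbind(rep(0, bm), rep(1, bm)))
        dlc_t <- if (beta_eff > 0)
          beta_eff * (fwd_t[[nn]]$class_probs - onehot(pseudo$labels))
        else NULL
        g <- net_backward(nets[[nn]], fwd_s[[nn]]$cache, dlc_s, dld_s)
        g <- add_grads(g, net_backward(nets[[nn]], fwd_t[[nn]]$cache,
                                       dlc_t, dld_t))
        nets[[nn]] <- adam_step(nets[[nn]], g, cfg$learning_rate)
        hr <- hr + 1L
        hist_rows[[hr]] <- data.frame(epoch = epoch, iter = it, net = nn,
                                      loss_adv = ladv, loss_s = ls,
                                      loss_t = lt, alpha = cfg$alpha,
                                      gamma = cfg$gamma, beta = beta_eff)
      }
      for (nn in seq_len(n_nets))
        hist_rows[[hr - n_nets + nn]]$total <- total
    }
    if (epoch == warmup_epochs && !selection_made) {
      sel <- shared_selection(nets, cand, weights, cfg$select_fraction)
      pool <- sel$pos; sel_index <- sel$trial_index
      selection_made <- TRUE
    }
    if (cfg$eval_each_epoch && !is.null(cand$labels)) {
      ev <- eval_group(nets, cand, weights)
      epoch_rows[[epoch]] <- data.frame(
        epoch = epoch, fused_f1 = ev$fused$f1,
        mean_net_f1 = mean(vapply(ev$per_network, function(mm) mm$f1,
                                  numeric(1))))
    }
  }
  list(nets = nets,
       history = do.call(rbind, hist_rows[seq_len(hr)]),
       epoch_history = if (length(epoch_rows)) do.call(rbind, epoch_rows),
       selection = sel_index,
       cfg = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Group-level target-domain sample selection: rank shared candidates by the
# weighted group-average target probability, keep the top fraction, frozen.
shared_selection <- function(nets, cand, weights, fraction) {
  n_cand <- length(cand$trial_index)
  probs <- matrix(NA_real_, length(nets), n_cand)
  for (nn in seq_along(nets))
    probs[nn, ] <- net_forward(nets[[nn]], cand$trials[[nn]])$class_probs[, 2]
  fused <- drop(crossprod(probs, weights)) / sum(weights)
  keep_n <- max(1L, floor(fraction * n_cand))
  ord <- order(-fused, cand$trial_index)
  pos <- sort(ord[seq_len(keep_n)])
  list(pos = pos, trial_index = cand$trial_index[pos])
}

eval_group <- function(nets, cand, weights) {
  probs <- matrix(NA_real_, length(nets), length(cand$trial_index))
  for (nn in seq_along(nets))
    probs[nn, ] <- net_forward(nets[[nn]], cand$trials[[nn]])$class_probs[, 2]
  fused <- fuse_and_binarize(probs, weights)
  per_net <- lapply(seq_along(nets), function(nn)
    compute_metrics(as.integer(probs[nn, ] >= 0.5), cand$labels))
  list(fused = compute_metrics(fused$labels, cand$labels),
       per_network = per_net, probs = probs, fused_probs = fused$prob)
}

#' Predict with a trained group and fuse decisions
#'
#' Evaluation-mode forward pass of every network on all shared valid trials
#' of its subject, fused by weighted average and binarized at 0.5.
#' Deterministic.
#'
#' @param nets List of trained `network_unit`s.
#' @param targets List of `aligned_trial_set` (same group layout as
#'   training).
#' @param weights Fusion weights (default equal).
#' @return List: `per_network_probs` (N x n matrix), `fused_probs`,
#'   `fused_labels`, `trial_index`, `true_labels`, `fused_metrics`,
#'   `per_network_metrics`.
#' @export
predict_group <- function(nets, targets, weights = NULL) {
  weights <- weights %||% rep(1, length(nets))
  cand <- group_candidates(targets)
  ev <- eval_group(nets, cand, weights)
  fused <- fuse_and_binarize(ev$probs, weights)
  list(per_network_probs = ev$probs,
       fused_probs = fused$prob,
       fused_labels = fused$labels,
       trial_index = cand$trial_index,
       true_labels = cand$labels,
       fused_metrics = ev$fused,
       per_network_metrics = ev$per_network)
}
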