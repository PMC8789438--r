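#' Network architecture settings for the individual decoder unit
#'
#' The individual network unit is a compact convolutional ERP decoder with
#' three heads sharing one feature extractor: a temporal convolution (kernel
#' `kernel_t` samples, `n_filters` filters, shared across channels), a
#' per-filter spatial projection over the 16 channels, ELU, average pooling
#' (`pool`), and a dense embedding of `embed` units; a 2-way softmax category
#' classifier and a 2-way softmax domain discriminator (behind a gradient
#' reversal) each with one `hidden`-unit layer sit on top of the embedding.
#' Because temporal kernel and spatial weights factorize, the spatial
#' projection is applied first — mathematically identical and cheaper.
#'
#' @param n_filters Number of temporal/spatial filter pairs.
#' @param kernel_t Temporal kernel length in samples.
#' @param pool Average-pooling width (and stride).
#' @param embed Embedding width.
#' @param hidden Hidden width of each head.
#' @param n_channels,n_samples Input trial shape.
#' @return A `net_arch` list.
#' @export
net_arch <- function(n_filters = 8L, kernel_t = 25L, pool = 4L,
                     embed = 64L, hidden = 32L,
                     n_channels = 16L, n_samples = 100L) {
  conv_len <- n_samples - kernel_t + 1L
  if (conv_len %% pool != 0)
    stop("pooling width must divide the post-convolution length (",
         conv_len, ")")
  a <- list(n_filters = as.integer(n_filters), kernel_t = as.integer(kernel_t),
            pool = as.integer(pool), embed = as.integer(embed),
            hidden = as.integer(hidden), n_channels = as.integer(n_channels),
            n_samples = as.integer(n_samples),
            conv_len = conv_len, pooled_len = conv_len %/% pool)
  class(a) <- "net_arch"
  a
}

he_init <- function(nr, nc, fan_in) {
  matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

#' Initialize an individual network unit
#'
#' Parameters are drawn from the current RNG stream (seed upstream for
#' reproducibility).
#'
#' @param arch A [net_arch()].
#' @return A `network_unit` holding the parameter list and Adam state.
#' @export
new_network <- function(arch = net_arch()) {
  f <- arch$n_filters
  nf_feat <- arch$pooled_len * f
  par <- list(
    Ws = he_init(arch$n_channels, f, arch$n_channels),
    Wt = he_init(arch$kernel_t, f, arch$kernel_t),
    bt = numeric(f),
    W1 = he_init(nf_feat, arch$embed, nf_feat),
    b1 = numeric(arch$embed),
    Wc1 = he_init(arch$embed, arch$hidden, arch$embed),
    bc1 = numeric(arch$hidden),
    Wc2 = he_init(arch$hidden, 2L, arch$hidden),
    bc2 = numeric(2L),
    Wd1 = he_init(arch$embed, arch$hidden, arch$embed),
    bd1 = numeric(arch$hidden),
    Wd2 = he_init(arch$hidden, 2L, arch$hidden),
    bd2 = numeric(2L))
  net <- list(arch = arch, par = par,
              adam = list(m = lapply(par, function(p) p * 0),
                          v = lapply(par, function(p) p * 0),
                          t = 0L))
  class(net) <- "network_unit"
  net
}

elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
elu_grad <- function(x, a) ifelse(x > 0, 1, a + 1)

softmax2 <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Per-trial standardization: zero mean, unit SD over all channels and samples.
standardize_trials <- function(x) {
  m <- dim(x)[1]
  for (i in seq_len(m)) {
    xi <- x[i, , ]
    s <- sd(xi)
    x[i, , ] <- if (s > 0) (xi - mean(xi)) / s else xi - mean(xi)
  }
  x
}

toeplitz_conv <- function(wt, n_in, n_out) {
  tm <- matrix(0, n_in, n_out)
  for (k in seq_along(wt)) tm[cbind(k + 0:(n_out - 1L), 1:n_out)] <- wt[k]
  tm
}

#' Forward pass of a network unit
#'
#' Computes 2-class category probabilities and 2-class domain probabilities
#' for a batch of trials.  Inputs are standardized per trial (zero mean, unit
#' SD) before the feature extractor.  Deterministic: identical inputs give
#' identical rows.
#'
#' @param net A `network_unit`.
#' @param x Array `m x channels x samples` (a single `channels x samples`
#'   matrix is promoted to `m = 1`).
#' @param keep_cache Keep intermediates for [net_backward()].
#' @return List with `class_probs` (m x 2, columns nontarget/target) and
#'   `domain_probs` (m x 2, columns source/target); rows sum to 1.  With
#'   `keep_cache = TRUE`, also `cache`.
#' @export
net_forward <- function(net, x, keep_cache = FALSE) {
  a <- net$arch; p <- net$par
  if (length(dim(x)) == 2) x <- array(x, c(1L, dim(x)))
  if (length(dim(x)) != 3 || dim(x)[2] != a$n_channels ||
      dim(x)[3] != a$n_samples)
    stop("batch must be m x ", a$n_channels, " x ", a$n_samples)
  m <- dim(x)[1]
  f <- a$n_filters
  xs <- standardize_trials(x)
  xp <- matrix(aperm(xs, c(1, 3, 2)), m * a$n_samples, a$n_channels)
  pr <- xp %*% p$Ws                              # (m*T) x F spatial proj
  pm <- pool_mat(a$conv_len, a$pool)
  s_arr <- array(NA_real_, c(m, a$conv_len, f))
  for (fi in seq_len(f)) {
    tf <- toeplitz_conv(p$Wt[, fi], a$n_samples, a$conv_len)
    s_arr[, , fi] <- matrix(pr[, fi], m, a$n_samples) %*% tf + p$bt[fi]
  }
  a_arr <- elu(s_arr)
  h0 <- matrix(NA_real_, m, a$pooled_len * f)
  for (fi in seq_len(f))
    h0[, ((fi - 1) * a$pooled_len + 1):(fi * a$pooled_len)] <-
      matrix(a_arr[, , fi], m, a$conv_len) %*% pm
  z1 <- h0 %*% p$W1 + matrix(p$b1, m, a$embed, byrow = TRUE)
  h1 <- elu(z1)
  zc1 <- h1 %*% p$Wc1 + matrix(p$bc1, m, a$hidden, byrow = TRUE)
  c1 <- elu(zc1)
  lc <- c1 %*% p$Wc2 + matrix(p$bc2, m, 2, byrow = TRUE)
  zd1 <- h1 %*% p$Wd1 + matrix(p$bd1, m, a$hidden, byrow = TRUE)
  d1 <- elu(zd1)
  ld <- d1 %*% p$Wd2 + matrix(p$bd2, m, 2, byrow = TRUE)
  out <- list(class_probs = softmax2(lc), domain_probs = softmax2(ld))
  if (keep_cache)
    out$cache <- list(m = m, xp = xp, pr = pr, s = s_arr, a = a_arr,
                      h0 = h0, z1 = z1, h1 = h1,
                      zc1 = zc1, c1 = c1, zd1 = zd1, d1 = d1)
  out
}

pool_mat <- function(n_in, pool) {
  n_out <- n_in %/% pool
  pm <- matrix(0, n_in, n_out)
  for (j in seq_len(n_out)) pm[((j - 1) * pool + 1):(j * pool), j] <- 1 / pool
  pm
}

# Backward pass.  dlc / dld are gradients of the (already weighted) loss with
# respect to the classifier / discriminator logits.  With
# `reverse_domain = TRUE` the discriminator gradient entering the shared
# trunk is negated (gradient reversal): the discriminator head still learns
# to tell domains apart while the feature extractor is pushed toward domain
# confusion.
net_backward <- function(net, cache, dlc = NULL, dld = NULL,
                         reverse_domain = TRUE) {
  a <- net$arch; p <- net$par
  m <- cache$m; f <- a$n_filters
  zero <- matrix(0, m, 2)
  if (is.null(dlc)) dlc <- zero
  if (is.null(dld)) dld <- zero
  g <- list()
  # classifier head
  g$Wc2 <- crossprod(cache$c1, dlc); g$bc2 <- colSums(dlc)
  dc1 <- dlc %*% t(p$Wc2)
  dzc1 <- dc1 * elu_grad(cache$zc1, cache$c1)
  g$Wc1 <- crossprod(cache$h1, dzc1); g$bc1 <- colSums(dzc1)
  dh1 <- dzc1 %*% t(p$Wc1)
  # discriminator head (+ gradient reversal into the trunk)
  g$Wd2 <- crossprod(cache$d1, dld); g$bd2 <- colSums(dld)
  dd1 <- dld %*% t(p$Wd2)
  dzd1 <- dd1 * elu_grad(cache$zd1, cache$d1)
  g$Wd1 <- crossprod(cache$h1, dzd1); g$bd1 <- colSums(dzd1)
  dh1 <- dh1 + (if (reverse_domain) -1 else 1) * (dzd1 %*% t(p$Wd1))
  # embedding
  dz1 <- dh1 * elu_grad(cache$z1, cache$h1)
  g$W1 <- crossprod(cache$h0, dz1); g$b1 <- colSums(dz1)
  dh0 <- dz1 %*% t(p$W1)
  # pooling, ELU, temporal conv, spatial projection
  pm <- pool_mat(a$conv_len, a$pool)
  g$Wt <- matrix(0, a$kernel_t, f); g$bt <- numeric(f)
  dpr <- matrix(0, m * a$n_samples, f)
  for (fi in seq_len(f)) {
    dg <- dh0[, ((fi - 1) * a$pooled_len + 1):(fi * a$pooled_len), drop = FALSE]
    da <- dg %*% t(pm)
    ds <- da * elu_grad(cache$s[, , fi], cache$a[, , fi])
    g$bt[fi] <- sum(ds)
    prm <- matrix(cache$pr[, fi], m, a$n_samples)
    for (k in seq_len(a$kernel_t))
      g$Wt[k, fi] <- sum(prm[, k:(k + a$conv_len - 1L)] * ds)
    tf <- toeplitz_conv(p$Wt[, fi], a$n_samples, a$conv_len)
    dpr[, fi] <- as.vector(ds %*% t(tf))
  }
  g$Ws <- crossprod(cache$xp, dpr)
  g[names(net$par)]
}

add_grads <- function(g1, g2) {
  if (is.null(g1)) return(g2)
  mapply(function(a, b) a + b, g1, g2, SIMPLIFY = FALSE)
}

adam_step <- function(net, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st <- net$adam
  st$t <- st$t + 1L
  for (nm in names(net$par)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    net$par[[nm]] <- net$par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  net$adam <- st
  net
}

# ---- loss functions ---------------------------------------------------------

clamp_probs <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1)

as_class_probs <- function(p) {
  if (is.matrix(p)) {
    if (ncol(p) != 2) stop("class probabilities must have 2 columns")
    p
  } else cbind(1 - p, p)
}

#' Source-domain category loss (summed cross-entropy)
#'
#' `-sum_k l_k log p_k` over the batch: each sample contributes the negative
#' log-probability its network assigned to the true class.  Probabilities are
#' clamped at 1e-12 before the log.
#'
#' @param class_probs `m x 2` matrix (columns nontarget/target) or a vector
#'   of target-class probabilities.
#' @param labels Binary vector (1 target / 0 nontarget).
#' @return Scalar loss.
#' @export
source_class_loss <- function(class_probs, labels) {
  p <- as_class_probs(class_probs)
  if (nrow(p) != length(labels)) stop("probabilities/labels length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  picked <- ifelse(labels == 1, p[, 2], p[, 1])
  -sum(log(clamp_probs(picked)))
}

#' Adversarial domain-discrimination loss (summed cross-entropy)
#'
#' `-sum_k [log p_source(x_k^s) + log p_target(x_k^t)]`: the discriminator's
#' cross-entropy for labeling source samples as source and target samples as
#' target.  The discriminator descends this loss; the feature extractor
#' receives its gradient reversed.
#'
#' @param domain_probs_s,domain_probs_t `m x 2` matrices (columns
#'   source/target) for the source and target batches.
#' @return Scalar loss.
#' @export
domain_adv_loss <- function(domain_probs_s, domain_probs_t) {
  -sum(log(clamp_probs(domain_probs_s[, 1]))) -
    sum(log(clamp_probs(domain_probs_t[, 2])))
}

#' Target-domain category loss against shared pseudo-labels
#'
#' Identical form to [source_class_loss()], with the collaborative
#' binarized pseudo-labels standing in for the unknown target labels.
#'
#' @param class_probs `m x 2` matrix or target-class probability vector.
#' @param pseudo A `pseudo_labels` object from [fuse_and_binarize()], or a
#'   binary label vector.
#' @return Scalar loss.
#' @export
target_class_loss <- function(class_probs, pseudo) {
  labels <- if (is.list(pseudo)) pseudo$labels else pseudo
  source_class_loss(class_probs, labels)
}

# ---- target-domain sample selection ----------------------------------------

#' Select the most target-like trials as the adaptation pool
#'
#' Valid trials are ranked by descending target-class probability (ties
#' broken by ascending trial index, so the selected set is invariant to trial
#' order) and the top `floor(fraction * n_valid)` are kept.  For imbalanced
#' streams this trims the trials the warm-started networks are least sure
#' about.
#'
#' @param aligned An `aligned_trial_set`.
#' @param net A `network_unit`, a list of them (probabilities averaged —
#'   the group selection), or a precomputed numeric vector of target-class
#'   probabilities for the valid trials in `trial_index` order.
#' @param fraction Fraction of valid trials to keep, in (0, 1].
#' @return A `target_domain`: `trials`, `trial_index`, `probs`,
#'   `eval_labels` (kept for evaluation only, never used in training),
#'   `validity_source` metadata.
#' @export
select_target_samples <- function(aligned, net, fraction = 0.8) {
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  vidx <- which(aligned$validity)
  vidx <- vidx[order(aligned$trial_index[vidx])]
  x <- aligned$trials[vidx, , , drop = FALSE]
  probs <- if (is.numeric(net)) {
    if (length(net) != length(vidx))
      stop("probability vector must match the number of valid trials")
    net
  } else if (inherits(net, "network_unit")) {
    net_forward(net, x)$class_probs[, 2]
  } else {
    rowMeans(vapply(net, function(nn) net_forward(nn, x)$class_probs[, 2],
                    numeric(length(vidx))))
  }
  keep_n <- floor(fraction * length(vidx))
  ord <- order(-probs, aligned$trial_index[vidx])
  sel <- sort(ord[seq_len(keep_n)])
  td <- list(subject_id = aligned$subject_id,
             trials = x[sel, , , drop = FALSE],
             trial_index = aligned$trial_index[vidx][sel],
             probs = probs[sel],
             eval_labels = aligned$labels[vidx][sel])
  class(td) <- "target_domain"
  td
}
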