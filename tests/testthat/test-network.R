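test_that("forward pass yields proper probabilities of the right shape", {
  set.seed(31)
  net <- new_network(net_arch())
  x <- array(rnorm(40 * 16 * 100), c(40, 16, 100))
  out <- net_forward(net, x)
  expect_equal(dim(out$class_probs), c(40, 2))
  expect_equal(dim(out$domain_probs), c(40, 2))
  expect_equal(rowSums(out$class_probs), rep(1, 40), tolerance = 1e-6)
  expect_equal(rowSums(out$domain_probs), rep(1, 40), tolerance = 1e-6)
  expect_true(all(out$class_probs > 0 & out$class_probs < 1))
  # duplicated sample -> identical rows (deterministic forward)
  x2 <- x[c(1, 1, 2), , ]
  out2 <- net_forward(net, x2)
  expect_identical(out2$class_probs[1, ], out2$class_probs[2, ])
  # shape errors
  expect_error(net_forward(net, array(0, c(2, 16, 99))), "must be m x")
})

test_that("category and domain losses match scalar arithmetic", {
  # worked examples
  expect_equal(source_class_loss(cbind(c(0.2, 0.7), c(0.8, 0.3)), c(1, 0)),
               -(log(0.8) + log(0.7)), tolerance = 1e-12)
  expect_equal(source_class_loss(cbind(c(0.5, 0.5), c(0.5, 0.5)), c(1, 0)),
               2 * log(2), tolerance = 1e-12)
  expect_equal(source_class_loss(cbind(0, 1), 1), 0)
  expect_equal(domain_adv_loss(cbind(1, 0), cbind(0, 1)), 0)
  expect_equal(domain_adv_loss(cbind(0.5, 0.5), cbind(0.5, 0.5)),
               2 * log(2), tolerance = 1e-12)
  expect_equal(target_class_loss(cbind(0.75, 0.25), list(labels = 1)),
               -log(0.25), tolerance = 1e-12)
  # zero probabilities are clamped, not -Inf
  expect_true(is.finite(source_class_loss(cbind(1, 0), 1)))
  # target loss and source loss share one formula
  p <- cbind(c(0.3, 0.6), c(0.7, 0.4))
  expect_identical(target_class_loss(p, c(1, 0)), source_class_loss(p, c(1, 0)))
})

test_that("backpropagation matches finite-difference gradients", {
  set.seed(32)
  arch <- net_arch(n_filters = 2, kernel_t = 5, pool = 4, embed = 6,
                   hidden = 4, n_channels = 3, n_samples = 12)
  net <- new_network(arch)
  m <- 3
  xs <- array(rnorm(m * 3 * 12), c(m, 3, 12))
  xt <- array(rnorm(m * 3 * 12), c(m, 3, 12))
  ys <- c(1, 0, 1); yt <- c(0, 1, 1)
  a <- 0.4; g <- 0.8; b <- 0.2
  loss_fn <- function(nn) {
    fs <- net_forward(nn, xs); ft <- net_forward(nn, xt)
    g * source_class_loss(fs$class_probs, ys) +
      a * domain_adv_loss(fs$domain_probs, ft$domain_probs) +
      b * source_class_loss(ft$class_probs, yt)
  }
  fs <- net_forward(net, xs, keep_cache = TRUE)
  ft <- net_forward(net, xt, keep_cache = TRUE)
  onehot <- function(l) cbind(1 - l, l)
  gr <- cobci:::net_backward(net, fs$cache,
                             g * (fs$class_probs - onehot(ys)),
                             a * (fs$domain_probs - cbind(rep(1, m), 0)),
                             reverse_domain = FALSE)
  gr <- cobci:::add_grads(gr,
    cobci:::net_backward(net, ft$cache,
                         b * (ft$class_probs - onehot(yt)),
                         a * (ft$domain_probs - cbind(rep(0, m), 1)),
                         reverse_domain = FALSE))
  eps <- 1e-6
  for (nm in names(net$par)) {
    p <- net$par[[nm]]
    for (i in sample(length(p), min(4, length(p)))) {
      n2 <- net
      n2$par[[nm]][i] <- p[i] + eps; lp <- loss_fn(n2)
      n2$par[[nm]][i] <- p[i] - eps; lm <- loss_fn(n2)
      expect_equal(as.numeric(gr[[nm]][i]), (lp - lm) / (2 * eps),
                   tolerance = 1e-5)
    }
  }
})

test_that("gradient reversal pushes features toward domain confusion", {
  set.seed(33)
  arch <- net_arch(n_filters = 2, kernel_t = 13, pool = 4, embed = 8,
                   hidden = 6)
  m <- 20
  # domain-shifted data: target trials carry an oscillatory offset on a
  # channel subset, an easy cue for an unopposed discriminator
  xs <- array(rnorm(m * 16 * 100), c(m, 16, 100))
  xt <- array(rnorm(m * 16 * 100), c(m, 16, 100))
  shift <- sin(2 * pi * seq_len(100) / 25)
  for (i in seq_len(m)) xt[i, 1:4, ] <- xt[i, 1:4, ] + 2 * rep(shift, each = 4)
  dacc <- function(nn) {
    fs <- net_forward(nn, xs); ft <- net_forward(nn, xt)
    (sum(fs$domain_probs[, 1] > 0.5) + sum(ft$domain_probs[, 2] > 0.5)) /
      (2 * m)
  }
  run <- function(reverse, frozen_trunk) {
    net <- new_network(arch)
    head_par <- c("Wd1", "bd1", "Wd2", "bd2")
    for (step in 1:80) {
      fs <- net_forward(net, xs, keep_cache = TRUE)
      ft <- net_forward(net, xt, keep_cache = TRUE)
      g <- cobci:::add_grads(
        cobci:::net_backward(net, fs$cache, NULL,
                             fs$domain_probs - cbind(rep(1, m), 0),
                             reverse_domain = reverse),
        cobci:::net_backward(net, ft$cache, NULL,
                             ft$domain_probs - cbind(rep(0, m), 1),
                             reverse_domain = reverse))
      if (frozen_trunk)
        for (nm in setdiff(names(g), head_par)) g[[nm]] <- g[[nm]] * 0
      net <- cobci:::adam_step(net, g, 3e-3)
    }
    net
  }
  set.seed(33); coop <- run(reverse = FALSE, frozen_trunk = FALSE)
  set.seed(33); adv <- run(reverse = TRUE, frozen_trunk = FALSE)
  acc_coop <- dacc(coop)
  acc_adv <- dacc(adv)
  # without reversal, features cooperate and the domains separate cleanly
  expect_gt(acc_coop, 0.9)
  # the reversed gradient shapes features the discriminator cannot separate
  expect_lt(acc_adv, acc_coop - 0.2)
})

test_that("target-domain sample selection ranks, floors and is equivariant", {
  al <- make_aligned(n = 20, seed = 34)
  al$validity[c(3, 7)] <- FALSE            # 18 valid
  probs <- seq(0.95, 0.10, length.out = 18)
  td <- select_target_samples(al, probs, fraction = 0.8)
  expect_equal(dim(td$trials)[1], floor(0.8 * 18))
  vidx <- which(al$validity)
  expect_identical(td$trial_index, vidx[seq_len(14)])   # top-ranked kept
  # fraction 1 keeps all valid trials
  td_all <- select_target_samples(al, probs, fraction = 1)
  expect_equal(dim(td_all$trials)[1], 18)
  # floor(0.8 * 621) = 496
  expect_equal(floor(0.8 * 621), 496L)
  # permutation equivariance: shuffling trial storage order does not change
  # the selected stimulus positions (ties broken by trial_index)
  set.seed(35)
  net <- new_network(tiny_arch())
  td_a <- select_target_samples(al, net, fraction = 0.5)
  perm <- sample(20)
  al_p <- al
  al_p$trials <- al$trials[perm, , ]
  al_p$labels <- al$labels[perm]
  al_p$validity <- al$validity[perm]
  al_p$trial_index <- al$trial_index[perm]
  td_b <- select_target_samples(al_p, net, fraction = 0.5)
  expect_setequal(td_a$trial_index, td_b$trial_index)
  expect_error(select_target_samples(al, probs, fraction = 0), "fraction")
})

test_that("easy targets survive the 80 percent selection", {
  grp <- make_tiny_group(n_trials = 40, seed = 36, noise = 0.2, amp = 6)
  al <- grp$targets[[1]]
  cfg <- train_config(batch_size = 20, epochs = 40, learning_rate = 3e-3,
                      seed = 2, beta = 0, arch = tiny_arch(),
                      eval_each_epoch = FALSE)
  fit <- train_group(grp$source, list(al), cfg)
  td <- select_target_samples(al, fit$nets[[1]], fraction = 0.8)
  expect_true(all(which(al$labels == 1) %in% td$trial_index))
})
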