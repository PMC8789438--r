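# Shared fixture builders: small in-memory objects that skip the simulator
# where a test only needs shapes and labels.

make_trial_set <- function(n = 10, nch = 16, ns = 150, labels = NULL,
                           subject_id = "subX", fs = 100, seed = 1) {
  set.seed(seed)
  ts <- list(subject_id = subject_id,
             trials = array(rnorm(n * nch * ns), c(n, nch, ns)),
             labels = labels %||% rep(c(1L, 0L), length.out = n),
             validity = rep(TRUE, n),
             trial_index = seq_len(n),
             fs = fs,
             channels = cobci::default_montage()[seq_len(nch)])
  class(ts) <- "trial_set"
  ts
}

make_aligned <- function(n = 10, nch = 16, ns = 100, labels = NULL,
                         subject_id = "subX", trial_index = seq_len(n),
                         seed = 1, trials = NULL) {
  set.seed(seed)
  al <- list(subject_id = subject_id,
             trials = trials %||% array(rnorm(n * nch * ns), c(n, nch, ns)),
             offsets = rep(0L, n),
             labels = labels %||% rep(c(1L, 0L), length.out = n),
             validity = rep(TRUE, n),
             trial_index = trial_index,
             fs = 100,
             channels = cobci::default_montage()[seq_len(nch)])
  class(al) <- "aligned_trial_set"
  al
}

# Small, separable source + 3-subject group of aligned sets: targets carry a
# posterior bump, nontargets none.  For fast trainer-contract tests.
make_tiny_group <- function(n_trials = 60, seed = 1, noise = 0.5, amp = 3) {
  set.seed(seed)
  pat <- cobci:::p3_scalp_pattern()
  bump <- amp * sin(pi * seq(0, 1, length.out = 40))
  build <- function(labels, sd_noise) {
    x <- array(rnorm(length(labels) * 16 * 100, sd = sd_noise),
               c(length(labels), 16, 100))
    for (i in which(labels == 1)) {
      at <- sample(20:50, 1)
      x[i, , at:(at + 39)] <- x[i, , at:(at + 39)] + pat %o% bump
    }
    x
  }
  labels <- rep(c(1L, 0L), length.out = n_trials)
  source <- list(trials = build(labels, noise), labels = labels,
                 subject = rep("s1", n_trials), member_ids = "s1",
                 template = NULL)
  class(source) <- "source_domain"
  targets <- lapply(1:3, function(k)
    make_aligned(n_trials, labels = labels, subject_id = paste0("t", k),
                 trials = build(labels, noise), seed = seed + k))
  list(source = source, targets = targets, labels = labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_arch <- function() {
  cobci::net_arch(n_filters = 2, kernel_t = 13, pool = 4, embed = 8,
                  hidden = 4, n_channels = 16, n_samples = 100)
}
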