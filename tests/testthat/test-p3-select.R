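fake_template <- function(w) {
  sf <- structure(list(weights = w, eigenvalue = 1),
                  class = "spatial_filter")
  structure(list(series = rep(0, 100), filter = sf, crop_start = 0L),
            class = "erp_template")
}

fake_map <- function(id, topo) {
  structure(list(subject_id = id,
                 topography = stats::setNames(topo, default_montage()),
                 peak_sample = 1L, peak_latency_ms = 0),
            class = "p3_map")
}

test_that("P3 map extraction recovers a planted topography", {
  set.seed(11)
  pat <- cobci:::p3_scalp_pattern()
  w <- pat / sqrt(sum(pat^2))
  tpl <- fake_template(w)
  bump <- 6 * sin(pi * seq(0, 1, length.out = 31))
  al <- make_aligned(n = 12, seed = 12)
  al$trials <- al$trials * 0.001           # near noise-free
  for (i in which(al$labels == 1))
    al$trials[i, , 40:70] <- al$trials[i, , 40:70] + pat %o% bump
  m <- extract_p3_map(al, tpl)
  cs <- sum(m$topography * pat) / sqrt(sum(m$topography^2) * sum(pat^2))
  expect_gt(cs, 0.99)
  expect_equal(m$peak_sample, 55, tolerance = 2)
  # linearity: doubled amplitude doubles the topography
  al2 <- al; al2$trials <- al$trials * 2
  m2 <- extract_p3_map(al2, tpl)
  expect_equal(m2$topography, 2 * m$topography)
  # all-zero trials: zero topography, first-max peak at sample 1
  alz <- al; alz$trials[] <- 0
  mz <- extract_p3_map(alz, tpl)
  expect_true(all(mz$topography == 0))
  expect_equal(mz$peak_sample, 1L)
  # no valid target trials is an error
  alv <- al; alv$validity[al$labels == 1] <- FALSE
  expect_error(extract_p3_map(alv, tpl), "no valid target trials")
})

test_that("K-means separates strong from weak maps with the right sizes", {
  set.seed(13)
  pat <- cobci:::p3_scalp_pattern()
  maps <- c(lapply(1:13, function(i)
              fake_map(sprintf("sub%02d", i), 9 * pat + rnorm(16, sd = 0.3))),
            lapply(14:29, function(i)
              fake_map(sprintf("sub%02d", i), 3 * pat + rnorm(16, sd = 0.3))))
  cl <- cluster_p3_maps(maps)
  expect_length(cl$strong_ids, 13)
  expect_length(cl$weak_ids, 16)
  expect_setequal(cl$strong_ids, sprintf("sub%02d", 1:13))
  expect_false(cl$degenerate)
})

test_that("two identical maps are handled as a degenerate pool", {
  pat <- cobci:::p3_scalp_pattern()
  maps <- list(fake_map("a", pat), fake_map("b", pat))
  cl <- cluster_p3_maps(maps)
  expect_true(cl$degenerate)
  expect_setequal(cl$strong_ids, c("a", "b"))
  expect_length(cl$weak_ids, 0)
})

test_that("K-means matches the brute-force best two-partition on small pools", {
  # exhaustive oracle: all 2-partitions of <= 10 maps by within-cluster SS
  brute_best <- function(x) {
    n <- nrow(x)
    best <- NULL; best_ss <- Inf
    for (mask in 1:(2^(n - 1) - 1)) {
      g <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
      if (!any(g) || all(g)) next
      ss <- 0
      for (part in list(x[g, , drop = FALSE], x[!g, , drop = FALSE]))
        ss <- ss + sum(scale(part, scale = FALSE)^2)
      if (ss < best_ss - 1e-10) { best_ss <- ss; best <- g }
    }
    best
  }
  set.seed(14)
  pat <- cobci:::p3_scalp_pattern()
  for (trial in 1:3) {
    amps <- sample(c(2, 3, 8, 9), 8, replace = TRUE)
    maps <- lapply(seq_along(amps), function(i)
      fake_map(paste0("s", i), amps[i] * pat + rnorm(16, sd = 0.4)))
    x <- t(vapply(maps, function(m) m$topography, numeric(16)))
    g <- brute_best(x)
    cl <- cluster_p3_maps(maps, seed = trial)
    km_strong <- paste0("s", which(g))
    same <- setequal(cl$strong_ids, km_strong) ||
      setequal(cl$weak_ids, km_strong)
    expect_true(same)
  }
})

test_that("clustering is invariant under a consistent channel permutation", {
  set.seed(15)
  pat <- cobci:::p3_scalp_pattern()
  amps <- c(9, 8.5, 9.2, 3, 2.8, 3.3)
  maps <- lapply(seq_along(amps), function(i)
    fake_map(paste0("s", i), amps[i] * pat + rnorm(16, sd = 0.2)))
  perm <- sample(16)
  pmaps <- lapply(maps, function(m) {
    m$topography <- m$topography[perm]
    m
  })
  a <- cluster_p3_maps(maps, seed = 3)
  b <- cluster_p3_maps(pmaps, seed = 3)
  expect_setequal(a$strong_ids, b$strong_ids)
})

test_that("strength ordering is total, posterior-weighted and id-tied", {
  pat <- cobci:::p3_scalp_pattern()
  maps <- list(fake_map("b", 3 * pat), fake_map("a", 3 * pat),
               fake_map("c", 9 * pat))
  expect_identical(order_by_p3_strength(maps), c("c", "a", "b"))
  expect_gt(p3_strength(maps[[3]]), p3_strength(maps[[1]]))
})

test_that("source-domain pooling keeps valid labeled trials in order", {
  a1 <- make_aligned(6, subject_id = "s1", seed = 21)
  a2 <- make_aligned(4, subject_id = "s2", seed = 22)
  a2$validity[2] <- FALSE
  sd_ <- build_source_domain(list(a1, a2), c("s1", "s2"))
  expect_equal(dim(sd_$trials)[1], 6 + 3)
  expect_identical(sd_$subject, c(rep("s1", 6), rep("s2", 3)))
  expect_identical(sd_$labels,
                   c(a1$labels, a2$labels[a2$validity]))
  # selection order defines pooling order
  sd2 <- build_source_domain(list(a1, a2), c("s2", "s1"))
  expect_identical(sd2$subject, c(rep("s2", 3), rep("s1", 6)))
  expect_error(build_source_domain(list(a1, a2), character(0)), "empty")
  expect_error(build_source_domain(list(a1, a2), "nope"), "not in pool")
})
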