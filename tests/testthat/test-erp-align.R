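# Independent oracle: generalized eigenproblem solved directly (non-symmetric
# route), trace-normalized covariances as in the implementation.
oracle_csp <- function(tt, nt, lambda = 1e-6) {
  ct <- cobci:::class_covariance(tt, lambda)
  cn <- cobci:::class_covariance(nt, lambda)
  e <- eigen(solve(ct + cn) %*% ct)
  w <- Re(e$vectors[, which.max(Re(e$values))])
  w / sqrt(sum(w^2))
}

cosine <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

planted_problem <- function(seed, n = 30, nch = 16, ns = 150, boost = 6) {
  set.seed(seed)
  dir <- rnorm(nch); dir <- dir / sqrt(sum(dir^2))
  nt <- array(rnorm(n * nch * ns), c(n, nch, ns))
  tt <- array(rnorm(n * nch * ns), c(n, nch, ns))
  for (i in seq_len(n)) {
    s <- rnorm(ns, sd = boost)
    tt[i, , ] <- tt[i, , ] + dir %o% s   # extra variance along dir
  }
  list(tt = tt, nt = nt, dir = dir)
}

test_that("CSP recovers a planted discriminative direction", {
  pb <- planted_problem(1)
  sf <- fit_csp(pb$tt, pb$nt)
  expect_equal(sqrt(sum(sf$weights^2)), 1, tolerance = 1e-12)
  expect_gt(cosine(sf$weights, pb$dir), 0.95)
  expect_gt(cosine(sf$weights, oracle_csp(pb$tt, pb$nt)), 0.999)
})

test_that("swapping class roles returns the opposite-extreme filter", {
  pb <- planted_problem(2)
  fwd <- fit_csp(pb$tt, pb$nt)
  swp <- fit_csp(pb$nt, pb$tt)
  # oracle on the swapped problem: minimal-variance direction for pb$tt
  ct <- cobci:::class_covariance(pb$nt, 1e-6)
  cn <- cobci:::class_covariance(pb$tt, 1e-6)
  e <- eigen(solve(ct + cn) %*% ct)
  w_or <- Re(e$vectors[, which.max(Re(e$values))])
  expect_gt(cosine(swp$weights, w_or), 0.999)
  # and it is (near) orthogonal to the planted direction
  expect_lt(cosine(swp$weights, pb$dir), 0.3)
  expect_gt(cosine(fwd$weights, pb$dir), 0.95)
})

test_that("identical class covariances still give a deterministic filter", {
  set.seed(3)
  x <- array(rnorm(20 * 16 * 150), c(20, 16, 150))
  a <- fit_csp(x, x)
  b <- fit_csp(x, x)
  expect_identical(a$weights, b$weights)
  expect_equal(sqrt(sum(a$weights^2)), 1, tolerance = 1e-12)
})

test_that("template averaging, cropping and degenerate inputs behave", {
  set.seed(4)
  nch <- 16; ns <- 150
  w <- rnorm(nch); w <- w / sqrt(sum(w^2))
  sf <- structure(list(weights = w, eigenvalue = 1),
                  class = "spatial_filter")
  # identical trials: template equals the cropped projection of one trial
  one <- matrix(rnorm(nch * ns), nch, ns)
  trials <- array(NA_real_, c(5, nch, ns))
  for (i in 1:5) trials[i, , ] <- one
  tpl <- build_template(sf, trials)
  expect_length(tpl$series, 100)
  p <- drop(crossprod(w, one))
  expect_equal(tpl$series, p[(tpl$crop_start + 1):(tpl$crop_start + 100)])
  # planted bump at 500 ms: template peak within +/- 20 ms of 500 - crop
  bump_tr <- array(rnorm(8 * nch * ns, sd = 0.01), c(8, nch, ns))
  bump <- 5 * sin(pi * seq(0, 1, length.out = 21))
  for (i in 1:8) bump_tr[i, , 41:61] <- bump_tr[i, , 41:61] + w %o% bump
  tpl2 <- build_template(sf, bump_tr)
  peak <- which.max(tpl2$series)
  expect_lt(abs((peak + tpl2$crop_start) - 51), 2.5)
  # zero signal: flat template
  tpl3 <- build_template(sf, array(0, c(3, nch, ns)))
  expect_true(all(abs(tpl3$series) < 1e-12))
})

test_that("alignment finds exact embeddings and breaks ties low", {
  set.seed(5)
  nch <- 16
  w <- rnorm(nch); w <- w / sqrt(sum(w^2))
  sf <- structure(list(weights = w, eigenvalue = 1),
                  class = "spatial_filter")
  series <- rnorm(100)
  tpl <- structure(list(series = series, filter = sf, crop_start = 0L),
                   class = "erp_template")
  # trial that embeds the template (as a rank-1 spatial pattern) at offset 20
  ts <- make_trial_set(n = 2, nch = nch, ns = 150, seed = 6)
  ts$trials[1, , ] <- 0
  ts$trials[1, , 21:120] <- w %o% series
  ts$trials[2, , ] <- 0                     # flat trial: tie -> offset 0
  al <- align_trials(ts, tpl)
  expect_equal(al$offsets, c(20L, 0L))
  expect_equal(dim(al$trials), c(2, nch, 100))
  expect_equal(al$trials[1, , ], ts$trials[1, , 21:120])
})

test_that("alignment is idempotent on re-padded aligned signal trials", {
  set.seed(7)
  nch <- 16
  w <- rnorm(nch); w <- w / sqrt(sum(w^2))
  sf <- structure(list(weights = w, eigenvalue = 1),
                  class = "spatial_filter")
  series <- 4 * sin(pi * seq(0, 1, length.out = 100))^2 * rnorm(100, 1, 0.2)
  tpl <- structure(list(series = series, filter = sf, crop_start = 0L),
                   class = "erp_template")
  # trials carrying the template pattern at known offsets, plus weak noise
  ts <- make_trial_set(n = 4, nch = nch, ns = 150, seed = 9)
  ts$trials <- ts$trials * 0.05
  offs <- c(5L, 20L, 35L, 50L)
  for (i in 1:4)
    ts$trials[i, , (offs[i] + 1):(offs[i] + 100)] <-
      ts$trials[i, , (offs[i] + 1):(offs[i] + 100)] + w %o% series
  al <- align_trials(ts, tpl)
  expect_equal(al$offsets, offs)
  # pad aligned trials back into a 150 frame at offset 25 and realign
  ts2 <- ts
  ts2$trials[] <- 0
  for (i in 1:4) ts2$trials[i, , 26:125] <- al$trials[i, , ]
  al2 <- align_trials(ts2, tpl)
  expect_true(all(al2$offsets == 25L))
  expect_equal(al2$trials, al$trials)
})
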