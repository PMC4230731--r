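fs <- 256
tt <- seq(1 / fs, 20, by = 1 / fs)
mid <- 1500:3500   # away from filter edge transients

test_that("preprocessing passes the band and kills line noise and DC", {
  rec <- channel_recording(rbind(sin(2 * pi * 10 * tt),
                                 sin(2 * pi * 50 * tt),
                                 rep(3, length(tt))), fs)
  pp <- preprocess_recording(rec)
  expect_gt(max(abs(pp$data[1, mid])), 0.98)   # 10 Hz within 2%
  expect_lt(max(abs(pp$data[2, mid])), 0.05)   # 50 Hz cut by >= 95%
  expect_lt(max(abs(pp$data[3, mid])), 1e-6)   # constant channel zeroed
  expect_error(preprocess_recording(channel_recording(matrix(rnorm(200),
                                                             2), 100)),
               "Nyquist")
})

test_that("band splitting keeps in-band and rejects out-of-band content", {
  rec <- channel_recording(rbind(sin(2 * pi * 4.5 * tt),
                                 sin(2 * pi * 4.5 * tt)), fs)
  bs <- band_split(rec, c("theta", "low_alpha"))
  expect_gt(max(abs(bs$theta$data[1, mid])), 0.95)
  expect_lt(max(abs(bs$low_alpha$data[1, mid])), 0.1)
  expect_identical(bs$theta$band, "theta")
  bad <- data.frame(name = "x", lo = 10, hi = 10)
  expect_error(band_split(rec, bad), "invalid band")
  ## Parseval-style check: band variances tile the broadband variance
  set.seed(8)
  wn <- channel_recording(matrix(rnorm(2 * length(tt)), 2), fs)
  broad <- preprocess_recording(wn, notch = NULL)
  bands <- band_split(broad)
  v_broad <- mean(apply(broad$data[, mid], 1, var))
  v_bands <- sum(vapply(bands, function(b)
    mean(apply(b$data[, mid], 1, var)), numeric(1)))
  expect_lt(abs(v_bands - v_broad) / v_broad, 0.15)
})

test_that("lagged cross-correlation recovers shifts with the stated
           conventions", {
  set.seed(4)
  x <- rnorm(2000)
  y <- c(rep(0, 5), head(x, -5))          # y lags x by 5 samples
  cc <- lagged_crosscorr(x, y, 20)
  expect_identical(cc$best_lag, 5L)        # positive: first series leads
  expect_gt(cc$corr, 0.99)
  self <- lagged_crosscorr(x, x, 20)
  expect_identical(self$best_lag, 0L)
  expect_equal(self$corr, 1)
  expect_true(all(abs(cc$by_lag) <= 1 + 1e-12))
  ## independent long series: the max over 103 lags stays small
  a <- rnorm(5120); b <- rnorm(5120)
  expect_lt(abs(lagged_crosscorr(a, b, 51)$corr), 0.1)
  expect_error(lagged_crosscorr(rep(1, 100), rnorm(100), 10),
               "zero-variance")
  expect_error(lagged_crosscorr(rnorm(30), rnorm(30), 20), "too short")
})

test_that("IAAFT surrogates keep the value multiset and the spectrum", {
  set.seed(2)
  ar <- as.numeric(stats::filter(rnorm(5120), 0.95, "recursive"))
  s <- iaaft_surrogate(ar, n_iter = 100, seed = 9)
  expect_identical(sort(s), sort(ar))
  rel_err <- sqrt(sum((Mod(fft(s)) - Mod(fft(ar)))^2) /
                    sum(Mod(fft(ar))^2))
  expect_lt(rel_err, 0.01)
  expect_identical(s, iaaft_surrogate(ar, n_iter = 100, seed = 9))
  expect_false(identical(s, iaaft_surrogate(ar, n_iter = 100, seed = 10)))
  expect_error(iaaft_surrogate(ar, n_iter = 0, seed = 1), "n_iter")
  expect_error(iaaft_surrogate(rnorm(8), seed = 1), "length")
  ## surrogating both members of a strongly cross-correlated pair
  ## destroys the cross-correlation
  y <- 0.9 * c(rep(0, 7), head(ar, -7)) + 0.4 * rnorm(5120)
  orig <- abs(lagged_crosscorr(ar, y, 20)$corr)
  surr <- abs(lagged_crosscorr(iaaft_surrogate(ar, seed = 3),
                               iaaft_surrogate(y, seed = 4), 20)$corr)
  expect_gt(orig, 0.8)
  expect_lt(surr, orig / 2)
})

test_that("directionalization applies the lag-sign rule and drops
           zero lags", {
  corr <- matrix(c(1, 0.8, 0.7, 0.8, 1, 0.6, 0.7, 0.6, 1), 3)
  lag <- rbind(c(0L, 4L, 0L),     # 1 leads 2 by 4; zero lag with 3
               c(-4L, 0L, -2L),   # 3 leads 2 by 2
               c(0L, 2L, 0L))
  mask <- matrix(TRUE, 3, 3); diag(mask) <- FALSE
  net <- directionalize(fake_lcm(corr, lag), mask)
  ## pair (1,2): lag 4 > 0, channel 1 leads -> edge 1 -> 2
  expect_equal(net$weights[2, 1], 0.8)
  expect_equal(net$weights[1, 2], 0)
  ## pair (2,3): lag -2, channel 3 leads -> edge 3 -> 2
  expect_equal(net$weights[2, 3], 0.6)
  ## pair (1,3): zero lag -> removed
  expect_equal(net$weights[1, 3] + net$weights[3, 1], 0)
  expect_identical(net$provenance$n_zero_lag_removed, 1L)
  ## antisymmetry: never both directions
  expect_true(all(net$weights * t(net$weights) == 0))
})

test_that("indirect pruning follows the bottleneck rule and is idempotent", {
  mk <- function(edges, n = 4) {
    W <- matrix(0, n, n)
    for (e in edges) W[e[2], e[1]] <- e[3]
    structure(list(weights = W, labels = paste0("Ch", 1:n), band = NULL,
                   provenance = list()),
              class = "directed_functional_network")
  }
  ## a->b 0.5 weaker than path a->c->b with bottleneck 0.7: removed
  n1 <- prune_indirect(mk(list(c(1, 2, 0.5), c(1, 3, 0.8), c(3, 2, 0.7))))
  expect_equal(n1$weights[2, 1], 0)
  expect_equal(n1$provenance$n_pruned_first, 1L)
  ## direct edge strongest: untouched
  n2 <- prune_indirect(mk(list(c(1, 2, 0.9), c(1, 3, 0.8), c(3, 2, 0.7))))
  expect_equal(n2$weights[2, 1], 0.9)
  expect_equal(sum(n2$weights > 0), 3)
  ## chain a->b->c->d of 0.9 plus weak direct a->d: second-order removal
  n3 <- prune_indirect(mk(list(c(1, 2, 0.9), c(2, 3, 0.9), c(3, 4, 0.9),
                               c(1, 4, 0.3))))
  expect_equal(n3$weights[4, 1], 0)
  expect_equal(n3$provenance$n_pruned_second, 1L)
  ## idempotent and never edge-increasing on random networks
  set.seed(5)
  for (i in 1:10) {
    W <- matrix(runif(36) * (runif(36) < 0.3), 6, 6); diag(W) <- 0
    W[upper.tri(W) & t(W) > 0] <- 0   # keep one direction per pair
    nw <- mk(list(), 6); nw$weights <- W
    p1 <- prune_indirect(nw)
    p2 <- prune_indirect(p1)
    expect_lte(sum(p1$weights > 0), sum(W > 0))
    expect_equal(p2$weights, p1$weights)
  }
})

test_that("inference pipeline is deterministic, label-preserving and
           rejects duplicate-channel pairs", {
  truth <- make_lagged_truth(n_channels = 4, n_edges = 1, fs = 128,
                             duration = 6, seed = 31)
  rec <- gen_lagged_recording(truth, seed = 32)
  cfg <- inference_config(n_surrogates = 19, alpha = 0.05)
  n1 <- infer_functional_network(rec, config = cfg, seed = 33)
  n2 <- infer_functional_network(rec, config = cfg, seed = 33)
  expect_identical(n1$weights, n2$weights)
  expect_identical(rownames(n1$weights), rec$labels)
  ## the planted edge comes out with the right direction
  e <- which(truth$true_adjacency > 0, arr.ind = TRUE)
  expect_gt(n1$weights[e[1], e[2]], 0)
  ## duplicated channel: perfect zero-lag correlation must not survive
  dup <- channel_recording(rbind(rec$data[1, ], rec$data[1, ],
                                 rec$data[2, ]), rec$fs,
                           labels = c("a", "b", "c"))
  nd <- infer_functional_network(dup, config = cfg, seed = 34)
  expect_equal(nd$weights["a", "b"] + nd$weights["b", "a"], 0)
  expect_gte(nd$provenance$n_zero_lag_removed, 1L)
})

test_that("recording CSV round-trips with labels and sampling rate", {
  rec <- channel_recording(matrix(rnorm(3 * 50), 3), 100,
                           labels = c("F7", "Fp1", "O2"))
  f <- tempfile(fileext = ".csv")
  write_recording_csv(rec, f)
  back <- read_recording_csv(f)
  expect_equal(back$fs, 100, tolerance = 1e-6)
  expect_identical(back$labels, rec$labels)
  expect_equal(back$data, rec$data, tolerance = 1e-6,
               ignore_attr = TRUE)
  unlink(f)
})
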