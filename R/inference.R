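#' Multichannel recording container
#'
#' @param data channels x samples numeric matrix.
#' @param fs sampling rate in Hz.
#' @param labels channel names; defaults to the 19-channel 10-20 montage
#'   when the recording has 19 channels, else `Ch1, Ch2, ...`.
#' @param band optional band label attached by [band_split()].
#' @return object of class `channel_recording`.
#' @export
channel_recording <- function(data, fs, labels = NULL, band = NULL) {
  data <- as.matrix(data)
  if (nrow(data) < 2) stop("need at least 2 channels", call. = FALSE)
  if (any(!is.finite(data))) stop("data contains non-finite values",
                                  call. = FALSE)
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive", call. = FALSE)
  if (is.null(labels))
    labels <- if (nrow(data) == 19) montage_1020
              else paste0("Ch", seq_len(nrow(data)))
  stopifnot(length(labels) == nrow(data))
  rownames(data) <- labels
  structure(list(labels = labels, fs = fs, data = data, band = band),
            class = "channel_recording")
}

#' @export
print.channel_recording <- function(x, ...) {
  cat(sprintf("Recording: %d channels x %d samples @ %g Hz (%.1f s)%s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              if (is.null(x$band)) "" else paste0(", band ", x$band)))
  invisible(x)
}

#' Read / write a multichannel recording as CSV
#'
#' CSV layout: one column per channel (header row = channel labels), one
#' row per sample; an optional leading `time` column is dropped on read.
#'
#' @param path CSV path.
#' @param fs sampling rate in Hz (required on read unless a `time` column
#'   is present, in which case it is inferred from the sample spacing).
#' @export
read_recording_csv <- function(path, fs = NULL) {
  d <- read.csv(path, check.names = FALSE)
  if (tolower(names(d)[1]) == "time") {
    if (is.null(fs)) fs <- 1 / mean(diff(d[[1]]))
    d <- d[, -1, drop = FALSE]
  }
  if (is.null(fs)) stop("fs must be given when no time column is present",
                        call. = FALSE)
  channel_recording(t(as.matrix(d)), fs = fs, labels = names(d))
}

#' @rdname read_recording_csv
#' @param rec a `channel_recording`.
#' @export
write_recording_csv <- function(rec, path) {
  d <- data.frame(time = seq_len(ncol(rec$data)) / rec$fs,
                  t(rec$data), check.names = FALSE)
  names(d) <- c("time", rec$labels)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Default EEG frequency bands
#'
#' The band table used to split recordings before network inference:
#' delta 1-3, theta 3-6, low alpha 6-9, high alpha 9-12, beta 12-25,
#' gamma 25-70 Hz.
#'
#' @return data.frame with columns `name`, `lo`, `hi` (Hz).
#' @export
eeg_bands <- function() {
  data.frame(name = c("delta", "theta", "low_alpha", "high_alpha",
                      "beta", "gamma"),
             lo = c(1, 3, 6, 9, 12, 25),
             hi = c(3, 6, 9, 12, 25, 70))
}

## zero-phase Butterworth filtering (forward-backward, so no phase
## distortion that would corrupt lag estimates)
zp_filter <- function(data, filt) {
  t(apply(data, 1, function(x) signal::filtfilt(filt, x)))
}

#' Preprocess a recording
#'
#' Per-channel demeaning, zero-phase band-pass (default 1-70 Hz) and
#' zero-phase band-stop notch (default 48-52 Hz, power-line interference).
#' All filters are 4th-order Butterworth applied forward-backward.
#'
#' @param rec a [channel_recording()].
#' @param lo,hi band-pass edges in Hz.
#' @param notch length-2 vector of band-stop edges in Hz, or `NULL` to
#'   skip the notch.
#' @param order Butterworth order; default 4.
#' @return filtered `channel_recording`.
#' @export
preprocess_recording <- function(rec, lo = 1, hi = 70, notch = c(48, 52),
                                 order = 4) {
  stopifnot(inherits(rec, "channel_recording"))
  if (rec$fs <= 2 * hi)
    stop(sprintf(paste0("sampling rate %g Hz violates the Nyquist ",
                        "constraint fs > 2 * %g Hz"), rec$fs, hi),
         call. = FALSE)
  x <- rec$data - rowMeans(rec$data)
  bp <- signal::butter(order, c(lo, hi) / (rec$fs / 2), type = "pass")
  x <- zp_filter(x, bp)
  if (!is.null(notch)) {
    bs <- signal::butter(order, notch / (rec$fs / 2), type = "stop")
    x <- zp_filter(x, bs)
  }
  channel_recording(x, rec$fs, rec$labels, rec$band)
}

#' Split a recording into frequency bands
#'
#' @param rec a [channel_recording()].
#' @param bands a data.frame with columns `name`, `lo`, `hi` (see
#'   [eeg_bands()]), or a character vector of band names resolved against
#'   the default table.
#' @param order Butterworth order; default 4 (zero-phase).
#' @return named list of band-filtered `channel_recording`s.
#' @export
band_split <- function(rec, bands = eeg_bands(), order = 4) {
  stopifnot(inherits(rec, "channel_recording"))
  if (is.character(bands)) {
    tab <- eeg_bands()
    miss <- setdiff(bands, tab$name)
    if (length(miss)) stop("unknown band(s): ", paste(miss, collapse = ", "),
                           call. = FALSE)
    bands <- tab[match(bands, tab$name), ]
  }
  out <- list()
  for (i in seq_len(nrow(bands))) {
    lo <- bands$lo[i]; hi <- bands$hi[i]
    if (!(0 < lo && lo < hi && hi <= rec$fs / 2))
      stop(sprintf("invalid band [%g, %g] Hz for fs = %g", lo, hi, rec$fs),
           call. = FALSE)
    bp <- signal::butter(order, c(lo, hi) / (rec$fs / 2), type = "pass")
    out[[bands$name[i]]] <- channel_recording(zp_filter(rec$data, bp),
                                              rec$fs, rec$labels,
                                              band = bands$name[i])
  }
  out
}

#' Maximum time-lagged cross-correlation of two series
#'
#' Pearson-normalized cross-correlation of the overlapping segments over
#' lags `-max_lag .. max_lag` (every lag's value lies in `[-1, 1]`);
#' returns the maximum of the absolute value and the lag attaining it.
#' Lag-sign convention: `best_lag > 0` means the first series leads (and
#' is assigned the source role downstream). Ties in `|corr|` are broken
#' toward the smallest `|lag|`, then toward the negative lag.
#'
#' @param x,y numeric series of equal length `> 2 * max_lag`.
#' @param max_lag maximum lag in samples.
#' @return list with `corr` (value at the best lag, signed), `best_lag`,
#'   and `by_lag` (full correlogram, names = lags).
#' @export
lagged_crosscorr <- function(x, y, max_lag) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  if (length(x) <= 2 * max_lag)
    stop("series too short for the requested max_lag", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: zero-variance series", call. = FALSE)
  cc <- .crosscorr_lags(x, y, as.integer(max_lag))
  lags <- seq(-max_lag, max_lag)
  names(cc) <- lags
  ## order candidate lags by (|lag|, lag) so that which.max's first-hit
  ## rule implements the tie-break: smallest |lag| first, negative before
  ## positive at equal |lag|
  ord <- order(abs(lags), lags)
  best <- ord[which.max(abs(cc[ord]))]
  list(corr = cc[[best]], best_lag = lags[best], by_lag = cc)
}

#' All-pairs lagged correlation matrix of a recording
#'
#' @param rec a [channel_recording()].
#' @param max_lag maximum lag in samples.
#' @return object of class `lagged_correlation_matrix`: `corr` (symmetric,
#'   `|corr| <= 1`, unit diagonal; entries are max-over-lags absolute
#'   correlations, signed by the value at the best lag), `lag`
#'   (antisymmetric integer matrix; `lag[i, j] > 0` means channel `i`
#'   leads channel `j`), `max_lag`, `labels`.
#' @export
lagged_corr_matrix <- function(rec, max_lag) {
  stopifnot(inherits(rec, "channel_recording"))
  n <- nrow(rec$data)
  corr <- diag(1, n)
  lag <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cc <- lagged_crosscorr(rec$data[i, ], rec$data[j, ], max_lag)
    corr[i, j] <- corr[j, i] <- cc$corr
    lag[i, j] <- cc$best_lag
    lag[j, i] <- -cc$best_lag
  }
  dimnames(corr) <- dimnames(lag) <- list(rec$labels, rec$labels)
  structure(list(corr = corr, lag = lag, max_lag = as.integer(max_lag),
                 labels = rec$labels),
            class = "lagged_correlation_matrix")
}

#' IAAFT surrogate of a time series
#'
#' Iterative amplitude-adjusted Fourier transform surrogate: alternates
#' between imposing the original amplitude spectrum (keeping the current
#' phases) and restoring the original value multiset by rank remapping.
#' The iteration stops early when the rank ordering stabilizes (further
#' iterations would be no-ops). The output always ends with the rank
#' remap, so its value multiset equals the original's exactly, while its
#' power spectrum approximates the original's; pairwise cross-correlation
#' between independently surrogated channels is destroyed.
#'
#' @param x numeric series, length >= 16.
#' @param n_iter maximum number of iterations; default 100.
#' @param seed integer seed for the initial random permutation.
#' @return numeric surrogate series of the same length.
#' @export
iaaft_surrogate <- function(x, n_iter = 100, seed = 1) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 16) stop("series too short for IAAFT (need length >= 16)",
                   call. = FALSE)
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  amp <- Mod(fft(x))
  sx <- sort(x)
  s <- local_seed(seed, sample(x))
  rk_prev <- NULL
  for (it in seq_len(n_iter)) {
    ph <- fft(s)
    mod <- Mod(ph)
    mod[mod == 0] <- 1
    s2 <- Re(fft(amp * ph / mod, inverse = TRUE)) / n
    rk <- rank(s2, ties.method = "first")
    s <- sx[rk]
    if (!is.null(rk_prev) && identical(rk, rk_prev)) break
    rk_prev <- rk
  }
  s
}

#' Surrogate-based significance mask for a correlation matrix
#'
#' For each channel pair, builds the null distribution of the
#' max-over-lags absolute lagged correlation from an ensemble of IAAFT
#' surrogate pairs (surrogate `k` of channel `i` against surrogate `k` of
#' channel `j`), which preserves each channel's autocorrelation while
#' destroying genuine cross-correlation. A pair is kept iff its observed
#' statistic exceeds the empirical `(1 - alpha)` level of the surrogate
#' ensemble, i.e. iff the rank-test p-value
#' `(1 + #{surrogate >= observed}) / (n_surrogates + 1)` is `<= alpha`.
#'
#' @param lcm a [lagged_corr_matrix()] of the recording.
#' @param rec the `channel_recording` the matrix was computed from.
#' @param n_surrogates surrogate ensemble size; default 99. For a level
#'   `alpha` the rank test needs `n_surrogates >= 1 / alpha - 1`.
#' @param alpha significance level; default 0.01.
#' @param seed integer seed.
#' @param n_iter IAAFT iterations; default 100.
#' @return symmetric logical matrix (diagonal `FALSE`).
#' @export
significance_mask <- function(lcm, rec, n_surrogates = 99, alpha = 0.01,
                              seed = 1, n_iter = 100) {
  stopifnot(inherits(lcm, "lagged_correlation_matrix"),
            inherits(rec, "channel_recording"))
  if (n_surrogates < 1 / alpha - 1)
    stop(sprintf("need at least %d surrogates for alpha = %g",
                 ceiling(1 / alpha - 1), alpha), call. = FALSE)
  n <- nrow(rec$data)
  ## one surrogate ensemble per channel, paired by index across channels
  surr <- vector("list", n)
  for (i in seq_len(n)) {
    surr[[i]] <- lapply(seq_len(n_surrogates), function(k)
      iaaft_surrogate(rec$data[i, ], n_iter = n_iter,
                      seed = seed + 7919L * i + k))
  }
  keep <- matrix(FALSE, n, n, dimnames = list(rec$labels, rec$labels))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    obs <- abs(lcm$corr[i, j])
    null_stats <- vapply(seq_len(n_surrogates), function(k) {
      cc <- .crosscorr_lags(surr[[i]][[k]], surr[[j]][[k]], lcm$max_lag)
      max(abs(cc))
    }, numeric(1))
    p <- (1 + sum(null_stats >= obs)) / (n_surrogates + 1)
    keep[i, j] <- keep[j, i] <- p <= alpha
  }
  keep
}

#' Directionalize a masked correlation matrix
#'
#' Each retained undirected pair becomes a single directed edge: the
#' channel that leads (positive best lag under the [lagged_crosscorr()]
#' convention) is the source. Pairs whose best lag is exactly zero are
#' removed entirely - an instantaneous correlation is the signature of
#' volume conduction from a common source, not of a directed interaction.
#'
#' @param lcm a `lagged_correlation_matrix`.
#' @param mask symmetric logical matrix from [significance_mask()].
#' @return object of class `directed_functional_network`: `weights`
#'   (non-negative, row = receiver, zero diagonal, at most one direction
#'   per pair), `labels`, `band`, `provenance`.
#' @export
directionalize <- function(lcm, mask) {
  n <- nrow(lcm$corr)
  stopifnot(identical(dim(mask), dim(lcm$corr)))
  W <- matrix(0, n, n, dimnames = list(lcm$labels, lcm$labels))
  zero_lag_dropped <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!mask[i, j]) next
    l <- lcm$lag[i, j]
    w <- abs(lcm$corr[i, j])
    if (l == 0) { zero_lag_dropped <- zero_lag_dropped + 1L; next }
    if (l > 0) W[j, i] <- w else W[i, j] <- w  # leader drives
  }
  structure(list(weights = W, labels = lcm$labels, band = NULL,
                 provenance = list(n_pairs = n * (n - 1) / 2,
                                   n_significant = sum(mask[upper.tri(mask)]),
                                   n_zero_lag_removed = zero_lag_dropped,
                                   n_directed = sum(W > 0))),
            class = "directed_functional_network")
}

#' @export
print.directed_functional_network <- function(x, ...) {
  cat(sprintf("Directed functional network: %d channels, %d edges%s\n",
              length(x$labels), sum(x$weights > 0),
              if (is.null(x$band)) "" else paste0(" (band ", x$band, ")")))
  invisible(x)
}

#' Prune indirect connections
#'
#' Removes a direct edge `i -> j` when a stronger indirect route exists:
#' first a pass over 2-edge paths `i -> k -> j` (evaluated on the original
#' weights, removals applied together), then a pass over 3-edge paths
#' `i -> k -> l -> j` on the weights left by the first pass. Path strength
#' is the bottleneck (minimum edge weight along the path) by default; a
#' product rule is available. Pruning never adds edges and is idempotent.
#'
#' @param net a `directed_functional_network`.
#' @param path_strength `"bottleneck"` (min edge weight) or `"product"`.
#' @return pruned `directed_functional_network`; the provenance records
#'   removal counts per pass.
#' @export
prune_indirect <- function(net,
                           path_strength = c("bottleneck", "product")) {
  stopifnot(inherits(net, "directed_functional_network"))
  path_strength <- match.arg(path_strength)
  comb <- if (path_strength == "bottleneck") pmin else `*`
  W <- net$weights
  n <- nrow(W)
  ## strongest 2-edge path s -> k -> r has strength comb(W[k, s], W[r, k]);
  ## an absent edge contributes weight 0, which zeroes the path strength
  ## under both rules, so no masking is needed
  best2 <- matrix(0, n, n)
  for (k in seq_len(n))
    best2 <- pmax(best2, comb(matrix(W[k, ], n, n, byrow = TRUE),
                              matrix(W[, k], n, n)))
  drop1 <- W > 0 & best2 > W
  W1 <- W; W1[drop1] <- 0
  ## 3-edge paths s -> k -> l -> r on the weights left by the first pass
  best3 <- matrix(0, n, n)
  for (k in seq_len(n)) for (l in seq_len(n)) {
    if (W1[l, k] == 0) next     # middle edge k -> l
    p <- comb(comb(matrix(W1[k, ], n, n, byrow = TRUE), W1[l, k]),
              matrix(W1[, l], n, n))
    best3 <- pmax(best3, p)
  }
  drop2 <- W1 > 0 & best3 > W1
  W2 <- W1; W2[drop2] <- 0
  out <- net
  out$weights <- W2
  out$provenance <- c(net$provenance,
                      list(n_pruned_first = sum(drop1),
                           n_pruned_second = sum(drop2),
                           path_strength = path_strength))
  out
}

#' Inference configuration
#'
#' @param max_lag_ms maximum cross-correlation lag in milliseconds
#'   (physiological conduction delays); default 200.
#' @param n_surrogates IAAFT surrogate ensemble size; default 99.
#' @param alpha per-pair significance level of the surrogate rank test;
#'   default 0.01 (the strictest level a 99-surrogate ensemble supports;
#'   with ~170 channel pairs a 0.05 level would admit several false edges
#'   per recording, swamping sparse true structure).
#' @param iaaft_iter IAAFT iteration cap; default 100.
#' @param path_strength indirect-path strength rule; default
#'   `"bottleneck"`.
#' @return list of settings for [infer_functional_network()].
#' @export
inference_config <- function(max_lag_ms = 200, n_surrogates = 99,
                             alpha = 0.01, iaaft_iter = 100,
                             path_strength = "bottleneck") {
  list(max_lag_ms = max_lag_ms, n_surrogates = n_surrogates, alpha = alpha,
       iaaft_iter = iaaft_iter, path_strength = path_strength)
}

#' Infer a directed functional network from a recording
#'
#' Full pipeline: optional band filtering, all-pairs maximum lagged
#' cross-correlation, IAAFT surrogate significance test, lag-based
#' directionalization (zero-lag pairs removed), and indirect-edge pruning.
#' The provenance record carries the removal counts of every stage.
#'
#' @param rec a preprocessed [channel_recording()].
#' @param band `NULL` (use the recording as-is, broadband), a band name
#'   from [eeg_bands()], or a one-row band data.frame.
#' @param config see [inference_config()].
#' @param seed integer seed for the surrogate ensembles.
#' @return a `directed_functional_network`.
#' @export
infer_functional_network <- function(rec, band = NULL,
                                     config = inference_config(),
                                     seed = 1) {
  stopifnot(inherits(rec, "channel_recording"))
  if (!is.null(band)) rec <- band_split(rec, band)[[1]]
  max_lag <- max(1L, as.integer(round(config$max_lag_ms / 1000 * rec$fs)))
  lcm <- lagged_corr_matrix(rec, max_lag)
  mask <- significance_mask(lcm, rec, n_surrogates = config$n_surrogates,
                            alpha = config$alpha, seed = seed,
                            n_iter = config$iaaft_iter)
  net <- directionalize(lcm, mask)
  net$band <- rec$band
  net <- prune_indirect(net, path_strength = config$path_strength)
  net$provenance$settings <- c(config, list(max_lag = max_lag, seed = seed))
  net
}
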