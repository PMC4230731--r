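## shared fixtures for the test suite

KC_NORMAL <- sqrt(8 / pi)   # single-node critical coupling, standard normal

two_node_bi_adj <- function(w = 1) matrix(c(0, w, w, 0), 2)

## hand-built trajectory object for order-parameter unit tests
fake_trajectory <- function(phase_matrix) {
  ## phase_matrix: oscillators in columns, one row per (time, node) slice
  ## builds a 1-time, 1-node trajectory per row
  nt <- nrow(phase_matrix)
  arr <- array(phase_matrix, dim = c(nt, 1, ncol(phase_matrix)))
  structure(list(times = seq_len(nt) - 1, phases = arr,
                 natural_frequencies = matrix(0, 1, ncol(phase_matrix)),
                 seed = 0, dt = 1),
            class = "phase_trajectory")
}

## hand-built lagged correlation matrix
fake_lcm <- function(corr, lag, labels = NULL, max_lag = 10L) {
  n <- nrow(corr)
  labels <- labels %||% paste0("Ch", seq_len(n))
  dimnames(corr) <- dimnames(lag) <- list(labels, labels)
  structure(list(corr = corr, lag = lag, max_lag = as.integer(max_lag),
                 labels = labels),
            class = "lagged_correlation_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## random strongly connected weighted digraph (cycle through a random
## permutation plus extra random edges)
random_scc_adjacency <- function(n, p_extra = 0.3) {
  ord <- sample(n)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) A[ord[i %% n + 1], ord[i]] <- runif(1, 0.2, 1.5)
  extra <- matrix(runif(n * n) < p_extra, n, n)
  diag(extra) <- FALSE
  A[extra & A == 0] <- runif(sum(extra & A == 0), 0.2, 1.5)
  A
}

## random DAG adjacency (upper triangular under a random permutation)
random_dag_adjacency <- function(n, p = 0.4) {
  ord <- sample(n)
  A <- matrix(0, n, n)
  for (a in seq_len(n - 1)) for (b in (a + 1):n)
    if (runif(1) < p) A[ord[b], ord[a]] <- runif(1, 0.2, 1.5)
  A
}
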