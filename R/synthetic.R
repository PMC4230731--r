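seven_node_edges <- function(variant = c("A", "B", "C")) {
  ## Reconstructed 7-node binary motifs (source, target): variant A has a
  ## 3-cycle {2,3,5} feeding nodes 6,7 downstream while nodes 1 and 4
  ## receive nothing from the cycle; B removes the cycle-closing edge
  ## 5 -> 2 (hierarchical flow only); C reverses the 1 -> 2 edge, creating
  ## a 4-node strongly connected component {1,2,3,5} that reaches every
  ## other node. The originally published edge lists are not fully
  ## available, so these fixtures are reconstructions that satisfy the
  ## described topology.
  variant <- match.arg(variant)
  e <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(3, 5), c(5, 2),
             c(5, 6), c(6, 7))
  if (variant == "B") e <- e[!(e[, 1] == 5 & e[, 2] == 2), ]
  if (variant == "C") e[e[, 1] == 1 & e[, 2] == 2, ] <- c(2, 1)
  e
}

edges_to_adjacency <- function(edges, n, weights = 1) {
  A <- matrix(0, n, n)
  A[cbind(edges[, 2], edges[, 1])] <- weights   # row = receiver
  A
}

#' Motif network fixtures
#'
#' Named small networks used throughout: `two_node_uni` (1 -> 2),
#' `two_node_bi` (feedback pair, the smallest strongly connected
#' component), `cycle_n` (directed n-cycle), `seven_node_partial`/`seven_node_hier`/`seven_node_global`
#' (reconstructed 7-node motifs: a partially synchronizing network with a
#' 3-cycle plus downstream nodes; the same with the cycle broken; the same
#' with one edge reversed so a 4-node strongly connected component
#' {1,2,3,5} drives the whole network), `dag_random` (random hierarchical
#' network) and `scc_random` (random strongly connected network).
#'
#' @param name motif name.
#' @param params optional list: `K` intrinsic coupling (default half the
#'   single-node critical coupling), `kappa` global coupling (default 1),
#'   `N` oscillators per node (default 1000), `n` node count for
#'   `cycle_n`/random motifs (default 5 / 7), `weights` edge weight(s)
#'   (default 1), `p_edge` extra-edge probability for random motifs
#'   (default 0.3), `seed` for random motifs (default 1).
#' @return a [modular_network_spec()].
#' @export
make_motif <- function(name = c("two_node_uni", "two_node_bi", "cycle_n",
                                "seven_node_partial", "seven_node_hier", "seven_node_global",
                                "dag_random", "scc_random"),
                       params = list()) {
  name <- match.arg(name)
  K_c <- sqrt(8 / pi)
  K <- params$K %||% (0.5 * K_c)
  kappa <- params$kappa %||% 1
  N <- params$N %||% 1000
  w <- params$weights %||% 1
  A <- switch(name,
    two_node_uni = edges_to_adjacency(rbind(c(1, 2)), 2, w),
    two_node_bi = edges_to_adjacency(rbind(c(1, 2), c(2, 1)), 2, w),
    cycle_n = cycle_adjacency(params$n %||% 5, w),
    seven_node_partial = edges_to_adjacency(seven_node_edges("A"), 7, w),
    seven_node_hier = edges_to_adjacency(seven_node_edges("B"), 7, w),
    seven_node_global = edges_to_adjacency(seven_node_edges("C"), 7, w),
    dag_random = local_seed(params$seed %||% 1, {
      n <- params$n %||% 7
      p <- params$p_edge %||% 0.3
      M <- matrix(0, n, n)
      ord <- sample(n)
      for (a in seq_len(n - 1)) for (b in (a + 1):n)
        if (runif(1) < p) M[ord[b], ord[a]] <- runif(1, 0.2, 1)
      M
    }),
    scc_random = local_seed(params$seed %||% 1, {
      n <- params$n %||% 7
      p <- params$p_edge %||% 0.3
      ord <- sample(n)
      M <- cycle_adjacency(n, runif(n, 0.2, 1))
      M <- M[ord, ord]    # random Hamiltonian cycle keeps it strongly
      extra <- matrix(runif(n * n) < p, n, n)
      diag(extra) <- FALSE
      M[extra] <- runif(sum(extra), 0.2, 1)
      M
    })
  )
  modular_network_spec(A, intrinsic_couplings = K, global_coupling = kappa,
                       oscillators_per_node = N)
}

#' Ground truth for a lag-coupled synthetic recording
#'
#' Plants `n_edges` directed, lagged linear dependencies arranged as
#' disjoint chains of at most 3 edges. Chains emulate propagating
#' activity while keeping the planted structure identifiable for a
#' correlation-based inference method: fan-out from a common driver with
#' unequal lags produces inter-sibling correlations that no
#' chain-pruning rule can attribute, so the generator does not plant it.
#'
#' @param n_channels number of channels; default 19 (10-20 montage).
#' @param n_edges number of planted directed edges; default 10.
#' @param fs sampling rate in Hz; default 256.
#' @param duration recording length in seconds; default 20.
#' @param gain coupling gain of each planted edge; default 0.8.
#' @param lag_range range (samples) the distinct planted lags are drawn
#'   from; default 4 to 40 (~16-160 ms at 256 Hz).
#' @param ar_coef AR(1) coefficient of the innovation processes; default
#'   0.95 (a 1/f-like background that gives the surrogate test nontrivial
#'   autocorrelation to control for).
#' @param noise_sd measurement noise standard deviation; default 0.1
#'   (innovations have unit sd).
#' @param seed integer seed.
#' @return object of class `synthetic_ground_truth` with `true_adjacency`
#'   (gain matrix, row = receiver), `true_lags` (samples, row = receiver)
#'   and `generator_params`.
#' @export
make_lagged_truth <- function(n_channels = 19, n_edges = 10, fs = 256,
                              duration = 20, gain = 0.8,
                              lag_range = c(4, 40), ar_coef = 0.95,
                              noise_sd = 0.1, seed = 1) {
  chain_lens <- integer(0)
  rem <- n_edges
  while (rem > 0) { l <- min(3L, rem); chain_lens <- c(chain_lens, l)
                    rem <- rem - l }
  if (sum(chain_lens + 1L) > n_channels)
    stop("not enough channels for the requested number of planted edges",
         call. = FALSE)
  local_seed(seed, {
    G <- matrix(0, n_channels, n_channels)
    L <- matrix(0L, n_channels, n_channels)
    nodes <- sample(n_channels)
    lags <- sample(seq(lag_range[1], lag_range[2]), n_edges)
    pos <- 1L; e <- 1L
    for (len in chain_lens) {
      chain <- nodes[pos:(pos + len)]
      for (i in seq_len(len)) {
        src <- chain[i]; dst <- chain[i + 1]
        G[dst, src] <- gain
        L[dst, src] <- lags[e]
        e <- e + 1L
      }
      pos <- pos + len + 1L
    }
    structure(list(true_adjacency = G, true_lags = L,
                   generator_params = list(fs = fs, duration = duration,
                                           gain = gain, ar_coef = ar_coef,
                                           noise_sd = noise_sd,
                                           seed = seed)),
              class = "synthetic_ground_truth")
  })
}

## band-limited AR(1) innovation series (one per channel, columns)
ar_innovations <- function(n_channels, n_samples, ar_coef, fs) {
  e <- matrix(rnorm(n_channels * n_samples), n_samples, n_channels)
  e <- apply(e, 2, function(x) as.numeric(stats::filter(x, ar_coef,
                                                        "recursive")))
  e <- scale(e, center = TRUE, scale = TRUE)
  hi <- min(70, 0.45 * fs)
  bp <- signal::butter(4, c(1, hi) / (fs / 2), type = "pass")
  apply(e, 2, function(x) signal::filtfilt(bp, x))
}

#' Generate a lag-coupled multichannel recording
#'
#' Linear lagged-coupling process: each channel is a band-limited AR(1)
#' innovation plus the gain-weighted, lag-delayed parent channels given by
#' the ground truth, plus additive white measurement noise. Channels are
#' labelled with the 10-20 montage when there are 19 of them.
#'
#' @param truth a [make_lagged_truth()] object.
#' @param seed integer seed (a fixed seed reproduces the recording
#'   exactly).
#' @return a [channel_recording()].
#' @export
gen_lagged_recording <- function(truth, seed = 1) {
  stopifnot(inherits(truth, "synthetic_ground_truth"))
  p <- truth$generator_params
  G <- truth$true_adjacency
  L <- truth$true_lags
  rho <- max(Mod(eigen(G, only.values = TRUE)$values))
  if (rho >= 1)
    stop(sprintf("unstable generator: spectral radius %.3f >= 1", rho),
         call. = FALSE)
  n <- nrow(G)
  Tn <- as.integer(round(p$fs * p$duration))
  local_seed(seed, {
    e <- ar_innovations(n, Tn, p$ar_coef, p$fs)  # samples x channels
    x <- e
    edges <- which(G != 0, arr.ind = TRUE)
    if (nrow(edges) > 0) {
      ## process channels in dependency (topological) order so each
      ## parent series is final before its children are assembled
      gr <- igraph::graph_from_edgelist(edges[, c(2, 1), drop = FALSE])
      ord <- as.integer(igraph::topo_sort(gr, mode = "out"))
      ord <- c(ord, setdiff(seq_len(n), ord))
      for (ch in ord) {
        prnts <- which(G[ch, ] != 0)
        for (pr in prnts) {
          lag <- L[ch, pr]
          x[(lag + 1):Tn, ch] <- x[(lag + 1):Tn, ch] +
            G[ch, pr] * x[seq_len(Tn - lag), pr]
        }
      }
    }
    obs <- t(x) + matrix(rnorm(n * Tn, sd = p$noise_sd), n, Tn)
    channel_recording(obs, fs = p$fs)
  })
}

#' Generate an EEG-like recording from a Kuramoto simulation
#'
#' Simulates the modular network and emits each node's summed-sine signal
#' resampled to the requested rate; model time is interpreted as seconds.
#' Supplying `kappa_switch` splices two coupling regimes mid-run
#' (phases carry over), e.g. to emulate a background-to-seizure
#' transition when the second regime is super-critical.
#'
#' @param spec a [modular_network_spec()].
#' @param fs output sampling rate (Hz).
#' @param duration total length in seconds.
#' @param seed integer seed.
#' @param kappa_switch optional `list(at = <time s>, kappa = <value>)`.
#' @param dt integrator step; default 0.01.
#' @return a [channel_recording()] with one channel per node.
#' @export
gen_kuramoto_recording <- function(spec, fs, duration, seed = 1,
                                   kappa_switch = NULL, dt = 0.01) {
  sim_one <- function(sp, dur, init) {
    simulate_network(sp, dur, dt = dt, seed = seed, store_every = 1,
                     init_phases = init,
                     natural_frequencies = draw_natural_frequencies(spec,
                                                                    seed))
  }
  if (is.null(kappa_switch)) {
    trajs <- list(sim_one(spec, duration, NULL))
  } else {
    t1 <- kappa_switch$at
    spec2 <- spec
    spec2$global_coupling <- kappa_switch$kappa
    tr1 <- sim_one(spec, t1, NULL)
    last <- tr1$phases[dim(tr1$phases)[1], , ]
    if (is.null(dim(last))) last <- matrix(last, nrow = spec$n_nodes)
    tr2 <- sim_one(spec2, duration - t1, last)
    tr2$times <- tr2$times + t1
    trajs <- list(tr1, tr2)
  }
  times <- unlist(lapply(trajs, `[[`, "times"))
  sig <- do.call(rbind, lapply(trajs, function(tr)
    vapply(seq_len(spec$n_nodes), function(i) node_signal(tr, i),
           numeric(length(tr$times)))))
  keep <- !duplicated(times)
  times <- times[keep]
  sig <- sig[keep, , drop = FALSE]
  grid <- seq(0, duration - 1 / fs, by = 1 / fs)
  out <- vapply(seq_len(spec$n_nodes), function(i)
    approx(times, sig[, i], xout = grid, rule = 2)$y,
    numeric(length(grid)))
  channel_recording(t(out), fs = fs)
}

#' Cohort generator parameters
#'
#' @param n_nodes nodes per subject network; default 19.
#' @param p_edge probability of each forward (hierarchy-respecting) edge;
#'   default 0.165 (about 28 edges per 19-node network, sparse like
#'   pruned functional networks).
#' @param reciprocal_base probability that an edge gains a reciprocal
#'   partner in the control group; default 0.1.
#' @param reciprocal_effect additional reciprocal-edge probability per
#'   unit effect in the case group; default 0.55.
#' @param weight_range edge weights drawn uniformly from this range;
#'   default `c(0.2, 1)`.
#' @export
cohort_gen_params <- function(n_nodes = 19, p_edge = 0.165,
                              reciprocal_base = 0.1,
                              reciprocal_effect = 0.55,
                              weight_range = c(0.2, 1)) {
  list(n_nodes = n_nodes, p_edge = p_edge,
       reciprocal_base = reciprocal_base,
       reciprocal_effect = reciprocal_effect,
       weight_range = weight_range)
}

random_cohort_network <- function(p, q_recip) {
  n <- p$n_nodes
  A <- matrix(0, n, n)
  ord <- sample(n)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    if (runif(1) < p$p_edge) {
      A[ord[b], ord[a]] <- runif(1, p$weight_range[1], p$weight_range[2])
      if (runif(1) < q_recip)
        A[ord[a], ord[b]] <- runif(1, p$weight_range[1], p$weight_range[2])
    }
  }
  labs <- if (n == 19) montage_1020 else paste0("Ch", seq_len(n))
  dimnames(A) <- list(labs, labs)
  structure(list(weights = A, labels = labs, band = NULL,
                 provenance = list(synthetic = TRUE)),
            class = "directed_functional_network")
}

#' Generate a two-group cohort of synthetic functional networks
#'
#' Control networks are sparse DAG-dominant random digraphs (forward
#' edges along a random hierarchy, occasionally with a reciprocal
#' partner). Case networks come from the same generator with an extra
#' reciprocal-edge probability proportional to `effect`, which plants
#' more strongly connected components and therefore stochastically lower
#' critical global couplings. `effect = 0` makes the groups exchangeable.
#'
#' @param n_cases,n_controls group sizes (>= 2).
#' @param effect effect size in `[0, 1]`.
#' @param base_params see [cohort_gen_params()].
#' @param seed integer seed.
#' @return list with `cases`, `controls` (lists of
#'   `directed_functional_network`s) and `truth` (generator record).
#' @export
gen_cohort <- function(n_cases, n_controls, effect,
                       base_params = cohort_gen_params(), seed = 1) {
  if (n_cases < 2 || n_controls < 2)
    stop("need at least 2 subjects per group", call. = FALSE)
  if (effect < 0 || effect > 1) stop("effect must be in [0, 1]",
                                     call. = FALSE)
  p <- base_params
  q_control <- p$reciprocal_base
  q_case <- p$reciprocal_base + p$reciprocal_effect * effect
  local_seed(seed, {
    cases <- replicate(n_cases, random_cohort_network(p, q_case),
                       simplify = FALSE)
    controls <- replicate(n_controls, random_cohort_network(p, q_control),
                          simplify = FALSE)
    list(cases = cases, controls = controls,
         truth = list(params = p, effect = effect,
                      q_case = q_case, q_control = q_control, seed = seed))
  })
}
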