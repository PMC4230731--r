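#' Linearization matrix of the synchronization onset problem
#'
#' Linearizing the per-node self-consistency relation around the
#' incoherent state (all order parameters zero) gives `D r = kappa A r`
#' for the vector of small order parameters, with `D` the diagonal
#' matrix of per-node linear deficits `D_ii = K_c - K_i` (positive, hence
#' invertible, because every node is individually sub-critical). Non-zero
#' solutions first appear at `kappa = 1 / lambda_max(D^{-1} A)`, so the
#' returned matrix is `M = D^{-1} A`.
#'
#' @param adjacency square non-negative matrix, zero diagonal
#'   (`A[i, j]`: `j` drives `i`).
#' @param intrinsic_couplings per-node `K_i` (recycled if scalar); every
#'   `K_i` must be below `K_c`.
#' @param K_c critical intrinsic coupling of an isolated node (see
#'   [single_node_critical_coupling()]).
#' @return n x n numeric matrix `D^{-1} A`.
#' @export
linearization_matrix <- function(adjacency, intrinsic_couplings, K_c) {
  adjacency <- as.matrix(adjacency)
  stop_if_not_square(adjacency)
  n <- nrow(adjacency)
  K <- rep_len(as.numeric(intrinsic_couplings), n)
  if (any(K >= K_c))
    stop("all intrinsic couplings must be below K_c: a self-synchronized ",
         "node makes the linearized onset analysis inapplicable; use the ",
         "node-driven scan instead", call. = FALSE)
  adjacency / (K_c - K)   # row-wise division = D^{-1} %*% A
}

#' Critical global coupling via the eigenvalue formulation
#'
#' Computes the spectrum of the linearization matrix `D^{-1} A`. Admissible
#' eigenvalues are (numerically) real and positive; each corresponds to a
#' coupling `kappa = 1 / lambda` at which non-trivial solutions branch off
#' the incoherent state, and the critical coupling is the inverse of the
#' largest. When no admissible eigenvalue exists (e.g. the adjacency is
#' nilpotent, as for any network with purely hierarchical flow),
#' `kappa_c = Inf` and only node-driven synchronization is possible.
#'
#' @inheritParams linearization_matrix
#' @param im_tol tolerance on the imaginary part for an eigenvalue to count
#'   as real: `|Im| <= im_tol * max(1, |lambda|)`.
#' @return object of class `critical_coupling_result`: `kappa_c`,
#'   `lambda_max` (0 when none admissible), `spectrum` (complex vector),
#'   `scenario` (`"network_driven"` or `"node_driven_only"`), `scc_nodes`
#'   (strongly connected components of size >= 2).
#' @export
kappa_c_eigen <- function(adjacency, intrinsic_couplings, K_c,
                          im_tol = 1e-9) {
  M <- linearization_matrix(adjacency, intrinsic_couplings, K_c)
  ev <- eigen(M, only.values = TRUE)$values
  admissible <- abs(Im(ev)) <= im_tol * pmax(1, Mod(ev)) & Re(ev) > 1e-12
  lambda_max <- if (any(admissible)) max(Re(ev[admissible])) else 0
  ## Perron-Frobenius cross-check: for the non-negative matrix M the
  ## spectral radius is itself attained by a real non-negative eigenvalue.
  rho <- max(Mod(ev))
  if (lambda_max > 0 && rho > lambda_max * (1 + 1e-6))
    warning("largest admissible eigenvalue below the spectral radius; ",
            "non-negative linearization matrix expected Perron structure")
  structure(list(
    kappa_c = if (lambda_max > 0) 1 / lambda_max else Inf,
    lambda_max = lambda_max,
    spectrum = ev,
    scenario = if (lambda_max > 0) "network_driven" else "node_driven_only",
    scc_nodes = classify_scenario(adjacency)$scc_nodes),
    class = "critical_coupling_result")
}

#' @export
print.critical_coupling_result <- function(x, ...) {
  cat(sprintf("kappa_c = %s (%s), lambda_max = %g\n",
              format(x$kappa_c), x$scenario, x$lambda_max))
  invisible(x)
}

#' Critical global coupling via the determinant condition
#'
#' Independent route to the onset: scans `det(D - kappa A)` for a sign
#' change over a logarithmic grid of `kappa` values and bisects the first
#' crossing. Cross-validates [kappa_c_eigen()].
#'
#' @inheritParams linearization_matrix
#' @param grid_points number of log-spaced scan points; default 400.
#' @param span scan range as multiples of `K_c - max(K)`; default
#'   `c(1e-3, 1e3)`.
#' @param rel_tol relative bisection tolerance; default 1e-10.
#' @return smallest positive root, or `Inf` (with attribute
#'   `scanned_up_to`) when no sign change occurs on the scanned range.
#' @export
kappa_c_determinant <- function(adjacency, intrinsic_couplings, K_c,
                                grid_points = 400L, span = c(1e-3, 1e3),
                                rel_tol = 1e-10) {
  adjacency <- as.matrix(adjacency)
  stop_if_not_square(adjacency)
  n <- nrow(adjacency)
  K <- rep_len(as.numeric(intrinsic_couplings), n)
  if (any(K >= K_c))
    stop("all intrinsic couplings must be below K_c", call. = FALSE)
  D <- diag(K_c - K, n)
  ## normalize by the largest entry before taking the determinant: the
  ## sign is unchanged and rounding noise no longer grows like kappa^n
  ## (a nilpotent adjacency keeps a constant-sign determinant this way)
  f <- function(kap) {
    M <- D - kap * adjacency
    det(M / max(abs(M)))
  }
  scale <- K_c - max(K)
  grid <- exp(seq(log(span[1] * scale), log(span[2] * scale),
                  length.out = grid_points))
  vals <- vapply(grid, f, numeric(1))
  sgn <- sign(vals)
  flip <- which(sgn[-1] * sgn[-length(sgn)] <= 0 &
                  (sgn[-1] != 0 | sgn[-length(sgn)] != 0))
  if (length(flip) == 0) {
    out <- Inf
    attr(out, "scanned_up_to") <- max(grid)
    return(out)
  }
  lo <- grid[flip[1]]; hi <- grid[flip[1] + 1]
  flo <- f(lo)
  while ((hi - lo) > rel_tol * hi) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (sign(fm) == sign(flo) && fm != 0) {
      lo <- mid; flo <- fm
    } else hi <- mid
  }
  (lo + hi) / 2
}

#' Classify the synchronization scenario of a directed network
#'
#' Network-driven synchronization (finite critical global coupling for
#' uniformly sub-critical nodes) requires at least one cycle, i.e. a
#' strongly connected component of the positive-weight digraph with two or
#' more nodes. Networks with purely hierarchical flow (DAGs) admit only
#' node-driven synchrony.
#'
#' @param adjacency square non-negative matrix (`A[i, j]`: `j` drives `i`).
#' @return list with `scenario` (`"network_driven_possible"` or
#'   `"node_driven_only"`) and `scc_nodes` (list of integer vectors, the
#'   strongly connected components of size >= 2).
#' @export
classify_scenario <- function(adjacency) {
  adjacency <- as.matrix(adjacency)
  stop_if_not_square(adjacency)
  g <- igraph::graph_from_adjacency_matrix(t(adjacency) > 0,
                                           mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- comp$csize
  big <- which(sizes >= 2)
  scc_nodes <- lapply(big, function(ci) which(comp$membership == ci))
  list(scenario = if (length(scc_nodes) > 0) "network_driven_possible"
       else "node_driven_only",
       scc_nodes = scc_nodes)
}

#' Closed-form critical coupling of elementary motifs
#'
#' Evaluates the closed forms obtained from the determinant condition for
#' small motifs: the general two-node motif
#' `kappa_c = sqrt((K_c - K_1)(K_c - K_2) / (a_12 a_21))`, its symmetric
#' special case `kappa_c = (K_c - K) / a`, and the n-node cycle
#' `kappa_c = prod_i ((K_c - K_i) / a_i)^(1/n)` (equal to the symmetric
#' two-node value for unit weights and uniform K).
#'
#' @param motif one of `"two_node_general"`, `"two_node_symmetric"`,
#'   `"cycle_n"`.
#' @param K_c critical intrinsic coupling of an isolated node.
#' @param K intrinsic coupling(s): scalar for `two_node_symmetric`, length
#'   2 for `two_node_general`, scalar or length n for `cycle_n`. All must
#'   be below `K_c`.
#' @param weights edge weight(s): scalar `a` for `two_node_symmetric`,
#'   `c(a_12, a_21)` for `two_node_general`, scalar or length n (the cycle
#'   edges) for `cycle_n`.
#' @param n cycle length for `cycle_n`.
#' @return positive scalar, or `Inf` when a motif weight is zero (the
#'   cycle is broken and network-driven synchrony is impossible).
#' @export
motif_kappa_c <- function(motif = c("two_node_general",
                                    "two_node_symmetric", "cycle_n"),
                          K_c, K, weights = 1, n = NULL) {
  motif <- match.arg(motif)
  if (any(K >= K_c))
    stop("motif closed forms are defined only for K < K_c", call. = FALSE)
  if (motif == "two_node_general") {
    K <- rep_len(K, 2); w <- rep_len(weights, 2)
    if (any(w == 0)) return(Inf)  # uni-directional: no network-driven onset
    return(sqrt((K_c - K[1]) * (K_c - K[2]) / (w[1] * w[2])))
  }
  if (motif == "two_node_symmetric") {
    if (weights[1] == 0) return(Inf)
    return((K_c - K[1]) / weights[1])
  }
  if (is.null(n)) n <- max(length(K), length(weights))
  if (n < 2) stop("cycle needs n >= 2", call. = FALSE)
  K <- rep_len(K, n); w <- rep_len(weights, n)
  if (any(w == 0)) return(Inf)   # a removed edge breaks the cycle
  exp(mean(log((K_c - K) / w)))
}

#' Adjacency matrix of an n-cycle
#'
#' Directed cycle `1 -> 2 -> ... -> n -> 1` in the package's receiver-row
#' orientation.
#'
#' @param n number of nodes.
#' @param weights edge weights (recycled); `weights[i]` is the weight of
#'   the edge leaving node `i`.
#' @return n x n adjacency matrix.
#' @export
cycle_adjacency <- function(n, weights = 1) {
  w <- rep_len(weights, n)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) A[i %% n + 1, i] <- w[i]
  A
}
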