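#' Specification of a modular Kuramoto network
#'
#' A modular network couples `n_nodes` populations ("nodes") of `N` phase
#' oscillators each. Within a node, oscillators are all-to-all coupled with
#' intrinsic strength `K_i`; between nodes, a directed weighted adjacency
#' matrix scaled by the global coupling `kappa` lets the mean field of one
#' node drive the oscillators of another.
#'
#' @param adjacency square numeric matrix with non-negative entries and zero
#'   diagonal. Orientation: `adjacency[i, j]` is the weight with which node
#'   `j`'s mean field drives node `i` (row = receiver). All readers, writers
#'   and solvers in the package use this convention.
#' @param intrinsic_couplings numeric vector of per-node intrinsic coupling
#'   strengths `K_i >= 0`; recycled if length 1.
#' @param global_coupling non-negative scalar `kappa` scaling the inter-node
#'   coupling.
#' @param freq_mean mean of the natural-frequency distribution (`Omega`).
#'   Default 0 (co-rotating frame); order parameters are invariant to it.
#' @param freq_sd standard deviation of the natural-frequency distribution;
#'   default 1.
#' @param oscillators_per_node number of oscillators `N` per node.
#'
#' @return An object of class `modular_network_spec`.
#' @examples
#' spec <- modular_network_spec(matrix(c(0, 1, 1, 0), 2),
#'                              intrinsic_couplings = 0.8,
#'                              global_coupling = 1)
#' @export
modular_network_spec <- function(adjacency, intrinsic_couplings,
                                 global_coupling = 0, freq_mean = 0,
                                 freq_sd = 1, oscillators_per_node = 1000) {
  adjacency <- as.matrix(adjacency)
  stop_if_not_square(adjacency)
  n <- nrow(adjacency)
  K <- rep_len(as.numeric(intrinsic_couplings), n)
  if (any(!is.finite(K)) || any(K < 0))
    stop("intrinsic couplings must be finite and non-negative", call. = FALSE)
  if (!is.finite(global_coupling) || global_coupling < 0)
    stop("global_coupling must be finite and non-negative", call. = FALSE)
  if (!is.finite(freq_mean)) stop("freq_mean must be finite", call. = FALSE)
  if (!is.finite(freq_sd) || freq_sd <= 0)
    stop("freq_sd must be positive", call. = FALSE)
  N <- as.integer(oscillators_per_node)
  if (is.na(N) || N < 1)
    stop("oscillators_per_node must be a positive integer", call. = FALSE)
  structure(list(n_nodes = n, adjacency = adjacency,
                 intrinsic_couplings = K,
                 global_coupling = as.numeric(global_coupling),
                 freq_mean = as.numeric(freq_mean),
                 freq_sd = as.numeric(freq_sd),
                 oscillators_per_node = N),
            class = "modular_network_spec")
}

#' @export
print.modular_network_spec <- function(x, ...) {
  cat(sprintf("Modular Kuramoto network: %d nodes x %d oscillators\n",
              x$n_nodes, x$oscillators_per_node))
  cat(sprintf("  kappa = %g, K in [%g, %g], Omega = %g, freq sd = %g\n",
              x$global_coupling, min(x$intrinsic_couplings),
              max(x$intrinsic_couplings), x$freq_mean, x$freq_sd))
  cat(sprintf("  edges: %d (A[i,j]: j drives i)\n", sum(x$adjacency > 0)))
  invisible(x)
}

#' Read a network adjacency matrix from CSV
#'
#' Two layouts are supported: a square matrix with a header row of node
#' labels (`A[i, j]`: column node `j` drives row node `i`), or a 3-column
#' edge list `source,target,weight` (a `source -> target` edge is stored as
#' `A[target, source]`).
#'
#' @param path path to a CSV file.
#' @return a square numeric matrix with node labels as dimnames.
#' @export
read_network_csv <- function(path) {
  d <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  is_edgelist <- ncol(d) == 3 &&
    (!all(vapply(d, is.numeric, TRUE)) ||
       identical(tolower(names(d)), c("source", "target", "weight")))
  if (is_edgelist) {
    labs <- sort(unique(c(as.character(d[[1]]), as.character(d[[2]]))))
    A <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
    A[cbind(as.character(d[[2]]), as.character(d[[1]]))] <- as.numeric(d[[3]])
  } else {
    A <- as.matrix(d)
    if (nrow(A) != ncol(A)) stop("CSV matrix is not square", call. = FALSE)
    rownames(A) <- colnames(A)
    storage.mode(A) <- "double"
  }
  stop_if_not_square(A)
  A
}

#' Write a network adjacency matrix to CSV
#'
#' @param A square adjacency matrix (`A[i, j]`: `j` drives `i`).
#' @param path output path.
#' @param format `"matrix"` (square CSV with header labels) or
#'   `"edgelist"` (`source,target,weight` rows).
#' @export
write_network_csv <- function(A, path, format = c("matrix", "edgelist")) {
  format <- match.arg(format)
  labs <- colnames(A) %||% as.character(seq_len(ncol(A)))
  if (format == "matrix") {
    d <- as.data.frame(A)
    names(d) <- labs
    write.csv(d, path, row.names = FALSE)
  } else {
    idx <- which(A > 0, arr.ind = TRUE)
    d <- data.frame(source = labs[idx[, 2]], target = labs[idx[, 1]],
                    weight = A[idx])
    write.csv(d, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read simulation parameters from a JSON sidecar
#'
#' Expects fields among `intrinsic_couplings` (`K`), `global_coupling`
#' (`kappa`), `freq_mean` (`Omega`), `freq_sd`, `oscillators_per_node` (`N`).
#'
#' @param path path to a JSON file.
#' @param adjacency adjacency matrix to pair the parameters with.
#' @return a [modular_network_spec()].
#' @export
read_network_params <- function(path, adjacency) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  modular_network_spec(
    adjacency,
    intrinsic_couplings = p$intrinsic_couplings %||% p$K %||% 0,
    global_coupling = p$global_coupling %||% p$kappa %||% 0,
    freq_mean = p$freq_mean %||% p$Omega %||% 0,
    freq_sd = p$freq_sd %||% 1,
    oscillators_per_node = p$oscillators_per_node %||% p$N %||% 1000)
}
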