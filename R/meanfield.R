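#' Natural-frequency densities
#'
#' The thermodynamic-limit theory requires a symmetric unimodal density
#' `g(omega)` with mean 0. `normal_freq_density()` is the default
#' (standard deviation `sd`); `uniform_freq_density()` is a uniform density
#' on `[-sqrt(3) sd, sqrt(3) sd]` (so its standard deviation is `sd`);
#' `freq_density()` wraps an arbitrary density function, verifying symmetry
#' on a grid of sample points.
#'
#' @param sd standard deviation of the density.
#' @param g for `freq_density()`, a vectorized density function.
#' @param name label for printing.
#' @return an object of class `freq_density` with fields `g` (density
#'   function), `g0` (`g(0)`), `type` and `sd`.
#' @export
normal_freq_density <- function(sd = 1) {
  force(sd)
  structure(list(g = function(w) dnorm(w, sd = sd), g0 = dnorm(0, sd = sd),
                 type = "normal", sd = sd, support = c(-Inf, Inf)),
            class = "freq_density")
}

#' @rdname normal_freq_density
#' @export
uniform_freq_density <- function(sd = 1) {
  h <- sqrt(3) * sd
  structure(list(g = function(w) ifelse(abs(w) <= h, 1 / (2 * h), 0),
                 g0 = 1 / (2 * h), type = "uniform", sd = sd,
                 support = c(-h, h)),
            class = "freq_density")
}

#' @rdname normal_freq_density
#' @param support support interval of the density (used to place
#'   quadrature break points at its edges); default unbounded.
#' @export
freq_density <- function(g, sd = NA_real_, name = "custom",
                         support = c(-Inf, Inf)) {
  w <- seq(0.05, 4, length.out = 40)
  if (max(abs(g(w) - g(-w))) > 1e-10)
    stop("frequency density must be symmetric about 0", call. = FALSE)
  if (g(0) <= 0)
    stop("frequency density must have positive mass at 0 (no onset ",
         "otherwise)", call. = FALSE)
  tot <- integrate(g, -Inf, Inf)$value
  if (abs(tot - 1) > 1e-6)
    stop("frequency density must integrate to 1", call. = FALSE)
  structure(list(g = g, g0 = g(0), type = name, sd = sd,
                 support = support),
            class = "freq_density")
}

#' Mean-field problem for a modular Kuramoto network
#'
#' @param adjacency square non-negative matrix with zero diagonal
#'   (`A[i, j]`: node `j` drives node `i`).
#' @param intrinsic_couplings per-node `K_i >= 0` (recycled if scalar).
#' @param global_coupling `kappa >= 0`.
#' @param density a `freq_density`; default standard normal.
#' @return an object of class `mean_field_problem`.
#' @export
mean_field_problem <- function(adjacency, intrinsic_couplings,
                               global_coupling,
                               density = normal_freq_density()) {
  adjacency <- as.matrix(adjacency)
  stop_if_not_square(adjacency)
  stopifnot(inherits(density, "freq_density"))
  n <- nrow(adjacency)
  K <- rep_len(as.numeric(intrinsic_couplings), n)
  if (any(K < 0) || global_coupling < 0)
    stop("couplings must be non-negative", call. = FALSE)
  structure(list(adjacency = adjacency, intrinsic_couplings = K,
                 global_coupling = as.numeric(global_coupling),
                 density = density, n_nodes = n),
            class = "mean_field_problem")
}

#' Per-node effective locking field
#'
#' The total field strength that determines each node's locking window:
#' `X_i = K_i r_i + kappa * sum_j A[i, j] r_j`.
#'
#' @param problem a [mean_field_problem()].
#' @param node_r per-node order parameters in `[0, 1]`.
#' @return numeric vector of per-node drives.
#' @export
effective_drive <- function(problem, node_r) {
  stopifnot(inherits(problem, "mean_field_problem"))
  node_r <- as.numeric(node_r)
  if (length(node_r) != problem$n_nodes || any(node_r < 0) || any(node_r > 1))
    stop("node_r must lie in [0, 1]^n", call. = FALSE)
  as.numeric(problem$intrinsic_couplings * node_r +
               problem$global_coupling * (problem$adjacency %*% node_r))
}

## Scalar self-consistency integral r = F(X): the oscillators with
## |omega| <= X lock at phase offset asin(omega / X); the contribution is
## integral of g(omega) cos(offset) over the locking window, i.e.
## F(X) = int_{-pi/2}^{pi/2} g(X sin(phi)) X cos(phi)^2 dphi.
## For the normal density this has the Bessel-function closed form
## F(X) = (X / sd) sqrt(pi/8) e^{-u} (I0(u) + I1(u)), u = X^2 / (4 sd^2).
sc_integral <- function(X, density, method = c("auto", "bessel",
                                               "quadrature"),
                        abs_tol = 1e-10) {
  method <- match.arg(method)
  if (method == "auto")
    method <- if (density$type == "normal") "bessel" else "quadrature"
  X <- pmax(as.numeric(X), 0)
  if (method == "bessel") {
    if (density$type != "normal")
      stop("Bessel form only applies to the normal density", call. = FALSE)
    s <- density$sd
    u <- X^2 / (4 * s^2)
    out <- (X / s) * sqrt(pi / 8) * exp(-u) *
      (besselI(u, 0) + besselI(u, 1))
    ## besselI overflows for very large arguments; the limit is full locking
    big <- u > 650
    if (any(big)) {
      # use exponentially scaled Bessel functions for large drives
      out[big] <- (X[big] / s) * sqrt(pi / 8) *
        (besselI(u[big], 0, expon.scaled = TRUE) +
           besselI(u[big], 1, expon.scaled = TRUE))
    }
    out[X == 0] <- 0
    return(out)
  }
  ## quadrature in the phase variable (omega = X sin(phi)); split the
  ## integration at the density's support edges, where the integrand can
  ## be discontinuous
  edge <- abs((density$support %||% c(-Inf, Inf))[1])
  vapply(X, function(x) {
    if (x <= 0) return(0)
    pts <- c(-pi / 2, pi / 2)
    if (is.finite(edge) && edge < x)
      pts <- sort(c(pts, asin(edge / x) * c(-1, 1)))
    total <- 0
    for (k in seq_len(length(pts) - 1)) {
      q <- integrate(function(p) density$g(x * sin(p)) * x * cos(p)^2,
                     pts[k], pts[k + 1], abs.tol = abs_tol,
                     rel.tol = 1e-12, subdivisions = 500L)
      if (q$message != "OK")
        stop("quadrature failed: ", q$message, call. = FALSE)
      total <- total + q$value
    }
    total
  }, numeric(1))
}

#' One application of the self-consistency map
#'
#' Evaluates the right-hand side of the per-node self-consistency relation:
#' each node's new order parameter is the locked-population integral of the
#' frequency density against the cosine of the locked phase offsets, at the
#' node's current effective drive. For the normal density a Bessel-function
#' closed form is used; otherwise (or on request) adaptive quadrature over
#' the locking window. Both routes agree to quadrature tolerance.
#'
#' @param problem a [mean_field_problem()].
#' @param node_r current iterate in `[0, 1]^n`.
#' @param method `"auto"` (Bessel form when the density is normal),
#'   `"bessel"` or `"quadrature"`.
#' @return updated node_r vector.
#' @export
self_consistency_map <- function(problem, node_r,
                                 method = c("auto", "bessel", "quadrature")) {
  X <- effective_drive(problem, node_r)
  sc_integral(X, problem$density, method = match.arg(method))
}

#' Solve the mean-field self-consistency system
#'
#' Damped fixed-point iteration started from the all-ones vector (an upper
#' seed; the map is monotone for non-negative weights, so the iteration
#' descends onto the largest fixed point). The zero vector is always a
#' fixed point; below the critical coupling the iteration collapses onto
#' it, beyond onset it converges to the strictly positive locked branch.
#'
#' @param problem a [mean_field_problem()].
#' @param damping damping factor in (0, 1]; default 0.5.
#' @param tol residual tolerance; default 1e-10.
#' @param max_iter iteration cap; default 10000.
#' @param method passed to [self_consistency_map()].
#' @return an object of class `mean_field_solution`: `node_r`, `residual`
#'   (max self-consistency residual), `residual_history` (tail),
#'   `converged`, `branch` (`"zero"` or `"locked"`), `iterations`.
#' @export
solve_mean_field <- function(problem, damping = 0.5, tol = 1e-10,
                             max_iter = 10000L,
                             method = c("auto", "bessel", "quadrature")) {
  method <- match.arg(method)
  r <- rep(1, problem$n_nodes)
  hist <- numeric(0)
  res <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    m <- self_consistency_map(problem, r, method = method)
    res <- max(abs(m - r))
    r <- (1 - damping) * r + damping * pmin(m, 1)
    if (res <= tol) break
    if (it > max_iter - 50L) hist <- c(hist, res)
  }
  if (res > tol && res > 1e-6)
    stop(sprintf(paste0("mean-field iteration did not converge after %d ",
                        "iterations (residual %.3g); residual history: %s"),
                 it, res, paste(signif(tail(hist, 5), 3), collapse = ", ")),
         call. = FALSE)
  zero_tol <- 1e-6
  node_r <- ifelse(r < zero_tol, 0, r)
  structure(list(node_r = node_r,
                 residual = res,
                 residual_history = hist,
                 converged = res <= tol,
                 branch = if (max(node_r) > 0) "locked" else "zero",
                 iterations = it),
            class = "mean_field_solution")
}

#' Critical intrinsic coupling of an isolated node
#'
#' The smallest `K` for which the single-node self-consistency relation
#' r = F(K r) admits a non-zero solution. Two independent routes:
#' `"linearized"` evaluates the onset condition `K_c = 2 / (pi g(0))`
#' (unit slope of the linearized map); `"bisection"` bisects on `K` using a
#' nonlinear existence test (a positive crossing of `K F(X) - X` on a fine
#' grid of drive values). For the standard normal density both give
#' `sqrt(8 / pi) ~= 1.59577`.
#'
#' @param density a `freq_density`.
#' @param method `"linearized"` or `"bisection"`.
#' @param tol bisection tolerance; default 1e-10.
#' @return positive scalar `K_c`.
#' @export
single_node_critical_coupling <- function(density,
                                          method = c("linearized",
                                                     "bisection"),
                                          tol = 1e-10) {
  stopifnot(inherits(density, "freq_density"))
  method <- match.arg(method)
  if (density$g0 <= 0)
    stop("density has zero mass at 0: no synchronization onset exists",
         call. = FALSE)
  if (method == "linearized") return(2 / (pi * density$g0))
  ## nonlinear existence test: a non-zero solution of r = F(K r) exists
  ## iff K F(X) > X somewhere on X > 0
  Xgrid <- exp(seq(log(1e-6), log(20), length.out = 2000))
  FX <- sc_integral(Xgrid, density)
  exists_locked <- function(K) any(K * FX > Xgrid)
  lo <- 1e-3; hi <- 1e3
  if (exists_locked(lo) || !exists_locked(hi))
    stop("bisection bracket invalid for this density", call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (exists_locked(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Analytic global order parameter
#'
#' Beyond the onset of synchronization (non-negative weights, ensemble
#' averages phase-aligned) the global order parameter equals the arithmetic
#' mean of the per-node order parameters; below onset it is 0 by the same
#' formula.
#'
#' @param solution a `mean_field_solution` (or a numeric node_r vector).
#' @param adjacency unused; accepted for interface symmetry with the
#'   simulation-side global order parameter.
#' @return scalar in `[0, 1]`.
#' @export
global_order_parameter <- function(solution, adjacency = NULL) {
  r <- if (inherits(solution, "mean_field_solution")) solution$node_r
       else as.numeric(solution)
  mean(r)
}
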