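#' Critical global coupling of a subject's functional network
#'
#' Fixes every node's intrinsic coupling at a common sub-critical value
#' and computes the critical global coupling of the subject's directed
#' weighted functional network by the eigenvalue route. A lower value
#' means the network synchronizes more readily (more seizure-prone under
#' the model's reading); `Inf` means the network has purely hierarchical
#' flow and cannot network-synchronize at any coupling.
#'
#' @param net a `directed_functional_network` (or a bare adjacency
#'   matrix, row = receiver).
#' @param K_default common intrinsic coupling, must be below `K_c`.
#' @param K_c critical intrinsic coupling of an isolated node.
#' @return list (class `subject_measure`) with `measure = "kappa_c"`,
#'   `value`, and the full `critical_coupling_result` as `detail`.
#' @export
subject_kappa_c <- function(net, K_default, K_c) {
  A <- if (inherits(net, "directed_functional_network")) net$weights
       else as.matrix(net)
  res <- kappa_c_eigen(A, K_default, K_c)
  structure(list(measure = "kappa_c", value = res$kappa_c, detail = res),
            class = "subject_measure")
}

#' Node-driven synchrony scan
#'
#' For each node `s` in turn, sets that node's intrinsic coupling above
#' the single-node critical value (so it self-synchronizes) while all
#' other nodes stay sub-critical, solves the nonlinear mean-field system,
#' and records the resulting global order parameter `R = mean(node_r)`.
#' A node whose synchronization spreads far downstream scores high; the
#' all-node average is the subject-level summary.
#'
#' @param net a `directed_functional_network` or adjacency matrix.
#' @param K_base sub-critical intrinsic coupling of non-seeded nodes.
#' @param K_self super-critical coupling of the seeded node.
#' @param kappa global coupling during the scan.
#' @param density frequency density; default standard normal.
#' @return list with `node_R` (named per-node global order parameter when
#'   that node is the seed), `average` (mean over converged seeds),
#'   `converged` (logical per seed).
#' @export
node_driven_scan <- function(net, K_base, K_self, kappa,
                             density = normal_freq_density()) {
  A <- if (inherits(net, "directed_functional_network")) net$weights
       else as.matrix(net)
  n <- nrow(A)
  K_c <- single_node_critical_coupling(density)
  if (!(K_base < K_c && K_c < K_self))
    stop("need K_base < K_c < K_self", call. = FALSE)
  if (kappa < 0) stop("kappa must be non-negative", call. = FALSE)
  node_R <- rep(NA_real_, n)
  ok <- rep(FALSE, n)
  for (s in seq_len(n)) {
    K <- rep(K_base, n)
    K[s] <- K_self
    sol <- tryCatch(
      solve_mean_field(mean_field_problem(A, K, kappa, density)),
      error = function(e) NULL)
    if (!is.null(sol) && sol$converged) {
      node_R[s] <- global_order_parameter(sol)
      ok[s] <- TRUE
    }
  }
  if (!all(ok))
    warning(sprintf("mean-field solve failed for %d seed node(s); ",
                    sum(!ok)), "excluded from the average")
  labs <- colnames(A) %||% as.character(seq_len(n))
  names(node_R) <- labs
  list(node_R = node_R, average = mean(node_R[ok]), converged = ok)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Thin wrapper around [stats::wilcox.test()]: exact enumeration for
#' small tie-free samples, normal approximation with tie and continuity
#' correction otherwise. Infinite values are legal (they carry extreme
#' ranks), and two identical pooled samples give p = 1.
#'
#' @param a,b numeric samples (non-empty; `Inf` allowed).
#' @return two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) == 0 || length(b) == 0)
    stop("both samples must be non-empty", call. = FALSE)
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1) return(1)
  ## rank-transform first: the test only depends on ranks, and this keeps
  ## infinite scores (which wilcox.test would silently drop) in play
  r <- rank(pooled)
  suppressWarnings(
    wilcox.test(r[seq_along(a)], r[-seq_along(a)],
                alternative = "two.sided", correct = TRUE)$p.value)
}

#' Bonferroni correction
#'
#' @param p_raw raw p-value(s).
#' @param n_hypotheses number of hypotheses in the family (e.g. 19 when
#'   testing every electrode of the 10-20 montage).
#' @return `min(1, n_hypotheses * p_raw)`, vectorized.
#' @export
bonferroni <- function(p_raw, n_hypotheses) {
  if (n_hypotheses < 1) stop("n_hypotheses must be >= 1", call. = FALSE)
  pmin(1, n_hypotheses * p_raw)
}

#' Receiver operating characteristic of a subject-level measure
#'
#' Sweeps all distinct thresholds; for `direction = "lower_is_positive"`
#' every sample strictly below the threshold is called positive (the
#' reading for the critical coupling, where lower means more
#' seizure-prone), for `"higher_is_positive"` every sample above it.
#' AUC by the trapezoid rule; the operating point is the curve point
#' closest to perfect classification (0, 1) (ties broken toward higher
#' TPR); PPV, FDR = 1 - PPV, sensitivity and specificity are reported at
#' that point. Infinite scores sort to the extremes.
#'
#' @param scores numeric scores, one per subject (`Inf` allowed).
#' @param labels logical or 0/1 vector, `TRUE`/1 = positive class.
#' @param direction `"lower_is_positive"` or `"higher_is_positive"`.
#' @return object of class `roc_result` with `fpr`, `tpr`, `thresholds`,
#'   `auc`, `best_point`, `ppv`, `fdr`, `sensitivity`, `specificity`.
#' @export
roc_analysis <- function(scores, labels,
                         direction = c("lower_is_positive",
                                       "higher_is_positive")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch",
                                             call. = FALSE)
  if (!any(labels) || all(labels))
    stop("both classes must be present", call. = FALSE)
  ## map to "higher predicts positive" and call positives as score > thr,
  ## which for the original scale is score < thr (strictly below)
  s <- if (direction == "lower_is_positive") -scores else scores
  nP <- sum(labels); nN <- sum(!labels)
  ord <- order(s, decreasing = TRUE)
  s_sorted <- s[ord]
  lab_sorted <- labels[ord]
  ## thresholds between distinct score values; cumulative counts give
  ## TP/FP when calling everything above the cut positive
  tp <- cumsum(lab_sorted)
  fp <- cumsum(!lab_sorted)
  last <- !duplicated(s_sorted, fromLast = TRUE)  # last index of each value
  tp <- c(0, tp[last]); fp <- c(0, fp[last])
  thr <- c(Inf, s_sorted[last])
  tpr <- tp / nP
  fpr <- fp / nN
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  d2 <- fpr^2 + (1 - tpr)^2
  best <- which(d2 == min(d2))
  best <- best[which.max(tpr[best])]
  ppv <- if (tp[best] + fp[best] > 0) tp[best] / (tp[best] + fp[best])
         else nP / (nP + nN)   # degenerate all-negative corner
  thr_out <- if (direction == "lower_is_positive") -thr else thr
  structure(list(fpr = fpr, tpr = tpr, thresholds = thr_out, auc = auc,
                 best_point = c(fpr = fpr[best], tpr = tpr[best],
                                threshold = thr_out[best]),
                 ppv = ppv, fdr = 1 - ppv,
                 sensitivity = tpr[best], specificity = 1 - fpr[best],
                 direction = direction),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(paste0("ROC: AUC = %.3f; best point FPR = %.3f, ",
                     "TPR = %.3f; PPV = %.3f, FDR = %.3f\n"),
              x$auc, x$best_point["fpr"], x$best_point["tpr"],
              x$ppv, x$fdr))
  invisible(x)
}

#' Cohort study configuration
#'
#' @param K_default_frac intrinsic coupling for the critical-coupling
#'   measure, as a fraction of `K_c`; default 0.5 (sub-critical).
#' @param K_self_frac seeded node's coupling in the node-driven scan, as
#'   a fraction of `K_c`; default 2 (self-synchronized).
#' @param kappa global coupling for the node-driven scan; default 0.4
#'   (below the global onset of the control generator's networks).
#' @param include_node_driven run the per-node scans (the expensive
#'   part); default TRUE.
#' @param alpha family-wise significance level after correction; 0.05.
#' @param density frequency density; default standard normal.
#' @export
cohort_config <- function(K_default_frac = 0.5, K_self_frac = 2,
                          kappa = 0.4, include_node_driven = TRUE,
                          alpha = 0.05, density = normal_freq_density()) {
  list(K_default_frac = K_default_frac, K_self_frac = K_self_frac,
       kappa = kappa, include_node_driven = include_node_driven,
       alpha = alpha, density = density)
}

#' Run a two-group cohort study
#'
#' Computes the model-based measures for every subject network (critical
#' global coupling; optionally the node-driven synchrony scan), compares
#' groups with the Wilcoxon rank-sum test, Bonferroni-corrects within
#' each measure family (the node-driven family is corrected by the number
#' of nodes), and runs ROC analysis for each significant measure
#' (direction: lower critical coupling is case-like; higher node-driven
#' synchrony is case-like).
#'
#' @param cases,controls lists of `directed_functional_network`s (or
#'   adjacency matrices), at least 2 per group.
#' @param config see [cohort_config()].
#' @return list (class `cohort_result`) with `measures` (data.frame:
#'   measure, node, group means/SEMs, p_raw, p_corrected, significant),
#'   `roc` (named list of `roc_result` for significant measures),
#'   `subject_values` (named list of per-subject score vectors,
#'   cases first), `groups`.
#' @export
run_cohort_study <- function(cases, controls, config = cohort_config()) {
  if (length(cases) < 2 || length(controls) < 2)
    stop("need at least 2 subjects per group", call. = FALSE)
  K_c <- single_node_critical_coupling(config$density)
  K_default <- config$K_default_frac * K_c
  K_self <- config$K_self_frac * K_c
  grp <- c(rep(TRUE, length(cases)), rep(FALSE, length(controls)))
  nets <- c(cases, controls)

  sem <- function(x) {
    xf <- x[is.finite(x)]
    if (length(xf) < 2) return(NA_real_)
    sd(xf) / sqrt(length(xf))
  }
  gmean <- function(x) mean(x)   # Inf-propagating by design

  values <- list()
  rows <- list()
  add_row <- function(name, node, vals, n_hyp, direction) {
    p <- wilcoxon_rank_sum(vals[grp], vals[!grp])
    pc <- bonferroni(p, n_hyp)
    rows[[length(rows) + 1]] <<- data.frame(
      measure = name, node = node,
      mean_case = gmean(vals[grp]), sem_case = sem(vals[grp]),
      mean_control = gmean(vals[!grp]), sem_control = sem(vals[!grp]),
      p_raw = p, p_corrected = pc,
      significant = pc < config$alpha,
      direction = direction, stringsAsFactors = FALSE)
    values[[paste0(name, if (nzchar(node)) paste0(":", node) else "")]] <<-
      vals
  }

  kc_vals <- vapply(nets, function(nw)
    subject_kappa_c(nw, K_default, K_c)$value, numeric(1))
  add_row("kappa_c", "", kc_vals, 1L, "lower_is_positive")

  if (isTRUE(config$include_node_driven)) {
    scans <- lapply(nets, function(nw)
      node_driven_scan(nw, K_default, K_self, config$kappa,
                       config$density))
    n_nodes <- length(scans[[1]]$node_R)
    labs <- names(scans[[1]]$node_R)
    avg <- vapply(scans, `[[`, numeric(1), "average")
    add_row("node_driven_R_avg", "", avg, 1L, "higher_is_positive")
    for (v in seq_len(n_nodes)) {
      nv <- vapply(scans, function(sc) sc$node_R[v], numeric(1))
      add_row("node_driven_R", labs[v], nv, n_nodes, "higher_is_positive")
    }
  }

  measures <- do.call(rbind, rows)
  roc <- list()
  for (i in which(measures$significant)) {
    key <- paste0(measures$measure[i],
                  if (nzchar(measures$node[i]))
                    paste0(":", measures$node[i]) else "")
    roc[[key]] <- roc_analysis(values[[key]], grp,
                               direction = measures$direction[i])
  }
  structure(list(measures = measures, roc = roc, subject_values = values,
                 groups = grp),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("Cohort study: %d cases vs %d controls; %d measure(s), ",
              sum(x$groups), sum(!x$groups), nrow(x$measures)))
  cat(sprintf("%d significant after correction\n",
              sum(x$measures$significant)))
  sig <- x$measures[x$measures$significant, c("measure", "node", "p_raw",
                                              "p_corrected")]
  if (nrow(sig)) print(sig, row.names = FALSE)
  invisible(x)
}
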