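Kc <- KC_NORMAL

test_that("subject critical coupling matches motif closed forms", {
  empty <- matrix(0, 4, 4)
  expect_identical(subject_kappa_c(empty, 0.5 * Kc, Kc)$value, Inf)
  A <- matrix(0, 4, 4); A[1, 2] <- A[2, 1] <- 1
  expect_equal(subject_kappa_c(A, 0.5 * Kc, Kc)$value, Kc - 0.5 * Kc,
               tolerance = 1e-12)
  set.seed(13)
  W <- random_scc_adjacency(6)
  e <- subject_kappa_c(W, 0.5 * Kc, Kc)$value
  d <- kappa_c_determinant(W, 0.5 * Kc, Kc)
  expect_lt(abs(e - d), 1e-6)
  ## scale covariance: scaling weights by c divides kappa_c by c
  expect_equal(subject_kappa_c(2.5 * W, 0.5 * Kc, Kc)$value, e / 2.5,
               tolerance = 1e-10)
})

test_that("node-driven scan spreads synchrony only along directed paths", {
  r_self <- solve_mean_field(mean_field_problem(matrix(0, 1, 1),
                                                2 * Kc, 0))$node_r
  ## isolated nodes: seeding any node gives R = r_self / n
  sc0 <- node_driven_scan(matrix(0, 3, 3), 0.5 * Kc, 2 * Kc, 1)
  expect_equal(unname(sc0$node_R), rep(r_self / 3, 3), tolerance = 1e-8)
  ## chain 1 -> 2 -> 3 with strong weights and coupling
  A <- matrix(0, 3, 3); A[2, 1] <- A[3, 2] <- 2
  sc <- node_driven_scan(A, 0.5 * Kc, 2 * Kc, 2)
  expect_gt(sc$node_R[1], sc$node_R[3])       # root drives downstream
  expect_equal(unname(sc$node_R[3]), r_self / 3, tolerance = 1e-8)
  ## root seed synchronizes the downstream nodes
  K <- rep(0.5 * Kc, 3); K[1] <- 2 * Kc
  sol <- solve_mean_field(mean_field_problem(A, K, 2))
  expect_true(all(sol$node_r > 0))
  ## the scan average is monotone non-decreasing in kappa
  avgs <- vapply(c(0.2, 0.6, 1.2), function(kap)
    node_driven_scan(two_node_bi_adj(), 0.5 * Kc, 2 * Kc, kap)$average,
    numeric(1))
  expect_true(all(diff(avgs) >= -1e-8))
})

test_that("rank-sum wrapper is exact, tie-safe and infinity-safe", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4)), 1 / 3,
               tolerance = 1e-12)
  expect_equal(wilcoxon_rank_sum(c(2, 2, 5), c(2, 2, 5)), 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
  ## invariance under strictly monotone transforms of the pooled scores
  set.seed(21)
  a <- rnorm(8); b <- rnorm(9) + 0.5
  expect_equal(wilcoxon_rank_sum(a, b),
               wilcoxon_rank_sum(exp(a), exp(b)), tolerance = 1e-12)
  ## infinite values keep their extreme rank instead of being dropped
  expect_equal(wilcoxon_rank_sum(c(1, 2, Inf), c(3, 4, 5)),
               wilcoxon_rank_sum(c(1, 2, 100), c(3, 4, 5)),
               tolerance = 1e-12)
})

test_that("Bonferroni correction is capped multiplication", {
  expect_equal(bonferroni(0.002, 19), 0.038)
  expect_equal(bonferroni(0.5, 6), 1)
  expect_equal(bonferroni(0.123, 1), 0.123)
  expect_error(bonferroni(0.1, 0), "n_hypotheses")
})

test_that("ROC analysis matches brute force and behaves under transforms", {
  ## perfectly separated: lower scores are cases
  r <- roc_analysis(c(1, 2, 3, 10, 11, 12), c(1, 1, 1, 0, 0, 0),
                    "lower_is_positive")
  expect_equal(r$auc, 1)
  expect_equal(r$ppv, 1)
  expect_equal(r$fdr, 0)
  ## degenerate: identical scores
  expect_equal(roc_analysis(rep(5, 6), c(1, 1, 1, 0, 0, 0),
                            "lower_is_positive")$auc, 0.5)
  expect_error(roc_analysis(1:4, c(1, 1, 1, 1), "lower_is_positive"),
               "classes")

  ## brute-force oracle: enumerate every threshold with plain loops
  brute <- function(scores, labels) {
    cuts <- c(-Inf, sort(unique(scores)), Inf)
    pts <- t(vapply(cuts, function(ct) {
      pos <- scores <= ct
      c(fpr = sum(pos & !labels) / sum(!labels),
        tpr = sum(pos & labels) / sum(labels))
    }, numeric(2)))
    pts <- pts[order(pts[, "fpr"], pts[, "tpr"]), ]
    auc <- 0
    for (i in 2:nrow(pts))
      auc <- auc + (pts[i, 1] - pts[i - 1, 1]) *
        (pts[i, 2] + pts[i - 1, 2]) / 2
    d <- sqrt(pts[, 1]^2 + (1 - pts[, 2])^2)
    best <- which(d == min(d))
    best <- best[which.max(pts[best, 2])]
    list(auc = unname(auc), best = unname(pts[best, ]))
  }
  set.seed(33)
  for (i in 1:20) {
    sc <- sample(c(rnorm(12), Inf), 12)
    lab <- as.logical(rbinom(12, 1, 0.5))
    if (!any(lab) || all(lab)) next
    mine <- roc_analysis(sc, lab, "lower_is_positive")
    oracle <- brute(sc, lab)
    expect_equal(mine$auc, oracle$auc, tolerance = 1e-12)
    expect_equal(unname(mine$best_point[c("fpr", "tpr")]),
                 unname(oracle$best), tolerance = 1e-12)
  }
  ## monotone invariance and direction flip
  sc <- c(0.3, 0.8, 0.1, 0.9, 0.4, 0.6)
  lab <- c(1, 0, 1, 0, 1, 0)
  m1 <- roc_analysis(sc, lab, "lower_is_positive")
  m2 <- roc_analysis(qnorm(sc), lab, "lower_is_positive")
  expect_equal(m1$auc, m2$auc)
  m3 <- roc_analysis(sc, lab, "higher_is_positive")
  expect_equal(m3$auc, 1 - m1$auc)
})

test_that("ROC area agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(44)
  sc <- rnorm(30)
  lab <- as.logical(rbinom(30, 1, 0.5))
  mine <- roc_analysis(sc, lab, "higher_is_positive")$auc
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("cohort study wires measures, correction and ROC together", {
  expect_error(run_cohort_study(list(matrix(0, 2, 2)),
                                list(matrix(0, 2, 2), matrix(0, 2, 2))),
               "at least 2")
  co <- gen_cohort(6, 6, 1, seed = 3)
  res <- run_cohort_study(co$cases, co$controls,
                          cohort_config(include_node_driven = FALSE))
  expect_identical(res$measures$measure[1], "kappa_c")
  expect_true(all(res$measures$p_corrected >=
                    res$measures$p_raw - 1e-12))
  expect_true(all(res$measures$p_corrected <= 1))
  ## node-driven rows appear when requested, corrected by the node count
  res2 <- run_cohort_study(co$cases[1:3], co$controls[1:3],
                           cohort_config(kappa = 0.3))
  nd <- res2$measures[res2$measures$measure == "node_driven_R", ]
  expect_equal(nrow(nd), 19)
  expect_equal(nd$p_corrected, pmin(1, 19 * nd$p_raw), tolerance = 1e-12)
})
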