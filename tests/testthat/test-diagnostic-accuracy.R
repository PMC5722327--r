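test_that("AUC worked examples: perfect separation, overlap with a tie, all ties", {
  lab <- rep(c("d", "c"), each = 3)
  expect_equal(roc_auc(c(4, 5, 6, 1, 2, 3), lab, positive = "d")$auc, 1)
  expect_equal(roc_auc(c(3, 4, 5, 1, 2, 3), lab, positive = "d")$auc, 8.5 / 9)
  expect_equal(roc_auc(rep(2, 6), lab, positive = "d")$auc, 0.5)
})

test_that("the rank-based AUC equals brute-force pair counting with tie credit", {
  withr::with_seed(21, {
    for (i in 1:50) {
      n1 <- sample(3:15, 1); n0 <- sample(3:15, 1)
      scores <- c(sample(0:8, n1, replace = TRUE) + 1,
                  sample(0:8, n0, replace = TRUE))
      is_pos <- rep(c(TRUE, FALSE), c(n1, n0))
      curve <- roc_auc(scores, is_pos, positive = TRUE, orient = FALSE)
      expect_equal(curve$auc, pair_count_auc(scores, is_pos), tolerance = 1e-12)
    }
  })
})

test_that("the Mann-Whitney AUC equals the trapezoidal area under the empirical ROC", {
  withr::with_seed(22, {
    for (i in 1:50) {
      scores <- c(rnorm(12, 1), round(rnorm(10), 1))
      is_pos <- rep(c(TRUE, FALSE), c(12, 10))
      curve <- roc_auc(scores, is_pos, positive = TRUE)
      expect_equal(curve$auc, trapezoid_area(curve), tolerance = 1e-12)
    }
  })
})

test_that("the AUC agrees with an independent ROC implementation", {
  withr::with_seed(23, {
    scores <- c(rnorm(20, 1.2), rnorm(25))
    labels <- rep(c(1, 0), c(20, 25))
    ours <- roc_auc(scores, labels, positive = 1)$auc
    theirs <- as.numeric(suppressMessages(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))))
    expect_equal(ours, theirs, tolerance = 1e-12)
  })
})

test_that("negating scores flips the unoriented AUC and auto-orientation undoes it", {
  withr::with_seed(24, {
    scores <- c(rnorm(15, 1), rnorm(15))
    labels <- rep(c("d", "c"), each = 15)
    a <- roc_auc(scores, labels, positive = "d", orient = FALSE)$auc
    b <- roc_auc(-scores, labels, positive = "d", orient = FALSE)$auc
    expect_equal(a + b, 1, tolerance = 1e-12)
    f1 <- roc_auc(scores, labels, positive = "d")
    f2 <- roc_auc(-scores, labels, positive = "d")
    expect_equal(f1$auc, f2$auc, tolerance = 1e-12)
    expect_equal(f2$orientation, "lower_is_positive")
  })
})

test_that("the Youden cut-off resolves ties toward higher specificity", {
  lab <- rep(c("d", "c"), each = 3)
  perfect <- optimal_cutoff(roc_auc(c(4, 5, 6, 1, 2, 3), lab, positive = "d"))
  expect_equal(perfect$se, 100)
  expect_equal(perfect$sp, 100)
  expect_equal(perfect$youden, 100)
  expect_gt(perfect$cutoff, 3)
  expect_lte(perfect$cutoff, 4)

  tied <- optimal_cutoff(roc_auc(c(3, 4, 5, 1, 2, 3), lab, positive = "d"))
  expect_equal(tied$youden, 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(tied$sp, 100)       # higher-specificity candidate wins
  expect_gt(tied$cutoff, 3)        # the cut sits above the shared score 3
  expect_equal(tied$cutoff, 3.5)
})

test_that("classifying by the reported cut-off and direction reproduces Se/Sp", {
  withr::with_seed(25, {
    scores <- c(rnorm(20, 0.011, 0.002), rnorm(20, 0.020, 0.003))  # disease lower
    labels <- rep(c("d", "c"), each = 20)
    curve <- roc_auc(scores, labels, positive = "d")
    expect_equal(curve$orientation, "lower_is_positive")
    cut <- optimal_cutoff(curve)
    expect_equal(cut$direction, "<=")
    called_pos <- scores <= cut$cutoff
    expect_equal(100 * mean(called_pos[labels == "d"]), cut$se, tolerance = 1e-9)
    expect_equal(100 * mean(!called_pos[labels == "c"]), cut$sp, tolerance = 1e-9)
  })
})

test_that("AUC accuracy bands use left-closed boundaries and the 0.75 adequacy bar", {
  out <- auc_band(c(0.82, 0.95, 0.70, 0.90, 0.74))
  expect_equal(out$band, c("moderate", "high", "moderate", "high", "moderate"))
  expect_equal(out$adequate, c(TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_error(auc_band(0.4), class = "oscillab_orientation_error")
})

test_that("Hanley-McNeil SE matches the direct variance formula", {
  a <- 0.8; n1 <- 12; n0 <- 17
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  direct <- sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) / (n1 * n0))
  expect_equal(hanley_mcneil_se(a, n1, n0), direct, tolerance = 1e-15)
})

test_that("the minimum sample size reproduces both sidedness conventions", {
  expect_equal(hanley_mcneil_min_n(), 20L)
  expect_equal(hanley_mcneil_min_n(sided = "one"), 15L)
  sizes <- hanley_mcneil_sample_sizes()
  expect_equal(sizes$n_per_group[sizes$sided == "two"], 20L)
  expect_equal(sizes$n_per_group[sizes$sided == "one"], 15L)
})

test_that("sample size shrinks with effect size and the inequality is tight", {
  expect_lt(hanley_mcneil_min_n(auc_alt = 0.999), hanley_mcneil_min_n(auc_alt = 0.75))
  expect_lte(hanley_mcneil_min_n(alpha = 0.20), hanley_mcneil_min_n(alpha = 0.10))
  expect_lte(hanley_mcneil_min_n(beta = 0.20), hanley_mcneil_min_n(beta = 0.10))
  kernel <- function(A) A / (2 - A) + 2 * A^2 / (1 + A) - 2 * A^2
  holds <- function(n, za, zb, a1 = 0.75, a0 = 0.5) {
    (a1 - a0) >= za * sqrt(kernel(a0) / n) + zb * sqrt(kernel(a1) / n)
  }
  for (case in list(c(0.75, 0.5, 0.10, 0.10), c(0.85, 0.5, 0.05, 0.20),
                    c(0.75, 0.6, 0.10, 0.10))) {
    n <- hanley_mcneil_min_n(case[1], case[2], case[3], case[4])
    za <- qnorm(1 - case[3] / 2); zb <- qnorm(1 - case[4])
    expect_true(holds(n, za, zb, case[1], case[2]))
    expect_false(holds(n - 1, za, zb, case[1], case[2]))
  }
  expect_error(hanley_mcneil_min_n(auc_alt = 0.4), class = "oscillab_domain_error")
})

test_that("roc_analysis summarises a feature contrast between groups", {
  tbl <- planted_feature_table(n_per_group = 20, shift = 2, seed = 31)
  curve <- roc_analysis(tbl, "signal", positive_group = "AE",
                        negative_group = "control")
  expect_s3_class(curve, "fot_roc")
  s <- glance(curve)
  expect_true(s$auc > 0.8)
  expect_true(s$ci_lower < s$auc && s$auc < s$ci_upper)
  expect_equal(nrow(tidy(curve)), nrow(curve$points))
})
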