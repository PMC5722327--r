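test_that("parzen posteriors favour the nearer class and respect symmetry", {
  s <- parzen_scores(matrix(c(0, 4)), c("A", "B"), matrix(0), bandwidth = 1,
                     positive = "A")
  expect_gt(s, 0.5)
  # equidistant point between symmetric classes with equal priors
  mid <- parzen_scores(matrix(c(-1, 1)), c("A", "B"), matrix(0), bandwidth = 1,
                       positive = "B")
  expect_equal(mid, 0.5, tolerance = 1e-12)
})

test_that("parzen posteriors match a naive double-loop kernel sum", {
  withr::with_seed(41, {
    xtr <- matrix(rnorm(40), ncol = 2)
    lab <- rep(c("a", "b"), each = 10)
    xte <- matrix(rnorm(12), ncol = 2)
    h <- c(0.7, 1.3)
    naive <- vapply(seq_len(nrow(xte)), function(i) {
      dens <- vapply(c("a", "b"), function(cl) {
        rows <- which(lab == cl)
        mean(vapply(rows, function(r) {
          prod(dnorm((xte[i, ] - xtr[r, ]) / h) / h)
        }, numeric(1)))
      }, numeric(1))
      pri <- c(a = 0.5, b = 0.5)
      (dens["b"] * pri["b"]) / sum(dens * pri)
    }, numeric(1))
    ours <- parzen_scores(xtr, lab, xte, bandwidth = h, positive = "b")
    expect_equal(ours, unname(naive), tolerance = 1e-12)
  })
})

test_that("parzen requires two classes and positive bandwidths", {
  expect_error(parzen_scores(matrix(1:3), c("a", "a", "a"), matrix(1)),
               class = "oscillab_class_error")
  expect_error(parzen_scores(matrix(c(0, 1)), c("a", "b"), matrix(1), bandwidth = 0),
               class = "oscillab_domain_error")
})

test_that("perfectly separable classes reach AUC 1 under any scheme and classifier", {
  tbl <- planted_feature_table(n_per_group = 12, n_noise = 1, shift = 30, seed = 42)
  for (clf in c("parzen", "knn", "svm_linear", "svm_rbf", "random_forest",
                "adaboost_tree")) {
    res <- cross_validate(classifier_spec(clf), tbl, c("signal", "noise1"),
                          cv_spec("kfold", k = 4, seed = 1), positive = "AE")
    expect_equal(res$auc, 1, tolerance = 1e-9)
  }
  loo <- cross_validate(classifier_spec("parzen"), tbl, "signal",
                        cv_spec("loocv"), positive = "AE")
  expect_equal(loo$auc, 1)
})

test_that("LOOCV is identical to k-fold with k = n", {
  tbl <- planted_feature_table(n_per_group = 8, shift = 1.5, seed = 43)
  a <- cross_validate(classifier_spec("parzen"), tbl, c("signal", "noise1"),
                      cv_spec("loocv"), positive = "AE")
  b <- cross_validate(classifier_spec("parzen"), tbl, c("signal", "noise1"),
                      cv_spec("kfold", k = nrow(tbl), stratified = FALSE, seed = 99),
                      positive = "AE")
  expect_equal(a$auc, b$auc, tolerance = 1e-12)
  expect_equal(dplyr::arrange(a$scores, row)$score,
               dplyr::arrange(b$scores, row)$score, tolerance = 1e-12)
})

test_that("evaluation is deterministic given the seed", {
  tbl <- planted_feature_table(n_per_group = 10, shift = 1, seed = 44)
  for (clf in c("parzen", "random_forest")) {
    r1 <- cross_validate(classifier_spec(clf), tbl, c("signal", "noise1"),
                         cv_spec("kfold", k = 5, seed = 3), positive = "AE")
    r2 <- cross_validate(classifier_spec(clf), tbl, c("signal", "noise1"),
                         cv_spec("kfold", k = 5, seed = 3), positive = "AE")
    expect_identical(r1$auc, r2$auc)
    expect_identical(r1$scores$score, r2$scores$score)
  }
})

test_that("a test subject's own label cannot influence its out-of-fold score", {
  tbl <- planted_feature_table(n_per_group = 8, shift = 1.5, seed = 45)
  res <- cross_validate(classifier_spec("parzen"), tbl, c("signal", "noise1"),
                        cv_spec("loocv"), positive = "AE")
  flipped <- tbl
  flipped$group[1] <- ifelse(tbl$group[1] == "AE", "control", "AE")
  res2 <- cross_validate(classifier_spec("parzen"), flipped, c("signal", "noise1"),
                         cv_spec("loocv"), positive = "AE")
  s1 <- res$scores$score[res$scores$row == 1]
  s2 <- res2$scores$score[res2$scores$row == 1]
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("permuted labels give chance-level cross-validated AUC", {
  tbl <- planted_feature_table(n_per_group = 20, shift = 1, seed = 46)
  aucs <- vapply(1:30, function(i) {
    perm <- tbl
    perm$group <- withr::with_seed(1000 + i, sample(tbl$group))
    cross_validate(classifier_spec("parzen"), perm, c("signal", "noise1"),
                   cv_spec("kfold", k = 5, seed = i), positive = "AE")$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("exhaustive search enumerates all subsets and finds the planted signal", {
  tbl <- planted_feature_table(n_per_group = 15, n_noise = 2, shift = 2.5, seed = 47)
  feats <- c("signal", "noise1", "noise2")
  hits <- vapply(1:5, function(s) {
    res <- exhaustive_search(classifier_spec("parzen"), tbl, feats,
                             cv_spec("kfold", k = 5, seed = s), positive = "AE")
    expect_equal(res$n_subsets, 7L)  # 2^3 - 1
    singles <- res$results$auc[res$results$size == 1]
    expect_gte(res$best$auc, max(singles))
    "signal" %in% res$best_features
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the feature-count guard limits the combinatorial search", {
  tbl <- planted_feature_table(seed = 48)
  expect_error(exhaustive_search(classifier_spec("parzen"), tbl, character(0),
                                 positive = "AE"),
               class = "oscillab_combinatorial_error")
  expect_error(exhaustive_search(classifier_spec("parzen"), tbl, paste0("f", 1:21),
                                 positive = "AE"),
               class = "oscillab_combinatorial_error")
})

test_that("unknown hyperparameters are rejected up front", {
  expect_error(classifier_spec("knn", params = list(bogus = 1)),
               class = "oscillab_validation_error")
})
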