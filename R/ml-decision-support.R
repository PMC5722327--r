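#' Classifier specification for the decision-support layer
#'
#' Declares one of the six supported classifier families together with its
#' hyperparameters. Defaults: `svm_linear` cost 1; `svm_rbf` cost 1, gamma
#' 1/p; `knn` k = 5; `random_forest` 500 trees; `adaboost_tree` 100 stumps;
#' `parzen` Gaussian kernel with per-feature Silverman bandwidths estimated
#' on the training fold. Features are z-scored inside each training fold by
#' default (distance- and kernel-based methods require comparable scales).
#'
#' @param name One of `"svm_linear"`, `"svm_rbf"`, `"knn"`,
#'   `"random_forest"`, `"adaboost_tree"`, `"parzen"`.
#' @param params Named list of hyperparameter overrides.
#' @param standardize Z-score features within training folds.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(name = c("parzen", "svm_linear", "svm_rbf", "knn",
                                     "random_forest", "adaboost_tree"),
                            params = list(), standardize = TRUE) {
  name <- match.arg(name)
  defaults <- switch(name,
    svm_linear = list(cost = 1),
    svm_rbf = list(cost = 1, gamma = NULL),
    knn = list(k = 5),
    random_forest = list(ntree = 500),
    adaboost_tree = list(n_rounds = 100),
    parzen = list(bandwidth = NULL)
  )
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) {
    abort(paste0("Unknown hyperparameters for ", name, ": ",
                 paste(unknown, collapse = ", ")),
          class = "oscillab_validation_error")
  }
  structure(list(name = name, params = modifyList(defaults, params),
                 standardize = isTRUE(standardize)),
            class = "classifier_spec")
}

#' Cross-validation specification
#'
#' @param scheme `"kfold"` or `"loocv"` (leave-one-out, the k = n limit of
#'   k-fold).
#' @param k Number of folds for `"kfold"`.
#' @param stratified Stratify fold assignment by class.
#' @param seed Seed for fold assignment and any classifier randomness.
#' @return An object of class `cv_spec`.
#' @export
cv_spec <- function(scheme = c("kfold", "loocv"), k = 10, stratified = TRUE,
                    seed = 1L) {
  scheme <- match.arg(scheme)
  if (scheme == "kfold" && (!is.numeric(k) || k < 2)) {
    abort("k-fold requires k >= 2.", class = "oscillab_validation_error")
  }
  structure(list(scheme = scheme, k = as.integer(k),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "cv_spec")
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

silverman_bandwidths <- function(x) {
  n <- nrow(x)
  h <- apply(x, 2, sd) * 1.06 * n^(-1/5)
  pmax(h, 1e-8)
}

#' Parzen-window (kernel density Bayes) classifier scores
#'
#' For each test point, estimates the class-conditional density of each
#' class with a product Gaussian kernel over the training points of that
#' class, multiplies by the class prior (training class proportion), and
#' returns the normalized posterior probability of the positive class.
#' Computations are done in log space for numerical stability.
#'
#' @param train_features Numeric matrix/data frame of training features.
#' @param train_labels Training class labels.
#' @param test_features Features of the points to score.
#' @param bandwidth Kernel bandwidth: a single number or per-feature vector;
#'   `NULL` uses Silverman's rule per feature on the training set.
#' @param positive Label value of the positive class (defaults to the last
#'   sorted unique label).
#' @return Numeric vector of positive-class posteriors in `[0, 1]`.
#' @export
parzen_scores <- function(train_features, train_labels, test_features,
                          bandwidth = NULL, positive = NULL) {
  x <- as.matrix(train_features)
  xt <- as.matrix(test_features)
  storage.mode(x) <- "double"; storage.mode(xt) <- "double"
  labs <- as.character(train_labels)
  classes <- sort(unique(labs))
  if (length(classes) != 2L) {
    abort("Parzen scoring requires exactly two classes in the training data.",
          class = "oscillab_class_error")
  }
  if (is.null(positive)) positive <- classes[2]
  if (!positive %in% classes) {
    abort("Positive class absent from training data.", class = "oscillab_class_error")
  }
  p <- ncol(x)
  h <- if (is.null(bandwidth)) silverman_bandwidths(x) else rep_len(bandwidth, p)
  if (any(h <= 0)) abort("Bandwidths must be positive.", class = "oscillab_domain_error")
  const <- -sum(log(h)) - p / 2 * log(2 * pi)
  log_class_density <- function(cls) {
    xc <- x[labs == cls, , drop = FALSE]
    xs <- sweep(xc, 2, h, `/`)
    ts <- sweep(xt, 2, h, `/`)
    # squared scaled distances, test rows x train rows
    d2 <- outer(rowSums(ts^2), rowSums(xs^2), `+`) - 2 * tcrossprod(ts, xs)
    d2[d2 < 0] <- 0
    apply(-0.5 * d2 + const, 1, logsumexp) - log(nrow(xc))
  }
  neg <- setdiff(classes, positive)
  lp_pos <- log_class_density(positive) + log(mean(labs == positive))
  lp_neg <- log_class_density(neg) + log(mean(labs == neg))
  denom <- mapply(function(a, b) logsumexp(c(a, b)), lp_pos, lp_neg)
  exp(lp_pos - denom)
}

fit_and_score <- function(spec, train_x, train_pos, test_x, seed) {
  pars <- spec$params
  ytr <- factor(ifelse(train_pos, "pos", "neg"), levels = c("neg", "pos"))
  switch(
    spec$name,
    parzen = parzen_scores(train_x, as.character(ytr), test_x,
                           bandwidth = pars$bandwidth, positive = "pos"),
    knn = withr::with_seed(seed, {
      pred <- class::knn(train_x, test_x, cl = ytr, k = min(pars$k, nrow(train_x)),
                         prob = TRUE, use.all = TRUE)
      pr <- attr(pred, "prob")
      ifelse(pred == "pos", pr, 1 - pr)
    }),
    random_forest = withr::with_seed(seed, {
      fit <- randomForest::randomForest(x = train_x, y = ytr, ntree = pars$ntree)
      unname(predict(fit, test_x, type = "prob")[, "pos"])
    }),
    svm_linear = ,
    svm_rbf = withr::with_seed(seed, {
      kern <- if (spec$name == "svm_rbf") "radial" else "linear"
      gamma <- pars$gamma %||% (1 / ncol(train_x))
      fit <- e1071::svm(x = train_x, y = ytr, kernel = kern, cost = pars$cost,
                        gamma = gamma, scale = FALSE)
      dv_te <- drop(attr(predict(fit, test_x, decision.values = TRUE), "decision.values"))
      dv_tr <- drop(attr(predict(fit, train_x, decision.values = TRUE), "decision.values"))
      # orient decision values so higher means positive
      if (mean(dv_tr[train_pos]) < mean(dv_tr[!train_pos])) dv_te <- -dv_te
      unname(dv_te)
    }),
    adaboost_tree = {
      y <- ifelse(train_pos, 1, -1)
      dtr <- as.data.frame(train_x); dte <- as.data.frame(test_x)
      names(dte) <- names(dtr)
      n <- nrow(dtr)
      w <- rep(1 / n, n)
      score <- numeric(nrow(dte))
      ctrl <- rpart::rpart.control(maxdepth = 1, minsplit = 2, cp = -1, xval = 0,
                                   maxcompete = 0, maxsurrogate = 0)
      for (m in seq_len(pars$n_rounds)) {
        dat <- cbind(.y = factor(y, levels = c(-1, 1)), dtr)
        fit <- rpart::rpart(.y ~ ., data = dat, weights = w, method = "class",
                            control = ctrl)
        pr_tr <- ifelse(predict(fit, dtr, type = "class") == "1", 1, -1)
        err <- sum(w * (pr_tr != y))
        pr_te <- ifelse(predict(fit, dte, type = "class") == "1", 1, -1)
        if (err <= 1e-12) { score <- score + 10 * pr_te; break }
        if (err >= 0.5) break
        alpha <- 0.5 * log((1 - err) / err)
        score <- score + alpha * pr_te
        w <- w * exp(-alpha * y * pr_tr)
        w <- w / sum(w)
      }
      score
    }
  )
}

assign_folds <- function(is_pos, cv) {
  n <- length(is_pos)
  if (cv$scheme == "loocv") return(seq_len(n))
  k <- cv$k
  if (k > n) abort("k cannot exceed the number of subjects.", class = "oscillab_validation_error")
  folds <- integer(n)
  withr::with_seed(cv$seed, {
    if (cv$stratified) {
      for (cls in c(TRUE, FALSE)) {
        idx <- which(is_pos == cls)
        folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      folds[sample.int(n)] <- rep_len(seq_len(k), n)
    }
  })
  folds
}

#' Cross-validated evaluation of a classifier on a feature subset
#'
#' Runs the chosen cross-validation scheme with standardization parameters
#' fitted on training folds only (no information leak into test folds),
#' pools the out-of-fold scores, and evaluates AUC with the Mann-Whitney
#' statistic plus sensitivity/specificity at the pooled-score Youden
#' cut-off. The pooled AUC is evaluated in the fixed higher-score-positive
#' direction (no auto-orientation), so an uninformative classifier centres
#' on 0.5. Deterministic given `(cv$seed, spec, data)`.
#'
#' An unstratified fold whose training part lacks a class is skipped with a
#' warning and its subjects are excluded from the pooled scores.
#'
#' @param spec A [classifier_spec()].
#' @param data Subject-level feature table.
#' @param features Character vector of feature column names.
#' @param cv A [cv_spec()].
#' @param positive Group label treated as positive; other rows are negative.
#' @param group Group column name.
#' @return An object of class `fot_cv_result`: list with `auc`, `se`, `sp`,
#'   `cutoff`, `scores` (tibble of out-of-fold scores), `features`,
#'   `classifier`, `cv`.
#' @export
cross_validate <- function(spec, data, features, cv = cv_spec(),
                           positive, group = "group") {
  stopifnot(inherits(spec, "classifier_spec"), inherits(cv, "cv_spec"),
            is.data.frame(data), all(features %in% names(data)))
  x <- as.matrix(data[, features, drop = FALSE])
  storage.mode(x) <- "double"
  is_pos <- as.character(data[[group]]) == positive
  if (!any(is_pos) || all(is_pos)) {
    abort("Both classes must be present.", class = "oscillab_class_error")
  }
  keep <- complete.cases(x)
  x <- x[keep, , drop = FALSE]; is_pos <- is_pos[keep]
  n <- nrow(x)
  if (cv$scheme == "kfold" && cv$stratified && min(sum(is_pos), sum(!is_pos)) < cv$k) {
    abort("Each class needs at least k subjects for stratified k-fold.",
          class = "oscillab_validation_error")
  }
  folds <- assign_folds(is_pos, cv)
  out <- vector("list", max(folds))
  for (f in sort(unique(folds))) {
    te <- which(folds == f); tr <- which(folds != f)
    if (length(unique(is_pos[tr])) < 2L) {
      warn(sprintf("Fold %d skipped: training data contains a single class.", f))
      next
    }
    xtr <- x[tr, , drop = FALSE]; xte <- x[te, , drop = FALSE]
    if (spec$standardize) {
      mu <- colMeans(xtr)
      sg <- apply(xtr, 2, sd); sg[sg == 0] <- 1
      xtr <- sweep(sweep(xtr, 2, mu), 2, sg, `/`)
      xte <- sweep(sweep(xte, 2, mu), 2, sg, `/`)
    }
    s <- fit_and_score(spec, xtr, is_pos[tr], xte,
                       seed = derive_seed(cv$seed, f, 7L))
    out[[f]] <- tibble::tibble(row = te, fold = f, score = as.numeric(s),
                               label = ifelse(is_pos[te], "pos", "neg"))
  }
  pooled <- dplyr::bind_rows(out)
  if (nrow(pooled) == 0L || length(unique(pooled$label)) < 2L) {
    abort("No usable out-of-fold scores.", class = "oscillab_class_error")
  }
  curve <- roc_auc(pooled$score, pooled$label, positive = "pos", orient = FALSE)
  cut <- optimal_cutoff(curve)
  structure(
    list(auc = curve$auc, se = cut$se, sp = cut$sp, cutoff = cut$cutoff,
         direction = cut$direction, scores = pooled, features = features,
         classifier = spec, cv = cv, roc = curve),
    class = "fot_cv_result"
  )
}

#' @export
print.fot_cv_result <- function(x, ...) {
  cat("<fot_cv_result>", x$classifier$name, "on {",
      paste(x$features, collapse = ", "), "}\n")
  cat(sprintf("  AUC = %.3f  Se = %.1f%%  Sp = %.1f%% (%s, %s)\n",
              x$auc, x$se, x$sp, x$cv$scheme,
              if (x$cv$scheme == "kfold") paste0("k=", x$cv$k) else "k=n"))
  invisible(x)
}

#' @describeIn cross_validate Out-of-fold scores as a tibble.
#' @param x A `fot_cv_result`.
#' @param ... Unused.
#' @exportS3Method
tidy.fot_cv_result <- function(x, ...) x$scores

#' @describeIn cross_validate One-row performance summary.
#' @exportS3Method
glance.fot_cv_result <- function(x, ...) {
  tibble::tibble(classifier = x$classifier$name,
                 features = paste(x$features, collapse = "+"),
                 scheme = x$cv$scheme, auc = x$auc, se = x$se, sp = x$sp,
                 cutoff = x$cutoff, direction = x$direction)
}

#' Exhaustive search over oscillometry feature subsets
#'
#' Evaluates every non-empty subset of the candidate features with
#' [cross_validate()] (same classifier, same folds) and returns the subset
#' with the highest cross-validated AUC. Ties are broken toward the smaller
#' subset and then toward the earlier subset in lexicographic feature
#' order. With the eight oscillometry parameters this enumerates
#' 2^8 - 1 = 255 subsets. The selection happens outside the
#' cross-validation loop, so the winning AUC carries the usual optimistic
#' selection bias; treat it as a model-selection score, not an unbiased
#' performance estimate.
#'
#' @inheritParams cross_validate
#' @param candidate_features Candidate feature columns (at most 20).
#' @return A list of class `fot_search_result`: `best_features`, `best`
#'   (its `fot_cv_result`), `n_subsets`, and `results` (tibble of every
#'   subset's AUC).
#' @export
exhaustive_search <- function(spec, data, candidate_features, cv = cv_spec(),
                              positive, group = "group") {
  p <- length(candidate_features)
  if (p < 1L || p > 20L) {
    abort("Exhaustive search supports 1 to 20 candidate features.",
          class = "oscillab_combinatorial_error")
  }
  subsets <- unlist(
    lapply(seq_len(p), function(k) {
      m <- combn(candidate_features, k)
      lapply(seq_len(ncol(m)), function(j) m[, j])
    }),
    recursive = FALSE
  )
  evals <- purrr::map(subsets, function(fs) {
    cross_validate(spec, data, fs, cv = cv, positive = positive, group = group)
  })
  aucs <- purrr::map_dbl(evals, "auc")
  best_i <- which.max(aucs)  # subsets are ordered by size then lexicographic
  structure(
    list(best_features = subsets[[best_i]], best = evals[[best_i]],
         n_subsets = length(subsets),
         results = tibble::tibble(
           subset = purrr::map_chr(subsets, paste, collapse = "+"),
           size = lengths(subsets), auc = aucs
         )),
    class = "fot_search_result"
  )
}

#' @export
print.fot_search_result <- function(x, ...) {
  cat("<fot_search_result>", x$n_subsets, "subsets evaluated\n")
  cat("  best: {", paste(x$best_features, collapse = ", "), "} AUC =",
      round(x$best$auc, 3), "\n")
  invisible(x)
}

#' @describeIn exhaustive_search All subset AUCs as a tibble.
#' @param x A `fot_search_result`.
#' @param ... Unused.
#' @exportS3Method
tidy.fot_search_result <- function(x, ...) x$results

#' @describeIn exhaustive_search Winning subset summary.
#' @exportS3Method
glance.fot_search_result <- function(x, ...) {
  dplyr::mutate(glance(x$best), n_subsets = x$n_subsets)
}
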