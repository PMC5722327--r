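#' Empirical ROC curve and Mann-Whitney AUC
#'
#' Builds the empirical ROC curve of a continuous score against a binary
#' outcome and computes the area under it with the Mann-Whitney
#' pair-counting statistic (ties count 1/2), which equals the trapezoidal
#' area under the empirical curve exactly. The curve is auto-oriented so
#' that AUC >= 0.5: when the raw score discriminates in the "lower is
#' diseased" direction the sign is flipped internally and the orientation
#' recorded.
#'
#' @param scores Numeric scores.
#' @param labels Class labels (any type with two values present).
#' @param positive The label value regarded as diseased/positive.
#' @param orient Auto-orient the curve so AUC >= 0.5 (default). Set to
#'   `FALSE` when the score's direction is fixed by construction, e.g. for
#'   pooled cross-validated classifier scores, where auto-orientation would
#'   bias an uninformative AUC above 0.5.
#' @return An object of class `fot_roc`: a list with `points` (tibble of
#'   `threshold` on the oriented scale, `fpr`, `tpr`, `se`, `sp`, `youden`
#'   in percent), `auc`, `orientation`, counts and the oriented scores.
#' @examples
#' roc_auc(c(4, 5, 6, 1, 2, 3), rep(c("d", "c"), each = 3), positive = "d")
#' @export
roc_auc <- function(scores, labels, positive, orient = TRUE) {
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  is_pos <- labels == positive
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L) {
    abort("Both classes must be present.", class = "oscillab_class_error")
  }
  mw_auc <- function(s) {
    r <- rank(s)  # midranks handle ties as 1/2
    (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }
  auc <- mw_auc(scores)
  orientation <- "higher_is_positive"
  os <- scores
  if (orient && auc < 0.5) {
    orientation <- "lower_is_positive"
    os <- -scores
    auc <- mw_auc(os)
  }
  u <- sort(unique(os), decreasing = TRUE)
  thr <- c(Inf, u)
  # integer counts keep threshold comparisons exact (no floating-point ties)
  tp <- vapply(thr, function(t) sum(os[is_pos] >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(os[!is_pos] >= t), numeric(1))
  tpr <- tp / n_pos
  fpr <- fp / n_neg
  points <- tibble::tibble(
    threshold = thr, tp = tp, fp = fp, fpr = fpr, tpr = tpr,
    se = 100 * tpr, sp = 100 * (1 - fpr), youden = 100 * (tpr - fpr)
  )
  structure(
    list(points = points, auc = auc, orientation = orientation,
         positive = positive, n_pos = n_pos, n_neg = n_neg,
         oriented_scores = os, is_pos = is_pos),
    class = "fot_roc"
  )
}

#' @export
print.fot_roc <- function(x, ...) {
  cat("<fot_roc> AUC =", round(x$auc, 4), "(", x$orientation, ")",
      "n+ =", x$n_pos, "n- =", x$n_neg, "\n")
  invisible(x)
}

#' Optimal diagnostic cut-off by Youden's index
#'
#' Selects the threshold maximizing Youden's J = Se + Sp - 100 (percent
#' scale) on the empirical ROC. Ties are broken toward higher specificity,
#' then toward the lower threshold. The reported cut-off is the midpoint
#' between the selected observed score and the next smaller one, expressed
#' in the feature's natural units together with the decision direction.
#'
#' @param curve A `fot_roc`.
#' @return A one-row tibble with `cutoff` (natural units), `direction`
#'   (`">="` positive when the score is at or above the cut-off, `"<="`
#'   for the flipped orientation), `se`, `sp` (percent) and `youden`.
#' @export
optimal_cutoff <- function(curve) {
  stopifnot(inherits(curve, "fot_roc"))
  pts <- curve$points[is.finite(curve$points$threshold), ]
  # rank by exact integer pair counts so ties in Youden's J are broken by
  # specificity as documented, not by floating-point rounding noise
  j_exact <- pts$tp * curve$n_neg - pts$fp * curve$n_pos
  ord <- order(-j_exact, pts$fp, pts$threshold)
  best <- pts[ord[1], ]
  u <- sort(unique(curve$oriented_scores), decreasing = TRUE)
  i <- match(best$threshold, u)
  cut_oriented <- if (!is.na(i) && i < length(u)) (u[i] + u[i + 1]) / 2 else best$threshold
  if (curve$orientation == "higher_is_positive") {
    cutoff <- cut_oriented; direction <- ">="
  } else {
    cutoff <- -cut_oriented; direction <- "<="
  }
  tibble::tibble(cutoff = cutoff, direction = direction,
                 se = best$se, sp = best$sp, youden = best$youden)
}

#' Diagnostic-accuracy band of an AUC
#'
#' Labels an (oriented) AUC with the conventional accuracy bands: 0.50 to
#' 0.70 low, 0.70 to 0.90 moderate, 0.90 to 1.00 high, with boundaries
#' closed on the left (0.70 is moderate, 0.90 is high). An AUC of at least
#' 0.75 is flagged as adequate for clinical use.
#'
#' @param auc AUC value(s) in `[0.5, 1]`.
#' @return A tibble with `auc`, `band`, `adequate`.
#' @examples
#' auc_band(c(0.82, 0.95, 0.70))
#' @export
auc_band <- function(auc) {
  if (any(auc < 0.5 | auc > 1 + 1e-12)) {
    abort("AUC must lie in [0.5, 1]; auto-orient the curve first.",
          class = "oscillab_orientation_error")
  }
  tibble::tibble(
    auc = auc,
    band = dplyr::case_when(auc < 0.70 ~ "low", auc < 0.90 ~ "moderate", TRUE ~ "high"),
    adequate = auc >= 0.75
  )
}

#' Hanley-McNeil standard error of an empirical AUC
#'
#' \eqn{SE^2 = [A(1-A) + (n_+-1)(Q_1-A^2) + (n_--1)(Q_2-A^2)] /
#' (n_+ n_-)} with \eqn{Q_1 = A/(2-A)} and \eqn{Q_2 = 2A^2/(1+A)}.
#'
#' @param auc AUC value.
#' @param n_pos,n_neg Group sizes.
#' @return Standard error of the AUC.
#' @export
hanley_mcneil_se <- function(auc, n_pos, n_neg) {
  stopifnot(auc >= 0, auc <= 1, n_pos >= 1, n_neg >= 1)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) + (n_neg - 1) * (q2 - auc^2)) /
         (n_pos * n_neg))
}

hm_variance_kernel <- function(auc) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  q1 + q2 - 2 * auc^2
}

#' Minimum sample size to detect an AUC by the Hanley-McNeil method
#'
#' Smallest equal per-group size n such that the normal-approximation test
#' of AUC = `auc_null` against the alternative `auc_alt` attains the stated
#' type I and type II errors, with the Hanley-McNeil AUC variance kernel
#' \eqn{v(A) = Q_1 + Q_2 - 2A^2} evaluated under the null and the
#' alternative (per-group variance `v(A)/n` at equal sizes). The smallest
#' n is found by iterating upward over the power inequality
#' \deqn{A_1 - A_0 \ge z_\alpha \sqrt{v(A_0)/n} + z_\beta \sqrt{v(A_1)/n}.}
#'
#' Whether the type I error is spent one- or two-sided is configurable;
#' with the defaults (detecting adequate accuracy, AUC 0.75, against no
#' discrimination at alpha = beta = 0.10) the two-sided convention yields
#' 20 subjects per group and the one-sided convention 15.
#'
#' @param auc_alt Alternative AUC, in (`auc_null`, 1].
#' @param auc_null Null AUC, in `[0.5, auc_alt`).
#' @param alpha Type I error.
#' @param beta Type II error.
#' @param sided `"two"` (default) or `"one"`.
#' @return Smallest per-group n (integer).
#' @examples
#' hanley_mcneil_min_n()                 # 20
#' hanley_mcneil_min_n(sided = "one")    # 15
#' @export
hanley_mcneil_min_n <- function(auc_alt = 0.75, auc_null = 0.5,
                                alpha = 0.10, beta = 0.10,
                                sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (!(auc_null >= 0.5 && auc_null < auc_alt && auc_alt <= 1)) {
    abort("Require 0.5 <= auc_null < auc_alt <= 1.", class = "oscillab_domain_error")
  }
  if (alpha <= 0 || alpha >= 1 || beta <= 0 || beta >= 1) {
    abort("alpha and beta must lie in (0, 1).", class = "oscillab_domain_error")
  }
  za <- if (sided == "two") qnorm(1 - alpha / 2) else qnorm(1 - alpha)
  zb <- qnorm(1 - beta)
  delta <- auc_alt - auc_null
  v0 <- hm_variance_kernel(auc_null)
  v1 <- hm_variance_kernel(auc_alt)
  n <- 2L
  while (delta < za * sqrt(v0 / n) + zb * sqrt(v1 / n)) {
    n <- n + 1L
    if (n > 1e7) abort("Sample-size search did not converge.", class = "oscillab_domain_error")
  }
  n
}

#' @describeIn hanley_mcneil_min_n Both sidedness conventions as a tibble.
#' @export
hanley_mcneil_sample_sizes <- function(auc_alt = 0.75, auc_null = 0.5,
                                       alpha = 0.10, beta = 0.10) {
  tibble::tibble(
    sided = c("one", "two"),
    n_per_group = c(
      hanley_mcneil_min_n(auc_alt, auc_null, alpha, beta, sided = "one"),
      hanley_mcneil_min_n(auc_alt, auc_null, alpha, beta, sided = "two")
    )
  )
}

#' ROC analysis of one feature between two study groups
#'
#' Data-frame-first wrapper: extracts the feature for the positive
#' (diseased) and negative (reference) groups, builds the ROC with
#' [roc_auc()], and attaches the Youden cut-off, accuracy band and
#' Hanley-McNeil confidence interval.
#'
#' @param data Subject-level feature table.
#' @param feature Feature column name (string).
#' @param positive_group Group label regarded as diseased.
#' @param negative_group Reference group label; defaults to all other rows.
#' @param group Group column name.
#' @param conf_level Confidence level for the AUC interval.
#' @return A `fot_roc` with an added `summary` element (one-row tibble:
#'   `feature`, `auc`, `auc_se`, `ci_lower`, `ci_upper`, `band`,
#'   `adequate`, `cutoff`, `direction`, `se`, `sp`).
#' @export
roc_analysis <- function(data, feature, positive_group, negative_group = NULL,
                         group = "group", conf_level = 0.95) {
  stopifnot(is.data.frame(data), feature %in% names(data), group %in% names(data))
  g <- as.character(data[[group]])
  keep <- if (is.null(negative_group)) rep(TRUE, nrow(data)) else g %in% c(positive_group, negative_group)
  scores <- data[[feature]][keep]
  labels <- ifelse(g[keep] == positive_group, "positive", "negative")
  curve <- roc_auc(scores, labels, positive = "positive")
  cut <- optimal_cutoff(curve)
  acc <- auc_band(curve$auc)
  se_auc <- hanley_mcneil_se(curve$auc, curve$n_pos, curve$n_neg)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  curve$summary <- tibble::tibble(
    feature = feature, auc = curve$auc, auc_se = se_auc,
    ci_lower = max(0, curve$auc - zq * se_auc),
    ci_upper = min(1, curve$auc + zq * se_auc),
    band = acc$band, adequate = acc$adequate,
    cutoff = cut$cutoff, direction = cut$direction, se = cut$se, sp = cut$sp
  )
  curve
}

#' @describeIn roc_auc ROC points as a tibble.
#' @param x A `fot_roc`.
#' @param ... Unused.
#' @exportS3Method
tidy.fot_roc <- function(x, ...) x$points

#' @describeIn roc_auc One-row AUC / cut-off summary.
#' @exportS3Method
glance.fot_roc <- function(x, ...) {
  if (!is.null(x$summary)) return(x$summary)
  cut <- optimal_cutoff(x)
  dplyr::bind_cols(auc_band(x$auc), cut)
}

#' @describeIn roc_auc Plot the empirical ROC curve.
#' @param object A `fot_roc`.
#' @exportS3Method
autoplot.fot_roc <- function(object, ...) {
  pts <- dplyr::arrange(object$points, .data$fpr, .data$tpr)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - Specificity", y = "Sensitivity",
                  title = sprintf("AUC = %.3f", object$auc))
}
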