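shapiro_pass <- function(x, alpha) {
  p <- tryCatch(shapiro.test(x)$p.value, error = function(e) NA_real_)
  list(p = p, pass = is.finite(p) && p > alpha)
}

#' Compare a feature across study groups
#'
#' Normality-gated three-group comparison: Shapiro-Wilk is applied per
#' group; when every group is compatible with normality the feature is
#' compared with one-way ANOVA followed by Tukey's HSD pairwise test,
#' otherwise with Kruskal-Wallis followed by pairwise Mann-Whitney tests.
#' Differences with p <= 0.05 (inclusive) are considered significant.
#' Pairwise p-values are reported raw; the number of pairwise comparisons
#' is recorded so users can apply their own multiplicity control.
#'
#' A group in which the statistic is undefined (e.g. a constant) fails the
#' normality gate and routes the comparison to the nonparametric branch.
#'
#' @param data A data frame of subjects.
#' @param feature Name of the numeric feature column (string).
#' @param group Name of the group label column (default `"group"`).
#' @param alpha Significance level (inclusive).
#' @param normality_alpha Level of the Shapiro-Wilk gate.
#' @return An object of class `fot_group_comparison`; see [tidy()] and
#'   [glance()] methods.
#' @export
compare_groups <- function(data, feature, group = "group", alpha = 0.05,
                           normality_alpha = 0.05) {
  stopifnot(is.data.frame(data), feature %in% names(data), group %in% names(data))
  x <- data[[feature]]
  g <- as.character(data[[group]])
  keep <- is.finite(x) & !is.na(g)
  x <- x[keep]; g <- g[keep]
  counts <- table(g)
  if (length(counts) < 2L) {
    abort("At least two groups are required.", class = "oscillab_insufficient_data_error")
  }
  if (any(counts < 3L)) {
    abort("Each group needs at least 3 observations.",
          class = "oscillab_insufficient_data_error")
  }
  levels_g <- names(counts)
  norm <- purrr::map_dfr(levels_g, function(l) {
    s <- shapiro_pass(x[g == l], normality_alpha)
    tibble::tibble(group = l, shapiro_p = s$p, normal = s$pass)
  })
  gf <- factor(g, levels = levels_g)
  if (all(norm$normal)) {
    test_used <- "anova_tukey"
    fit <- aov(x ~ gf)
    omnibus_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- TukeyHSD(fit)$gf
    pw <- tibble::tibble(
      contrast = rownames(tk),
      p = unname(tk[, "p adj"])
    )
  } else {
    test_used <- "kruskal_mannwhitney"
    omnibus_p <- kruskal.test(x, gf)$p.value
    pairs <- combn(levels_g, 2)
    pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      p <- suppressWarnings(wilcox.test(x[g == a], x[g == b], exact = FALSE)$p.value)
      tibble::tibble(contrast = paste(b, a, sep = "-"), p = p)
    })
  }
  structure(
    list(feature = feature, normality = norm, test_used = test_used,
         omnibus_p = omnibus_p, pairwise = pw,
         n_pairwise = nrow(pw), alpha = alpha,
         significant = is.finite(omnibus_p) && omnibus_p <= alpha),
    class = "fot_group_comparison"
  )
}

#' @export
print.fot_group_comparison <- function(x, ...) {
  cat("<fot_group_comparison>", x$feature, "\n")
  cat("  test:", x$test_used, " omnibus p =", format.pval(x$omnibus_p), "\n")
  print(x$pairwise)
  invisible(x)
}

#' @describeIn compare_groups Pairwise p-values as a tibble.
#' @param x A `fot_group_comparison`.
#' @param ... Unused.
#' @exportS3Method
tidy.fot_group_comparison <- function(x, ...) {
  dplyr::mutate(x$pairwise, feature = x$feature, test_used = x$test_used,
                .before = 1)
}

#' @describeIn compare_groups One-row summary.
#' @exportS3Method
glance.fot_group_comparison <- function(x, ...) {
  tibble::tibble(feature = x$feature, test_used = x$test_used,
                 omnibus_p = x$omnibus_p, n_pairwise = x$n_pairwise,
                 significant = x$significant)
}

#' Qualitative correlation strength band
#'
#' Assigns the conventional descriptive band from the absolute value of a
#' correlation coefficient: below 0.25 "small or no correlation", 0.25 to
#' 0.50 "reasonable", 0.50 to 0.75 "moderate to good", above 0.75
#' "very good to excellent". Boundaries are closed on the lower edge of the
#' higher band (|r| = 0.25 is "reasonable", etc.); banding is symmetric in
#' sign.
#'
#' @param r Correlation coefficient(s) in `[-1, 1]`.
#' @return Character vector of band labels.
#' @examples
#' correlation_band(c(0.1, -0.38, 0.54, 0.8))
#' @export
correlation_band <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    abort("|r| cannot exceed 1.", class = "oscillab_domain_error")
  }
  a <- abs(r)
  dplyr::case_when(
    a < 0.25 ~ "small or no correlation",
    a < 0.50 ~ "reasonable",
    a < 0.75 ~ "moderate to good",
    TRUE ~ "very good to excellent"
  )
}

#' Modified Bonferroni significance level for correlation analyses
#'
#' Divides the base significance level by an estimate of the effective
#' number of independent correlations: the number of independent
#' oscillometry dimensions (resistive and reactive, hence 2 by default)
#' times the number of independent variables in the comparator exams
#' (4 by default), giving 8 effective correlations and a reported corrected
#' level of 0.0063 at base 0.05. The reported value is rounded half-up to
#' 4 decimals; the raw quotient is retained.
#'
#' @param n_fot_vars Effective independent oscillometry variables.
#' @param n_other_vars Effective independent comparator variables.
#' @param base_alpha Uncorrected significance level.
#' @return A one-row tibble with `n_effective`, `alpha_raw`,
#'   `alpha_reported`.
#' @examples
#' corrected_alpha()           # 0.05 / 8 -> 0.0063
#' corrected_alpha(1, 1, 0.05) # no correction
#' @export
corrected_alpha <- function(n_fot_vars = 2, n_other_vars = 4, base_alpha = 0.05) {
  if (n_fot_vars < 1 || n_other_vars < 1 || n_fot_vars %% 1 != 0 || n_other_vars %% 1 != 0) {
    abort("Variable counts must be positive integers.", class = "oscillab_domain_error")
  }
  m <- n_fot_vars * n_other_vars
  raw <- base_alpha / m
  tibble::tibble(n_effective = as.integer(m), alpha_raw = raw,
                 alpha_reported = floor(raw * 1e4 + 0.5 + 1e-12) / 1e4)
}

#' Correlation between two subject-level variables
#'
#' Pearson's correlation when both variables are compatible with normality
#' (Shapiro-Wilk), Spearman's otherwise. The qualitative band and a flag
#' against the modified-Bonferroni corrected level are attached.
#'
#' @param x,y Paired numeric vectors (length >= 4 after removing
#'   incomplete pairs).
#' @param normality_alpha Level of the Shapiro-Wilk gate.
#' @param corrected_level Significance level for `passes_corrected_alpha`;
#'   defaults to the reported [corrected_alpha()] value.
#' @return A one-row tibble with `r`, `p`, `method`, `band`,
#'   `passes_corrected_alpha`, `n`.
#' @export
correlate_pair <- function(x, y, normality_alpha = 0.05,
                           corrected_level = corrected_alpha()$alpha_reported) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4L) {
    abort("At least 4 complete pairs are required.",
          class = "oscillab_insufficient_data_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation is undefined for a zero-variance variable.",
          class = "oscillab_degenerate_error")
  }
  method <- if (shapiro_pass(x, normality_alpha)$pass &&
                shapiro_pass(y, normality_alpha)$pass) "pearson" else "spearman"
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  r <- unname(ct$estimate)
  tibble::tibble(r = r, p = ct$p.value, method = method,
                 band = correlation_band(r),
                 passes_corrected_alpha = ct$p.value <= corrected_level,
                 n = length(x))
}

#' Correlate named feature columns of a table
#'
#' Data-frame-first wrapper around [correlate_pair()] for one or more pairs
#' of columns.
#'
#' @param data A data frame.
#' @param x,y Column names (strings, same length, recycled pairwise).
#' @param ... Passed to [correlate_pair()].
#' @return A tibble with one row per pair.
#' @export
correlate_features <- function(data, x, y, ...) {
  stopifnot(is.data.frame(data))
  purrr::map2_dfr(x, y, function(xi, yi) {
    dplyr::bind_cols(tibble::tibble(x = xi, y = yi),
                     correlate_pair(data[[xi]], data[[yi]], ...))
  })
}
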