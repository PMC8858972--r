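#' One-way ANOVA of a feature across fibrosis groups
#'
#' Classical fixed-effects one-way ANOVA (equal-variance F test,
#' df = k-1, N-k), with Tukey HSD post-hoc p-values for the two
#' adjacent-group contrasts (group1 vs group2, group2 vs group3).
#'
#' @param values Numeric feature values.
#' @param groups Group labels (3 levels expected for post-hoc contrasts).
#' @param posthoc Compute the Tukey contrasts (`TRUE`) or F/p only.
#' @return List of class `anova_result`: `f`, `p`, `df`, `group_means`,
#'   `p_g1g2`, `p_g2g3`.
#' @export
anova_f <- function(values, groups, posthoc = TRUE) {
  stopifnot(length(values) == length(groups))
  g <- factor(groups)
  if (any(table(g) < 2L))
    stop("each group needs at least 2 samples", call. = FALSE)
  if (stats::var(values) == 0)
    stop("degenerate feature: zero variance", call. = FALSE)
  fit <- stats::aov(values ~ g)
  tab <- summary(fit)[[1]]
  f <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  if (!is.finite(f)) {  # zero within-group variance but nonzero between
    f <- Inf; p <- 0
  }
  means <- tapply(values, g, mean)
  res <- list(f = f, p = p, df = c(nlevels(g) - 1L, length(values) - nlevels(g)),
              group_means = means, p_g1g2 = NA_real_, p_g2g3 = NA_real_)
  if (posthoc && nlevels(g) >= 3L && is.finite(tab[["F value"]][1])) {
    tk <- stats::TukeyHSD(fit)$g
    lv <- levels(g)
    nm12 <- paste(lv[2], lv[1], sep = "-")
    nm23 <- paste(lv[3], lv[2], sep = "-")
    if (nm12 %in% rownames(tk)) res$p_g1g2 <- tk[nm12, "p adj"]
    if (nm23 %in% rownames(tk)) res$p_g2g3 <- tk[nm23, "p adj"]
  }
  class(res) <- "anova_result"
  res
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d,%d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$f, x$p))
  invisible(x)
}

#' Univariate ANOVA screen of a cohort table
#'
#' Runs [anova_f()] on every feature and discards those with p > `alpha`
#' (no statistical difference among the three groups). Degenerate
#' (zero-variance) features are dropped with a warning. Optionally a
#' multiplicity correction can be applied to the screen p-values before
#' thresholding; the default screen uses raw p-values.
#'
#' @param cohort A `cohort_table` with a 3-level `group` column.
#' @param alpha Significance threshold of the F test.
#' @param adjust P-value adjustment method (see [stats::p.adjust()];
#'   default `"none"`).
#' @return List with `retained` (feature names), `results` (data frame of
#'   per-feature F, p, adjusted p, group means and post-hoc p-values) and
#'   `alpha`.
#' @export
filter_features <- function(cohort, alpha = 0.05, adjust = "none") {
  feats <- cohort_features(cohort)
  g <- factor(cohort$group)
  stopifnot(nlevels(g) == 3L)
  rows <- lapply(feats, function(f) {
    r <- tryCatch(anova_f(cohort[[f]], g),
                  error = function(e) {
                    warning(sprintf("feature '%s' excluded: %s",
                                    f, conditionMessage(e)), call. = FALSE)
                    NULL
                  })
    if (is.null(r)) return(NULL)
    data.frame(feature = f, f_stat = r$f, p = r$p,
               mean_group1 = r$group_means[[1]],
               mean_group2 = r$group_means[[2]],
               mean_group3 = r$group_means[[3]],
               p_g1g2 = r$p_g1g2, p_g2g3 = r$p_g2g3,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res) || nrow(res) == 0L)
    stop("no testable features in cohort", call. = FALSE)
  res$p_adj <- stats::p.adjust(res$p, method = adjust)
  res$retained <- res$p_adj <= alpha
  res$timing <- ifelse(res$retained,
                       vapply(seq_len(nrow(res)), function(i)
                         timing_class(res$p_g1g2[i], res$p_g2g3[i], alpha),
                         character(1)),
                       NA_character_)
  retained <- res$feature[res$retained]
  if (length(retained) == 0L)
    stop(paste("no features pass the ANOVA screen;",
               "check the data or (for synthetic cohorts) increase effect sizes"),
         call. = FALSE)
  list(retained = retained, results = res, alpha = alpha)
}

timing_class <- function(p12, p23, alpha) {
  s12 <- isTRUE(p12 <= alpha); s23 <- isTRUE(p23 <= alpha)
  if (s12 && s23) "both"
  else if (s12) "early"
  else if (s23) "late"
  else "indeterminate"
}

#' Timing classification of a screened feature
#'
#' Features that pass the overall screen are classified by which group
#' transition moves them: `early` if only the group1-vs-group2 post-hoc
#' contrast is significant, `late` if only group2-vs-group3, `both` if
#' both, and `indeterminate` if neither (possible when the overall F is
#' driven by the group1-vs-group3 contrast alone).
#'
#' @param result An `anova_result` with post-hoc p-values.
#' @param alpha Post-hoc significance threshold.
#' @return One of `"early"`, `"late"`, `"both"`, `"indeterminate"`.
#' @export
classify_timing <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "anova_result"))
  out <- timing_class(result$p_g1g2, result$p_g2g3, alpha)
  if (out == "indeterminate")
    message("no adjacent-group contrast significant; timing indeterminate")
  out
}

#' Write ANOVA screen results as TSV
#' @param screen Result of [filter_features()].
#' @param path File path.
#' @export
write_anova_results <- function(screen, path) {
  utils::write.table(screen$results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
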