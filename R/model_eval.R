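CV_SCHEMES <- c("apparent", "loocv", "subsample3fold", "repeated3fold")

#' Cross-validated classification scores
#'
#' Produces out-of-fold class-1 probability scores from a seeded random
#' forest under one of four schemes: `apparent` (train and score on all
#' data; optimistic by construction), `loocv` (leave-one-out),
#' `subsample3fold` (`reps` random stratified 2:1 train/test splits, scores
#' on each held-out third) and `repeated3fold` (`reps` repetitions of a
#' full stratified 3-fold partition, scores for every sample per
#' repetition). Folds are stratified by class throughout.
#'
#' @param X Feature matrix or data frame, samples in rows.
#' @param y Binary labels; the second factor level is the positive class.
#' @param scheme One of `"apparent"`, `"loocv"`, `"subsample3fold"`,
#'   `"repeated3fold"`.
#' @param reps Repetitions for the two repeated schemes.
#' @param ntree Trees per forest.
#' @param seed Integer seed.
#' @return List of class `cv_scores`: `scheme`, `labels` (0/1), `positive`
#'   (level name), and `scores` - a numeric vector (apparent, loocv) or an
#'   `n x reps` matrix (`NA` where a sample was in the training split).
#' @export
cv_scores <- function(X, y, scheme = CV_SCHEMES, reps = 200, ntree = 200,
                      seed = 1L) {
  scheme <- match.arg(scheme)
  X <- as.data.frame(X, check.names = FALSE)
  y <- droplevels(factor(y))
  if (nlevels(y) != 2L) stop("y must have exactly 2 classes", call. = FALSE)
  if (any(table(y) < 2L))
    stop("each class needs at least 2 samples for stratified folds",
         call. = FALSE)
  stopifnot(reps >= 1)
  pos <- levels(y)[2]
  n <- length(y)
  prob_pos <- function(train, test) {
    fit <- randomForest::randomForest(
      x = X[train, , drop = FALSE], y = y[train], ntree = ntree,
      mtry = max(1L, floor(sqrt(ncol(X)))))
    stats::predict(fit, X[test, , drop = FALSE], type = "prob")[, pos]
  }
  scores <- with_seed_(seed, switch(
    scheme,
    apparent = prob_pos(seq_len(n), seq_len(n)),
    loocv = vapply(seq_len(n), function(i)
      prob_pos(setdiff(seq_len(n), i), i), numeric(1)),
    subsample3fold = vapply(seq_len(reps), function(r) {
      folds <- stratified_folds(y, 3)
      test <- folds == 1L          # one random stratified third held out
      s <- rep(NA_real_, n)
      s[test] <- prob_pos(which(!test), which(test))
      s
    }, numeric(n)),
    repeated3fold = vapply(seq_len(reps), function(r) {
      folds <- stratified_folds(y, 3)
      s <- rep(NA_real_, n)
      for (f in 1:3)
        s[folds == f] <- prob_pos(which(folds != f), which(folds == f))
      s
    }, numeric(n))
  ))
  structure(list(scheme = scheme, scores = scores,
                 labels = as.integer(y == pos), positive = pos),
            class = "cv_scores")
}

#' AUC with a DeLong 95 percent confidence interval
#'
#' The AUC is the Mann-Whitney two-sample statistic (ties counted half);
#' the confidence interval uses DeLong's placement-value variance estimate,
#' clipped to `[0, 1]`.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (0/1, logical, or 2-level factor).
#' @return Named vector `auc, ci_lo, ci_hi`.
#' @examples
#' auc_ci(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # AUC 0.75
#' @export
auc_ci <- function(scores, labels) {
  lab <- as_binary_labels(labels)
  x <- scores[lab == 1L]; y <- scores[lab == 0L]
  if (length(x) == 0L || length(y) == 0L)
    stop("both classes must be present", call. = FALSE)
  # placement values: V10_i = P(score of case i exceeds a random control)
  cmp <- outer(x, y, ">") + 0.5 * outer(x, y, "==")
  v10 <- rowMeans(cmp)
  v01 <- colMeans(cmp)
  auc <- mean(v10)
  s10 <- if (length(x) > 1L) stats::var(v10) else 0
  s01 <- if (length(y) > 1L) stats::var(v01) else 0
  se <- sqrt(s10 / length(x) + s01 / length(y))
  z <- stats::qnorm(0.975)
  c(auc = auc,
    ci_lo = max(0, auc - z * se),
    ci_hi = min(1, auc + z * se))
}

as_binary_labels <- function(labels) {
  if (is.factor(labels) || is.character(labels)) {
    f <- droplevels(factor(labels))
    stopifnot(nlevels(f) == 2L)
    as.integer(f == levels(f)[2])
  } else {
    l <- as.integer(labels)
    stopifnot(all(l %in% c(0L, 1L)))
    l
  }
}

# threshold scan: classify score >= t as positive; returns one row per
# candidate threshold (observed scores plus +Inf)
threshold_scan <- function(scores, labels) {
  lab <- as_binary_labels(labels)
  ts <- c(sort(unique(scores)), Inf)
  do.call(rbind, lapply(ts, function(t) {
    pred <- as.integer(scores >= t)
    tp <- sum(pred == 1 & lab == 1); fp <- sum(pred == 1 & lab == 0)
    tn <- sum(pred == 0 & lab == 0); fn <- sum(pred == 0 & lab == 1)
    data.frame(threshold = t,
               sensitivity = tp / (tp + fn),
               specificity = tn / (tn + fp),
               tp = tp, fp = fp, tn = tn, fn = fn)
  }))
}

#' Sensitivity at a fixed specificity
#'
#' Among decision thresholds achieving specificity at least `target_spec`
#' on the observed scores (no ROC interpolation), reports the maximum
#' sensitivity. The attribute `"threshold"` carries the operating
#' threshold.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @param target_spec Required specificity (default 0.90).
#' @return Sensitivity in `[0, 1]`, with attribute `threshold`.
#' @export
sens_at_spec <- function(scores, labels, target_spec = 0.90) {
  scan <- threshold_scan(scores, labels)
  ok <- scan[scan$specificity >= target_spec, , drop = FALSE]
  if (nrow(ok) == 0L) {
    warning(sprintf("no threshold reaches specificity %.2f; returning 0",
                    target_spec), call. = FALSE)
    return(structure(0, threshold = Inf))
  }
  best <- ok[which.max(ok$sensitivity), ]
  structure(best$sensitivity, threshold = best$threshold)
}

# full operating-point metrics at the sens_at_spec threshold; prevalence
# defaults to the observed class-1 fraction
operating_metrics <- function(scores, labels, target_spec = 0.90,
                              prevalence = NULL) {
  lab <- as_binary_labels(labels)
  ss <- sens_at_spec(scores, lab, target_spec)
  t <- attr(ss, "threshold")
  scan <- threshold_scan(scores, lab)
  row <- scan[match(t, scan$threshold), ]
  prev <- if (is.null(prevalence)) mean(lab) else prevalence
  sens <- row$sensitivity; spec <- row$specificity
  ppv <- sens * prev / (sens * prev + (1 - spec) * (1 - prev))
  npv <- spec * (1 - prev) / (spec * (1 - prev) + (1 - sens) * prev)
  auc <- auc_ci(scores, lab)
  c(auc = unname(auc["auc"]), ci_lo = unname(auc["ci_lo"]),
    ci_hi = unname(auc["ci_hi"]),
    accuracy = (row$tp + row$tn) / (row$tp + row$tn + row$fp + row$fn),
    sensitivity = sens, specificity = spec,
    ppv = if (is.nan(ppv)) NA_real_ else ppv,
    npv = if (is.nan(npv)) NA_real_ else npv)
}

# per-scheme metrics from a cv_scores object; repeated schemes are
# summarized as the mean over repetitions (SD kept for the AUC)
scheme_metrics <- function(cv, target_spec = 0.90, prevalence = NULL) {
  if (is.matrix(cv$scores)) {
    per_rep <- apply(cv$scores, 2, function(s) {
      keep <- !is.na(s)
      if (length(unique(cv$labels[keep])) < 2L) return(rep(NA_real_, 8))
      operating_metrics(s[keep], cv$labels[keep], target_spec, prevalence)
    })
    m <- rowMeans(per_rep, na.rm = TRUE)
    names(m) <- c("auc", "ci_lo", "ci_hi", "accuracy", "sensitivity",
                  "specificity", "ppv", "npv")
    c(m, auc_sd = stats::sd(per_rep["auc", ], na.rm = TRUE))
  } else {
    c(operating_metrics(cv$scores, cv$labels, target_spec, prevalence),
      auc_sd = NA_real_)
  }
}

# the pairwise comparisons evaluated: adjacent and extreme fibrosis groups,
# plus (when METAVIR stages are recorded) the alternate stage regrouping
group_comparisons <- function(cohort, regroup = TRUE) {
  cmp <- list(
    group1_vs_group2 = list(neg = cohort$group == "group1",
                            pos = cohort$group == "group2"),
    group2_vs_group3 = list(neg = cohort$group == "group2",
                            pos = cohort$group == "group3"),
    group1_vs_group3 = list(neg = cohort$group == "group1",
                            pos = cohort$group == "group3"))
  if (regroup) {
    if (all(is.na(cohort$stage))) {
      warning("no METAVIR stage recorded; skipping stage regrouping",
              call. = FALSE)
    } else {
      st <- cohort$stage
      cmp$stage01_vs_stage23 <- list(neg = st %in% c("healthy", "0", "1"),
                                     pos = st %in% c("2", "3"))
      cmp$stage23_vs_stage4 <- list(neg = st %in% c("2", "3"),
                                    pos = st == "4")
    }
  }
  cmp
}

#' Evaluate a glycan panel on all pairwise group comparisons
#'
#' For each comparison (group1 vs group2, group2 vs group3, group1 vs
#' group3, and optionally the METAVIR stage regrouping 0&1 vs 2&3 and
#' 2&3 vs 4) a binary random-forest model on the panel features is scored
#' under the requested cross-validation schemes. Each scheme reports AUC
#' with a DeLong 95 percent CI, and accuracy, sensitivity, specificity, PPV and
#' NPV at the maximum-sensitivity threshold achieving the target
#' specificity (PPV/NPV from observed prevalence unless overridden).
#'
#' @param cohort A `cohort_table`.
#' @param panel Character vector of feature names to model.
#' @param schemes Subset of the four CV schemes.
#' @param reps Repetitions for the repeated schemes.
#' @param ntree Trees per forest.
#' @param target_spec Operating-point specificity.
#' @param prevalence Optional prevalence override for PPV/NPV.
#' @param regroup Also evaluate the stage regrouping when stages exist.
#' @param keep_scores Retain score vectors for ROC plotting.
#' @param seed Integer seed.
#' @return List of `eval_report` objects, one per comparison, each with
#'   `comparison`, `n_neg`, `n_pos`, `metrics` (one row per scheme) and
#'   optionally `scores`.
#' @export
evaluate_groupings <- function(cohort, panel, schemes = CV_SCHEMES,
                               reps = 200, ntree = 200, target_spec = 0.90,
                               prevalence = NULL, regroup = TRUE,
                               keep_scores = FALSE, seed = 1L) {
  schemes <- match.arg(schemes, several.ok = TRUE)
  missing <- setdiff(panel, cohort_features(cohort))
  if (length(missing))
    stop("panel features absent from cohort: ",
         paste(missing, collapse = ", "), call. = FALSE)
  cmps <- group_comparisons(cohort, regroup)
  out <- lapply(names(cmps), function(nm) {
    sel <- cmps[[nm]]
    keep <- sel$neg | sel$pos
    X <- cohort_matrix(cohort[keep, , drop = FALSE], panel)
    y <- factor(ifelse(sel$pos[keep], "pos", "neg"), levels = c("neg", "pos"))
    rows <- list(); score_sets <- list()
    for (i in seq_along(schemes)) {
      sc <- schemes[i]
      cv <- cv_scores(X, y, scheme = sc, reps = reps, ntree = ntree,
                      seed = seed + i)
      m <- scheme_metrics(cv, target_spec, prevalence)
      rows[[sc]] <- data.frame(scheme = sc, t(m), check.names = FALSE,
                               stringsAsFactors = FALSE)
      if (keep_scores) score_sets[[sc]] <- cv
    }
    structure(list(comparison = nm, n_neg = sum(sel$neg & keep),
                   n_pos = sum(sel$pos & keep),
                   target_spec = target_spec,
                   metrics = do.call(rbind, rows),
                   scores = if (keep_scores) score_sets else NULL),
              class = "eval_report")
  })
  names(out) <- names(cmps)
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s (n=%d vs %d)\n", x$comparison,
              x$n_neg, x$n_pos))
  m <- x$metrics
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-15s AUC %.4f (95%%CI %.4f-%.4f)  sens %.0f%% @ %.0f%% spec\n",
                m$scheme[i], m$auc[i], m$ci_lo[i], m$ci_hi[i],
                100 * m$sensitivity[i], 100 * x$target_spec))
  invisible(x)
}

#' Write evaluation reports (JSON + TSV summary)
#' @param reports List of `eval_report` from [evaluate_groupings()].
#' @param json_path,tsv_path Output paths (`NULL` to skip one).
#' @export
write_eval_reports <- function(reports, json_path = NULL, tsv_path = NULL) {
  summary <- do.call(rbind, lapply(reports, function(r)
    data.frame(comparison = r$comparison, n_neg = r$n_neg, n_pos = r$n_pos,
               r$metrics, check.names = FALSE, row.names = NULL)))
  if (!is.null(json_path))
    jsonlite::write_json(
      lapply(reports, function(r) r[c("comparison", "n_neg", "n_pos",
                                      "target_spec", "metrics")]),
      json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows",
      pretty = TRUE)
  if (!is.null(tsv_path))
    utils::write.table(summary, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(summary)
}

#' ROC curve coordinates for plotting
#' @param scores,labels As in [auc_ci()].
#' @return Data frame `threshold, sensitivity, specificity`.
#' @export
roc_coordinates <- function(scores, labels) {
  threshold_scan(scores, labels)[, c("threshold", "sensitivity", "specificity")]
}
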