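# phi(a, b) comparison matrix for Hoeffding's bivariate rank Q:
# M[i, j] = 1 if v_j < v_i, 1/2 if v_j == v_i, 0 otherwise.
hoeffding_cmp <- function(v) {
  outer(v, v, ">") + 0.5 * outer(v, v, "==")
}

hoeffding_from_cmp <- function(A, B, R, S, n) {
  # Q_i = sum_{j != i} phi(x_j, x_i) phi(y_j, y_i); the self term is
  # phi()^2 = 1/4 and is subtracted.
  Q <- rowSums(A * B) - 0.25
  D1 <- sum(Q * (Q - 1))
  D2 <- sum((R - 1) * (R - 2) * (S - 1) * (S - 2))
  D3 <- sum((R - 2) * (S - 2) * Q)
  30 * ((n - 2) * (n - 3) * D1 + D2 - 2 * (n - 2) * D3) /
    (n * (n - 1) * (n - 2) * (n - 3) * (n - 4))
}

#' Hoeffding's D statistic of dependence
#'
#' Scaled rank statistic measuring deviation from bivariate independence.
#' Ranks are midranks; the bivariate rank `Q` uses the standard half-weight
#' convention for ties in either coordinate (quarter weight when tied in
#' both). The scaled statistic lies in `[-0.5, 1]` and equals 1 for any
#' strictly monotone relationship, regardless of direction.
#'
#' @param x,y Numeric vectors of equal length, `n >= 5`.
#' @return Scaled D.
#' @examples
#' hoeffding_d(1:5, c(5, 4, 3, 2, 1))  # 1: perfectly dependent
#' @export
hoeffding_d <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  n <- length(x)
  if (n < 5L) stop("Hoeffding's D requires n >= 5", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("degenerate variable (all ties)", call. = FALSE)
  R <- rank(x); S <- rank(y)
  hoeffding_from_cmp(hoeffding_cmp(x), hoeffding_cmp(y), R, S, n)
}

#' Pairwise Hoeffding-D similarity matrix
#'
#' The "variable clustering" similarity used for panel pruning: off-diagonal
#' entries are pairwise scaled D, the diagonal is 1 by convention.
#' Degenerate (constant) features are excluded with a warning.
#'
#' @param X Numeric matrix or data frame, samples in rows, features in
#'   columns (named).
#' @return Symmetric matrix of scaled D with unit diagonal.
#' @export
similarity_matrix <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 5L) stop("need at least 5 samples", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  keep <- apply(X, 2, function(v) length(unique(v)) > 1L)
  if (any(!keep))
    warning("excluding degenerate feature(s): ",
            paste(colnames(X)[!keep], collapse = ", "), call. = FALSE)
  X <- X[, keep, drop = FALSE]
  p <- ncol(X)
  if (p < 2L) stop("need at least 2 non-degenerate features", call. = FALSE)
  cmp <- lapply(seq_len(p), function(j) hoeffding_cmp(X[, j]))
  rk <- apply(X, 2, rank)
  D <- diag(1, p)
  dimnames(D) <- list(colnames(X), colnames(X))
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    D[i, j] <- D[j, i] <-
      hoeffding_from_cmp(cmp[[i]], cmp[[j]], rk[, i], rk[, j], n)
  }
  D
}

#' Most similar feature pair
#'
#' Argmax over off-diagonal similarity entries; exact ties broken by
#' lexicographic order of the (sorted) feature-name pair, so the result is
#' deterministic.
#'
#' @param sim Symmetric similarity matrix with feature names.
#' @return Character vector of the two feature names, lexicographically
#'   ordered, with attribute `"similarity"`.
#' @export
most_correlated_pair <- function(sim) {
  stopifnot(is.matrix(sim), nrow(sim) >= 2L, !is.null(rownames(sim)))
  p <- nrow(sim)
  best <- NULL; best_val <- -Inf
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    pair <- sort(c(rownames(sim)[i], colnames(sim)[j]))
    v <- sim[i, j]
    if (v > best_val ||
        (v == best_val && paste(pair, collapse = "\r") <
           paste(best, collapse = "\r"))) {
      best <- pair; best_val <- v
    }
  }
  structure(best, similarity = best_val)
}

#' Random-forest feature importance
#'
#' Out-of-bag permutation importance (mean decrease in accuracy) from a
#' seeded random forest. Negative raw importances (pure-noise features) are
#' floored at zero; the raw values are kept in attribute `"raw"`.
#'
#' @param X Feature matrix or data frame, samples in rows.
#' @param y Class labels (2 or more classes present).
#' @param ntree Number of trees.
#' @param seed Integer seed.
#' @return Named nonnegative importance vector.
#' @export
rf_importance <- function(X, y, ntree = 500, seed = 1L) {
  X <- as.data.frame(X, check.names = FALSE)
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2L)
    stop("y must contain at least 2 classes", call. = FALSE)
  with_seed_(seed, {
    fit <- randomForest::randomForest(
      x = X, y = y, ntree = ntree,
      mtry = max(1L, floor(sqrt(ncol(X)))), importance = TRUE)
    raw <- fit$importance[, "MeanDecreaseAccuracy"]
    structure(pmax(raw, 0), raw = raw)
  })
}

# mean accuracy (%) over `reps` repetitions of stratified 3-fold CV with a
# random forest; used as the stopping metric of the elimination loop
repeated_kfold_accuracy <- function(X, y, reps = 5, k = 3, ntree = 200,
                                    seed = 1L) {
  X <- as.data.frame(X, check.names = FALSE)
  y <- factor(y)
  with_seed_(seed, {
    accs <- vapply(seq_len(reps), function(r) {
      folds <- stratified_folds(y, k)
      pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
      for (f in seq_len(k)) {
        test <- folds == f
        fit <- randomForest::randomForest(
          x = X[!test, , drop = FALSE], y = y[!test], ntree = ntree,
          mtry = max(1L, floor(sqrt(ncol(X)))))
        pred[test] <- stats::predict(fit, X[test, , drop = FALSE])
      }
      mean(pred == y) * 100
    }, numeric(1))
    mean(accs)
  })
}

# fold assignment 1..k, stratified within class, random within strata
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Iterative panel pruning by similarity and importance
#'
#' Implements the panel-reduction loop: repeatedly (1) find the most
#' similar remaining feature pair by Hoeffding's D, (2) rank all remaining
#' features by random-forest importance, (3) discard the pair member with
#' the lower importance, (4) score the reduced panel by repeated stratified
#' 3-fold cross-validated accuracy. The loop stops when the accuracy has
#' fallen more than `delta` percentage points below the best mean accuracy
#' seen, for `patience` consecutive iterations, or when `min_features`
#' remain; the best-scoring panel (ties favouring fewer features) is
#' returned, not the last.
#'
#' The full similarity matrix is computed once and subset as features drop
#' out (the D statistic of a pair does not depend on the other features).
#'
#' @param X Feature matrix or data frame (typically the ANOVA-retained
#'   features), samples in rows, named columns.
#' @param y Group labels.
#' @param min_features Stop when this many features remain.
#' @param delta Tolerated accuracy drop in percentage points.
#' @param patience Consecutive below-tolerance iterations before stopping.
#' @param ntree Trees for the importance forest.
#' @param eval_reps,eval_ntree Repetitions and trees of the CV scoring.
#' @param seed Integer seed controlling the whole procedure.
#' @return List of class `selection_trace`: `panel` (retained feature
#'   names), `best_accuracy`, `initial_accuracy`, and `trace` (one row per
#'   iteration: eliminated feature, its importance, the partner kept, pair
#'   similarity, CV accuracy of the reduced panel, features remaining).
#' @export
iterative_elimination <- function(X, y, min_features = 5, delta = 2,
                                  patience = 2, ntree = 500,
                                  eval_reps = 5, eval_ntree = 200,
                                  seed = 1L) {
  X <- as.data.frame(X, check.names = FALSE)
  stopifnot(!is.null(colnames(X)))
  y <- factor(y)
  sim_full <- similarity_matrix(X)
  remaining <- colnames(sim_full)   # degenerate columns already dropped
  X <- X[, remaining, drop = FALSE]

  acc0 <- repeated_kfold_accuracy(X, y, reps = eval_reps, ntree = eval_ntree,
                                  seed = seed)
  best_acc <- acc0; best_panel <- remaining
  bad_streak <- 0L
  trace <- list()
  it <- 0L
  while (length(remaining) > min_features) {
    it <- it + 1L
    sim <- sim_full[remaining, remaining, drop = FALSE]
    pair <- most_correlated_pair(sim)
    imp <- rf_importance(X[, remaining, drop = FALSE], y, ntree = ntree,
                         seed = seed + it)
    # drop the lower-importance member; exact tie -> drop the
    # lexicographically later name
    drop <- if (imp[pair[1]] < imp[pair[2]]) pair[1]
            else if (imp[pair[2]] < imp[pair[1]]) pair[2]
            else pair[2]
    keep_partner <- setdiff(pair, drop)
    remaining <- setdiff(remaining, drop)
    acc <- repeated_kfold_accuracy(X[, remaining, drop = FALSE], y,
                                   reps = eval_reps, ntree = eval_ntree,
                                   seed = seed + 1000L + it)
    trace[[it]] <- data.frame(
      iteration = it, eliminated = drop,
      eliminated_importance = unname(imp[drop]),
      partner = keep_partner, partner_importance = unname(imp[keep_partner]),
      pair_similarity = unname(attr(pair, "similarity")),
      cv_accuracy = acc, n_remaining = length(remaining),
      stringsAsFactors = FALSE)
    if (acc >= best_acc) {       # ties favour the smaller panel
      best_acc <- acc; best_panel <- remaining; bad_streak <- 0L
    } else if (acc < best_acc - delta) {
      bad_streak <- bad_streak + 1L
      if (bad_streak >= patience) break
    } else {
      bad_streak <- 0L
    }
  }
  structure(list(panel = best_panel, best_accuracy = best_acc,
                 initial_accuracy = acc0,
                 trace = if (length(trace)) do.call(rbind, trace)
                         else data.frame()),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("<selection_trace> %d eliminations; best CV accuracy %.1f%% with %d features\n",
              nrow(x$trace), x$best_accuracy, length(x$panel)))
  cat("panel:", paste(x$panel, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a selection trace to JSON
#' @param trace A `selection_trace`.
#' @param path File path.
#' @export
write_selection_trace <- function(trace, path) {
  jsonlite::write_json(unclass(trace), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
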