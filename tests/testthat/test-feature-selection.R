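test_that("Hoeffding's D reproduces hand-ranked examples exactly", {
  # monotone: D1=20, D2=184, D3=50 -> D = 1
  expect_equal(hoeffding_d(1:5, 1:5), 1, tolerance = 1e-15)
  # dependence, not direction
  expect_equal(hoeffding_d(1:5, 5:1), 1, tolerance = 1e-15)
  # permutation with zero numerator: D1=12, D2=144, D3=36
  expect_equal(hoeffding_d(1:5, c(1, 3, 2, 5, 4)), 0, tolerance = 1e-15)
  expect_error(hoeffding_d(1:4, 1:4), "n >= 5")
  expect_error(hoeffding_d(rep(1, 6), 1:6), "degenerate")
})

test_that("Hoeffding's D agrees with the brute-force oracle, with ties", {
  set.seed(21)
  for (k in 1:30) {
    n <- sample(5:30, 1)
    if (k %% 2 == 0) {
      x <- sample(1:5, n, replace = TRUE)  # heavy ties
      y <- sample(1:4, n, replace = TRUE)
    } else {
      x <- rnorm(n); y <- rnorm(n)
    }
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(hoeffding_d(x, y), hoeffding_brute(x, y),
                 tolerance = 1e-12, info = paste("case", k))
  }
})

test_that("D is symmetric and invariant under increasing transforms", {
  set.seed(33)
  x <- rnorm(25); y <- x + rnorm(25, sd = 0.5)
  d <- hoeffding_d(x, y)
  expect_equal(hoeffding_d(y, x), d, tolerance = 1e-12)
  expect_equal(hoeffding_d(exp(x), y^3 + 2 * y), d, tolerance = 1e-12)
  expect_gte(d, -0.5); expect_lte(d, 1)
})

test_that("similarity matrix is symmetric with unit diagonal", {
  set.seed(5)
  X <- matrix(rnorm(200 * 6), 200, dimnames = list(NULL, paste0("f", 1:6)))
  X <- cbind(X, f7 = X[, "f1"])  # duplicated column
  S <- similarity_matrix(X)
  expect_equal(S, t(S))
  expect_equal(unname(diag(S)), rep(1, 7))
  expect_equal(S["f1", "f7"], 1, tolerance = 1e-12)
  # independent features: mean off-diagonal near 0
  off <- S[1:6, 1:6][upper.tri(diag(6))]
  expect_lt(abs(mean(off)), 0.01)
  # degenerate column dropped with warning
  X[, "f2"] <- 3
  expect_warning(S2 <- similarity_matrix(X), "degenerate")
  expect_false("f2" %in% rownames(S2))
})

test_that("most correlated pair is the argmax with lexicographic ties", {
  S <- diag(1, 3)
  dimnames(S) <- list(c("fa", "fb", "fc"), c("fa", "fb", "fc"))
  S["fa", "fc"] <- S["fc", "fa"] <- 0.8
  S["fa", "fb"] <- S["fb", "fa"] <- 0.3
  expect_equal(as.character(most_correlated_pair(S)), c("fa", "fc"))
  # exact tie -> lexicographically first pair
  S["fb", "fc"] <- S["fc", "fb"] <- 0.8
  expect_equal(as.character(most_correlated_pair(S)), c("fa", "fc"))
  expect_equal(attr(most_correlated_pair(S), "similarity"), 0.8)
})

test_that("importance singles out a perfectly separating feature", {
  set.seed(61)
  n <- 60
  y <- rep(c("a", "b"), each = n / 2)
  hits <- 0L
  for (s in 1:10) {
    X <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("f", 1:6)))
    X[, "f3"] <- ifelse(y == "a", 0, 4) + rnorm(n, sd = 0.1)
    imp <- rf_importance(X, y, seed = s)
    hits <- hits + (names(which.max(imp)) == "f3")
    expect_true(all(imp >= 0))
  }
  expect_equal(hits, 10L)
  expect_error(rf_importance(matrix(rnorm(20), 10), rep("a", 10)),
               "2 classes")
})

test_that("importance is reproducible given a seed", {
  set.seed(1)
  X <- matrix(rnorm(40 * 4), 40, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(c("a", "b"), 20)
  expect_identical(rf_importance(X, y, seed = 5), rf_importance(X, y, seed = 5))
})

test_that("label permutation leaves no feature systematically important", {
  set.seed(77)
  n <- 60
  X <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("f", 1:5)))
  X[, "f1"] <- rep(c(0, 3), each = n / 2) + rnorm(n, sd = 0.2)
  y <- rep(c("a", "b"), each = n / 2)
  raw_signal <- attr(rf_importance(X, y, seed = 1), "raw")[["f1"]]
  perm <- sapply(1:20, function(s) {
    yp <- sample(y)
    max(attr(rf_importance(X, yp, seed = s), "raw"))
  })
  expect_gt(raw_signal, quantile(perm, 0.95))
})

test_that("elimination drops the lower-importance twin and keeps invariants", {
  for (s in 1:5) {
    sim <- generate_cohort(synthetic_config(), seed = s)
    co <- sim$cohort
    screen <- suppressWarnings(filter_features(co))
    sel <- iterative_elimination(cohort_matrix(co, screen$retained),
                                 co$group, seed = s)
    tr <- sel$trace
    # one elimination per iteration; importance ordering respected
    expect_equal(tr$iteration, seq_len(nrow(tr)))
    expect_true(all(tr$eliminated_importance <= tr$partner_importance))
    expect_lte(nrow(tr), length(screen$retained) - 5)
    # decoy twins fall before their planted partners
    for (k in seq_len(nrow(sim$truth$decoys))) {
      dec <- sim$truth$decoys$feature[k]
      par <- sim$truth$decoys$of[k]
      if (!dec %in% screen$retained) next
      it_dec <- match(dec, tr$eliminated)
      it_par <- match(par, tr$eliminated)
      expect_false(is.na(it_dec))
      expect_true(is.na(it_par) || it_par > it_dec)
    }
  }
})

test_that("elimination on independent informative features keeps accuracy", {
  set.seed(9)
  n <- 90
  y <- rep(c("a", "b", "c"), each = n / 3)
  mu <- cbind(a = c(0, 0, 0, 0), b = c(2, -2, 0, 2), c = c(4, -4, 2, 0))
  X <- t(mu[, y]) + matrix(rnorm(n * 4), n)
  colnames(X) <- paste0("f", 1:4)
  sel <- iterative_elimination(X, y, min_features = 2, seed = 3)
  expect_gte(sel$best_accuracy, sel$initial_accuracy - 2)
})
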