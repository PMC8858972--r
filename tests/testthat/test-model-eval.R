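test_that("AUC matches brute-force concordant-pair counting", {
  expect_equal(unname(auc_ci(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))["auc"]),
               0.75)
  set.seed(14)
  for (k in 1:10) {
    n <- 40
    lab <- rbinom(n, 1, 0.5)
    if (length(unique(lab)) < 2) next
    sc <- round(rnorm(n), 1)  # rounding forces ties
    expect_equal(unname(auc_ci(sc, lab)["auc"]), auc_brute(sc, lab),
                 tolerance = 1e-12)
  }
  expect_error(auc_ci(1:5, rep(1, 5)), "both classes")
})

test_that("AUC ranking properties hold", {
  expect_equal(unname(auc_ci(c(0, 0, 1, 1), c(0, 0, 1, 1))["auc"]), 1)
  expect_equal(unname(auc_ci(c(1, 1, 0, 0), c(0, 0, 1, 1))["auc"]), 0)
  set.seed(3)
  sc <- rnorm(50); lab <- rbinom(50, 1, 0.4)
  a <- unname(auc_ci(sc, lab)["auc"])
  expect_equal(unname(auc_ci(-sc, lab)["auc"]), 1 - a, tolerance = 1e-12)
  expect_equal(unname(auc_ci(exp(sc), lab)["auc"]), a, tolerance = 1e-12)
})

test_that("DeLong interval brackets the AUC, shrinks with n, matches pROC", {
  skip_if_not_installed("pROC")
  set.seed(4)
  widths <- sapply(c(30, 100, 300), function(n) {
    lab <- rep(0:1, length.out = n)
    sc <- lab + rnorm(n)
    ours <- auc_ci(sc, lab)
    ref <- suppressMessages(pROC::ci.auc(lab, sc, method = "delong"))
    expect_equal(unname(ours["auc"]), as.numeric(ref[2]), tolerance = 1e-9)
    expect_equal(unname(ours["ci_lo"]), max(0, as.numeric(ref[1])),
                 tolerance = 1e-6)
    expect_equal(unname(ours["ci_hi"]), min(1, as.numeric(ref[3])),
                 tolerance = 1e-6)
    expect_lte(ours["ci_lo"], ours["auc"])
    expect_gte(ours["ci_hi"], ours["auc"])
    unname(ours["ci_hi"] - ours["ci_lo"])
  })
  expect_true(all(diff(widths) < 0))
})

test_that("sensitivity at fixed specificity scans observed thresholds", {
  # perfect separation: 1 at any target
  for (t in c(0.5, 0.9, 0.99))
    expect_equal(as.numeric(sens_at_spec(c(1, 2, 8, 9), c(0, 0, 1, 1), t)), 1)
  # 4-point example at target 0.5: threshold 0.35 gives spec 0.5, sens 1
  s <- sens_at_spec(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), 0.5)
  expect_equal(as.numeric(s), 1)
  expect_equal(attr(s, "threshold"), 0.35)
  # independent scores: sens at spec >= t is about 1 - t
  set.seed(10)
  sc <- runif(4000); lab <- rep(0:1, 2000)
  expect_equal(as.numeric(sens_at_spec(sc, lab, 0.9)), 0.1, tolerance = 0.05)
})

test_that("operating-point PPV/NPV follow observed prevalence", {
  sc <- c(0.1, 0.2, 0.3, 0.6, 0.7, 0.9)
  lab <- c(0, 0, 0, 1, 1, 1)
  m <- glycospot:::operating_metrics(sc, lab, target_spec = 0.9)
  expect_equal(unname(m["ppv"]), 1)
  expect_equal(unname(m["npv"]), 1)
  expect_equal(unname(m["accuracy"]), 1)
  # prevalence override moves PPV down for a rarer positive class
  m2 <- glycospot:::operating_metrics(c(sc, 0.65), c(lab, 0),
                                      target_spec = 0.5, prevalence = 0.05)
  expect_lt(unname(m2["ppv"]), unname(m["ppv"]))
})

test_that("cv_scores schemes have the right shape and are seeded", {
  set.seed(2)
  n <- 30
  X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, paste0("f", 1:3)))
  y <- rep(c("a", "b"), each = n / 2)
  ap <- cv_scores(X, y, "apparent", seed = 1)
  expect_length(ap$scores, n)
  lo <- cv_scores(X, y, "loocv", seed = 1)
  expect_length(lo$scores, n)
  su <- cv_scores(X, y, "subsample3fold", reps = 7, seed = 1)
  expect_equal(dim(su$scores), c(n, 7))
  expect_true(all(colSums(!is.na(su$scores)) == 10))  # one stratified third
  re <- cv_scores(X, y, "repeated3fold", reps = 4, seed = 1)
  expect_equal(dim(re$scores), c(n, 4))
  expect_false(anyNA(re$scores))
  # determinism
  expect_identical(cv_scores(X, y, "loocv", seed = 9)$scores,
                   cv_scores(X, y, "loocv", seed = 9)$scores)
  expect_error(cv_scores(X, rep("a", n), "loocv"), "2 classes")
})

test_that("separable classes reach LOOCV AUC 1 and apparent is optimistic", {
  set.seed(6)
  n <- 40
  y <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("f1", "f2")))
  X[, "f1"] <- ifelse(y == "b", 6, 0) + rnorm(n, sd = 0.3)
  lo <- cv_scores(X, y, "loocv", seed = 2)
  expect_equal(unname(auc_ci(lo$scores, lo$labels)["auc"]), 1)
  # on pure noise, apparent AUC far exceeds LOOCV AUC
  Xn <- matrix(rnorm(n * 3), n, dimnames = list(NULL, paste0("f", 1:3)))
  ap <- cv_scores(Xn, y, "apparent", seed = 3)
  lon <- cv_scores(Xn, y, "loocv", seed = 3)
  expect_gt(unname(auc_ci(ap$scores, ap$labels)["auc"]),
            unname(auc_ci(lon$scores, lon$labels)["auc"]))
})

test_that("evaluation reports cover all comparisons and schemes", {
  co <- generate_cohort(synthetic_config(), seed = 8)$cohort
  panel <- c("G.A2BG0F", "G1.A2G1F", "G3.A2BG1F")
  reps <- evaluate_groupings(co, panel,
                             schemes = c("apparent", "loocv",
                                         "subsample3fold", "repeated3fold"),
                             reps = 5, seed = 8)
  expect_setequal(names(reps),
                  c("group1_vs_group2", "group2_vs_group3",
                    "group1_vs_group3", "stage01_vs_stage23",
                    "stage23_vs_stage4"))
  r <- reps$group1_vs_group3
  expect_equal(sort(r$metrics$scheme),
               sort(c("apparent", "loocv", "subsample3fold", "repeated3fold")))
  with(r$metrics, {
    expect_true(all(auc >= 0 & auc <= 1))
    expect_true(all(ci_lo <= auc + 1e-9 & auc <= ci_hi + 1e-9))
    expect_true(all(accuracy >= 0 & accuracy <= 1))
  })
  expect_false(is.na(r$metrics$auc_sd[r$metrics$scheme == "repeated3fold"]))
  expect_error(evaluate_groupings(co, c("G.NOPE")), "absent")
})

test_that("stage regrouping is skipped with a warning when stages missing", {
  co <- generate_cohort(synthetic_config(), seed = 8)$cohort
  co$stage <- NA_character_
  expect_warning(
    reps <- evaluate_groupings(co, "G.A2BG0F", schemes = "apparent", seed = 1),
    "skipping stage regrouping")
  expect_length(reps, 3)
})

test_that("roc_coordinates trace a valid ROC staircase", {
  rc <- roc_coordinates(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_true(all(diff(rc$sensitivity) <= 0))
  expect_true(all(diff(rc$specificity) >= 0))
  expect_equal(rc$sensitivity[1], 1)
  expect_equal(rc$specificity[nrow(rc)], 1)
})
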