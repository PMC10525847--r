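test_that("auc matches closed forms and the pairwise oracle", {
  expect_equal(auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1.0)
  expect_equal(auc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_equal(auc(c(0.9, 0.8, 0.3), c(1, 0, 1)), 0.5)
  expect_error(auc(c(0.1, 0.2), c(1, 1)), "single class")

  set.seed(31)
  for (i in 1:100) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5)) # both classes guaranteed
    scores <- round(runif(n), sample(1:3, 1)) # induce ties
    expect_equal(auc(scores, labels), pairwise_auc(scores, labels),
                 tolerance = 1e-9)
  }
})

test_that("confusion counts use the strict cut-off rule", {
  cc <- confusion_at(c(0.2, 0.6), c(0, 1), 0.5)
  expect_identical(unclass(cc)[c("tp", "tn", "fp", "fn")],
                   list(tp = 1L, tn = 1L, fp = 0L, fn = 0L))
  # threshold 1.0: nothing is predicted positive
  cc <- confusion_at(c(0.3, 1.0), c(1, 1), 1.0)
  expect_identical(cc$tp, 0L)
  expect_identical(cc$fp, 0L)
  # score exactly at the threshold is negative (strictly greater wins)
  cc <- confusion_at(c(0.5), c(1), 0.5)
  expect_identical(cc$fn, 1L)

  set.seed(5)
  scores <- runif(50); labels <- rbinom(50, 1, 0.4); t <- runif(1)
  cc <- confusion_at(scores, labels, t)
  expect_identical(cc$tp, sum(scores > t & labels == 1))
  expect_identical(cc$tn, sum(scores <= t & labels == 0))
  expect_identical(cc$tp + cc$tn + cc$fp + cc$fn, 50L)
})

test_that("threshold tuning maximizes sensitivity x specificity", {
  expect_equal(tune_threshold(c(0.1, 0.2, 0.7, 0.9), c(0, 0, 1, 1)), 0.45)
  # separable at 0.5: the tuned threshold achieves product 1
  set.seed(6)
  scores <- runif(30)
  labels <- as.integer(scores > 0.5)
  t <- tune_threshold(scores, labels)
  cc <- confusion_at(scores, labels, t)
  expect_equal((cc$tp / (cc$tp + cc$fn)) * (cc$tn / (cc$tn + cc$fp)), 1)
  expect_error(tune_threshold(runif(5), rep(1, 5)), "single class")

  # dense-grid oracle agreement on random instances
  prod_at <- function(scores, labels, t) {
    cc <- confusion_at(scores, labels, t)
    (cc$tp / (cc$tp + cc$fn)) * (cc$tn / (cc$tn + cc$fp))
  }
  set.seed(41)
  for (i in 1:100) {
    n <- sample(10:100, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), 3)
    t <- tune_threshold(scores, labels)
    expect_equal(prod_at(scores, labels, t),
                 grid_best_product(scores, labels), tolerance = 1e-9)
  }
})

test_that("micro averages equal the pooled-count formulas", {
  cc <- function(tp, tn, fp, fn) {
    structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
              class = "confusion_counts")
  }
  one <- cc(3, 4, 2, 1)
  m1 <- micro_average(list(one))
  expect_equal(m1$micro_sensitivity, 3 / 4)
  expect_equal(m1$micro_specificity, 4 / 6)
  expect_equal(m1$micro_accuracy, 7 / 10)

  # hand-pooled two-class example
  a <- cc(2, 3, 1, 0); b <- cc(1, 4, 0, 1)
  m <- micro_average(list(a, b))
  expect_equal(m$micro_sensitivity, 3 / 4)
  expect_equal(m$micro_specificity, 7 / 8)
  expect_equal(m$micro_accuracy, 10 / 12)
  # permutation symmetry
  expect_identical(micro_average(list(b, a)), m)
  expect_error(micro_average(list(cc(0, 0, 0, 0))), "undefined")
})

test_that("accuracy decomposes as prevalence-weighted sensitivity/specificity", {
  set.seed(9)
  scores <- runif(200); labels <- rbinom(200, 1, 0.2)
  cc <- confusion_at(scores, labels, 0.6)
  prev <- mean(labels)
  acc <- (cc$tp + cc$tn) / 200
  sens <- cc$tp / (cc$tp + cc$fn)
  spec <- cc$tn / (cc$tn + cc$fp)
  expect_equal(acc, prev * sens + (1 - prev) * spec, tolerance = 1e-12)
})

test_that("the derived Normal class is scored on the all-negative rule", {
  thr <- setNames(rep(0.5, 6), disease_names())
  probs <- matrix(0, 4, 6)
  labels <- matrix(0L, 4, 6)
  cc <- normal_eval(probs, labels, thr)
  expect_identical(cc$tp, 4L)
  expect_identical(cc$fp, 0L)

  # one DR-positive image predicted DR-positive counts as a true negative
  probs <- matrix(0, 1, 6); probs[1, 1] <- 0.9
  labels <- matrix(0L, 1, 6); labels[1, 1] <- 1L
  cc <- normal_eval(probs, labels, thr)
  expect_identical(unclass(cc)[c("tp", "tn", "fp", "fn")],
                   list(tp = 0L, tn = 1L, fp = 0L, fn = 0L))

  # brute-force agreement on random vectors
  set.seed(12)
  probs <- matrix(runif(50 * 6), 50, 6)
  labels <- matrix(rbinom(50 * 6, 1, 0.25), 50, 6)
  thr <- setNames(runif(6), disease_names())
  cc <- normal_eval(probs, labels, thr)
  tp <- tn <- fp <- fn <- 0L
  for (i in 1:50) {
    truly <- all(labels[i, ] == 0L)
    pred <- all(probs[i, ] <= thr)
    if (pred && truly) tp <- tp + 1L
    if (!pred && !truly) tn <- tn + 1L
    if (pred && !truly) fp <- fp + 1L
    if (!pred && truly) fn <- fn + 1L
  }
  expect_identical(unclass(cc)[c("tp", "tn", "fp", "fn")],
                   list(tp = tp, tn = tn, fp = fp, fn = fn))
})

test_that("repeated-run confidence intervals follow the Student-t formula", {
  expect_equal(run_ci(c(0.8, 0.8, 0.8))$half_width, 0)
  ci <- run_ci(1:5)
  expect_equal(ci$mean, 3)
  expect_equal(ci$half_width, qt(0.975, 4) * sd(1:5) / sqrt(5),
               tolerance = 1e-12)
  expect_equal(ci$half_width, 1.9633, tolerance = 1e-4)
  # adding a run at the mean shrinks the half-width
  expect_lt(run_ci(c(1:5, 3))$half_width, ci$half_width)
  expect_error(run_ci(0.9), "at least 2")
})

test_that("significance testing is a symmetric Welch t-test", {
  expect_equal(significance(c(0.9, 0.9), c(0.9, 0.9)), 1.0)
  a <- c(0.90, 0.91, 0.92); b <- c(0.70, 0.71, 0.72)
  p <- significance(a, b)
  expect_lt(p, 0.05)
  expect_equal(significance(b, a), p)
  # matches stats::t.test where the latter is defined
  set.seed(3)
  x <- rnorm(5, 0.9, 0.02); y <- rnorm(5, 0.85, 0.03)
  expect_equal(significance(x, y), t.test(x, y)$p.value, tolerance = 1e-12)
})

test_that("the misclassification matrix covers single-label images only", {
  thr <- setNames(rep(0.5, 6), disease_names())
  probs <- matrix(0, 3, 6)
  labels <- matrix(0L, 3, 6)
  # true AMD image where only GS fires -> amd->gs
  labels[1, 5] <- 1L; probs[1, 6] <- 0.9
  # true Normal image, nothing fires -> normal->normal
  # (row 2 left all zero)
  # two-disease image is excluded entirely
  labels[3, 1] <- 1L; labels[3, 2] <- 1L; probs[3, 1] <- 0.9
  m <- misclassification_matrix(probs, labels, thr)
  expect_identical(m["amd", "gs"], 1L)
  expect_identical(m["normal", "normal"], 1L)
  expect_identical(sum(m), 2L)

  # multi-positive predictions increment every predicted cell
  probs2 <- matrix(0, 1, 6); probs2[1, c(1, 4)] <- 0.9
  labels2 <- matrix(0L, 1, 6); labels2[1, 1] <- 1L
  m2 <- misclassification_matrix(probs2, labels2, thr)
  expect_identical(m2["dr", "dr"], 1L)
  expect_identical(m2["dr", "erm"], 1L)
})

test_that("exported ROC curves integrate back to the AUC", {
  set.seed(15)
  p <- withr::local_tempfile(fileext = ".csv")
  for (i in 1:5) {
    n <- sample(10:60, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), 2)
    curve <- roc_export(scores, labels, p)
    expect_true(file.exists(p))
    # endpoints
    expect_equal(curve$fpr[1], 0); expect_equal(curve$tpr[nrow(curve)], 1)
    area <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                     utils::tail(curve$tpr, -1)) / 2)
    expect_equal(area, auc(scores, labels), tolerance = 1e-9)
  }
  # separable data passes through (0, 1)
  curve <- roc_export(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1), p)
  expect_true(any(curve$fpr == 0 & curve$tpr == 1))
  expect_error(roc_export(runif(4), rep(0, 4), p), "single class")
})

test_that("metrics_report assembles per-class, micro and Normal blocks", {
  set.seed(19)
  probs <- matrix(runif(80 * 6), 80, 6)
  labels <- matrix(rbinom(80 * 6, 1, 0.3), 80, 6)
  thr <- tune_thresholds(probs, labels)
  rep <- metrics_report(probs, labels, thr)
  expect_identical(rep$per_class$class, disease_names())
  expect_true(all(rep$per_class$auc >= 0 & rep$per_class$auc <= 1))
  counts <- lapply(1:6, function(j) confusion_at(probs[, j], labels[, j],
                                                 thr[[j]]))
  expect_equal(rep$micro, micro_average(counts))
  expect_identical(rep$n, 80L)
})
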