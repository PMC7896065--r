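test_that("the 7:3 split takes floor(0.7 n) records and partitions the set", {
  man <- data.frame(scan_id = sprintf("s%04d", 1:2390),
                    label = rep(c("normal", "metastasis"), c(1200, 1190)))
  sp <- split_dataset(man, c(7, 3), seed = 1L)
  expect_identical(nrow(sp$train), 1673L)
  expect_identical(nrow(sp$test), 717L)
  expect_identical(sort(c(sp$train$scan_id, sp$test$scan_id)), sort(man$scan_id))
  expect_length(intersect(sp$train$scan_id, sp$test$scan_id), 0L)
  # determinism
  sp2 <- split_dataset(man, c(7, 3), seed = 1L)
  expect_identical(sp$train$scan_id, sp2$train$scan_id)
  expect_error(split_dataset(man[0, , drop = FALSE]), "empty")
})

test_that("augmented derivatives never leak across the split", {
  man <- data.frame(
    record_id = sprintf("r%03d", 1:120),
    source_id = rep(sprintf("s%02d", 1:30), each = 4),
    label = "normal")
  for (seed in 1:5) {
    sp <- split_dataset(man, c(7, 3), seed = seed)
    expect_length(intersect(unique(sp$train$source_id),
                            unique(sp$test$source_id)), 0L)
    expect_identical(nrow(sp$train) + nrow(sp$test), 120L)
  }
})

test_that("confusion counts follow the four clinical definitions", {
  all_pos <- confusion_counts(rep("metastasis", 10), rep("metastasis", 10))
  expect_identical(unlist(unclass(all_pos)),
                   c(TP = 10L, FP = 0L, FN = 0L, TN = 0L))
  # predictions are the exact complement of the truths
  comp <- confusion_counts(c("metastasis", "normal"), c("normal", "metastasis"))
  expect_identical(comp$TP, 0L); expect_identical(comp$TN, 0L)
  expect_identical(comp$FP + comp$FN, 2L)
  expect_error(confusion_counts(c("a", "b"), "a"), "length")
  # random vectors match a brute-force tally
  set.seed(20)
  for (i in 1:10) {
    n <- sample(20:80, 1)
    pred <- sample(c(TRUE, FALSE), n, replace = TRUE)
    truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
    cc <- confusion_counts(pred, truth)
    expect_identical(cc$TP, sum(pred & truth))
    expect_identical(cc$FP, sum(pred & !truth))
    expect_identical(cc$FN, sum(!pred & truth))
    expect_identical(cc$TN, sum(!pred & !truth))
    expect_identical(cc$TP + cc$FP + cc$FN + cc$TN, n)
  }
})

test_that("metric identities hold on random confusion tables", {
  set.seed(21)
  for (i in 1:20) {
    counts <- structure(as.list(c(TP = sample(1:50, 1), FP = sample(1:50, 1),
                                  FN = sample(1:50, 1), TN = sample(1:50, 1))),
                        class = "confusion_counts")
    m <- metrics_report(counts)
    total <- with(counts, TP + FP + FN + TN)
    expect_equal(m$acc * total, counts$TP + counts$TN)
    expect_equal(m$f1, 2 * m$prec * m$rec / (m$prec + m$rec))
    expect_equal(m$spe + m$fpr, 1)
  }
})

test_that("perfect classification yields all-one metrics", {
  m <- metrics_report(structure(list(TP = 50L, FP = 0L, FN = 0L, TN = 50L),
                                class = "confusion_counts"))
  expect_identical(c(m$acc, m$prec, m$rec, m$spe, m$f1), rep(1, 5))
  expect_identical(m$fpr, 0)
})

test_that("zero denominators yield NA metrics, not errors", {
  m <- metrics_report(structure(list(TP = 0L, FP = 0L, FN = 5L, TN = 5L),
                                class = "confusion_counts"))
  expect_true(is.na(m$prec))
  expect_true("prec" %in% m$undefined)
  expect_false(is.na(m$acc))
  expect_error(metrics_report(structure(list(TP = 0L, FP = 0L, FN = 0L,
                                             TN = 0L),
                                        class = "confusion_counts")),
               "no evaluated")
})

test_that("published precision/recall pairs reproduce their printed F-1", {
  expect_identical(round(f1_score(0.9775, 0.9830), 4), 0.9802)
  expect_identical(round(f1_score(0.6875, 0.9361), 4), 0.7928)
  expect_identical(round(f1_score(0.9750, 0.8298), 4), 0.8966)
  expect_identical(round(f1_score(0.9634, 0.8952), 4), 0.9280)
})

test_that("AUC equals the O(n^2) pairwise-ranking oracle", {
  pair_auc <- function(scores, pos) {
    ps <- scores[pos]; ns <- scores[!pos]
    tot <- 0
    for (p in ps) for (q in ns) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(ps) * length(ns))
  }
  set.seed(22)
  for (i in 1:50) {
    n <- sample(10:200, 1)
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) pos[sample(n, 2)] <- c(TRUE, FALSE)
    # coarse scores force plenty of ties
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    r <- roc_auc(scores, pos)
    expect_equal(r$auc, pair_auc(scores, pos), tolerance = 1e-9)
    # trapezoidal area under the ROC equals the rank probability
    expect_equal(r$auc_trapezoid, r$auc, tolerance = 1e-9)
  }
})

test_that("perfectly separating scores give AUC 1 and shuffling gives 0.5", {
  truth <- rep(c("metastasis", "normal"), each = 50)
  scores <- c(runif(50, 0.8, 1), runif(50, 0, 0.2))
  expect_identical(roc_auc(scores, truth)$auc, 1)
  set.seed(23)
  n <- 2000L
  truth2 <- sample(rep(c("metastasis", "normal"), each = n / 2))
  scores2 <- runif(n)
  expect_lt(abs(roc_auc(scores2, truth2)$auc - 0.5), 0.03)
  expect_error(roc_auc(runif(5), rep("normal", 5)), "both classes")
})

test_that("repeated evaluation of a deterministic model is invariant", {
  set.seed(24)
  n <- 40
  truth <- rep(c("metastasis", "normal"), each = n / 2)
  probs <- matrix(runif(2 * n), n, 2)
  predict_fn <- function(images, seed) probs  # deterministic
  ev <- repeat_evaluate(predict_fn, vector("list", n), truth, repeats = 10L,
                        positive_col = 1L)
  expect_identical(nrow(ev$runs), 10L)
  expect_true(all(ev$sd[c("acc", "auc")] == 0))
  one <- repeat_evaluate(predict_fn, vector("list", n), truth, repeats = 1L,
                         positive_col = 1L)
  expect_equal(ev$mean, one$mean)
  # the mean equals the brute-force average of the stored per-run values
  expect_equal(unname(ev$mean["acc"]), mean(ev$runs$acc))
})

test_that("stochastic evaluations average over the repetitions", {
  set.seed(25)
  truth <- rep(c("metastasis", "normal"), each = 20)
  predict_fn <- function(images, seed) {
    set.seed(seed)
    base <- ifelse(truth == "metastasis", 0.7, 0.3)
    cbind(base + rnorm(40, 0, 0.1), 1 - base)
  }
  ev <- repeat_evaluate(predict_fn, vector("list", 40), truth, repeats = 6L,
                        seed = 3L, positive_col = 1L)
  expect_identical(nrow(ev$runs), 6L)
  expect_gt(ev$sd[["acc"]], 0)
  expect_equal(unname(ev$mean["auc"]), mean(ev$runs$auc))
})

test_that("the shipped benchmark table is internally consistent", {
  b <- benchmark_scores()
  expect_identical(nrow(b), 21L)
  recomputed <- round(f1_score(b$prec, b$rec), 4)
  # the four headline rows reproduce their printed F-1 exactly to 4 d.p.
  headline <- (b$dataset == "D3" & b$classifier == "V21") |
    (b$dataset == "D1" & b$classifier %in% c("V7", "V21")) |
    (b$dataset == "D2" & b$classifier == "D121")
  expect_identical(recomputed[headline], b$f1[headline])
  # every other row agrees to within last-digit rounding of a 10-run
  # average, except the one grossly inconsistent row (V24 / augmented)
  broken <- b$dataset == "D3" & b$classifier == "V24"
  expect_true(all(abs(recomputed[!broken] - b$f1[!broken]) <= 2.5e-4))
  expect_gt(abs(recomputed[broken] - b$f1[broken]), 0.05)
})
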