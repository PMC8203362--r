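# Evaluation metrics: LOSO folds, confusion-matrix statistics against
# independent oracles, AUCs, clinical items and the paired t-test.

test_that("loso_splits builds one clean fold per subject", {
  folds <- loso_splits(sprintf("subj%02d", 1:13))
  expect_equal(length(folds), 13L)
  tests <- vapply(folds, `[[`, character(1), "test")
  expect_setequal(tests, sprintf("subj%02d", 1:13))
  for (f in folds) {
    expect_false(f$test %in% f$train)
    expect_equal(length(f$train), 12L)
  }
  two <- loso_splits(c("a", "b", "a"))
  expect_equal(length(two), 2L)
  expect_equal(lengths(lapply(two, `[[`, "train")), c(1L, 1L))
  expect_error(loso_splits("a"), ">= 2")
})

test_that("confusion_and_metrics matches hand-computed tables", {
  r <- confusion_and_metrics(c(0, 1, 2, 0), c(0, 1, 2, 0),
                             levels = c("0", "1", "2"))
  expect_equal(r$accuracy, 1)
  expect_equal(c(r$precision, r$recall, r$f1), c(1, 1, 1))
  expect_equal(diag(r$confusion), c(`0` = 2L, `1` = 1L, `2` = 1L))
  expect_equal(sum(r$confusion) - sum(diag(r$confusion)), 0L)

  # hand-computed 2x2 table: class-0 F1 = 0.8, class-1 F1 = 2/3
  r2 <- confusion_and_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0),
                              levels = c("0", "1"))
  expect_equal(r2$accuracy, 0.75)
  expect_equal(r2$per_class$precision[r2$per_class$class == "1"], 1)
  expect_equal(r2$per_class$recall[r2$per_class$class == "1"], 0.5)
  expect_equal(r2$per_class$f1[r2$per_class$class == "1"], 2 / 3)
  expect_equal(r2$f1, (0.8 + 2 / 3) / 2, tolerance = 1e-7)     # 0.73333

  expect_error(confusion_and_metrics(c(0, 1), c(0, 1, 1)), "lengths differ")
})

test_that("metrics agree with an independent oracle on random labelings", {
  set.seed(71)
  worst <- 0
  for (i in 1:100) {
    C <- sample(2:4, 1); n <- sample(10:60, 1)
    lv <- as.character(seq_len(C) - 1L)
    yt <- sample(lv, n, TRUE); yp <- sample(lv, n, TRUE)
    r <- confusion_and_metrics(yt, yp, levels = lv)
    o <- brute_metrics(yt, yp, lv)
    worst <- max(worst, abs(r$accuracy - o$accuracy),
                 abs(r$precision - o$precision),
                 abs(r$recall - o$recall), abs(r$f1 - o$f1))
  }
  expect_lt(worst, 1e-9)
})

test_that("binary AUCs agree with rank/threshold oracles and pROC", {
  set.seed(72)
  worst_roc <- worst_pr <- 0
  for (i in 1:100) {
    n <- sample(20:80, 1)
    yt <- sample(c("normal", "tic"), n, TRUE)
    if (length(unique(yt)) < 2) yt[1:2] <- c("normal", "tic")
    sc <- runif(n)
    r <- confusion_and_metrics(yt, ifelse(sc > 0.5, "tic", "normal"),
                               scores = sc, levels = c("normal", "tic"))
    worst_roc <- max(worst_roc, abs(r$auc_roc - brute_auc(sc, yt == "tic")))
    worst_pr <- max(worst_pr, abs(r$auc_pr - brute_ap(sc, yt == "tic")))
  }
  expect_lt(worst_roc, 1e-9)
  expect_lt(worst_pr, 1e-9)

  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(73)
    yt <- sample(c("normal", "tic"), 200, TRUE)
    sc <- runif(200) + 0.5 * (yt == "tic")
    r <- confusion_and_metrics(yt, ifelse(sc > 0.75, "tic", "normal"),
                               scores = sc, levels = c("normal", "tic"))
    ref <- as.numeric(pROC::auc(pROC::roc(yt == "tic", sc, quiet = TRUE)))
    expect_equal(r$auc_roc, ref, tolerance = 1e-9)
  }
})

test_that("perfect ranking gives AUC 1; random balanced scores give ~0.5", {
  yt <- rep(c("tic", "normal"), each = 50)
  sc <- c(runif(50, 0.6, 1), runif(50, 0, 0.4))
  r <- confusion_and_metrics(yt, yt, scores = sc, levels = c("normal", "tic"))
  expect_equal(r$auc_roc, 1)

  set.seed(74)
  yt <- rep(c("tic", "normal"), each = 5000)
  sc <- runif(10000)
  r <- confusion_and_metrics(yt, sample(yt), scores = sc,
                             levels = c("normal", "tic"))
  expect_lt(abs(r$auc_roc - 0.5), 0.05)
})

test_that("tic signs, frequency and areas follow their counting rules", {
  expect_equal(tic_frequency(12, 2), 6)
  expect_equal(tic_frequency(0, 5), 0)
  expect_error(tic_frequency(3, 0), "positive")

  expect_equal(count_tic_signs(c("normal", "eye_tic", "eye_tic",
                                 "normal", "eye_tic")), 2L)
  expect_equal(count_tic_signs(rep("normal", 5)), 0L)
  expect_equal(count_tic_signs(c("eye_tic", "normal", "eye_tic"),
                               gap_tolerance = 1), 1L)
  expect_equal(count_tic_signs(c("eye_tic", "mouth_tic", "normal")), 1L)

  expect_equal(count_tic_areas(c("eye_tic", "normal")), 1L)
  expect_equal(count_tic_areas(c("eye_tic", "mouth_tic", "normal")), 2L)
  expect_equal(count_tic_areas(rep("normal", 4)), 0L)
})

test_that("paired t-test reproduces the hand case and its symmetries", {
  r <- paired_ttest(c(6, 6, 2), c(5, 7, 1))
  expect_equal(r$statistic, 0.5, tolerance = 1e-9)
  expect_equal(r$p.value, 2 / 3, tolerance = 1e-5)          # 0.66667
  expect_equal(r$df, 2)

  rs <- paired_ttest(c(5, 7, 1), c(6, 6, 2))
  expect_equal(rs$statistic, -0.5, tolerance = 1e-9)
  expect_equal(rs$p.value, r$p.value, tolerance = 1e-12)

  rd <- paired_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_true(rd$degenerate)
  expect_equal(c(rd$statistic, rd$p.value), c(0, 1))

  expect_error(paired_ttest(1, 1), "n >= 2")
  expect_error(paired_ttest(1:3, 1:4), "equal length")
})

test_that("paired t-test matches stats::t.test on random data (property)", {
  set.seed(75)
  for (i in 1:20) {
    n <- sample(3:15, 1)
    a <- rnorm(n); b <- rnorm(n, 0.3)
    r <- paired_ttest(a, b)
    tt <- t.test(a, b, paired = TRUE)
    expect_equal(r$statistic, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(r$p.value, tt$p.value, tolerance = 1e-12)
  }
})
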