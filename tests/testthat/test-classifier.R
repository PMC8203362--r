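# Stage 2: frame sampling, feature extraction through the frozen encoder,
# focal-loss properties, LSTM training with watch-metric checkpointing.

test_that("sample_frames draws sorted distinct indices under the k < len rule", {
  idx <- sample_frames(25L, 24L, seed = 3)
  expect_equal(length(idx), 24L)
  expect_equal(idx, sort(unique(idx)))
  expect_true(all(idx >= 0 & idx < 25))
  expect_error(sample_frames(25L, 25L), "strictly less")

  clip <- data.frame(start_frame = 100L, end_frame = 125L)
  a <- sample_frames(clip, 16L, seed = 8)
  expect_true(all(a >= 100 & a < 125))
  expect_identical(a, sample_frames(clip, 16L, seed = 8))
  expect_false(identical(a, sample_frames(clip, 16L, seed = 9)))
})

test_that("focal loss limits: cross-entropy at gamma 0, hand value, monotone", {
  expect_equal(focal_loss(0.8, 1, focal_config(1, 0)), -log(0.8), tolerance = 1e-12)
  # 1000 random draws: gamma = 0, alpha_t = 1 reduces exactly to cross-entropy
  set.seed(61)
  p <- runif(1000, 0.01, 0.99); y <- rbinom(1000, 1, 0.5)
  ce <- ifelse(y == 1, -log(p), -log(1 - p))
  expect_lt(max(abs(focal_loss(p, y, focal_config(1, 0)) - ce)), 1e-9)

  # hand case: -0.25 * (1 - 0.9)^2 * log(0.9)
  expect_equal(focal_loss(0.9, 1, focal_config(0.25, 2)),
               -0.25 * 0.01 * log(0.9), tolerance = 1e-12)
  expect_lt(abs(focal_loss(0.9, 1, focal_config(0.25, 2)) - 2.634013e-4), 1e-8)

  # monotone decreasing in p_t; -> 0 as p_t -> 1
  pt <- seq(0.05, 0.999, length.out = 50)
  for (g in c(0.5, 1, 2)) {
    l <- focal_loss(pt, 1, focal_config(1, g))
    expect_true(all(diff(l) < 0))
  }
  expect_lt(focal_loss(1 - 1e-9, 1, focal_config(1, 2)), 1e-17)
  expect_error(focal_loss(1.2, 1, focal_config()), "strictly in")
  expect_error(focal_config(gamma = -1), "gamma")
})

test_that("multiclass focal total is invariant to class re-indexing", {
  set.seed(62)
  logits <- matrix(rnorm(3 * 10), 3, 10)
  y <- sample(1:3, 10, TRUE)
  alpha <- c(0.2, 0.7, 1)
  L <- ticmotion:::focal_softmax_loss(logits, y, alpha, 2)
  perm <- c(3L, 1L, 2L)                  # new row j holds old class perm[j]
  inv <- order(perm)                     # old class c now lives at row inv[c]
  L2 <- ticmotion:::focal_softmax_loss(logits[perm, ], inv[y], alpha[perm], 2)
  expect_equal(L2, L, tolerance = 1e-12)
})

test_that("extract_features maps frames row-wise through the frozen encoder", {
  set.seed(63)
  frames <- list(s1 = replicate(6, array(runif(192, 0, 255), c(8, 8, 3)),
                                simplify = FALSE),
                 s2 = replicate(6, array(runif(192, 0, 255), c(8, 8, 3)),
                                simplify = FALSE))
  enc <- tic_pretrain(frames,
                      contrastive_config(batch_pairs = 4L, max_epochs = 1L, seed = 1L),
                      encoder_spec(8L, c(2L), 6L), projection_spec(6L, 4L, 3L),
                      augment_config(out_size = 8L))
  imgs <- frames$s1[c(1, 2, 1, 3)]
  fs <- extract_features(enc, imgs)
  expect_equal(dim(fs), c(4L, 6L))
  expect_equal(fs[1, ], fs[3, ], tolerance = 1e-12)   # identical frames, identical rows
  sw <- extract_features(enc, imgs[c(2, 1, 3, 4)])
  expect_equal(sw[1, ], fs[2, ], tolerance = 1e-12)   # row-wise map
})

test_that("LSTM training separates Gaussian classes and respects contracts", {
  seqs <- gaussian_seqs(30, k = 4, D = 8, sep = 3, seed = 64)
  set.seed(65)
  idx <- sample(length(seqs))
  tr <- seqs[idx[1:40]]; va <- seqs[idx[41:60]]
  spec <- lstm_spec(input_dim = 8L, hidden_dim = 12L, dropout = 0.2,
                    n_classes = 2L)
  fit <- train_classifier(tr, va, spec, epochs = 30L, seed = 5L)
  expect_s3_class(fit, "tic_lstm")
  expect_gt(fit$best_metric, 0.95)                    # separable data

  P <- predict(fit, va)
  expect_equal(dim(P), c(20L, 2L))
  expect_true(all(abs(rowSums(P) - 1) < 1e-6))
  expect_true(all(P >= 0))
  expect_identical(predict(fit, va), P)               # deterministic inference

  fit2 <- train_classifier(tr, va, spec, epochs = 30L, seed = 5L)
  expect_equal(fit$history, fit2$history, tolerance = 1e-12)

  onecls <- Filter(function(s) s$label == "normal", tr)
  expect_error(train_classifier(onecls, va, spec), "two classes")
  expect_error(train_classifier(tr, list(), spec), "nonempty")
})

test_that("the watched metric, not the loss, selects the checkpoint", {
  seqs <- gaussian_seqs(24, k = 3, D = 6, sep = 1.2, seed = 66)
  # imbalance: drop most tic validation clips
  tr <- seqs[1:36]
  va <- c(seqs[37:44], Filter(function(s) s$label == "tic", seqs[45:48]))
  spec <- lstm_spec(6L, 10L, 0.2, 2L)
  facc <- train_classifier(tr, va, spec, strategy = train_strategy("accuracy"),
                           epochs = 15L, seed = 7L)
  ff1 <- train_classifier(tr, va, spec, strategy = train_strategy("f1_tic"),
                          epochs = 15L, seed = 7L)
  h_acc <- sapply(seq_len(15), function(e) facc$history$val_metric[e])
  expect_equal(facc$best_epoch, which.max(h_acc))
  expect_equal(ff1$best_epoch, which.max(ff1$history$val_metric))
  # the two strategies watch genuinely different series
  expect_false(isTRUE(all.equal(facc$history$val_metric,
                                ff1$history$val_metric)))
})

test_that("predict.tic_lstm validates dimensions and returns 3-class vectors", {
  seqs <- gaussian_seqs(10, k = 3, D = 5, sep = 4, seed = 67,
                        labels = c("normal", "eye_tic", "mouth_tic"))
  tr <- seqs[c(1:8, 11:18, 21:28)]; va <- seqs[c(9, 10, 19, 20, 29, 30)]
  fit <- train_classifier(tr, va, lstm_spec(5L, 8L, 0.1, 3L),
                          epochs = 10L, seed = 2L)
  P <- predict(fit, va[[1]])
  expect_equal(ncol(P), 3L)
  expect_equal(colnames(P), c("normal", "eye_tic", "mouth_tic"))
  bad <- va[[1]]; bad$features <- bad$features[, 1:3]
  expect_error(predict(fit, bad), "dimension")
})
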