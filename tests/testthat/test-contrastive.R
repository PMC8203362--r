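# The contrastive stage: cosine similarity, NT-Xent pair and total losses
# against a literal brute-force oracle, the subject-restricted sampler, and
# the pretraining loop's contracts (split, early stop, determinism).

test_that("cosine_sim handles the canonical hand cases", {
  expect_equal(cosine_sim(c(1, 0), c(1, 0)), 1)
  expect_equal(cosine_sim(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_sim(c(1, 1), c(1, 0)), 1 / sqrt(2), tolerance = 1e-7)
  expect_error(cosine_sim(c(0, 0), c(1, 0)), "zero-norm")
})

test_that("NT-Xent pair loss: single-pair batch, hand case, high-tau limit", {
  z1 <- rbind(c(0.3, 1.2), c(-2, 0.4))
  expect_equal(ntxent_pair_loss(1, 2, z1, 0.7), 0)        # denominator = numerator

  zb <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  expect_equal(ntxent_pair_loss(1, 2, zb, 1), -log(exp(1) / (exp(1) + 2)),
               tolerance = 1e-7)                           # 0.551445

  set.seed(41)
  z <- matrix(rnorm(6 * 4), 6, 4)
  expect_equal(ntxent_pair_loss(1, 2, z, 1e6), log(nrow(z) - 1),
               tolerance = 1e-4)                           # uniform-softmax limit
  expect_error(ntxent_pair_loss(1, 2, z, -1), "temperature")
  expect_error(ntxent_pair_loss(2, 2, z, 1), "pair indices")
})

test_that("vectorized total loss equals the brute-force double loop", {
  set.seed(42)
  worst <- 0
  for (i in 1:100) {
    N <- sample(2:8, 1); D <- sample(2:16, 1)
    z <- matrix(rnorm(2 * N * D), 2 * N, D)
    tau <- runif(1, 0.1, 1)
    worst <- max(worst, abs(ntxent_total_loss(z, tau) - brute_ntxent(z, tau)))
  }
  expect_lt(worst, 1e-6)
})

test_that("total loss symmetric hand case, N = 1, and permutation invariance", {
  zb <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  expect_equal(ntxent_total_loss(zb, 1), -log(exp(1) / (exp(1) + 2)),
               tolerance = 1e-7)
  expect_equal(ntxent_total_loss(matrix(rnorm(4), 2, 2), 0.5), 0)

  set.seed(43)
  z <- matrix(rnorm(12 * 5), 12, 5)
  L <- ntxent_total_loss(z, 0.4)
  expect_gte(L, 0)
  perm <- sample(6)                                   # permute pair order
  rows <- as.vector(rbind(2 * perm - 1, 2 * perm))
  expect_equal(ntxent_total_loss(z[rows, ], 0.4), L, tolerance = 1e-12)

  expect_error(ntxent_total_loss(z[1:3, ], 0.4), "even")
  zz <- z; zz[2, ] <- 0
  expect_error(ntxent_total_loss(zz, 0.4), "zero")
})

test_that("subject-restricted batches are single-subject, consecutive, seeded", {
  fi <- list(a = 1:100, b = 201:300, c = 1:10)
  expect_warning(batches <- subject_restricted_batches(fi, 32, seed = 7),
                 "skipped")
  expect_equal(length(batches), 3L + 3L)              # floor(100/32) each
  for (b in batches) {
    expect_equal(length(b$frames), 32L)
    expect_true(b$subject %in% c("a", "b"))
    expect_equal(diff(b$frames), rep(1L, 31))         # consecutive
    expect_true(all(b$frames %in% fi[[b$subject]]))
  }
  expect_setequal(unique(vapply(batches, `[[`, character(1), "subject")),
                  c("a", "b"))                        # every eligible subject
  b2 <- suppressWarnings(subject_restricted_batches(fi, 32, seed = 7))
  expect_identical(batches, b2)                       # deterministic schedule
  expect_error(suppressWarnings(subject_restricted_batches(list(a = 1:5), 32)),
               "batch_size")

  # batch covering a subject's whole stream starts at its first frame
  whole <- subject_restricted_batches(list(a = 11:20), 10, seed = 1)
  expect_equal(whole[[1]]$frames, 11:20)
})

test_that("pretraining splits by subject, stops on patience, is reproducible", {
  set.seed(51)
  mk_frames <- function(n) replicate(n, array(runif(8 * 8 * 3, 0, 255),
                                              c(8, 8, 3)), simplify = FALSE)
  frames <- list(s1 = mk_frames(10), s2 = mk_frames(10),
                 s3 = mk_frames(10), s4 = mk_frames(10))
  cfg <- contrastive_config(batch_pairs = 8L, max_epochs = 3L,
                            patience_epochs = 1L, seed = 9L)
  es <- encoder_spec(8L, c(2L, 2L), 4L)
  ps <- projection_spec(4L, 4L, 2L)
  aug <- augment_config(out_size = 8L)
  fit <- tic_pretrain(frames, cfg, es, ps, aug)
  expect_s3_class(fit, "tic_encoder")
  # patient-level split: validation subjects excluded from training
  expect_true(length(fit$val_subjects) >= 1)
  expect_true(all(fit$val_subjects %in% names(frames)))
  # patience 1: once validation fails to improve, exactly one more epoch ran
  h <- fit$history
  if (nrow(h) < cfg$max_epochs)
    expect_equal(nrow(h), fit$best_epoch + 1L)

  fit2 <- tic_pretrain(frames, cfg, es, ps, aug)
  expect_equal(fit$history, fit2$history, tolerance = 1e-12)
  expect_equal(ticmotion:::net_params(fit$encoder),
               ticmotion:::net_params(fit2$encoder), tolerance = 1e-12)

  expect_error(tic_pretrain(frames["s1"], cfg, es, ps, aug), "2 subjects")
})

test_that("features from the fitted encoder have the declared geometry", {
  set.seed(52)
  frames <- list(s1 = replicate(6, array(runif(192, 0, 255), c(8, 8, 3)),
                                simplify = FALSE),
                 s2 = replicate(6, array(runif(192, 0, 255), c(8, 8, 3)),
                                simplify = FALSE))
  cfg <- contrastive_config(batch_pairs = 4L, max_epochs = 1L, seed = 2L)
  fit <- tic_pretrain(frames, cfg, encoder_spec(8L, c(2L), 5L),
                      projection_spec(5L, 4L, 3L), augment_config(out_size = 8L))
  Fm <- predict(fit, frames$s1[1:4])
  expect_equal(dim(Fm), c(4L, 5L))
  expect_equal(Fm[2, ], predict(fit, frames$s1[[2]])[1, ], tolerance = 1e-12)
})
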