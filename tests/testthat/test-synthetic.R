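# The synthetic cohort generator: schedules, rendering, determinism,
# annotation round-trips, realized class mix, and learnability of the
# benchmark it produces.

test_that("tic schedules follow the Poisson/duration/no-overlap contract", {
  expect_equal(nrow(sample_schedule(60, 0, seed = 1)), 0L)

  # rate 6/min over 10 min: count within the +/- 2 sigma Poisson band
  sch <- sample_schedule(600, 6, seed = 2)
  expect_gt(nrow(sch), 60 - 16)
  expect_lt(nrow(sch), 60 + 16)
  expect_true(all(sch$start_s >= 0 & sch$end_s <= 600))
  expect_true(all(sch$end_s - sch$start_s >= 0.4 - 1e-9))
  expect_true(all(sch$end_s - sch$start_s <= 1.5 + 1e-9))
  if (nrow(sch) > 1)
    expect_true(all(sch$start_s[-1] >= head(sch$end_s, -1)))  # non-overlap
  expect_true(all(sch$category %in% c("eye_tic", "mouth_tic")))

  expect_identical(sample_schedule(60, 10, seed = 9),
                   sample_schedule(60, 10, seed = 9))
  expect_error(sample_schedule(5, 2000, seed = 1), "infeasible")
})

test_that("rendered frames: baseline, null-intensity events, box containment", {
  st <- subject_style(101)
  empty <- sample_schedule(10, 0, seed = 1)
  base <- render_frame(st, 2.0, empty, size = 64)
  expect_equal(dim(base$img), c(64, 64, 3))
  expect_true(all(base$img >= 0 & base$img <= 255))

  # an event of intensity 0 renders identically to no event at all
  sch0 <- data.frame(category = "eye_tic", start_s = 1.5, end_s = 2.5,
                     intensity = 0)
  expect_equal(render_frame(st, 2.0, sch0, size = 64)$img, base$img)

  # outside events, only noise differs from the event-free render
  sch <- data.frame(category = "eye_tic", start_s = 5, end_s = 6, intensity = 1)
  a <- render_frame(st, 2.0, sch, size = 64, noise_sigma = 3, seed = 7)
  b <- render_frame(st, 2.0, empty, size = 64, noise_sigma = 3, seed = 7)
  expect_equal(a$img, b$img)
  # during the event the eyes genuinely change
  mid <- render_frame(st, 5.6, sch, size = 64)
  expect_gt(mean(abs(mid$img - base$img)), 0)

  # face box contains both eye centers and the mouth center (geometry check)
  set.seed(102)
  for (i in 1:40) {
    sti <- subject_style(sample.int(1e6, 1))
    t <- runif(1, 0, 30)
    fr <- render_frame(sti, t, empty, size = 64)
    bx <- fr$box
    W <- 64
    cx <- bx$x + bx$w / 2 + 1; cy <- bx$y + bx$h / 2 + 1
    eyes_x <- cx + c(-1, 1) * sti$eye_dx * W
    eyes_y <- cy - sti$eye_dy * W
    mouth_y <- cy + sti$mouth_dy * W
    expect_true(all(eyes_x > bx$x & eyes_x < bx$x + bx$w))
    expect_true(all(eyes_y > bx$y & eyes_y < bx$y + bx$h))
    expect_true(mouth_y > bx$y & mouth_y < bx$y + bx$h)
  }
})

test_that("ground-truth boxes drift continuously between frames", {
  co <- tiny_cohort()
  su <- co$subjects[[1]]
  prev <- cohort_frame(co, su$subject_id, 0L)$box
  for (i in 1:30) {
    cur <- cohort_frame(co, su$subject_id, i)$box
    expect_lte(abs(cur$x - prev$x), su$style$drift_amplitude)
    expect_lte(abs(cur$y - prev$y), su$style$drift_amplitude)
    prev <- cur
  }
})

test_that("cohorts are deterministic and their annotations round-trip", {
  cfg <- cohort_config(n_subjects = 2L, duration_s = 15, seed = 33L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$subjects[[1]]$schedule, b$subjects[[1]]$schedule)
  f1 <- cohort_frame(a, "subj01", 17L)
  f2 <- cohort_frame(b, "subj01", 17L)
  expect_identical(f1$img, f2$img)                   # bitwise regeneration

  for (su in a$subjects) {
    back <- parse_vott(write_vott(su$events, su$subject_id))
    expect_equal(back, su$events, ignore_attr = TRUE)
    # annotations exactly describe the rendered schedule
    expect_equal(back$start_s, su$schedule$start_s)
    expect_equal(back$end_s, su$schedule$end_s)
    expect_equal(back$category, su$schedule$category)
  }
})

test_that("on-disk layout round-trips frames, manifest and annotations", {
  co <- generate_cohort(cohort_config(n_subjects = 2L, duration_s = 4,
                                      seed = 55L, render_size = 32L))
  dir <- withr::local_tempdir()
  write_cohort(co, dir, max_frames = 5L)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 2L)
  expect_setequal(man$subject_id, c("subj01", "subj02"))
  expect_true(all(man$fps == 25))

  ev <- parse_vott(file.path(dir, "rec01_annotations.json"))
  expect_equal(ev, co$subjects$subj01$events, ignore_attr = TRUE)

  fr <- read_frames(file.path(dir, "rec01"), 0:2)
  orig <- cohort_frame(co, "subj01", 1L)$img
  expect_equal(dim(fr[[2]]), dim(orig))
  expect_lt(max(abs(fr[[2]] - orig)), 0.51)          # 8-bit quantization only
})

test_that("realized clip-label proportions track the configured mix", {
  co <- generate_cohort(cohort_config(n_subjects = 2L, duration_s = 600,
                                      seed = 77L,
                                      class_mix = c(eye_tic = 0.1,
                                                    mouth_tic = 0.1,
                                                    normal = 0.8)))
  cl <- cohort_clips(co)
  p <- table(factor(cl$label, c("eye_tic", "mouth_tic", "normal"))) / nrow(cl)
  expect_lt(abs(p[["eye_tic"]] - 0.1), 0.05)
  expect_lt(abs(p[["mouth_tic"]] - 0.1), 0.05)
  expect_lt(abs(p[["normal"]] - 0.8), 0.05)
})

test_that("a pixel-difference detector separates eye-tic clips (learnability)", {
  co <- tiny_cohort()
  cl <- cohort_clips(co)
  cl <- cl[cl$label %in% c("normal", "eye_tic"), ]
  # mean absolute inter-frame difference inside the eye region of the ROI
  score_clip <- function(i) {
    sub <- cl$subject_id[i]
    idx <- seq(cl$start_frame[i], cl$end_frame[i] - 1L, by = 2L)
    imgs <- lapply(idx, function(f) roi_frame(co, sub, f, 32L))
    eye <- lapply(imgs, function(im) im[6:16, 4:28, 1])
    mean(abs(Reduce(`+`, Map(function(a, b) abs(a - b),
                             eye[-1], head(eye, -1)))) / (length(eye) - 1))
  }
  sc <- vapply(seq_len(nrow(cl)), score_clip, numeric(1))
  auc <- brute_auc(sc, cl$label == "eye_tic")
  expect_gt(auc, 0.9)
})
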