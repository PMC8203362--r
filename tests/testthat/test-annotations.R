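# Annotation parsing, recording segmentation and 1-second clip windowing.

test_that("parse_vott reads well-formed, empty and unordered documents", {
  one <- '{"subject_id":"s1","events":[{"category":"eye_tic","start":3.0,"end":4.2}]}'
  ev <- parse_vott(one)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$category, "eye_tic")
  expect_equal(ev$start_s, 3.0)
  expect_equal(ev$end_s, 4.2)

  expect_equal(nrow(parse_vott('{"subject_id":"s1","events":[]}')), 0L)
  expect_equal(nrow(parse_vott("[]")), 0L)

  two <- '[{"category":"mouth_tic","start":10,"end":11},
           {"category":"eye_tic","start":2,"end":3}]'
  ev <- parse_vott(two)
  expect_equal(ev$start_s, c(2, 10))            # sorted by onset
  expect_equal(ev$category, c("eye_tic", "mouth_tic"))
})

test_that("parse_vott maps unknown categories and flags malformed input", {
  ev <- parse_vott('[{"category":"shoulder_shrug","start":1,"end":2}]')
  expect_equal(ev$category, "other_tic")
  expect_error(parse_vott('{"events":[{"category":"eye_tic","start":1}]}'),
               "missing field 'end'")
  expect_error(parse_vott('[{"category":"eye_tic","start":5,"end":5}]'),
               "region 1")
  expect_error(parse_vott("{not json"), "malformed")
})

test_that("tic events round-trip through the JSON dialect exactly", {
  ev <- tic_events(subject_id = rep("s7", 3),
                   category = c("eye_tic", "other_tic", "mouth_tic"),
                   start_s = c(0.52, 10, 30.25), end_s = c(1.48, 11.5, 31))
  back <- parse_vott(write_vott(ev, "s7"))
  expect_equal(back, ev, ignore_attr = TRUE)
})

test_that("cut_segments converts seconds to frames with floor/ceil and tiles", {
  m <- recording_meta("r", "s", 25, 250)
  segs <- cut_segments(m, tic_events("s", "eye_tic", 3.0, 4.0))
  expect_equal(segs$label, c("normal", "eye_tic", "normal"))
  expect_equal(segs$start_frame, c(0L, 75L, 100L))
  expect_equal(segs$end_frame, c(75L, 100L, 250L))

  # no events: one normal segment covering the recording
  segs0 <- cut_segments(m)
  expect_equal(nrow(segs0), 1L)
  expect_equal(c(segs0$start_frame, segs0$end_frame, segs0$label),
               c("0", "250", "normal"))

  # back-to-back events leave no zero-length normal segment between them
  segs2 <- cut_segments(m, tic_events(rep("s", 2), c("eye_tic", "mouth_tic"),
                                      c(1, 2), c(2, 3)))
  expect_false(any(segs2$end_frame == segs2$start_frame))
  expect_equal(sum(segs2$label == "normal"), 2L)

  expect_error(cut_segments(m, tic_events("s", "eye_tic", 9, 11)), "beyond")
})

test_that("segment tiling covers every frame exactly once (property)", {
  set.seed(11)
  for (rep in 1:20) {
    fps <- sample(c(25L, 30L), 1)
    n_frames <- sample(100:2000, 1)
    dur <- n_frames / fps
    k <- sample(0:6, 1)
    ev <- if (k == 0) tic_events() else {
      on <- sort(runif(k, 0, dur - 0.5))
      len <- runif(k, 0.1, 0.8)
      keep <- c(TRUE, on[-1] > head(on + len, -1))[seq_len(k)]
      tic_events(rep("s", sum(keep)),
                 sample(c("eye_tic", "mouth_tic"), sum(keep), TRUE),
                 on[keep], pmin(on[keep] + len[keep], dur))
    }
    m <- recording_meta("r", "s", fps, n_frames)
    segs <- cut_segments(m, ev)
    segs <- segs[order(segs$start_frame), ]
    expect_equal(segs$start_frame[1], 0L)
    expect_equal(segs$end_frame[nrow(segs)], n_frames)
    if (nrow(segs) > 1)
      expect_equal(segs$start_frame[-1], head(segs$end_frame, -1))
  }
})

test_that("window_clips tiles left-aligned and drops the sub-second remainder", {
  seg <- data.frame(recording_id = "r", subject_id = "s", label = "eye_tic",
                    start_frame = 10L, end_frame = 148L)  # 138 frames
  cl <- window_clips(seg, 25)
  expect_equal(nrow(cl), 5L)                       # 138 = 5*25 + 13
  expect_equal(cl$start_frame, 10L + (0:4) * 25L)
  expect_equal(cl$end_frame - cl$start_frame, rep(25L, 5))
  expect_true(all(cl$label == "eye_tic"))

  seg$end_frame <- 34L                             # 24 frames: sub-second
  expect_equal(nrow(window_clips(seg, 25)), 0L)

  seg$start_frame <- 0L; seg$end_frame <- 50L
  cl <- window_clips(seg, 25)
  expect_equal(cl$start_frame, c(0L, 25L))
  expect_equal(cl$end_frame, c(25L, 50L))
})

test_that("clip counts per label match floor(len/fps) over segments (property)", {
  co <- tiny_cohort()
  for (su in co$subjects) {
    segs <- cut_segments(su$meta, su$events)
    clips <- recording_clips(su$meta, su$events)
    for (lab in unique(segs$label)) {
      len <- segs$end_frame[segs$label == lab] - segs$start_frame[segs$label == lab]
      expect_equal(sum(clips$label == lab), sum(len %/% su$meta$fps))
    }
    # clip frames are consecutive and within the parent recording
    expect_true(all(clips$end_frame - clips$start_frame == su$meta$fps))
    expect_true(all(clips$end_frame <= su$meta$n_frames))
  }
})

test_that("guard margin trims normal segments only next to tic events", {
  m <- recording_meta("r", "s", 25, 500)
  ev <- tic_events("s", "eye_tic", 8, 9)
  g0 <- cut_segments(m, ev)
  g1 <- cut_segments(m, ev, guard_s = 1)
  n0 <- g0[g0$label == "normal", ]; n1 <- g1[g1$label == "normal", ]
  expect_equal(n1$start_frame[1], 0L)              # recording start untouched
  expect_equal(n0$end_frame[1] - n1$end_frame[1], 25L)
  expect_equal(n1$start_frame[2] - n0$start_frame[2], 25L)
  expect_equal(n1$end_frame[2], 500L)
})
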