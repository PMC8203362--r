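# Procedural synthetic tic-video cohorts. Each subject is a parametric
# cartoon face (ellipse, two eyes, mouth) that drifts slowly in the frame;
# eye tics oscillate the eye aperture at ~4 Hz, mouth tics displace the
# mouth corner. Ground-truth face boxes and VoTT-style annotations are
# emitted alongside, so every pipeline stage is testable without clinical
# data. Frames are rendered lazily and deterministically from the cohort
# seed, which keeps memory flat and regeneration bitwise identical.

#' Subject appearance and motion style
#'
#' Geometry is drawn in units of the render size so one style serves any
#' resolution; the sampled ranges keep both eyes and the mouth strictly
#' inside the face ellipse.
#'
#' @param identity_seed integer seed fixing this subject's appearance.
#' @param drift_amplitude head-sway positional amplitude in pixels (the
#'   fundamental of a two-harmonic sway; per-frame displacement stays well
#'   below this value).
#' @return a list of class \code{"subject_style"}.
#' @export
subject_style <- function(identity_seed, drift_amplitude = 4) {
  with_seed(identity_seed, {
    base <- stats::runif(1, 150, 210)
    structure(list(
      skin = c(base * stats::runif(1, 1.0, 1.08),
               base * stats::runif(1, 0.82, 0.9),
               base * stats::runif(1, 0.68, 0.78)),
      face_ax = stats::runif(1, 0.26, 0.32),    # half axes, fraction of size
      face_by = stats::runif(1, 0.34, 0.40),
      eye_dx = stats::runif(1, 0.11, 0.14),
      eye_dy = stats::runif(1, 0.10, 0.14),
      eye_rx = stats::runif(1, 0.045, 0.06),
      eye_ry = stats::runif(1, 0.028, 0.038),
      mouth_dy = stats::runif(1, 0.16, 0.22),
      mouth_rx = stats::runif(1, 0.09, 0.13),
      mouth_ry = stats::runif(1, 0.022, 0.034),
      # seated subjects sway continuously: two harmonics per axis
      drift_amplitude = drift_amplitude,
      drift_f = stats::runif(2, 0.1, 0.3),      # Hz, fundamental per axis
      drift_f2 = stats::runif(2, 0.5, 0.9),     # Hz, faster small component
      drift_phi = stats::runif(4, 0, 2 * pi),
      # spontaneous blinking (not a tic): rate and slow mouth micro-motion
      blink_rate_per_min = stats::runif(1, 12, 20),
      mouth_motion_amp = stats::runif(1, 0.1, 0.25),
      mouth_motion_f = stats::runif(1, 0.2, 0.5),
      mouth_motion_phi = stats::runif(1, 0, 2 * pi),
      identity_seed = identity_seed), class = "subject_style")
  })
}

# Spontaneous blink schedule: Poisson onsets, short smooth closures. Blinks
# are rendered but never annotated -- they are the natural confound an
# eye-tic detector must tell apart from true tics (a blink is one brief
# closure; an eye tic squeezes repetitively at ~4 Hz for 0.4-1.5 s).
sample_blinks <- function(duration_s, rate_per_min, seed) {
  with_seed(seed, {
    n <- stats::rpois(1, rate_per_min * duration_s / 60)
    if (n == 0)
      data.frame(start_s = numeric(), end_s = numeric())
    else {
      on <- sort(stats::runif(n, 0, duration_s))
      dur <- stats::runif(n, 0.15, 0.35)
      out <- data.frame(start_s = on, end_s = pmin(on + dur, duration_s))
      # drop overlapping blinks (keep the earlier one)
      keep <- c(TRUE, out$start_s[-1] > utils::head(out$end_s, -1))
      out[keep, , drop = FALSE]
    }
  })
}

#' Sample a tic schedule as a marked Poisson renewal process
#'
#' Event onsets follow a Poisson process at \code{rate_per_min}; durations
#' are uniform on [0.4, 1.5] s; categories are drawn from
#' \code{category_mix}; overlapping candidates are resampled so events never
#' overlap (a 0.1 s refractory gap separates consecutive events).
#'
#' @param duration_s recording length in seconds.
#' @param rate_per_min expected tic events per minute (>= 0).
#' @param category_mix named nonnegative weights over \code{eye_tic} and
#'   \code{mouth_tic}.
#' @param seed integer seed.
#' @return a data.frame (class \code{"tic_schedule"}) with columns category,
#'   start_s, end_s, intensity; attribute \code{rate_per_min}.
#' @export
sample_schedule <- function(duration_s, rate_per_min,
                            category_mix = c(eye_tic = 0.5, mouth_tic = 0.5),
                            seed = 1L) {
  if (rate_per_min < 0) stopf("rate_per_min must be >= 0")
  gap <- 0.1
  empty <- data.frame(category = character(), start_s = numeric(),
                      end_s = numeric(), intensity = numeric(),
                      stringsAsFactors = FALSE)
  out <- with_seed(seed, {
    n <- stats::rpois(1, rate_per_min * duration_s / 60)
    if (n > 0 && n * (0.4 + gap) > duration_s)
      stopf("infeasible rate: %d events cannot fit in %.4g s", n, duration_s)
    acc <- empty
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in 1:200) {
        d <- stats::runif(1, 0.4, 1.5)
        s <- stats::runif(1, 0, max(duration_s - d, 0))
        if (nrow(acc) == 0 ||
            all(s >= acc$end_s + gap | s + d <= acc$start_s - gap)) {
          acc <- rbind(acc, data.frame(
            category = sample(names(category_mix), 1, prob = category_mix),
            start_s = s, end_s = s + d,
            intensity = stats::runif(1, 0.6, 1),
            stringsAsFactors = FALSE))
          ok <- TRUE
          break
        }
      }
      if (!ok) stopf("infeasible rate: could not place event %d of %d", i, n)
    }
    acc[order(acc$start_s), , drop = FALSE]
  })
  rownames(out) <- NULL
  attr(out, "rate_per_min") <- rate_per_min
  class(out) <- c("tic_schedule", class(out))
  out
}

#' Cohort configuration for the synthetic generator
#'
#' Defaults define the desk-scale study conditions: 6 subjects, 60 s
#' recordings at 25 fps rendered at 64 x 64, an imbalanced clip-label mix of
#' 15\% eye tics / 15\% mouth tics / 70\% normal, and pixel noise sigma 5.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param duration_s recording length per subject in seconds.
#' @param fps frames per second, 25 or 30.
#' @param class_mix named proportions (eye_tic, mouth_tic, normal) of the
#'   emitted 1-second clips; must sum to 1.
#' @param noise_sigma additive Gaussian pixel noise, 8-bit intensity units.
#' @param render_size rendered frame side in pixels.
#' @param drift_amplitude head-drift amplitude in pixels.
#' @param seed master cohort seed.
#' @export
cohort_config <- function(n_subjects = 6L, duration_s = 60, fps = 25L,
                          class_mix = c(eye_tic = 0.15, mouth_tic = 0.15,
                                        normal = 0.7),
                          noise_sigma = 5, render_size = 64L,
                          drift_amplitude = 3, seed = 1L) {
  if (n_subjects < 2L) stopf("n_subjects must be >= 2")
  if (!fps %in% c(25L, 30L)) stopf("fps must be 25 or 30")
  if (abs(sum(class_mix) - 1) > 1e-8) stopf("class_mix must sum to 1")
  need <- c("eye_tic", "mouth_tic", "normal")
  if (!all(need %in% names(class_mix))) stopf("class_mix needs %s",
                                              paste(need, collapse = ", "))
  structure(list(n_subjects = as.integer(n_subjects), duration_s = duration_s,
                 fps = as.integer(fps), class_mix = class_mix[need],
                 noise_sigma = noise_sigma,
                 render_size = as.integer(render_size),
                 drift_amplitude = drift_amplitude, seed = as.integer(seed)),
            class = "cohort_config")
}

# Find the Poisson event rate whose realized 1-second clip-label mix matches
# the configured class mix: tic events shorter than a second often yield no
# clip at all, so the rate is calibrated by simulating the schedule and
# windowing arithmetic (no rendering) and bisecting on the tic-clip fraction.
calibrate_rate <- function(cfg, n_sim = 30L) {
  target <- unname(cfg$class_mix[["eye_tic"]] + cfg$class_mix[["mouth_tic"]])
  if (target <= 0) return(0)
  cal_dur <- min(cfg$duration_s, 120)   # clip fraction is duration-invariant
  n_frames <- round(cal_dur * cfg$fps)
  tic_frac <- function(rate) {
    fr <- vapply(seq_len(n_sim), function(i) {
      # an infeasibly dense draw counts as "too many tics", not an error
      sch <- tryCatch(
        sample_schedule(cal_dur, rate,
                        seed = derive_seed(cfg$seed, paste0("cal", rate, "_", i))),
        error = function(e) NULL)
      if (is.null(sch)) return(1)
      if (nrow(sch) == 0) return(0)
      # same frame arithmetic as cut_segments/window_clips, on plain vectors
      sf <- pmin(floor(sch$start_s * cfg$fps), n_frames - 1)
      ef <- pmin(ceiling(sch$end_s * cfg$fps), n_frames)
      if (length(sf) > 1) for (j in 2:length(sf)) sf[j] <- max(sf[j], ef[j - 1])
      tic <- sum((ef - sf) %/% cfg$fps)
      gaps <- c(sf, n_frames) - c(0, ef)
      nor <- sum(gaps %/% cfg$fps)
      if (tic + nor == 0) return(NA_real_)
      tic / (tic + nor)
    }, numeric(1))
    mean(fr, na.rm = TRUE)
  }
  lo <- 0.2; hi <- min(40, 60 / (0.5 + 0.1))
  for (it in 1:10) {
    mid <- (lo + hi) / 2
    if (tic_frac(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Generate a synthetic multi-subject tic-video cohort
#'
#' Draws one style and one tic schedule per subject (the Poisson event rate
#' is calibrated so the realized clip-label proportions match
#' \code{class_mix}), together with recording metadata and VoTT-style
#' annotations that exactly describe the rendered schedules. Frames are
#' rendered on demand by \code{\link{cohort_frame}}; the whole cohort is a
#' deterministic function of \code{cfg$seed}.
#'
#' @param cfg a \code{\link{cohort_config}}.
#' @return an object of class \code{"tic_cohort"}.
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  rate <- calibrate_rate(cfg)
  mix <- cfg$class_mix[c("eye_tic", "mouth_tic")]
  subjects <- lapply(seq_len(cfg$n_subjects), function(i) {
    sid <- sprintf("subj%02d", i)
    style <- subject_style(derive_seed(cfg$seed, paste0("style", i)),
                           cfg$drift_amplitude)
    sch <- sample_schedule(cfg$duration_s, rate, mix,
                           seed = derive_seed(cfg$seed, paste0("sched", i)))
    blinks <- sample_blinks(cfg$duration_s, style$blink_rate_per_min,
                            derive_seed(cfg$seed, paste0("blink", i)))
    meta <- recording_meta(sprintf("rec%02d", i), sid, cfg$fps,
                           round(cfg$duration_s * cfg$fps),
                           width = cfg$render_size, height = cfg$render_size)
    ev <- tic_events(subject_id = rep(sid, nrow(sch)), category = sch$category,
                     start_s = sch$start_s, end_s = sch$end_s)
    list(subject_id = sid, style = style, schedule = sch, blinks = blinks,
         meta = meta, events = ev)
  })
  names(subjects) <- vapply(subjects, `[[`, character(1), "subject_id")
  structure(list(config = cfg, rate_per_min = rate, subjects = subjects),
            class = "tic_cohort")
}

# ellipse mask on a precomputed pixel grid (1-based pixel centers)
ellipse_mask <- function(gx, gy, cx, cy, rx, ry) {
  ((gx - cx) / rx)^2 + ((gy - cy) / ry)^2 <= 1
}

#' Render one frame of a synthetic recording
#'
#' @param style a \code{\link{subject_style}}.
#' @param t time in seconds.
#' @param schedule a tic schedule (see \code{\link{sample_schedule}}).
#' @param size frame side in pixels.
#' @param noise_sigma additive Gaussian noise sigma (intensity units).
#' @param seed seed for the noise draw; \code{NULL} uses the current stream.
#' @param blinks optional spontaneous-blink table (start_s, end_s); blinks
#'   close the eyes briefly but are not tics and are never annotated. An
#'   active eye tic overrides a coinciding blink.
#' @return \code{list(img = size x size x 3 array in [0,255],
#'   box = \link{face_box})}; the box is the tight face-ellipse bound and
#'   always contains both eye centers and the mouth center.
#' @export
render_frame <- function(style, t, schedule, size = 64L, noise_sigma = 0,
                         seed = NULL, blinks = NULL) {
  s <- style; W <- size
  cx <- W / 2 +
    s$drift_amplitude * sin(2 * pi * s$drift_f[1] * t + s$drift_phi[1]) +
    0.35 * s$drift_amplitude * sin(2 * pi * s$drift_f2[1] * t + s$drift_phi[3])
  cy <- W / 2 +
    s$drift_amplitude * sin(2 * pi * s$drift_f[2] * t + s$drift_phi[2]) +
    0.35 * s$drift_amplitude * sin(2 * pi * s$drift_f2[2] * t + s$drift_phi[4])
  # slow non-tic mouth micro-motion (talking/expression noise)
  mouth_stretch <- 1 + s$mouth_motion_amp *
    sin(2 * pi * s$mouth_motion_f * t + s$mouth_motion_phi)
  aperture <- 1; mouth_dx <- 0
  if (!is.null(blinks) && nrow(blinks)) {
    bi <- which(blinks$start_s <= t & t < blinks$end_s)
    if (length(bi)) {
      frac <- (t - blinks$start_s[bi[1]]) /
        (blinks$end_s[bi[1]] - blinks$start_s[bi[1]])
      aperture <- 1 - 0.95 * sin(pi * frac)    # one smooth closure
    }
  }
  if (nrow(schedule)) {
    act <- which(schedule$start_s <= t & t < schedule$end_s)
    if (length(act)) {
      evc <- schedule$category[act[1]]; inten <- schedule$intensity[act[1]]
      tloc <- t - schedule$start_s[act[1]]
      if (evc == "eye_tic") {
        # repetitive ~4 Hz squeezing, unlike a single blink closure
        aperture <- 1 - inten * (0.5 + 0.5 * sin(2 * pi * 4 * tloc - pi / 2))
      } else if (evc == "mouth_tic") {
        mouth_dx <- inten * 0.6 * s$mouth_rx * W * sin(2 * pi * 3 * tloc)
        mouth_stretch <- mouth_stretch + 0.8 * inten * abs(sin(2 * pi * 3 * tloc))
      }
    }
  }
  gx <- matrix(rep(seq_len(W), each = W), W, W)    # column index
  gy <- matrix(rep(seq_len(W), W), W, W)           # row index
  img <- array(110, c(W, W, 3))
  face <- ellipse_mask(gx, gy, cx, cy, s$face_ax * W, s$face_by * W)
  eyeL <- ellipse_mask(gx, gy, cx - s$eye_dx * W, cy - s$eye_dy * W,
                       s$eye_rx * W, max(s$eye_ry * W * aperture, 0.5))
  eyeR <- ellipse_mask(gx, gy, cx + s$eye_dx * W, cy - s$eye_dy * W,
                       s$eye_rx * W, max(s$eye_ry * W * aperture, 0.5))
  mouth <- ellipse_mask(gx, gy, cx + mouth_dx, cy + s$mouth_dy * W,
                        s$mouth_rx * W, s$mouth_ry * W * mouth_stretch)
  eye_col <- c(45, 45, 45); mouth_col <- c(120, 50, 50)
  for (ch in 1:3) {
    p <- img[, , ch]
    p[face] <- s$skin[ch]
    p[eyeL | eyeR] <- eye_col[ch]
    p[mouth] <- mouth_col[ch]
    img[, , ch] <- p
  }
  if (noise_sigma > 0) {
    addn <- function() img + stats::rnorm(length(img), 0, noise_sigma)
    img <- if (is.null(seed)) addn() else with_seed(seed, addn())
    img <- pmin(pmax(img, 0), 255)
  }
  box <- face_box(cx - s$face_ax * W - 1, cy - s$face_by * W - 1,
                  2 * s$face_ax * W + 2, 2 * s$face_by * W + 2)
  list(img = img, box = box)
}

#' Render one frame of a cohort recording (deterministic in the cohort seed)
#'
#' @param cohort a \code{"tic_cohort"}.
#' @param subject_id subject identifier (name in \code{cohort$subjects}).
#' @param frame_idx 0-based frame index.
#' @return \code{list(img, box)} as \code{\link{render_frame}}.
#' @export
cohort_frame <- function(cohort, subject_id, frame_idx) {
  su <- cohort$subjects[[subject_id]]
  if (is.null(su)) stopf("unknown subject '%s'", subject_id)
  cfg <- cohort$config
  render_frame(su$style, frame_idx / cfg$fps, su$schedule,
               size = cfg$render_size, noise_sigma = cfg$noise_sigma,
               seed = derive_seed(cfg$seed,
                                  paste0("noise_", subject_id, "_", frame_idx)),
               blinks = su$blinks)
}

#' Ground-truth face detector backed by the synthetic generator
#'
#' The face-detection interface of the pipeline: a function
#' \code{(subject_id, frame_idx) -> face_box or NULL}. The default
#' implementation returns the generator's ground-truth boxes; an external
#' detector can be slotted in by supplying any function with the same shape
#' to the preprocessing helpers.
#'
#' @param cohort a \code{"tic_cohort"}.
#' @export
gt_face_detector <- function(cohort) {
  force(cohort)
  function(subject_id, frame_idx) cohort_frame(cohort, subject_id, frame_idx)$box
}

#' Render, ROI-crop and resize one cohort frame for the encoder
#'
#' Applies the standard preprocessing: ground-truth (or supplied) face box,
#' 20\% expansion, crop and bilinear resize to \code{out_size}.
#'
#' @param cohort a \code{"tic_cohort"}.
#' @param subject_id,frame_idx frame address.
#' @param out_size encoder input side.
#' @param roi_factor box expansion factor (default 0.2).
#' @param detector optional face detector \code{(subject_id, frame_idx) -> box}.
#' @return an out_size x out_size x 3 array in [0, 255].
#' @export
roi_frame <- function(cohort, subject_id, frame_idx, out_size,
                      roi_factor = 0.2, detector = NULL) {
  fr <- cohort_frame(cohort, subject_id, frame_idx)
  box <- if (is.null(detector)) fr$box else detector(subject_id, frame_idx)
  sz <- cohort$config$render_size
  roi <- expand_roi(box, roi_factor, sz, sz)
  crop_resize(fr$img, roi, out_size)
}

#' Write a cohort to disk in the canonical on-disk layout
#'
#' Emits \code{manifest.csv} (recording_id, subject_id, fps, n_frames, width,
#' height, labeled), one VoTT-style JSON annotation file and one ground-truth
#' box CSV per recording, and the frames as \code{frame_\%06d.png} under one
#' directory per recording. Intended for small cohorts and interoperability
#' tests; the in-memory path renders frames lazily instead.
#'
#' @param cohort a \code{"tic_cohort"}.
#' @param dir output directory (created if needed).
#' @param max_frames optional cap on frames written per recording.
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir, max_frames = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- do.call(rbind, lapply(cohort$subjects, function(su) {
    m <- su$meta
    data.frame(recording_id = m$recording_id, subject_id = m$subject_id,
               fps = m$fps, n_frames = m$n_frames, width = m$width,
               height = m$height, labeled = m$labeled,
               stringsAsFactors = FALSE)
  }))
  rownames(man) <- NULL
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  for (su in cohort$subjects) {
    rid <- su$meta$recording_id
    write_vott(su$events, su$subject_id,
               file.path(dir, paste0(rid, "_annotations.json")))
    n <- su$meta$n_frames
    if (!is.null(max_frames)) n <- min(n, max_frames)
    fdir <- file.path(dir, rid)
    dir.create(fdir, showWarnings = FALSE)
    boxes <- data.frame(frame = integer(n), x = numeric(n), y = numeric(n),
                        w = numeric(n), h = numeric(n))
    for (i in seq_len(n)) {
      fr <- cohort_frame(cohort, su$subject_id, i - 1L)
      png::writePNG(fr$img / 255,
                    file.path(fdir, sprintf("frame_%06d.png", i - 1L)))
      boxes[i, ] <- c(i - 1L, fr$box$x, fr$box$y, fr$box$w, fr$box$h)
    }
    utils::write.csv(boxes, file.path(dir, paste0(rid, "_boxes.csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read frames back from the on-disk layout
#'
#' @param dir recording frame directory holding \code{frame_\%06d.png}.
#' @param indices 0-based frame indices.
#' @return list of h x w x 3 arrays in [0, 255].
#' @export
read_frames <- function(dir, indices) {
  lapply(indices, function(i) {
    p <- png::readPNG(file.path(dir, sprintf("frame_%06d.png", i)))
    if (length(dim(p)) == 2L) p <- array(rep(p, 3), c(dim(p), 3L))
    p[, , 1:3, drop = FALSE] * 255
  })
}

#' @export
print.tic_cohort <- function(x, ...) {
  cfg <- x$config
  nev <- sum(vapply(x$subjects, function(s) nrow(s$schedule), integer(1)))
  cat(sprintf("Synthetic tic cohort: %d subjects x %.4g s at %d fps (%dx%d px)\n",
              cfg$n_subjects, cfg$duration_s, cfg$fps, cfg$render_size,
              cfg$render_size))
  cat(sprintf("  clip-label mix target eye/mouth/normal = %s; calibrated rate %.2f tics/min\n",
              paste(cfg$class_mix, collapse = "/"), x$rate_per_min))
  cat(sprintf("  %d tic events scheduled; noise sigma %.3g; seed %d\n",
              nev, cfg$noise_sigma, cfg$seed))
  invisible(x)
}
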