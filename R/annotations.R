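# Annotation and recording handling: VoTT-style JSON tic events, frame-level
# segmentation of recordings, and 1-second clip windowing.

TIC_CATEGORIES <- c("eye_tic", "mouth_tic", "other_tic")
CLIP_LABELS <- c("normal", TIC_CATEGORIES)

#' Recording metadata record
#'
#' @param recording_id,subject_id identifiers.
#' @param fps frames per second; recordings are acquired at 25 or 30 fps.
#' @param n_frames total number of frames (>= 1).
#' @param width,height frame resolution in pixels.
#' @param labeled whether tic annotations exist for this recording.
#' @return a list of class \code{"recording_meta"}.
#' @export
recording_meta <- function(recording_id, subject_id, fps, n_frames,
                           width = 1920L, height = 1080L, labeled = TRUE) {
  fps <- as.integer(fps)
  if (!fps %in% c(25L, 30L)) stopf("fps must be 25 or 30, got %s", fps)
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stopf("n_frames must be >= 1")
  if (width < 1L || height < 1L) stopf("width and height must be >= 1")
  structure(list(recording_id = as.character(recording_id),
                 subject_id = as.character(subject_id),
                 fps = fps, n_frames = n_frames,
                 width = as.integer(width), height = as.integer(height),
                 labeled = isTRUE(labeled)),
            class = "recording_meta")
}

#' Construct a table of tic events
#'
#' @param subject_id subject identifier (recycled).
#' @param category tic category; anything outside \code{eye_tic},
#'   \code{mouth_tic} is coerced to \code{other_tic}.
#' @param start_s,end_s event boundaries in seconds, \code{start_s < end_s}.
#' @return a data.frame with columns subject_id, category, start_s, end_s,
#'   sorted by start_s.
#' @export
tic_events <- function(subject_id = character(), category = character(),
                       start_s = numeric(), end_s = numeric()) {
  ev <- data.frame(subject_id = as.character(subject_id),
                   category = normalize_category(category),
                   start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                   stringsAsFactors = FALSE)
  validate_events(ev)
  ev[order(ev$start_s), , drop = FALSE]
}

normalize_category <- function(x) {
  x <- as.character(x)
  x[!(x %in% TIC_CATEGORIES)] <- "other_tic"
  x
}

validate_events <- function(ev) {
  if (nrow(ev) == 0L) return(invisible(ev))
  bad <- which(!(ev$start_s >= 0 & ev$start_s < ev$end_s))
  if (length(bad))
    stopf("event %d invalid: need 0 <= start_s < end_s (got %.4g, %.4g)",
          bad[1], ev$start_s[bad[1]], ev$end_s[bad[1]])
  o <- order(ev$start_s)
  s <- ev$start_s[o]; e <- ev$end_s[o]
  if (nrow(ev) > 1L && any(s[-1] < e[-length(e)] - 1e-9))
    stopf("events overlap (event starting at %.4g s)", s[which(s[-1] < e[-length(e)])[1] + 1])
  invisible(ev)
}

#' Parse a VoTT-style annotation JSON document
#'
#' Accepts the minimal dialect written by \code{\link{write_vott}}: either a
#' top-level JSON array of \code{{category, start, end}} records (seconds), or
#' an object with a \code{subject_id} and an \code{events} array. Unknown
#' categories map to \code{other_tic}; events are returned sorted by start
#' time.
#'
#' @param json_text a JSON string or the path of a JSON file.
#' @return a tic-event data.frame (see \code{\link{tic_events}}).
#' @export
parse_vott <- function(json_text) {
  if (length(json_text) == 1L && !grepl("[{\\[]", substr(json_text, 1, 1)) &&
      file.exists(json_text))
    json_text <- paste(readLines(json_text, warn = FALSE), collapse = "\n")
  doc <- tryCatch(jsonlite::fromJSON(json_text, simplifyDataFrame = FALSE),
                  error = function(e) stopf("malformed annotation JSON: %s",
                                            conditionMessage(e)))
  subject <- "unknown"
  regions <- doc
  if (is.list(doc) && !is.null(names(doc))) {
    subject <- doc$subject_id %||% "unknown"
    regions <- doc$events
    if (is.null(regions)) stopf("malformed annotation JSON: missing field 'events'")
  }
  if (length(regions) == 0L) return(tic_events())
  rows <- lapply(seq_along(regions), function(i) {
    r <- regions[[i]]
    for (f in c("category", "start", "end"))
      if (is.null(r[[f]])) stopf("malformed annotation JSON: region %d missing field '%s'", i, f)
    if (!is.numeric(r$start) || !is.numeric(r$end) || r$end <= r$start)
      stopf("invalid timestamps in region %d: end (%s) must exceed start (%s)",
            i, format(r$end), format(r$start))
    data.frame(subject_id = as.character(r$subject %||% subject),
               category = normalize_category(r$category),
               start_s = as.numeric(r$start), end_s = as.numeric(r$end),
               stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, rows)
  validate_events(ev)
  ev[order(ev$start_s), , drop = FALSE]
}

#' Serialize tic events to the VoTT-style JSON dialect
#'
#' @param events a tic-event data.frame.
#' @param subject_id subject identifier stored at the top level.
#' @param path optional file path; if given, the JSON is written there.
#' @return the JSON string, invisibly when written to a file.
#' @export
write_vott <- function(events, subject_id = NULL, path = NULL) {
  subject_id <- subject_id %||% (if (nrow(events)) events$subject_id[1] else "unknown")
  doc <- list(subject_id = subject_id,
              events = lapply(seq_len(nrow(events)), function(i)
                list(category = events$category[i],
                     start = events$start_s[i], end = events$end_s[i])))
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' Cut a recording into labeled tic segments and inter-event normal segments
#'
#' Event timestamps are converted to frames with \code{floor} at the start and
#' \code{ceiling} at the end so no tic frame is lost to rounding; the gaps
#' between consecutive events (and the recording's ends) become
#' \code{normal} segments, optionally buffered away from tic boundaries by a
#' guard margin. With the default zero guard the segments tile
#' \code{[0, n_frames)} exactly.
#'
#' @param meta a \code{\link{recording_meta}}.
#' @param events tic events for this recording (non-overlapping, within the
#'   recording duration).
#' @param guard_s guard margin in seconds trimmed from each side of every
#'   normal segment adjacent to a tic event (default 0).
#' @return a data.frame with columns recording_id, subject_id, label,
#'   start_frame (0-based inclusive), end_frame (exclusive).
#' @export
cut_segments <- function(meta, events = tic_events(), guard_s = 0) {
  stopifnot(inherits(meta, "recording_meta"))
  validate_events(events)
  dur <- meta$n_frames / meta$fps
  if (nrow(events) && any(events$end_s > dur + 1e-9))
    stopf("event ending at %.4g s extends beyond the %.4g s recording",
          max(events$end_s), dur)
  g <- as.integer(round(guard_s * meta$fps))
  events <- events[order(events$start_s), , drop = FALSE]
  sf <- pmin(as.integer(floor(events$start_s * meta$fps)), meta$n_frames - 1L)
  ef <- pmin(as.integer(ceiling(events$end_s * meta$fps)), meta$n_frames)
  # rounding can make adjacent events touch; keep the tiling disjoint
  if (length(sf) > 1L) for (i in 2:length(sf)) sf[i] <- max(sf[i], ef[i - 1L])
  seg <- list()
  add <- function(label, s, e) {
    if (e > s) seg[[length(seg) + 1L]] <<- data.frame(
      recording_id = meta$recording_id, subject_id = meta$subject_id,
      label = label, start_frame = as.integer(s), end_frame = as.integer(e),
      stringsAsFactors = FALSE)
  }
  cursor <- 0L
  for (i in seq_len(nrow(events))) {
    # normal gap before event i; the guard trims only sides touching a tic
    gap_lo <- cursor + (if (i > 1L) g else 0L)
    add("normal", gap_lo, sf[i] - g)
    add(events$category[i], sf[i], ef[i])
    cursor <- ef[i]
  }
  add("normal", cursor + (if (nrow(events)) g else 0L), meta$n_frames)
  out <- do.call(rbind, seg)
  rownames(out) <- NULL
  out
}

#' Window a segment into non-overlapping 1-second clips
#'
#' A segment of L frames at f fps yields \code{floor(L/f)} clips of exactly f
#' consecutive frames, left-aligned; the trailing remainder shorter than one
#' second is discarded. Clips inherit the segment label.
#'
#' @param segment one row of the data.frame returned by
#'   \code{\link{cut_segments}}.
#' @param fps frames per second of the parent recording.
#' @return a data.frame with columns clip_id, recording_id, subject_id, label,
#'   start_frame, end_frame (absolute, half-open); zero rows for sub-second
#'   segments.
#' @export
window_clips <- function(segment, fps) {
  fps <- as.integer(fps)
  len <- segment$end_frame - segment$start_frame
  n <- len %/% fps
  if (n <= 0L) return(empty_clips())
  starts <- segment$start_frame + (0:(n - 1L)) * fps
  data.frame(clip_id = sprintf("%s_f%06d", segment$recording_id, starts),
             recording_id = segment$recording_id,
             subject_id = segment$subject_id,
             label = segment$label,
             start_frame = starts, end_frame = starts + fps,
             stringsAsFactors = FALSE)
}

empty_clips <- function() {
  data.frame(clip_id = character(), recording_id = character(),
             subject_id = character(), label = character(),
             start_frame = integer(), end_frame = integer(),
             stringsAsFactors = FALSE)
}

#' Segment and window a whole recording in one step
#'
#' @inheritParams cut_segments
#' @return the row-bound clips of all segments (see \code{\link{window_clips}}).
#' @export
recording_clips <- function(meta, events = tic_events(), guard_s = 0) {
  segs <- cut_segments(meta, events, guard_s = guard_s)
  out <- do.call(rbind, lapply(seq_len(nrow(segs)),
                               function(i) window_clips(segs[i, ], meta$fps)))
  out %||% empty_clips()
}

#' Frame indices covered by one clip row
#' @param clip one row of a clips data.frame.
#' @return the 0-based frame indices, consecutive and strictly increasing.
#' @export
clip_frames <- function(clip) seq.int(clip$start_frame, clip$end_frame - 1L)
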