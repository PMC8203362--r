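# Face-ROI preprocessing: bounding-box expansion, temporal downsampling,
# bilinear crop-resize to the encoder input size, and the stochastic
# augmentation pairs that feed the contrastive stage.

#' Face bounding box
#'
#' Pixel coordinates are 0-based with \code{x,y} the top-left corner; boxes
#' may extend beyond the frame before clamping.
#' @param x,y top-left corner in pixels.
#' @param w,h box width and height in pixels (> 0).
#' @export
face_box <- function(x, y, w, h) {
  if (w <= 0 || h <= 0) stopf("face box must have positive size")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 w = as.numeric(w), h = as.numeric(h)), class = "face_box")
}

#' Expand a face box around its center and clamp to the frame
#'
#' The detected face box is enlarged by \code{factor} (default 20\%) in width
#' and height, keeping the center fixed, so the ROI keeps the margin around
#' the face that free patient motion requires; the result is clamped to the
#' frame. The output always contains the (clamped) input box.
#'
#' @param box a \code{\link{face_box}}.
#' @param factor fractional enlargement per axis (>= 0); \code{factor_h}
#'   defaults to \code{factor} but can differ.
#' @param frame_w,frame_h frame size in pixels.
#' @return the expanded, clamped \code{face_box}.
#' @export
expand_roi <- function(box, factor = 0.2, frame_w, frame_h, factor_h = factor) {
  stopifnot(inherits(box, "face_box"), factor >= 0, factor_h >= 0)
  if (box$x >= frame_w || box$y >= frame_h ||
      box$x + box$w <= 0 || box$y + box$h <= 0)
    stopf("face box lies entirely outside the %dx%d frame: subject lost",
          frame_w, frame_h)
  cx <- box$x + box$w / 2; cy <- box$y + box$h / 2
  w <- box$w * (1 + factor); h <- box$h * (1 + factor_h)
  x0 <- max(0, cx - w / 2); y0 <- max(0, cy - h / 2)
  x1 <- min(frame_w, cx + w / 2); y1 <- min(frame_h, cy + h / 2)
  face_box(x0, y0, x1 - x0, y1 - y0)
}

#' Keep the first of every three consecutive frames
#'
#' Temporal 3-fold downsampling applied before the contrastive stage:
#' consecutive video frames are highly redundant, so only every third frame
#' (starting from the first) is retained; the output length is
#' \code{ceiling(n/3)}.
#'
#' @param frame_indices strictly increasing integer vector.
#' @return the retained indices.
#' @export
downsample_3fold <- function(frame_indices) {
  n <- length(frame_indices)
  if (n == 0L) return(frame_indices)
  if (n > 1L && any(diff(frame_indices) <= 0))
    stopf("frame indices must be strictly increasing")
  frame_indices[seq.int(1L, n, by = 3L)]
}

# Dense row/column interpolation matrices for bilinear resizing with
# half-pixel centers: output pixel o samples source coordinate
# (o - 0.5) * src/out + 0.5 (1-based pixel centers), clamped to the border.
bilinear_weights <- function(src, out) {
  pos <- (seq_len(out) - 0.5) * src / out + 0.5
  pos <- pmin(pmax(pos, 1), src)
  i0 <- pmin(floor(pos), src - 1L); i0[src == 1L] <- 1
  fr <- pos - i0
  A <- matrix(0, out, src)
  A[cbind(seq_len(out), i0)] <- 1 - fr
  if (src > 1L) A[cbind(seq_len(out), i0 + 1L)] <- A[cbind(seq_len(out), i0 + 1L)] + fr
  A
}

#' Bilinear image resize (half-pixel centers)
#'
#' @param img numeric array h x w x c (or matrix) with intensities in [0,255].
#' @param out_h,out_w output size in pixels.
#' @return resized array of the same channel count.
#' @export
resize_bilinear <- function(img, out_h, out_w = out_h) {
  m <- if (length(dim(img)) == 2L) array(img, c(dim(img), 1L)) else img
  A <- bilinear_weights(dim(m)[1], out_h)
  B <- bilinear_weights(dim(m)[2], out_w)
  out <- array(0, c(out_h, out_w, dim(m)[3]))
  for (ch in seq_len(dim(m)[3])) out[, , ch] <- A %*% m[, , ch] %*% t(B)
  if (length(dim(img)) == 2L) out[, , 1] else out
}

#' Crop a face ROI and resample it to the network input size
#'
#' @param frame numeric array h x w x 3, intensities in [0,255].
#' @param box a \code{\link{face_box}} (clamped to the frame).
#' @param out_size side length of the square output (112 for the full-scale
#'   encoder).
#' @return an out_size x out_size x 3 array.
#' @export
crop_resize <- function(frame, box, out_size) {
  h <- dim(frame)[1]; w <- dim(frame)[2]
  x0 <- max(0L, as.integer(floor(box$x))); y0 <- max(0L, as.integer(floor(box$y)))
  x1 <- min(w, as.integer(ceiling(box$x + box$w)))
  y1 <- min(h, as.integer(ceiling(box$y + box$h)))
  if (x1 - x0 < 1L || y1 - y0 < 1L) stopf("degenerate (zero-area) face box")
  roi <- frame[(y0 + 1L):y1, (x0 + 1L):x1, , drop = FALSE]
  resize_bilinear(roi, out_size, out_size)
}

#' Augmentation configuration for contrastive view pairs
#'
#' @param crop_scale_range range of the area fraction retained by the random
#'   crop (defaults follow common contrastive-learning practice).
#' @param noise_sigma standard deviation of the additive Gaussian pixel noise,
#'   in 8-bit intensity units.
#' @param color_strength amplitude of the channel-wise affine color jitter
#'   (gain in [1 - s, 1 + s], offset in [-32 s, 32 s] intensity units).
#' @param out_size side length of the augmented output.
#' @export
augment_config <- function(crop_scale_range = c(0.6, 1.0), noise_sigma = 5,
                           color_strength = 0.4, out_size = 112) {
  stopifnot(length(crop_scale_range) == 2L,
            crop_scale_range[1] > 0,
            crop_scale_range[1] <= crop_scale_range[2],
            crop_scale_range[2] <= 1,
            noise_sigma >= 0, color_strength >= 0)
  structure(list(crop_scale_range = as.numeric(crop_scale_range),
                 noise_sigma = as.numeric(noise_sigma),
                 color_strength = as.numeric(color_strength),
                 out_size = as.integer(out_size)), class = "augment_config")
}

# One stochastic view, drawn from the current RNG stream.
# Order fixed as crop -> color -> noise (noise must not be color-jittered).
augment_one <- function(img, cfg) {
  h <- dim(img)[1]; w <- dim(img)[2]
  a <- stats::runif(1, cfg$crop_scale_range[1], cfg$crop_scale_range[2])
  side <- sqrt(a)
  chh <- max(1L, as.integer(round(h * side)))
  cww <- max(1L, as.integer(round(w * side)))
  y0 <- if (h > chh) sample.int(h - chh + 1L, 1L) - 1L else 0L
  x0 <- if (w > cww) sample.int(w - cww + 1L, 1L) - 1L else 0L
  v <- img[(y0 + 1L):(y0 + chh), (x0 + 1L):(x0 + cww), , drop = FALSE]
  if (chh != cfg$out_size || cww != cfg$out_size)
    v <- resize_bilinear(v, cfg$out_size, cfg$out_size)
  if (cfg$color_strength > 0) {
    gain <- stats::runif(3, 1 - cfg$color_strength, 1 + cfg$color_strength)
    off <- stats::runif(3, -32 * cfg$color_strength, 32 * cfg$color_strength)
    for (ch in 1:3) v[, , ch] <- v[, , ch] * gain[ch] + off[ch]
    v <- pmin(pmax(v, 0), 255)
  }
  if (cfg$noise_sigma > 0) {
    v <- v + stats::rnorm(length(v), 0, cfg$noise_sigma)
    v <- pmin(pmax(v, 0), 255)
  }
  v
}

#' Generate a positive pair of augmented views
#'
#' Produces the two independently augmented views of one ROI image that form
#' a positive pair in the contrastive prediction task: random crop (resized
#' back to \code{out_size}), channel-wise color jitter, then additive Gaussian
#' noise. The same \code{seed} reproduces the identical pair bitwise.
#'
#' @param img ROI image array (h x w x 3, intensities in [0,255]).
#' @param cfg an \code{\link{augment_config}}.
#' @param seed integer seed for this draw; \code{NULL} uses the current RNG
#'   stream (as the training loop does).
#' @return a list of two out_size x out_size x 3 arrays.
#' @export
augment_pair <- function(img, cfg, seed = NULL) {
  go <- function() list(augment_one(img, cfg), augment_one(img, cfg))
  if (is.null(seed)) go() else with_seed(seed, go())
}
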