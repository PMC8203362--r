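# Grad-CAM saliency: gradients of a scalar target with respect to the final
# residual stage's output activations, spatially averaged into per-channel
# weights, combined into a ReLU-rectified map and upsampled to input size.

#' Grad-CAM saliency map for one encoder input
#'
#' Computes the gradient of \code{target} with respect to the final
#' convolutional activation block of the encoder, averages it spatially into
#' per-channel weights, forms \code{ReLU(sum_c w_c A_c)}, bilinearly upsamples
#' the map to the input size and normalizes its maximum to 1 (an identically
#' zero map — e.g. a target independent of the image — stays all zero).
#'
#' @param encoder a fitted \code{"tic_encoder"} (or its bare \code{tic_net}).
#' @param image one ROI image at the encoder input size, intensities [0,255].
#' @param target the scalar output selector: a weight vector w over the D
#'   feature dimensions (target = w . f), or a function mapping the feature
#'   vector to \code{list(value, grad)}.
#' @return a list of class \code{"cam_map"}: \code{heatmap} (input-sized,
#'   values in [0,1]), \code{raw} (conv-resolution map), \code{weights}.
#' @export
grad_cam <- function(encoder, image, target) {
  net <- if (inherits(encoder, "tic_encoder")) encoder$encoder else encoder
  if (!inherits(net, "tic_net")) stopf("unsupported model: need a tic_net encoder")
  sz <- dim(image)[1]
  X <- array(image / 255, c(dim(image)[1], dim(image)[2], 3L, 1L))
  fw <- net_forward(net, X, keep = TRUE)
  if (is.null(fw$last_conv))
    stopf("unsupported model: encoder exposes no spatial activation block")
  f <- fw$out[, 1]
  dF <- if (is.function(target)) target(f)$grad else {
    if (length(target) != length(f))
      stopf("target weight vector length (%d) != feature dim (%d)",
            length(target), length(f))
    as.numeric(target)
  }
  bw <- net_backward(net, fw, matrix(dF, ncol = 1))
  dA <- bw$d_last_conv                       # (h, w, c, 1) grad at last block
  # activation at the last residual block output
  A_pre <- fw$caches[[fw$last_conv]]$pre
  A <- pmax(A_pre, 0)
  d <- dim(A)
  w <- colMeans(matrix(dA, d[1] * d[2], d[3]))          # spatial mean per channel
  cam <- matrix(matrix(A[, , , 1], d[1] * d[2], d[3]) %*% w, d[1], d[2])
  cam <- pmax(cam, 0)
  up <- resize_bilinear(cam, sz, dim(image)[2])
  up <- pmax(up, 0)
  if (max(up) > 0) up <- up / max(up)
  structure(list(heatmap = up, raw = cam, weights = w), class = "cam_map")
}

#' Locate the peak of a saliency map
#'
#' Grad-CAM's native spatial resolution is the final convolutional grid;
#' the input-sized heatmap is only its bilinear upsampling, whose maximum
#' is a plateau rather than a point (for a border grid cell the plateau
#' extends to the image edge, so a naive argmax lands on a boundary
#' pixel). The peak is therefore located on the raw grid and reported as
#' the attended cell's center in input-pixel coordinates. The
#' \code{"heatmap"} mode (intensity-weighted centroid of the near-maximal
#' upsampled region) is available for comparison.
#'
#' @param cam a \code{"cam_map"}.
#' @param at \code{"grid"} (default) or \code{"heatmap"}.
#' @return c(row, col), 1-based input-pixel coordinates; \code{NA} for an
#'   all-zero map.
#' @export
cam_peak <- function(cam, at = c("grid", "heatmap")) {
  at <- match.arg(at)
  if (max(cam$heatmap) == 0) return(c(row = NA_real_, col = NA_real_))
  if (at == "grid") {
    ind <- which(cam$raw == max(cam$raw), arr.ind = TRUE)[1, ]
    scale_r <- nrow(cam$heatmap) / nrow(cam$raw)
    scale_c <- ncol(cam$heatmap) / ncol(cam$raw)
    return(c(row = (ind[1] - 0.5) * scale_r, col = (ind[2] - 0.5) * scale_c))
  }
  M <- cam$heatmap
  sel <- which(M >= 0.95 * max(M), arr.ind = TRUE)
  w <- M[sel]
  c(row = stats::weighted.mean(sel[, 1], w),
    col = stats::weighted.mean(sel[, 2], w))
}

#' @export
print.cam_map <- function(x, ...) {
  pk <- cam_peak(x)
  cat(sprintf("Grad-CAM map %dx%d (conv resolution %dx%d), peak at (%s, %s)\n",
              nrow(x$heatmap), ncol(x$heatmap), nrow(x$raw), ncol(x$raw),
              format(pk[1], digits = 3), format(pk[2], digits = 3)))
  invisible(x)
}

#' @export
plot.cam_map <- function(x, ...) {
  graphics::image(t(x$heatmap)[, nrow(x$heatmap):1],
                  col = grDevices::hcl.colors(32, "inferno"), axes = FALSE, ...)
  invisible(x)
}
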