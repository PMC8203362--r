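# Focal loss: cross-entropy reweighted by (1 - p_t)^gamma and a class weight
# alpha_t, emphasizing hard and rare examples under class imbalance.

#' Focal loss configuration
#'
#' @param alpha class weight(s) \eqn{\alpha_t} in [0, 1]: a scalar, or one
#'   weight per class for the multiclass one-vs-rest treatment. The package
#'   default when training (\code{alpha = NULL}) is inverse class frequency
#'   normalized so the largest weight is 1.
#' @param gamma focusing exponent \eqn{\gamma \ge 0}; 0 recovers plain
#'   cross-entropy.
#' @export
focal_config <- function(alpha = NULL, gamma = 2) {
  if (gamma < 0) stopf("gamma must be >= 0")
  if (!is.null(alpha) && (any(alpha < 0) || any(alpha > 1)))
    stopf("alpha weights must lie in [0, 1]")
  structure(list(alpha = alpha, gamma = gamma), class = "focal_config")
}

#' Focal loss of a single binary prediction
#'
#' With \eqn{p_t = p} when \eqn{y = 1} and \eqn{1 - p} otherwise, returns
#' \eqn{-\alpha_t (1 - p_t)^\gamma \log p_t}, computed from \code{log(p_t)}
#' directly so small probabilities stay accurate. Non-negative, and equal to
#' the cross-entropy when \eqn{\gamma = 0, \alpha_t = 1}.
#'
#' @param p predicted probability of class 1, strictly inside (0, 1).
#' @param y observed label, 0 or 1 (one-vs-rest per class for multiclass).
#' @param cfg a \code{\link{focal_config}}; a scalar \code{alpha} is used as
#'   \eqn{\alpha_t} directly.
#' @export
focal_loss <- function(p, y, cfg = focal_config(alpha = 1)) {
  if (any(p <= 0) || any(p >= 1)) stopf("p must lie strictly in (0, 1)")
  alpha <- cfg$alpha %||% 1
  logpt <- ifelse(y == 1, log(p), log1p(-p))
  pt <- exp(logpt)
  -alpha * (1 - pt)^cfg$gamma * logpt
}

# Mean one-vs-rest focal loss over classes and samples, plus gradient w.r.t.
# logits. logits: (C x B); y: integer class in 1..C; alpha: length-C weights.
focal_softmax_loss <- function(logits, y, alpha, gamma, grad = FALSE) {
  C <- nrow(logits); B <- ncol(logits)
  m <- apply(logits, 2, max)
  Z <- sweep(logits, 2, m)
  lse <- log(colSums(exp(Z)))
  logp <- sweep(Z, 2, lse)
  P <- exp(logp)
  Y <- matrix(0, C, B); Y[cbind(y, seq_len(B))] <- 1
  # per-entry p_t and log(p_t): p for the true class, 1-p elsewhere
  logpt <- ifelse(Y == 1, logp, log1p(-P))
  pt <- exp(logpt)
  A <- matrix(alpha, C, B)
  terms <- -A * (1 - pt)^gamma * logpt
  L <- mean(colMeans(terms))
  if (!grad) return(L)
  # d term / d p_t, then d p_t / d p = +1 (true class) or -1 (others)
  pt <- pmin(pmax(pt, 1e-12), 1 - 1e-12)
  t1 <- if (gamma > 0) gamma * (1 - pt)^(gamma - 1) * logpt else 0
  dl_dpt <- A * (t1 - (1 - pt)^gamma / pt)
  dl_dp <- ifelse(Y == 1, dl_dpt, -dl_dpt) / (C * B)
  # softmax Jacobian: dz_j = p_j (g_j - sum_c g_c p_c)
  s <- colSums(dl_dp * P)
  dZ <- P * sweep(dl_dp, 2, s)
  list(loss = L, grad = dZ)
}
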