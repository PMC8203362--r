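# Stage 1: self-supervised contrastive pretraining of the visual encoder.
# Each minibatch of N frames becomes 2N augmented views arranged so rows
# (2k-1, 2k) form the k-th positive pair; the NT-Xent objective pulls
# positive pairs together and pushes all other views in the batch apart.

#' Cosine similarity of two vectors
#'
#' @param u,v numeric vectors of equal length with positive norm.
#' @return \code{sum(u*v) / (||u|| ||v||)}, in [-1, 1].
#' @export
cosine_sim <- function(u, v) {
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0) stopf("cosine similarity undefined for zero-norm input")
  sum(u * v) / (nu * nv)
}

check_embedding_batch <- function(z) {
  if (!is.matrix(z)) z <- as.matrix(z)
  if (nrow(z) %% 2L != 0L) stopf("embedding batch must have an even row count (2N)")
  nrm <- sqrt(rowSums(z * z))
  if (any(nrm == 0)) stopf("embedding batch contains an all-zero row")
  z
}

# Temperature-scaled cosine-similarity matrix with -Inf diagonal mask.
ntxent_logits <- function(z, tau) {
  if (tau <= 0) stopf("temperature must be > 0")
  u <- z / sqrt(rowSums(z * z))
  A <- tcrossprod(u) / tau
  diag(A) <- -Inf
  list(A = A, u = u)
}

#' Directed NT-Xent loss of one positive pair
#'
#' \code{-log( exp(sim(i,j)/tau) / sum_{k != i} exp(sim(i,k)/tau) )}, the sum
#' running over all 2N - 1 other rows of the batch; computed with a
#' numerically stable log-sum-exp. Always >= 0 and exactly 0 when the batch
#' holds a single pair.
#'
#' @param i,j 1-based row indices of the directed pair (anchor \code{i}).
#' @param batch 2N x P matrix of projected embeddings, rows (2k-1, 2k) being
#'   the k-th positive pair.
#' @param tau temperature (> 0).
#' @export
ntxent_pair_loss <- function(i, j, batch, tau) {
  z <- check_embedding_batch(batch)
  if (i == j || i < 1 || j < 1 || i > nrow(z) || j > nrow(z))
    stopf("invalid pair indices (%s, %s)", i, j)
  A <- ntxent_logits(z, tau)$A
  row <- A[i, -i]
  m <- max(row)
  (m + log(sum(exp(row - m)))) - A[i, j]
}

#' Total NT-Xent loss of an augmented minibatch
#'
#' The mean of the 2N directed pair losses
#' \code{loss(2k-1, 2k)} and \code{loss(2k, 2k-1)} over the N pairs.
#' Optionally returns the analytic gradient with respect to the (unnormalized)
#' embeddings, used by the training loop and verified against numerical
#' differentiation in the tests.
#'
#' @inheritParams ntxent_pair_loss
#' @param grad if TRUE, also return \code{d loss / d batch}.
#' @return the scalar loss, or \code{list(loss, grad)} when \code{grad = TRUE}.
#' @export
ntxent_total_loss <- function(batch, tau, grad = FALSE) {
  z <- check_embedding_batch(batch)
  ntxent_core(z, tau, grad)
}

# Training-loop variant: a projection head can momentarily emit an all-zero
# row (dead ReLU path early in optimization); rather than aborting the run,
# such rows are treated as directionless (zero similarity, zero gradient).
ntxent_lenient <- function(z, tau, grad = FALSE) {
  if (!is.matrix(z)) z <- as.matrix(z)
  if (nrow(z) %% 2L != 0L) stopf("embedding batch must have an even row count (2N)")
  dead <- rowSums(z * z) == 0
  if (any(dead)) z[dead, 1] <- 1e-8
  out <- ntxent_core(z, tau, grad)
  if (grad && any(dead)) out$grad[dead, ] <- 0
  out
}

ntxent_core <- function(z, tau, grad = FALSE) {
  n2 <- nrow(z)
  lg <- ntxent_logits(z, tau)
  A <- lg$A
  partner <- seq_len(n2) + c(1L, -1L)    # (1,2)->(2,1), (3,4)->(4,3), ...
  m <- apply(A, 1L, max)
  P <- exp(A - m)                        # row-wise stabilized
  rs <- rowSums(P)
  lse <- m + log(rs)
  losses <- lse - A[cbind(seq_len(n2), partner)]
  L <- mean(losses)
  if (!grad) return(L)
  G <- P / rs / (n2 * tau)               # softmax weights, prefactor 1/(2N tau)
  G[cbind(seq_len(n2), partner)] <- G[cbind(seq_len(n2), partner)] - 1 / (n2 * tau)
  diag(G) <- 0
  dU <- (G + t(G)) %*% lg$u
  nrm <- sqrt(rowSums(z * z))
  dZ <- (dU - lg$u * rowSums(lg$u * dU)) / nrm
  list(loss = L, grad = dZ)
}

#' Subject-restricted continuous-frame minibatch schedule
#'
#' Stage-1 minibatches must consist of consecutive downsampled frames of a
#' single subject, with the subject and window start drawn at random: the
#' negatives are then nearby frames of the same person, which forces the
#' encoder to discriminate facial configuration rather than identity. One
#' epoch emits \code{floor(n_s / batch_size)} windows per eligible subject
#' (so every eligible subject is visited at least once); subjects with fewer
#' than \code{batch_size} frames are skipped with a warning.
#'
#' @param frame_index named list: per subject, the ordered vector of frame
#'   references (indices into that subject's downsampled stream).
#' @param batch_size frames per minibatch (512 full scale).
#' @param seed integer seed for the schedule.
#' @return a list of batches; each batch is a list with \code{subject} and
#'   \code{frames} (a consecutive slice of that subject's reference vector).
#' @export
subject_restricted_batches <- function(frame_index, batch_size, seed = 1L) {
  ns <- vapply(frame_index, length, integer(1))
  eligible <- names(frame_index)[ns >= batch_size]
  if (length(eligible) < length(frame_index))
    warning(sprintf("%d subject(s) with fewer than %d frames skipped",
                    length(frame_index) - length(eligible), batch_size))
  if (length(eligible) == 0L)
    stopf("no subject has at least batch_size = %d frames", batch_size)
  with_seed(seed, {
    sched <- unlist(lapply(eligible,
                           function(s) rep(s, ns[[s]] %/% batch_size)))
    sched <- sample(sched)
    lapply(sched, function(s) {
      n <- ns[[s]]
      start <- sample.int(n - batch_size + 1L, 1L)
      list(subject = s,
           frames = frame_index[[s]][start:(start + batch_size - 1L)])
    })
  })
}

#' Configuration of the contrastive pretraining stage
#'
#' Defaults follow the full-scale recipe: batch of 512 frames, Adam at
#' 3e-4 with cosine-annealed learning rate, weight decay 1e-6, early stop
#' when the validation loss has not improved for 10 epochs. The temperature
#' default of 0.5 is a package choice (exposed here).
#'
#' @param batch_pairs frames (= positive pairs) per minibatch.
#' @param temperature NT-Xent temperature tau (> 0).
#' @param lr initial Adam learning rate.
#' @param weight_decay L2 penalty added to gradients.
#' @param max_epochs annealing period and epoch cap.
#' @param patience_epochs early-stopping patience on the validation loss.
#' @param val_fraction subject-level fraction held out for validation (0.3).
#' @param seed master seed for split, sampler, augmentation and init.
#' @export
contrastive_config <- function(batch_pairs = 512L, temperature = 0.5,
                               lr = 3e-4, weight_decay = 1e-6,
                               max_epochs = 100L, patience_epochs = 10L,
                               val_fraction = 0.3, seed = 1L) {
  if (temperature <= 0) stopf("temperature must be > 0")
  if (patience_epochs < 1) stopf("patience_epochs must be >= 1")
  structure(list(batch_pairs = as.integer(batch_pairs),
                 temperature = temperature, lr = lr,
                 weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs),
                 patience_epochs = as.integer(patience_epochs),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "contrastive_config")
}

# one optimisation (or evaluation) pass over a batch of ROI images;
# training passes use batch statistics in the normalization layers and hand
# the updated running stats to the caller through update()
contrastive_batch_pass <- function(enc, proj, imgs, aug, tau, update = NULL) {
  B <- length(imgs)
  osz <- aug$out_size
  X <- array(0, c(osz, osz, 3L, 2L * B))
  for (k in seq_len(B)) {
    pr <- augment_pair(imgs[[k]], aug)
    X[, , , 2L * k - 1L] <- pr[[1]]
    X[, , , 2L * k] <- pr[[2]]
  }
  X <- X / 255
  train <- !is.null(update)
  fe <- net_forward(enc, X, keep = train, train = train)
  fp <- net_forward(proj, fe$out, keep = train)
  z <- t(fp$out)                                    # rows = views
  if (!train) return(ntxent_lenient(z, tau))
  r <- ntxent_lenient(z, tau, grad = TRUE)
  bp <- net_backward(proj, fp, t(r$grad), want_input_grad = TRUE)
  be <- net_backward(enc, fe, bp$d_input)
  update(bp$grads, be$grads, fe$bn_upd)
  r$loss
}

#' Pretrain the visual encoder by contrastive learning (Stage 1)
#'
#' Splits subjects 70/30 into training and validation at the subject level,
#' then minimizes the NT-Xent objective over subject-restricted
#' continuous-frame minibatches: every frame is augmented into a positive
#' pair, encoded, projected, and the batch loss backpropagated through both
#' networks with Adam under a cosine-annealed learning rate. Training stops
#' at \code{max_epochs} or when the validation loss has not reached a new
#' minimum for \code{patience_epochs} epochs; the parameters of the best
#' validation epoch are returned.
#'
#' @param frames named list: per subject, a list of ROI images (arrays
#'   h x w x 3, intensities in [0,255]) in temporal order, already
#'   3-fold-downsampled.
#' @param cfg a \code{\link{contrastive_config}}.
#' @param enc_spec an \code{\link{encoder_spec}}.
#' @param proj_spec a \code{\link{projection_spec}} (defaults to dimensions
#'   derived from \code{enc_spec}).
#' @param aug an \code{\link{augment_config}} sized to the encoder input.
#' @param verbose print per-epoch losses.
#' @return an object of class \code{"tic_encoder"}: the trained encoder and
#'   projection nets, configuration echo, and the loss history (one row per
#'   epoch: train and validation NT-Xent loss).
#' @export
tic_pretrain <- function(frames, cfg = contrastive_config(),
                         enc_spec = encoder_spec(),
                         proj_spec = NULL, aug = NULL, verbose = FALSE) {
  if (length(frames) < 2L)
    stopf("need >= 2 subjects for a subject-level train/validation split")
  proj_spec <- proj_spec %||% projection_spec(enc_spec$out_dim,
                                              enc_spec$out_dim,
                                              max(2L, enc_spec$out_dim %/% 2L))
  aug <- aug %||% augment_config(out_size = enc_spec$input_size)
  if (aug$out_size != enc_spec$input_size)
    stopf("augmentation out_size (%d) must match encoder input (%d)",
          aug$out_size, enc_spec$input_size)

  subjects <- names(frames)
  n_val <- max(1L, round(cfg$val_fraction * length(subjects)))
  if (n_val >= length(subjects)) n_val <- length(subjects) - 1L
  val_subj <- with_seed(derive_seed(cfg$seed, "split"),
                        sample(subjects, n_val))
  train_subj <- setdiff(subjects, val_subj)

  enc <- with_seed(derive_seed(cfg$seed, "init"), init_encoder_net(enc_spec))
  proj <- with_seed(derive_seed(cfg$seed, "init_proj"),
                    init_projection_net(proj_spec))
  pe <- net_params(enc); pp <- net_params(proj)
  st_e <- adam_init(pe); st_p <- adam_init(pp)

  idx_of <- function(sub) {
    fi <- lapply(frames[sub], seq_along)
    names(fi) <- sub
    fi
  }
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, pe = pe, pp = pp, bn = net_bn_stats(enc), epoch = 0L)
  since_best <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    lr <- cosine_lr(cfg$lr, epoch, cfg$max_epochs)
    batches <- subject_restricted_batches(idx_of(train_subj), cfg$batch_pairs,
                                          derive_seed(cfg$seed, paste0("ep", epoch)))
    tr_losses <- numeric(length(batches))
    set.seed(derive_seed(cfg$seed, paste0("aug", epoch)))
    for (bi in seq_along(batches)) {
      b <- batches[[bi]]
      upd <- function(gp, ge, bn_upd) {
        rp <- adam_step(pp, gp, st_p, lr, cfg$weight_decay)
        pp <<- rp$params; st_p <<- rp$state
        re <- adam_step(pe, ge, st_e, lr, cfg$weight_decay)
        pe <<- re$params; st_e <<- re$state
        enc <<- net_apply_bn(enc, bn_upd)
      }
      enc <- net_set_params(enc, pe); proj <- net_set_params(proj, pp)
      tr_losses[bi] <- contrastive_batch_pass(enc, proj,
                                              frames[[b$subject]][b$frames],
                                              aug, cfg$temperature, upd)
    }
    enc <- net_set_params(enc, pe); proj <- net_set_params(proj, pp)
    vb <- subject_restricted_batches(idx_of(val_subj), cfg$batch_pairs,
                                     derive_seed(cfg$seed, paste0("vep", epoch)))
    set.seed(derive_seed(cfg$seed, paste0("vaug", epoch)))
    val_losses <- vapply(vb, function(b)
      contrastive_batch_pass(enc, proj, frames[[b$subject]][b$frames],
                             aug, cfg$temperature), numeric(1))
    tl <- mean(tr_losses); vl <- mean(val_losses)
    history <- rbind(history, data.frame(epoch = epoch, train_loss = tl,
                                         val_loss = vl))
    if (verbose) message(sprintf("epoch %3d  lr %.2e  train %.4f  val %.4f",
                                 epoch, lr, tl, vl))
    if (vl < best$loss - 1e-12) {
      best <- list(loss = vl, pe = pe, pp = pp, bn = net_bn_stats(enc),
                   epoch = epoch)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= cfg$patience_epochs) break
    }
  }
  enc <- net_set_bn_stats(net_set_params(enc, best$pe), best$bn)
  proj <- net_set_params(proj, best$pp)
  structure(list(encoder = enc, projection = proj, spec = enc_spec,
                 proj_spec = proj_spec, config = cfg, augment = aug,
                 history = history, best_epoch = best$epoch,
                 val_subjects = val_subj),
            class = "tic_encoder")
}

#' Encode preprocessed images into feature vectors
#'
#' @param object a fitted \code{"tic_encoder"}.
#' @param newdata one image (h x w x 3) or a list of images, already at the
#'   encoder input size, intensities in [0,255].
#' @param ... unused.
#' @return a matrix with one D-dimensional feature row per image.
#' @export
predict.tic_encoder <- function(object, newdata, ...) {
  imgs <- if (is.list(newdata)) newdata else list(newdata)
  sz <- object$spec$input_size
  X <- array(0, c(sz, sz, 3L, length(imgs)))
  for (k in seq_along(imgs)) X[, , , k] <- imgs[[k]]
  X <- X / 255
  t(net_forward(object$encoder, X, keep = FALSE)$out)
}

#' @export
print.tic_encoder <- function(x, ...) {
  cat(sprintf("Contrastively pretrained tic-video encoder (%s)\n",
              x$spec$depth_tag))
  cat(sprintf("  input %dx%dx3 -> features %d-d -> projection %d-d\n",
              x$spec$input_size, x$spec$input_size, x$spec$out_dim,
              x$proj_spec$proj_dim))
  cat(sprintf("  temperature %.3g, batch %d pairs, trained %d epoch(s), best epoch %d\n",
              x$config$temperature, x$config$batch_pairs,
              nrow(x$history), x$best_epoch))
  cat(sprintf("  final val NT-Xent loss %.4f\n",
              x$history$val_loss[x$best_epoch]))
  invisible(x)
}

#' @export
plot.tic_encoder <- function(x, ...) {
  graphics::matplot(x$history$epoch,
                    cbind(x$history$train_loss, x$history$val_loss),
                    type = "l", lty = 1, col = c("black", "red"),
                    xlab = "epoch", ylab = "NT-Xent loss", ...)
  graphics::legend("topright", c("train", "validation"),
                   col = c("black", "red"), lty = 1, bty = "n")
  graphics::abline(v = x$best_epoch, lty = 3)
  invisible(x)
}
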