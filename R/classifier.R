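# Stage 2: the frozen encoder turns each 1-second clip into a k x D feature
# sequence; a single-layer LSTM with a ReLU/dropout head and focal loss
# classifies the sequence. Checkpoint selection follows a "watch" strategy:
# the epoch maximizing either validation accuracy or the validation F1 of
# the tic class(es).

#' LSTM classifier specification
#'
#' Full-scale defaults: 512-d inputs, hidden size 128, dropout 0.8 on the
#' final hidden state. The head applies ReLU and dropout to the last hidden
#' state, then a fully connected layer sized to the number of classes and a
#' softmax.
#'
#' @param input_dim encoder feature dimension D.
#' @param hidden_dim LSTM hidden size.
#' @param dropout drop rate in [0, 1) applied to the final hidden state
#'   during training (inverted dropout; inference is deterministic).
#' @param n_classes number of output classes (>= 2).
#' @export
lstm_spec <- function(input_dim = 512L, hidden_dim = 128L, dropout = 0.8,
                      n_classes = 2L) {
  if (dropout < 0 || dropout >= 1) stopf("dropout must lie in [0, 1)")
  if (n_classes < 2) stopf("n_classes must be >= 2")
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dim = as.integer(hidden_dim),
                 dropout = dropout, n_classes = as.integer(n_classes)),
            class = "lstm_spec")
}

#' Training strategy: which validation metric selects the checkpoint
#'
#' @param watch \code{"accuracy"} (overall validation accuracy) or
#'   \code{"f1_tic"} (macro F1 over the tic classes, i.e. all classes except
#'   \code{normal}).
#' @export
train_strategy <- function(watch = c("accuracy", "f1_tic")) {
  structure(list(watch = match.arg(watch)), class = "train_strategy")
}

#' Randomly sample k frames of a clip, in chronological order
#'
#' @param clip one row of a clips data.frame (see
#'   \code{\link{recording_clips}}), or an integer clip length.
#' @param k number of frames to draw, strictly less than the clip length.
#' @param seed integer seed; \code{NULL} uses the current RNG stream.
#' @return k distinct 0-based frame indices (absolute when \code{clip} is a
#'   clip row), strictly increasing.
#' @export
sample_frames <- function(clip, k, seed = NULL) {
  if (is.numeric(clip) && length(clip) == 1L) {
    len <- as.integer(clip); offset <- 0L
  } else {
    len <- clip$end_frame - clip$start_frame
    offset <- clip$start_frame
  }
  if (k >= len) stopf("k (%d) must be strictly less than the clip length (%d)", k, len)
  draw <- function() sort(sample.int(len, k)) - 1L + offset
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Extract the feature sequence of one clip through the frozen encoder
#'
#' @param encoder a fitted \code{"tic_encoder"}.
#' @param frames list of preprocessed ROI images (encoder input size), in
#'   chronological order.
#' @return a k x D feature matrix, row t the encoding of frame t.
#' @export
extract_features <- function(encoder, frames) {
  predict(encoder, frames)
}

new_feature_sequence <- function(features, clip_id, label) {
  list(features = features, clip_id = clip_id, label = label)
}

lstm_net_params <- function(par) par   # flat list already (Wx, Wh, b, Wo, bo)

lstm_head_fwd <- function(par, h, dropout, train) {
  a <- pmax(h, 0)
  mask <- NULL
  if (train && dropout > 0) {
    keep <- 1 - dropout
    mask <- matrix(stats::rbinom(length(a), 1L, keep) / keep, nrow(a), ncol(a))
    a <- a * mask
  }
  logits <- par$Wo %*% a + par$bo
  list(logits = logits, a = a, mask = mask, h = h)
}

lstm_model_fwd <- function(par, spec, X, train = FALSE) {
  fw <- lstm_fwd(par, X, spec$hidden_dim)
  hd <- lstm_head_fwd(par, fw$h, spec$dropout, train)
  list(fw = fw, hd = hd, logits = hd$logits)
}

lstm_model_bwd <- function(par, spec, run, dLogits) {
  dWo <- tcrossprod(dLogits, run$hd$a)
  dbo <- rowSums(dLogits)
  da <- crossprod(par$Wo, dLogits)
  if (!is.null(run$hd$mask)) da <- da * run$hd$mask
  dh <- da * (run$hd$h > 0)
  g <- lstm_bwd(par, run$fw$cache, dh, spec$hidden_dim)
  list(Wx = g$Wx, Wh = g$Wh, b = g$b, Wo = dWo, bo = dbo)
}

softmax_cols <- function(logits) {
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  sweep(e, 2, colSums(e), "/")
}

seqs_to_steps <- function(seqs, k, D) {
  B <- length(seqs)
  lapply(seq_len(k), function(t) {
    m <- matrix(0, D, B)
    for (b in seq_len(B)) m[, b] <- seqs[[b]]$features[t, ]
    m
  })
}

watch_metric <- function(y_true, y_pred, levels, watch) {
  if (watch == "accuracy") return(mean(y_true == y_pred))
  tic_classes <- setdiff(levels, "normal")
  if (length(tic_classes) == 0L) tic_classes <- levels[-1]
  f1s <- vapply(tic_classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1s)
}

#' Train the LSTM clip classifier (Stage 2)
#'
#' Minimizes the mean one-vs-rest focal loss over softmax outputs with Adam.
#' After every epoch the watched validation metric is computed (overall
#' accuracy, or macro F1 of the tic classes); the returned parameters are
#' those of the epoch that maximized it. The encoder is not part of this
#' optimization: Stage-1 parameters stay frozen.
#'
#' @param train,val lists of feature sequences, each
#'   \code{list(features = k x D matrix, clip_id, label)}; labels must cover
#'   at least two classes in \code{train} and \code{val} must be nonempty.
#' @param spec an \code{\link{lstm_spec}} (its \code{input_dim} must match D).
#' @param focal a \code{\link{focal_config}}; \code{alpha = NULL} uses
#'   inverse-class-frequency weights normalized to max 1.
#' @param strategy a \code{\link{train_strategy}}.
#' @param epochs number of training epochs.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param seed integer seed (init, shuffling, dropout).
#' @param class_levels explicit class ordering; defaults to sorted unique
#'   training labels with \code{normal} first when present.
#' @return an object of class \code{"tic_lstm"}.
#' @export
train_classifier <- function(train, val, spec, focal = focal_config(),
                             strategy = train_strategy("accuracy"),
                             epochs = 40L, batch_size = 32L, lr = 1e-3,
                             seed = 1L, class_levels = NULL) {
  if (length(val) == 0L) stopf("validation set must be nonempty")
  labs <- vapply(train, function(s) as.character(s$label), character(1))
  if (length(unique(labs)) < 2L)
    stopf("training labels must cover at least two classes")
  class_levels <- class_levels %||% {
    u <- sort(unique(labs))
    if ("normal" %in% u) c("normal", setdiff(u, "normal")) else u
  }
  if (spec$n_classes != length(class_levels))
    spec$n_classes <- length(class_levels)
  C <- spec$n_classes
  k <- nrow(train[[1]]$features); D <- ncol(train[[1]]$features)
  if (D != spec$input_dim)
    stopf("feature dimension (%d) does not match spec input_dim (%d)", D, spec$input_dim)

  y_tr <- match(labs, class_levels)
  if (anyNA(y_tr)) stopf("training label outside class_levels")
  y_val <- match(vapply(val, function(s) as.character(s$label), character(1)),
                 class_levels)
  alpha <- focal$alpha %||% {
    freq <- tabulate(y_tr, C)
    w <- 1 / pmax(freq, 1L)
    w / max(w)
  }
  if (length(alpha) == 1L) alpha <- rep(alpha, C)

  par <- with_seed(derive_seed(seed, "lstm_init"), {
    p <- lstm_init(spec$input_dim, spec$hidden_dim)
    p$Wo <- matrix(stats::rnorm(C * spec$hidden_dim, 0, sqrt(2 / spec$hidden_dim)),
                   C, spec$hidden_dim)
    p$bo <- numeric(C)
    p
  })
  st <- adam_init(par)
  Xval <- seqs_to_steps(val, k, D)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_metric = numeric())
  best <- list(metric = -Inf, par = par, epoch = 0L)
  n <- length(train)
  for (epoch in seq_len(epochs)) {
    set.seed(derive_seed(seed, paste0("lstm_ep", epoch)))
    ord <- sample.int(n)
    losses <- c()
    for (bs in split(ord, ceiling(seq_along(ord) / batch_size))) {
      X <- seqs_to_steps(train[bs], k, D)
      run <- lstm_model_fwd(par, spec, X, train = TRUE)
      fl <- focal_softmax_loss(run$logits, y_tr[bs], alpha, focal$gamma,
                               grad = TRUE)
      g <- lstm_model_bwd(par, spec, run, fl$grad)
      r <- adam_step(par, g, st, lr)
      par <- r$params; st <- r$state
      losses <- c(losses, fl$loss)
    }
    pv <- lstm_model_fwd(par, spec, Xval, train = FALSE)
    pred <- apply(pv$logits, 2, which.max)
    metric <- watch_metric(class_levels[y_val], class_levels[pred],
                           class_levels, strategy$watch)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(losses),
                                         val_metric = metric))
    if (metric > best$metric + 1e-12) best <- list(metric = metric, par = par,
                                                   epoch = epoch)
  }
  structure(list(par = best$par, spec = spec, focal = focal, alpha = alpha,
                 strategy = strategy, class_levels = class_levels,
                 history = history, best_epoch = best$epoch,
                 best_metric = best$metric, k = k),
            class = "tic_lstm")
}

#' Predict class probabilities for feature sequences
#'
#' Dropout is disabled: inference is deterministic. Probabilities are
#' non-negative and sum to one per clip; the predicted label is the argmax.
#'
#' @param object a fitted \code{"tic_lstm"}.
#' @param newdata a single k x D matrix, one feature sequence, or a list of
#'   feature sequences.
#' @param type \code{"prob"} for the probability matrix, \code{"class"} for
#'   predicted labels.
#' @param ... unused.
#' @export
predict.tic_lstm <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (is.matrix(newdata)) newdata <- list(list(features = newdata))
  if (!is.null(newdata$features)) newdata <- list(newdata)
  k <- nrow(newdata[[1]]$features); D <- ncol(newdata[[1]]$features)
  if (D != object$spec$input_dim)
    stopf("feature dimension (%d) does not match the classifier (%d)",
          D, object$spec$input_dim)
  X <- seqs_to_steps(newdata, k, D)
  run <- lstm_model_fwd(object$par, object$spec, X, train = FALSE)
  P <- t(softmax_cols(run$logits))
  colnames(P) <- object$class_levels
  if (type == "class")
    return(object$class_levels[apply(P, 1, which.max)])
  P
}

#' @export
print.tic_lstm <- function(x, ...) {
  cat("LSTM tic-clip classifier (focal loss)\n")
  cat(sprintf("  input %d-d x %d steps -> hidden %d (dropout %.2g) -> %d classes: %s\n",
              x$spec$input_dim, x$k, x$spec$hidden_dim, x$spec$dropout,
              x$spec$n_classes, paste(x$class_levels, collapse = ", ")))
  cat(sprintf("  gamma %.2g, alpha %s\n", x$focal$gamma,
              paste(signif(x$alpha, 3), collapse = "/")))
  cat(sprintf("  watch = %s: best validation %.4f at epoch %d/%d\n",
              x$strategy$watch, x$best_metric, x$best_epoch, nrow(x$history)))
  invisible(x)
}

#' @export
plot.tic_lstm <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  plot(x$history$epoch, x$history$train_loss, type = "l",
       xlab = "epoch", ylab = "train focal loss", ...)
  plot(x$history$epoch, x$history$val_metric, type = "l",
       xlab = "epoch", ylab = paste("validation", x$strategy$watch), ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  invisible(x)
}
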