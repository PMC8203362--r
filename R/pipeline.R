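# Pipeline glue: turn a cohort into Stage-1 frame streams and Stage-2
# feature sequences, drive the leave-one-subject-out evaluation, and run
# the whole two-stage experiment end to end at desk scale.

#' All 1-second clips of a cohort
#'
#' Cuts every recording into tic/normal segments from its annotations and
#' windows them into non-overlapping 1-second clips.
#'
#' @param cohort a \code{"tic_cohort"}.
#' @param guard_s normal-segment guard margin in seconds (see
#'   \code{\link{cut_segments}}).
#' @return a clips data.frame (see \code{\link{window_clips}}).
#' @export
cohort_clips <- function(cohort, guard_s = 0) {
  out <- do.call(rbind, lapply(cohort$subjects, function(su)
    recording_clips(su$meta, su$events, guard_s = guard_s)))
  rownames(out) <- NULL
  out
}

#' Stage-1 frame streams: downsampled, ROI-cropped frames per subject
#'
#' Applies the Stage-1 preprocessing rules: 3-fold temporal downsampling of
#' each recording, ground-truth face detection, 20\% ROI expansion and
#' bilinear resize to the encoder input. Frames are returned per subject in
#' temporal order, ready for \code{\link{tic_pretrain}}.
#'
#' @param cohort a \code{"tic_cohort"}.
#' @param out_size encoder input side.
#' @param max_frames_per_subject optional cap (after downsampling) to bound
#'   desk-scale runtimes.
#' @return named list: per subject, a list of ROI image arrays.
#' @export
stage1_frames <- function(cohort, out_size, max_frames_per_subject = NULL) {
  out <- lapply(cohort$subjects, function(su) {
    idx <- downsample_3fold(seq_len(su$meta$n_frames) - 1L)
    if (!is.null(max_frames_per_subject) && length(idx) > max_frames_per_subject)
      idx <- idx[seq_len(max_frames_per_subject)]
    lapply(idx, function(i) roi_frame(cohort, su$subject_id, i, out_size))
  })
  names(out) <- names(cohort$subjects)
  out
}

map_task_label <- function(labels, task) {
  if (task == "binary") ifelse(labels == "normal", "normal", "tic")
  else labels
}

task_levels <- function(task) {
  if (task == "binary") c("normal", "tic") else c("normal", "eye_tic", "mouth_tic")
}

#' Stage-2 feature sequences for a set of clips
#'
#' For every clip, k frames are sampled uniformly without replacement (in
#' chronological order), rendered, ROI-cropped and pushed through the frozen
#' encoder, yielding one k x D feature sequence per clip. Encoder forwards
#' are batched for speed.
#'
#' @param cohort a \code{"tic_cohort"}.
#' @param encoder a fitted \code{"tic_encoder"}.
#' @param clips clips data.frame (see \code{\link{cohort_clips}}).
#' @param k frames sampled per clip (must be < clip length, i.e. < fps).
#' @param seed integer seed for the frame draws.
#' @param chunk encoder batch size.
#' @return a list of feature sequences
#'   \code{list(features, clip_id, label, subject_id)}.
#' @export
cohort_features <- function(cohort, encoder, clips, k = 16L, seed = 1L,
                            chunk = 256L) {
  osz <- encoder$spec$input_size
  frame_plan <- lapply(seq_len(nrow(clips)), function(i)
    sample_frames(clips[i, ], k, seed = derive_seed(seed, paste0("sf", i))))
  all_imgs <- vector("list", nrow(clips) * k)
  p <- 1L
  for (i in seq_len(nrow(clips))) {
    for (fi in frame_plan[[i]]) {
      all_imgs[[p]] <- roi_frame(cohort, clips$subject_id[i], fi, osz)
      p <- p + 1L
    }
  }
  n <- length(all_imgs)
  feats <- matrix(0, n, encoder$spec$out_dim)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    feats[s:e, ] <- predict(encoder, all_imgs[s:e])
  }
  lapply(seq_len(nrow(clips)), function(i)
    list(features = feats[((i - 1L) * k + 1L):(i * k), , drop = FALSE],
         clip_id = clips$clip_id[i], label = clips$label[i],
         subject_id = clips$subject_id[i]))
}

#' Leave-one-subject-out evaluation of the two-stage pipeline
#'
#' For each subject, an LSTM classifier is trained on all other subjects'
#' feature sequences (with a subject-stratified 20\% validation split of the
#' training clips driving the watch-metric checkpoint) and evaluated on the
#' held-out subject's clips. The held-out subject never touches training or
#' checkpoint selection.
#'
#' @param features feature-sequence list from \code{\link{cohort_features}}
#'   (labels still in cohort categories).
#' @param task \code{"binary"} (normal vs any tic) or \code{"multiclass"}
#'   (normal / eye_tic / mouth_tic; other-tic clips are dropped).
#' @param spec an \code{\link{lstm_spec}} sized to the encoder features.
#' @param focal a \code{\link{focal_config}}.
#' @param strategy a \code{\link{train_strategy}}.
#' @param epochs,lr,batch_size LSTM training hyperparameters.
#' @param val_fraction within-fold validation fraction per training subject.
#' @param seed integer seed.
#' @param average macro or weighted metric averaging.
#' @return an object of class \code{"tic_loso"}: per-fold reports, pooled
#'   predictions, aggregate mean/sd metrics, and per-subject clinical items.
#' @export
tic_loso <- function(features, task = c("binary", "multiclass"),
                     spec, focal = focal_config(),
                     strategy = train_strategy("accuracy"),
                     epochs = 40L, lr = 1e-3, batch_size = 32L,
                     val_fraction = 0.2, seed = 1L,
                     average = "macro") {
  task <- match.arg(task)
  levels <- task_levels(task)
  if (task == "multiclass")
    features <- Filter(function(s) s$label != "other_tic", features)
  subs <- vapply(features, `[[`, character(1), "subject_id")
  folds <- loso_splits(subs)
  fold_reports <- list()
  preds <- list()
  models <- list()
  for (fd in folds) {
    tr_all <- features[subs %in% fd$train]
    te <- features[subs == fd$test]
    tr_subs <- vapply(tr_all, `[[`, character(1), "subject_id")
    val_idx <- unlist(lapply(unique(tr_subs), function(s) {
      ii <- which(tr_subs == s)
      with_seed(derive_seed(seed, paste0("val_", fd$test, "_", s)),
                sample(ii, max(1L, round(val_fraction * length(ii)))))
    }))
    tr <- tr_all[-val_idx]; va <- tr_all[val_idx]
    relab <- function(ss) lapply(ss, function(s) {
      s$label <- map_task_label(s$label, task); s
    })
    clf <- train_classifier(relab(tr), relab(va), spec, focal, strategy,
                            epochs = epochs, batch_size = batch_size, lr = lr,
                            seed = derive_seed(seed, paste0("clf_", fd$test)),
                            class_levels = levels)
    P <- predict(clf, relab(te))
    y_true <- map_task_label(vapply(te, `[[`, character(1), "label"), task)
    y_pred <- levels[apply(P, 1, which.max)]
    rep_ <- confusion_and_metrics(y_true, y_pred,
                                  scores = if (task == "binary") P else NULL,
                                  levels = levels, average = average)
    rep_$held_out_subject <- fd$test
    fold_reports[[fd$test]] <- rep_
    models[[fd$test]] <- clf
    preds[[fd$test]] <- data.frame(
      clip_id = vapply(te, `[[`, character(1), "clip_id"),
      subject_id = fd$test, true_label = y_true, pred_label = y_pred,
      P, check.names = FALSE, stringsAsFactors = FALSE)
  }
  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL
  metric_names <- c("accuracy", "precision", "recall", "f1",
                    if (task == "binary") c("auc_roc", "auc_pr"))
  agg <- sapply(metric_names, function(m)
    vapply(fold_reports, function(r) r[[m]] %||% NA_real_, numeric(1)))
  aggregate <- data.frame(metric = metric_names,
                          mean = colMeans(agg, na.rm = TRUE),
                          sd = apply(agg, 2, stats::sd, na.rm = TRUE))
  rownames(aggregate) <- NULL
  clinical <- do.call(rbind, lapply(names(fold_reports), function(s) {
    pp <- predictions[predictions$subject_id == s, ]
    dur_min <- nrow(pp) / 60    # each clip is one second
    data.frame(subject_id = s,
               n_tic_areas = count_tic_areas(pp$pred_label),
               tic_frequency = tic_frequency(count_tic_signs(pp$pred_label),
                                             dur_min),
               n_tic_areas_true = count_tic_areas(pp$true_label),
               tic_frequency_true = tic_frequency(count_tic_signs(pp$true_label),
                                                  dur_min),
               stringsAsFactors = FALSE)
  }))
  structure(list(task = task, levels = levels, folds = fold_reports,
                 models = models, predictions = predictions,
                 aggregate = aggregate, clinical = clinical,
                 strategy = strategy, seed = seed),
            class = "tic_loso")
}

#' @export
print.tic_loso <- function(x, ...) {
  cat(sprintf("Leave-one-subject-out evaluation (%s task, watch = %s)\n",
              x$task, x$strategy$watch))
  cat(sprintf("  %d folds, %d clips; metrics mean (sd) over folds:\n",
              length(x$folds), nrow(x$predictions)))
  for (i in seq_len(nrow(x$aggregate)))
    cat(sprintf("  %-9s %.4f (+/-%.4f)\n", x$aggregate$metric[i],
                x$aggregate$mean[i], x$aggregate$sd[i]))
  invisible(x)
}

#' @export
summary.tic_loso <- function(object, ...) {
  print(object)
  cat("\nPer-subject clinical items (predicted | ground truth):\n")
  cl <- object$clinical
  for (i in seq_len(nrow(cl)))
    cat(sprintf("  %s: tic areas %d | %d, tic frequency %.2f | %.2f /min\n",
                cl$subject_id[i], cl$n_tic_areas[i], cl$n_tic_areas_true[i],
                cl$tic_frequency[i], cl$tic_frequency_true[i]))
  invisible(object)
}

#' @export
plot.tic_loso <- function(x, ...) {
  acc <- vapply(x$folds, `[[`, numeric(1), "accuracy")
  f1 <- vapply(x$folds, `[[`, numeric(1), "f1")
  graphics::matplot(seq_along(acc), cbind(acc, f1), type = "b", pch = 1,
                    lty = 1, col = c("black", "red"), ylim = c(0, 1),
                    xlab = "held-out subject", ylab = "metric", ...)
  graphics::legend("bottomleft", c("accuracy", "macro F1"),
                   col = c("black", "red"), lty = 1, bty = "n")
  invisible(x)
}

#' Run the full two-stage experiment on a synthetic cohort
#'
#' Desk-scale end-to-end driver: generates (or accepts) a cohort, runs
#' Stage-1 contrastive pretraining on the downsampled unlabeled frame
#' streams, extracts clip feature sequences through the frozen encoder, and
#' evaluates Stage-2 LSTM classification under leave-one-subject-out
#' cross-validation.
#'
#' @param seed master seed for the whole experiment.
#' @param cohort optional pre-built \code{"tic_cohort"}; by default one is
#'   generated from \code{cohort_config(seed = seed)}.
#' @param task classification task, \code{"binary"} or \code{"multiclass"}.
#' @param input_size,channels,out_dim reduced encoder geometry.
#' @param batch_pairs,max_epochs,patience,lr Stage-1 sampler/optimizer
#'   settings (desk-scale defaults; the full-scale recipe lives in
#'   \code{\link{contrastive_config}}).
#' @param crop_scale_range augmentation crop range for this profile: at a
#'   32-pixel input the package-default strong crops remove most of the
#'   few-pixel structure that distinguishes nearby frames, so the
#'   desk-scale profile crops mildly.
#' @param max_frames_per_subject Stage-1 stream cap per subject.
#' @param k frames sampled per clip for Stage 2.
#' @param hidden_dim,dropout,lstm_epochs Stage-2 settings.
#' @param strategy watch strategy for checkpoint selection.
#' @param verbose print stage progress.
#' @return list with the cohort, encoder, features, and the
#'   \code{"tic_loso"} result.
#' @export
run_tic_pipeline <- function(seed = 1L, cohort = NULL,
                             task = "binary",
                             input_size = 32L, channels = c(8L, 16L, 32L),
                             out_dim = 64L, batch_pairs = 48L,
                             max_epochs = 16L, patience = 10L, lr = 2e-3,
                             crop_scale_range = c(0.85, 1),
                             max_frames_per_subject = 500L, k = 16L,
                             hidden_dim = 48L, dropout = 0.8,
                             lstm_epochs = 30L,
                             strategy = train_strategy("accuracy"),
                             verbose = FALSE) {
  cohort <- cohort %||% generate_cohort(cohort_config(seed = seed))
  if (verbose) message("rendering stage-1 frame streams...")
  frames <- stage1_frames(cohort, input_size, max_frames_per_subject)
  espec <- encoder_spec(input_size, channels, out_dim)
  pspec <- projection_spec(out_dim, out_dim, out_dim %/% 2L)
  aug <- augment_config(crop_scale_range = crop_scale_range,
                        out_size = input_size)
  cfg <- contrastive_config(batch_pairs = batch_pairs, max_epochs = max_epochs,
                            patience_epochs = patience, lr = lr,
                            seed = derive_seed(seed, "stage1"))
  if (verbose) message("stage 1: contrastive pretraining...")
  encoder <- tic_pretrain(frames, cfg, espec, pspec, aug, verbose = verbose)
  clips <- cohort_clips(cohort)
  if (verbose) message(sprintf("stage 2: %d clips -> features...", nrow(clips)))
  features <- cohort_features(cohort, encoder, clips, k = k,
                              seed = derive_seed(seed, "features"))
  spec <- lstm_spec(input_dim = out_dim, hidden_dim = hidden_dim,
                    dropout = dropout, n_classes = length(task_levels(task)))
  if (verbose) message("stage 2: LOSO evaluation...")
  loso <- tic_loso(features, task = task, spec = spec, strategy = strategy,
                   epochs = lstm_epochs,
                   seed = derive_seed(seed, "stage2"))
  list(cohort = cohort, encoder = encoder, clips = clips,
       features = features, loso = loso)
}
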