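# Independent oracles used across the suite. These deliberately re-derive
# quantities with the most literal, unvectorized formulations so they share
# no code path with the package implementation.

# literal double-loop NT-Xent: cosine similarities, per-pair directed losses
brute_ntxent <- function(z, tau) {
  n2 <- nrow(z)
  sim <- function(u, v) sum(u * v) / (sqrt(sum(u * u)) * sqrt(sum(v * v)))
  loss_ij <- function(i, j) {
    den <- 0
    for (k in seq_len(n2)) if (k != i) den <- den + exp(sim(z[i, ], z[k, ]) / tau)
    -log(exp(sim(z[i, ], z[j, ]) / tau) / den)
  }
  tot <- 0
  for (k in seq_len(n2 / 2)) tot <- tot + loss_ij(2 * k - 1, 2 * k) + loss_ij(2 * k, 2 * k - 1)
  tot / n2
}

# naive per-class confusion-table metrics
brute_metrics <- function(y_true, y_pred, levels) {
  prec <- rec <- f1 <- numeric(length(levels))
  for (ci in seq_along(levels)) {
    cl <- levels[ci]
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    prec[ci] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec[ci] <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1[ci] <- if (prec[ci] + rec[ci] == 0) 0 else
      2 * prec[ci] * rec[ci] / (prec[ci] + rec[ci])
  }
  list(accuracy = mean(y_true == y_pred),
       precision = mean(prec), recall = mean(rec), f1 = mean(f1))
}

# rank-based AUC (Mann-Whitney), independent of the trapezoid construction
brute_auc <- function(scores, pos) {
  r <- rank(scores)
  np <- sum(pos); nn <- sum(!pos)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

# threshold-sweep average precision
brute_ap <- function(scores, pos) {
  ths <- sort(unique(scores), decreasing = TRUE)
  rec_prev <- 0; ap <- 0
  for (th in ths) {
    sel <- scores >= th
    prec <- sum(pos & sel) / sum(sel)
    rec <- sum(pos & sel) / sum(pos)
    ap <- ap + (rec - rec_prev) * prec
    rec_prev <- rec
  }
  ap
}

# small shared cohort, built once per test run
tiny_cohort <- local({
  co <- NULL
  function() {
    if (is.null(co)) co <<- generate_cohort(
      cohort_config(n_subjects = 3L, duration_s = 20, seed = 404L))
    co
  }
})

# tiny feature-sequence set: two well-separated Gaussian classes in D dims
gaussian_seqs <- function(n_per_class, k = 4L, D = 8L, sep = 3, seed = 1L,
                          labels = c("normal", "tic")) {
  set.seed(seed)
  out <- list()
  for (ci in seq_along(labels)) {
    mu <- rep(0, D); mu[ci] <- sep
    for (i in seq_len(n_per_class)) {
      out[[length(out) + 1L]] <- list(
        features = matrix(stats::rnorm(k * D, mean = rep(mu, each = k), sd = 1), k, D),
        clip_id = sprintf("%s_%03d", labels[ci], i),
        label = labels[ci],
        subject_id = sprintf("s%d", (i %% 3) + 1L))
    }
  }
  out
}

# multi-subject feature-sequence fixture with three separable classes
make_cohort_seqs <- function(n_subj = 4, per_subj = 18, seed = 91) {
  set.seed(seed)
  out <- list()
  for (s in seq_len(n_subj)) {
    for (i in seq_len(per_subj)) {
      lab <- sample(c("normal", "eye_tic", "mouth_tic"), 1,
                    prob = c(0.6, 0.2, 0.2))
      mu <- switch(lab, normal = c(0, 0), eye_tic = c(3, 0), mouth_tic = c(0, 3))
      out[[length(out) + 1L]] <- list(
        features = matrix(rnorm(4 * 6, rep(c(mu, 0, 0, 0, 0), each = 4)), 4, 6),
        clip_id = sprintf("s%d_c%02d", s, i),
        label = lab, subject_id = sprintf("subj%02d", s))
    }
  }
  out
}
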