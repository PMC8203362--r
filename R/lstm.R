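# Single-layer unidirectional LSTM with manual backpropagation through time.
# Gate layout in the stacked weight matrices: input (i), forget (f),
# candidate (g), output (o). The final hidden state feeds the classifier
# head; gradients are exact (checked numerically in the tests).

sigm <- function(x) 1 / (1 + exp(-x))

lstm_init <- function(input_dim, hidden_dim) {
  s <- 1 / sqrt(hidden_dim)
  list(Wx = matrix(stats::runif(4 * hidden_dim * input_dim, -s, s),
                   4 * hidden_dim, input_dim),
       Wh = matrix(stats::runif(4 * hidden_dim * hidden_dim, -s, s),
                   4 * hidden_dim, hidden_dim),
       b = c(rep(0, hidden_dim), rep(1, hidden_dim),   # forget bias +1
             rep(0, 2 * hidden_dim)))
}

# X: list over timesteps of (D x B) matrices. Returns final hidden state and
# the per-step cache for BPTT.
lstm_fwd <- function(par, X, hidden_dim) {
  B <- ncol(X[[1]])
  H <- hidden_dim
  h <- matrix(0, H, B); cst <- matrix(0, H, B)
  cache <- vector("list", length(X))
  ii <- 1:H; ff <- (H + 1):(2 * H); gg <- (2 * H + 1):(3 * H); oo <- (3 * H + 1):(4 * H)
  for (t in seq_along(X)) {
    zb <- par$Wx %*% X[[t]] + par$Wh %*% h + par$b
    gi <- sigm(zb[ii, , drop = FALSE]); gf <- sigm(zb[ff, , drop = FALSE])
    gg_ <- tanh(zb[gg, , drop = FALSE]); go <- sigm(zb[oo, , drop = FALSE])
    c_new <- gf * cst + gi * gg_
    tc <- tanh(c_new)
    cache[[t]] <- list(x = X[[t]], h_prev = h, c_prev = cst,
                       gi = gi, gf = gf, gg = gg_, go = go, tc = tc)
    cst <- c_new
    h <- go * tc
  }
  list(h = h, cache = cache)
}

# dH: gradient w.r.t. the final hidden state (H x B).
lstm_bwd <- function(par, cache, dH, hidden_dim) {
  H <- hidden_dim
  dWx <- par$Wx * 0; dWh <- par$Wh * 0; db <- par$b * 0
  dh <- dH; dc <- dH * 0
  for (t in rev(seq_along(cache))) {
    cc <- cache[[t]]
    do_ <- dh * cc$tc * cc$go * (1 - cc$go)
    dc <- dc + dh * cc$go * (1 - cc$tc^2)
    di <- dc * cc$gg * cc$gi * (1 - cc$gi)
    df <- dc * cc$c_prev * cc$gf * (1 - cc$gf)
    dg <- dc * cc$gi * (1 - cc$gg^2)
    dz <- rbind(di, df, dg, do_)
    dWx <- dWx + tcrossprod(dz, cc$x)
    dWh <- dWh + tcrossprod(dz, cc$h_prev)
    db <- db + rowSums(dz)
    dh <- crossprod(par$Wh, dz)
    dc <- dc * cc$gf
  }
  list(Wx = dWx, Wh = dWh, b = db)
}
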