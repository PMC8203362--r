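# Minimal neural-network core used by both stages: 3x3 convolutions via a
# sparse gather/scatter im2col, ReLU, residual blocks, global average
# pooling, linear layers, and an Adam optimizer with cosine-annealed
# learning rate. Forward passes cache what backward needs; gradients are
# exact (verified against numerical differentiation in the test suite).

# ---- geometry cache ---------------------------------------------------------
# im2col index vector and sparse scatter matrix for a given input shape;
# building them is the expensive part, so they are memoised per shape.
.geom_cache <- new.env(parent = emptyenv())

conv_geom <- function(h, w, cin, stride) {
  key <- paste(h, w, cin, stride, sep = "_")
  g <- .geom_cache[[key]]
  if (!is.null(g)) return(g)
  hp <- h + 2L; wp <- w + 2L
  ho <- (hp - 3L) %/% stride + 1L
  wo <- (wp - 3L) %/% stride + 1L
  grid <- expand.grid(di = 0:2, dj = 0:2, ch = 0:(cin - 1L))
  base <- grid$di + grid$dj * hp + grid$ch * hp * wp + 1L
  starts <- expand.grid(oi = seq.int(1L, by = stride, length.out = ho),
                        oj = seq.int(1L, by = stride, length.out = wo))
  start_lin <- (starts$oi - 1L) + (starts$oj - 1L) * hp
  idx <- as.vector(outer(base, start_lin, "+"))
  npix <- hp * wp * cin
  S <- Matrix::sparseMatrix(i = idx, j = seq_along(idx), x = 1,
                            dims = c(npix, length(idx)))
  g <- list(idx = idx, S = S, hp = hp, wp = wp, ho = ho, wo = wo,
            npix = npix, k2c = 9L * cin)
  .geom_cache[[key]] <- g
  g
}

# ---- layers -----------------------------------------------------------------

layer_conv <- function(cin, cout, stride = 1L, id) {
  sd <- sqrt(2 / (9 * cin))
  list(type = "conv", id = id, cin = cin, cout = cout, stride = as.integer(stride),
       W = array(stats::rnorm(9 * cin * cout, 0, sd), c(3, 3, cin, cout)),
       # bias is omitted: batch normalization absorbs any channel shift
       # batch normalization (channel-wise); running stats for inference
       gamma = rep(1, cout), beta = numeric(cout),
       run_mean = numeric(cout), run_var = rep(1, cout))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# channel-wise batch norm on an (h, w, c, B) tensor; layout keeps each
# channel's h*w block contiguous per image, so per-(c, B) stats come from a
# single reshape and vectors of length h*w*c recycle correctly across B
bn_fwd <- function(X, gamma, beta, run_mean, run_var, train) {
  d <- dim(X); hw <- d[1] * d[2]; C <- d[3]; B <- d[4]
  if (train) {
    cb <- matrix(colMeans(matrix(X, hw, C * B)), C, B)
    mu <- rowMeans(cb)
    cb2 <- matrix(colMeans(matrix(X * X, hw, C * B)), C, B)
    v <- rowMeans(cb2) - mu^2
  } else {
    mu <- run_mean; v <- run_var
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  cmu <- rep(mu, each = hw); cis <- rep(invstd, each = hw)
  xhat <- (X - cmu) * cis
  Y <- xhat * rep(gamma, each = hw) + rep(beta, each = hw)
  upd <- if (train) list(mean = (1 - BN_MOMENTUM) * run_mean + BN_MOMENTUM * mu,
                         var = (1 - BN_MOMENTUM) * run_var + BN_MOMENTUM * v)
         else NULL
  list(out = Y, xhat = xhat, invstd = invstd, train = train, upd = upd)
}

bn_bwd <- function(cache, gamma, dY) {
  d <- dim(dY); hw <- d[1] * d[2]; C <- d[3]; B <- d[4]
  xhat <- cache$xhat
  dgamma <- rowMeans(matrix(colMeans(matrix(dY * xhat, hw, C * B)), C, B)) * hw * B
  dbeta <- rowMeans(matrix(colMeans(matrix(dY, hw, C * B)), C, B)) * hw * B
  gis <- rep(gamma * cache$invstd, each = hw)
  if (!cache$train) return(list(dgamma = dgamma, dbeta = dbeta, dX = dY * gis))
  m <- hw * B
  dX <- gis * (dY - rep(dbeta / m, each = hw) - xhat * rep(dgamma / m, each = hw))
  list(dgamma = dgamma, dbeta = dbeta, dX = dX)
}

layer_linear <- function(din, dout, id, bn = FALSE) {
  ly <- list(type = "linear", id = id, din = din, dout = dout, bn = bn,
             W = matrix(stats::rnorm(dout * din, 0, sqrt(2 / din)), dout, din),
             b = numeric(dout))
  if (bn) {
    ly$gamma <- rep(1, dout); ly$beta <- numeric(dout)
    ly$run_mean <- numeric(dout); ly$run_var <- rep(1, dout)
  }
  ly
}

# feature-wise batch norm on a (dout x B) matrix: reuse the tensor kernels
# with a 1x1 spatial extent
bn_fwd_mat <- function(X, gamma, beta, run_mean, run_var, train) {
  A <- X; dim(A) <- c(1L, 1L, nrow(X), ncol(X))
  r <- bn_fwd(A, gamma, beta, run_mean, run_var, train)
  out <- r$out; dim(out) <- dim(X)
  r$out <- out
  r
}

conv_fwd <- function(ly, X, train = FALSE) {
  d <- dim(X); h <- d[1]; w <- d[2]; B <- d[4]
  g <- conv_geom(h, w, ly$cin, ly$stride)
  Xpad <- array(0, c(g$hp, g$wp, ly$cin, B))
  Xpad[2:(h + 1L), 2:(w + 1L), , ] <- X
  cols <- Matrix::crossprod(g$S, matrix(Xpad, g$npix, B))@x   # dense slot, no S4 copy
  dim(cols) <- c(g$k2c, g$ho * g$wo * B)
  Wm <- matrix(ly$W, g$k2c, ly$cout)
  Y <- crossprod(Wm, cols)
  out <- aperm(array(Y, c(ly$cout, g$ho, g$wo, B)), c(2, 3, 1, 4))
  bn <- bn_fwd(out, ly$gamma, ly$beta, ly$run_mean, ly$run_var, train)
  list(out = bn$out,
       cache = list(cols = cols, h = h, w = w, B = B, g = g, bn = bn))
}

conv_bwd <- function(ly, cache, dOut) {
  g <- cache$g; B <- cache$B
  bb <- bn_bwd(cache$bn, ly$gamma, dOut)
  dY <- matrix(aperm(bb$dX, c(3, 1, 2, 4)), ly$cout, g$ho * g$wo * B)
  dWm <- tcrossprod(cache$cols, dY)                      # (k2c, cout)
  Wm <- matrix(ly$W, g$k2c, ly$cout)
  dcols <- Wm %*% dY                                     # (k2c, ho*wo*B)
  dim(dcols) <- c(g$k2c * g$ho * g$wo, B)
  dXpad <- (g$S %*% dcols)@x
  dX <- array(dXpad, c(g$hp, g$wp, ly$cin, B))[2:(cache$h + 1L),
                                               2:(cache$w + 1L), , , drop = FALSE]
  list(dW = array(dWm, c(3, 3, ly$cin, ly$cout)),
       dgamma = bb$dgamma, dbeta = bb$dbeta, dX = dX)
}

linear_fwd <- function(ly, X, train = FALSE) {
  Y <- ly$W %*% X + ly$b
  if (!isTRUE(ly$bn)) return(list(out = Y, cache = list(X = X)))
  r <- bn_fwd_mat(Y, ly$gamma, ly$beta, ly$run_mean, ly$run_var, train)
  list(out = r$out, cache = list(X = X, bn = r))
}

linear_bwd <- function(ly, cache, dOut) {
  extra <- NULL
  if (isTRUE(ly$bn)) {
    dA <- dOut; dim(dA) <- c(1L, 1L, nrow(dOut), ncol(dOut))
    bb <- bn_bwd(cache$bn, ly$gamma, dA)
    dOut <- bb$dX; dim(dOut) <- dim(cache$bn$out)
    extra <- list(dgamma = bb$dgamma, dbeta = bb$dbeta)
  }
  c(list(dW = tcrossprod(dOut, cache$X), db = rowSums(dOut),
         dX = crossprod(ly$W, dOut)), extra)
}

# ---- network assembly -------------------------------------------------------
# A net is a list of layers; "resblock" nests two convolutions with a skip
# connection: out = relu(conv2(relu(conv1(x))) + x).

#' Encoder architecture specification
#'
#' A small residual convolutional network: a stride-2 stem convolution, one
#' residual block per channel stage with stride-2 transition convolutions
#' between stages, global average pooling and a linear map to the feature
#' dimension. The full-scale configuration mirrors a reduced ResNet-18-style
#' encoder (112 x 112 x 3 input, 512-d output); tests and desk-scale runs use
#' smaller instances of the same family.
#'
#' @param input_size square input side in pixels (112 full scale).
#' @param channels channel widths per stage.
#' @param out_dim feature dimension D (512 full scale).
#' @export
encoder_spec <- function(input_size = 112L, channels = c(16L, 32L, 64L, 128L),
                         out_dim = 512L) {
  stopifnot(out_dim >= 1, length(channels) >= 1)
  structure(list(input_size = as.integer(input_size),
                 channels = as.integer(channels),
                 out_dim = as.integer(out_dim),
                 depth_tag = sprintf("res%d", length(channels))),
            class = "encoder_spec")
}

#' Projection head specification (two-layer MLP)
#'
#' @param in_dim encoder feature dimension.
#' @param hidden_dim first-layer width (512 full scale).
#' @param proj_dim projection dimension where the contrastive loss is applied
#'   (256 full scale).
#' @export
projection_spec <- function(in_dim = 512L, hidden_dim = 512L, proj_dim = 256L) {
  stopifnot(hidden_dim >= 1, proj_dim >= 1)
  structure(list(in_dim = as.integer(in_dim), hidden_dim = as.integer(hidden_dim),
                 proj_dim = as.integer(proj_dim)), class = "projection_spec")
}

init_encoder_net <- function(spec) {
  ch <- spec$channels
  layers <- list(layer_conv(3L, ch[1], stride = 2L, id = "stem"))
  for (i in seq_along(ch)) {
    layers[[length(layers) + 1L]] <- list(
      type = "resblock", id = sprintf("res%d", i),
      conv1 = layer_conv(ch[i], ch[i], 1L, sprintf("res%d.c1", i)),
      conv2 = layer_conv(ch[i], ch[i], 1L, sprintf("res%d.c2", i)))
    if (i < length(ch))
      layers[[length(layers) + 1L]] <- layer_conv(ch[i], ch[i + 1L], 2L,
                                                  sprintf("down%d", i))
  }
  layers[[length(layers) + 1L]] <- list(type = "gap", id = "gap")
  layers[[length(layers) + 1L]] <- layer_linear(ch[length(ch)], spec$out_dim, "head")
  structure(list(layers = layers, spec = spec), class = "tic_net")
}

init_projection_net <- function(spec) {
  # hidden layer carries batch norm: at initialization the encoder features
  # of nearby video frames are nearly collinear, and normalizing the hidden
  # activations spreads the projected embeddings over the sphere so the
  # contrastive loss has usable gradients from the first step
  layers <- list(layer_linear(spec$in_dim, spec$hidden_dim, "proj1", bn = TRUE),
                 list(type = "relu", id = "projrelu"),
                 layer_linear(spec$hidden_dim, spec$proj_dim, "proj2"))
  structure(list(layers = layers, spec = spec), class = "tic_net")
}

#' @keywords internal
net_forward <- function(net, X, keep = TRUE, train = FALSE) {
  caches <- vector("list", length(net$layers))
  bn_upd <- list()
  last_conv <- NULL
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type == "conv") {
      r <- conv_fwd(ly, X, train); X <- pmax(r$out, 0)  # conv layers carry BN+ReLU
      if (train) bn_upd[[ly$id]] <- r$cache$bn$upd
      caches[[i]] <- if (keep) list(conv = r$cache, pre = r$out) else NULL
    } else if (ly$type == "resblock") {
      r1 <- conv_fwd(ly$conv1, X, train); a1 <- pmax(r1$out, 0)
      r2 <- conv_fwd(ly$conv2, a1, train)
      if (train) {
        bn_upd[[ly$conv1$id]] <- r1$cache$bn$upd
        bn_upd[[ly$conv2$id]] <- r2$cache$bn$upd
      }
      pre <- r2$out + X
      out <- pmax(pre, 0)
      caches[[i]] <- if (keep) list(c1 = r1$cache, pre1 = r1$out,
                                    c2 = r2$cache, pre = pre) else NULL
      X <- out
      last_conv <- i
    } else if (ly$type == "relu") {
      caches[[i]] <- if (keep) list(pre = X) else NULL
      X <- pmax(X, 0)
    } else if (ly$type == "gap") {
      d <- dim(X)
      caches[[i]] <- list(dim = d, act = if (keep) X else NULL)
      X <- t(colMeans(matrix(X, d[1] * d[2], d[3] * d[4])))
      dim(X) <- c(d[3], d[4])
    } else if (ly$type == "linear") {
      r <- linear_fwd(ly, X, train)
      if (train && isTRUE(ly$bn)) bn_upd[[ly$id]] <- r$cache$bn$upd
      caches[[i]] <- if (keep) r$cache else NULL
      X <- r$out
    }
  }
  list(out = X, caches = caches, last_conv = last_conv, bn_upd = bn_upd)
}

# merge running batch-norm statistics produced by a training forward pass
net_apply_bn <- function(net, bn_upd) {
  if (length(bn_upd) == 0L) return(net)
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type %in% c("conv", "linear") && !is.null(bn_upd[[ly$id]])) {
      net$layers[[i]]$run_mean <- bn_upd[[ly$id]]$mean
      net$layers[[i]]$run_var <- bn_upd[[ly$id]]$var
    } else if (ly$type == "resblock") {
      for (cv in c("conv1", "conv2")) {
        u <- bn_upd[[ly[[cv]]$id]]
        if (!is.null(u)) {
          net$layers[[i]][[cv]]$run_mean <- u$mean
          net$layers[[i]][[cv]]$run_var <- u$var
        }
      }
    }
  }
  net
}

net_set_bn_stats <- function(net, stats) {
  net_apply_bn(net, stats)
}

net_bn_stats <- function(net) {
  out <- list()
  for (ly in net$layers) {
    if (ly$type == "conv" || (ly$type == "linear" && isTRUE(ly$bn)))
      out[[ly$id]] <- list(mean = ly$run_mean, var = ly$run_var)
    else if (ly$type == "resblock")
      for (cv in c("conv1", "conv2"))
        out[[ly[[cv]]$id]] <- list(mean = ly[[cv]]$run_mean,
                                   var = ly[[cv]]$run_var)
  }
  out
}

# Backward pass; returns flat named gradient list and, when requested, the
# gradient with respect to the final residual stage's output activation
# (used by Grad-CAM) and/or the input.
net_backward <- function(net, fw, dOut, want_input_grad = FALSE) {
  grads <- list()
  d <- dOut
  d_last_conv <- NULL
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    cc <- fw$caches[[i]]
    if (ly$type == "conv") {
      d <- d * (cc$pre > 0)
      r <- conv_bwd(ly, cc$conv, d)
      grads[[paste0(ly$id, ".W")]] <- r$dW
      grads[[paste0(ly$id, ".gamma")]] <- r$dgamma
      grads[[paste0(ly$id, ".beta")]] <- r$dbeta
      d <- r$dX
    } else if (ly$type == "resblock") {
      if (identical(i, fw$last_conv)) d_last_conv <- d
      d <- d * (cc$pre > 0)
      dskip <- d
      r2 <- conv_bwd(ly$conv2, cc$c2, d)
      grads[[paste0(ly$conv2$id, ".W")]] <- r2$dW
      grads[[paste0(ly$conv2$id, ".gamma")]] <- r2$dgamma
      grads[[paste0(ly$conv2$id, ".beta")]] <- r2$dbeta
      d1 <- r2$dX * (cc$pre1 > 0)
      r1 <- conv_bwd(ly$conv1, cc$c1, d1)
      grads[[paste0(ly$conv1$id, ".W")]] <- r1$dW
      grads[[paste0(ly$conv1$id, ".gamma")]] <- r1$dgamma
      grads[[paste0(ly$conv1$id, ".beta")]] <- r1$dbeta
      d <- r1$dX + dskip
    } else if (ly$type == "relu") {
      d <- d * (cc$pre > 0)
    } else if (ly$type == "gap") {
      dd <- cc$dim
      d <- array(rep(d, each = dd[1] * dd[2]) / (dd[1] * dd[2]), dd)
    } else if (ly$type == "linear") {
      r <- linear_bwd(ly, cc, d)
      grads[[paste0(ly$id, ".W")]] <- r$dW
      grads[[paste0(ly$id, ".b")]] <- r$db
      if (!is.null(r$dgamma)) {
        grads[[paste0(ly$id, ".gamma")]] <- r$dgamma
        grads[[paste0(ly$id, ".beta")]] <- r$dbeta
      }
      if (i == 1L && !want_input_grad) { d <- NULL; break }
      d <- r$dX
    }
  }
  list(grads = grads, d_input = d, d_last_conv = d_last_conv)
}

# flat named parameter list <-> net
conv_param_list <- function(ly)
  stats::setNames(list(ly$W, ly$gamma, ly$beta),
                  paste0(ly$id, c(".W", ".gamma", ".beta")))

net_params <- function(net) {
  out <- list()
  for (ly in net$layers) {
    if (ly$type == "conv") {
      out <- c(out, conv_param_list(ly))
    } else if (ly$type == "linear") {
      out[[paste0(ly$id, ".W")]] <- ly$W; out[[paste0(ly$id, ".b")]] <- ly$b
      if (isTRUE(ly$bn)) {
        out[[paste0(ly$id, ".gamma")]] <- ly$gamma
        out[[paste0(ly$id, ".beta")]] <- ly$beta
      }
    } else if (ly$type == "resblock") {
      out <- c(out, conv_param_list(ly$conv1), conv_param_list(ly$conv2))
    }
  }
  out
}

set_conv_params <- function(ly, params) {
  ly$W <- params[[paste0(ly$id, ".W")]]
  ly$gamma <- params[[paste0(ly$id, ".gamma")]]
  ly$beta <- params[[paste0(ly$id, ".beta")]]
  ly
}

net_set_params <- function(net, params) {
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type == "conv") {
      net$layers[[i]] <- set_conv_params(ly, params)
    } else if (ly$type == "linear") {
      net$layers[[i]]$W <- params[[paste0(ly$id, ".W")]]
      net$layers[[i]]$b <- params[[paste0(ly$id, ".b")]]
      if (isTRUE(ly$bn)) {
        net$layers[[i]]$gamma <- params[[paste0(ly$id, ".gamma")]]
        net$layers[[i]]$beta <- params[[paste0(ly$id, ".beta")]]
      }
    } else if (ly$type == "resblock") {
      net$layers[[i]]$conv1 <- set_conv_params(ly$conv1, params)
      net$layers[[i]]$conv2 <- set_conv_params(ly$conv2, params)
    }
  }
  net
}

# ---- optimizer --------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

# Adam with decoupled-from-nothing classic L2 weight decay added to the
# gradient (the convention the reference hyperparameters assume).
adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]] + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Cosine-annealed learning rate
#'
#' @param lr0 initial learning rate.
#' @param epoch current epoch (1-based).
#' @param total planned total epochs (annealing period, no warm restarts).
#' @return the learning rate for \code{epoch}.
#' @export
cosine_lr <- function(lr0, epoch, total) {
  if (total <= 1) return(lr0)
  lr0 * 0.5 * (1 + cos(pi * (epoch - 1) / total))
}
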