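# Minimal 1D CNN machinery (forward + backprop) for the two small networks
# in this package. Feature maps are matrices with rows = time positions and
# columns = channels; a batch is the row-concatenation of the signals'
# feature maps plus the vector of per-signal row counts. Convolutions are
# "valid" (no padding). Implemented natively: the networks are tiny (a few
# thousand parameters) and the training schedule (SGD + Nesterov momentum,
# geometric learning-rate decay, early stopping) is specific enough that a
# direct implementation is the simplest faithful one.

NN_EPS <- 1e-7
BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# -- im2col ------------------------------------------------------------------

# x: C x T signal matrix. Returns T_f x (C*k) patch matrix, rows unrolled
# column-major (channel fastest within each kernel offset).
im2col_signal <- function(x, k, stride) {
  Tn <- ncol(x)
  if (Tn < k) stop(sprintf("input length %d shorter than kernel %d", Tn, k),
                   call. = FALSE)
  Tf <- (Tn - k) %/% stride + 1L
  idx <- outer(seq_len(k), (seq_len(Tf) - 1L) * stride, `+`)  # k x Tf
  # build (C*k) x Tf then transpose
  out <- matrix(0, Tf, nrow(x) * k)
  C <- nrow(x)
  for (j in seq_len(k)) {
    cols <- idx[j, ]
    out[, ((j - 1L) * C + 1L):(j * C)] <- t(x[, cols, drop = FALSE])
  }
  out
}

# F: Tf x C feature map (single signal). Patches for a k-tap stride-1 conv:
# (Tf-k+1) x (C*k), unrolled offset-fastest within each channel.
im2col_feat <- function(F, k) {
  Tf <- nrow(F); C <- ncol(F)
  To <- Tf - k + 1L
  out <- matrix(0, To, C * k)
  for (c in seq_len(C)) for (j in seq_len(k))
    out[, (c - 1L) * k + j] <- F[j:(j + To - 1L), c]
  out
}

# Scatter patch gradients back to the feature map (inverse of im2col_feat).
col2im_feat <- function(dpatch, Tf, C, k) {
  To <- nrow(dpatch)
  dF <- matrix(0, Tf, C)
  for (c in seq_len(C)) for (j in seq_len(k)) {
    rows <- j:(j + To - 1L)
    dF[rows, c] <- dF[rows, c] + dpatch[, (c - 1L) * k + j]
  }
  dF
}

# -- layers ------------------------------------------------------------------

bn_init <- function(C) list(gamma = rep(1, C), beta = rep(0, C),
                            rmean = rep(0, C), rvar = rep(1, C))

bn_forward <- function(x, bn, training) {
  if (training) {
    n <- nrow(x)
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    va <- colMeans(xc^2)
    inv_std <- 1 / sqrt(va + BN_EPS)
    xhat <- sweep(xc, 2, inv_std, `*`)
    y <- sweep(sweep(xhat, 2, bn$gamma, `*`), 2, bn$beta, `+`)
    bn$rmean <- (1 - BN_MOMENTUM) * bn$rmean + BN_MOMENTUM * mu
    bn$rvar <- (1 - BN_MOMENTUM) * bn$rvar + BN_MOMENTUM * va
    list(y = y, bn = bn, cache = list(xhat = xhat, inv_std = inv_std, xc = xc))
  } else {
    inv_std <- 1 / sqrt(bn$rvar + BN_EPS)
    xhat <- sweep(sweep(x, 2, bn$rmean), 2, inv_std, `*`)
    y <- sweep(sweep(xhat, 2, bn$gamma, `*`), 2, bn$beta, `+`)
    list(y = y, bn = bn, cache = NULL)
  }
}

bn_backward <- function(dy, bn, cache) {
  n <- nrow(dy)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, bn$gamma, `*`)
  dvar <- colSums(dxhat * cache$xc) * (-0.5) * cache$inv_std^3
  dmu <- -colSums(dxhat) * cache$inv_std
  dx <- sweep(dxhat, 2, cache$inv_std, `*`) +
    sweep(cache$xc, 2, dvar * 2 / n, `*`) +
    matrix(dmu / n, n, length(dmu), byrow = TRUE)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

dropout_forward <- function(x, p, training) {
  if (!training || p <= 0) return(list(y = x, mask = NULL))
  mask <- matrix(stats::runif(length(x)) >= p, nrow(x), ncol(x)) / (1 - p)
  list(y = x * mask, mask = mask)
}

affine <- function(x, W, b) sweep(x %*% W, 2, b, `+`)

sigmoid <- function(x) 1 / (1 + exp(-x))

# -- parameter containers ----------------------------------------------------

conv_init <- function(n_in, n_out, sd) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sd), n_in, n_out),
       b = stats::rnorm(n_out, sd = sd))
}

# Shared trunk: conv(C_in -> 32, kernel 60, stride 10) + BN + tanh,
# conv 1x1 32 -> 16 + BN + tanh, conv 1x1 16 -> 8 + BN + tanh.
blocks_init <- function(in_ch, sd) {
  list(conv1 = conv_init(in_ch * 60L, 32L, sd), bn1 = bn_init(32L),
       conv2 = conv_init(32L, 16L, sd), bn2 = bn_init(16L),
       conv3 = conv_init(16L, 8L, sd), bn3 = bn_init(8L))
}

# Z: batch patch matrix (rows x C_in*60). dropout_p > 0 inserts dropout
# after each BatchNorm (the step-proposal training regularisation).
blocks_forward <- function(Z, p, training, dropout_p = 0) {
  cache <- list(Z = Z)
  a1 <- affine(Z, p$conv1$W, p$conv1$b)
  f1 <- bn_forward(a1, p$bn1, training); p$bn1 <- f1$bn
  h1 <- tanh(f1$y)
  d1 <- dropout_forward(h1, dropout_p, training)
  a2 <- affine(d1$y, p$conv2$W, p$conv2$b)
  f2 <- bn_forward(a2, p$bn2, training); p$bn2 <- f2$bn
  h2 <- tanh(f2$y)
  d2 <- dropout_forward(h2, dropout_p, training)
  a3 <- affine(d2$y, p$conv3$W, p$conv3$b)
  f3 <- bn_forward(a3, p$bn3, training); p$bn3 <- f3$bn
  h3 <- tanh(f3$y)
  d3 <- dropout_forward(h3, dropout_p, training)
  cache <- c(cache, list(bn1 = f1$cache, h1 = h1, m1 = d1$mask, x1 = d1$y,
                         bn2 = f2$cache, h2 = h2, m2 = d2$mask, x2 = d2$y,
                         bn3 = f3$cache, h3 = h3, m3 = d3$mask))
  list(H = d3$y, p = p, cache = cache)
}

blocks_backward <- function(dH, p, cache) {
  if (!is.null(cache$m3)) dH <- dH * cache$m3
  dh3 <- dH * (1 - cache$h3^2)
  b3 <- bn_backward(dh3, p$bn3, cache$bn3)
  dW3 <- crossprod(cache$x2, b3$dx); db3 <- colSums(b3$dx)
  dx2 <- b3$dx %*% t(p$conv3$W)
  if (!is.null(cache$m2)) dx2 <- dx2 * cache$m2
  dh2 <- dx2 * (1 - cache$h2^2)
  b2 <- bn_backward(dh2, p$bn2, cache$bn2)
  dW2 <- crossprod(cache$x1, b2$dx); db2 <- colSums(b2$dx)
  dx1 <- b2$dx %*% t(p$conv2$W)
  if (!is.null(cache$m1)) dx1 <- dx1 * cache$m1
  dh1 <- dx1 * (1 - cache$h1^2)
  b1 <- bn_backward(dh1, p$bn1, cache$bn1)
  dW1 <- crossprod(cache$Z, b1$dx); db1 <- colSums(b1$dx)
  list(conv1 = list(W = dW1, b = db1),
       bn1 = list(gamma = b1$dgamma, beta = b1$dbeta),
       conv2 = list(W = dW2, b = db2),
       bn2 = list(gamma = b2$dgamma, beta = b2$dbeta),
       conv3 = list(W = dW3, b = db3),
       bn3 = list(gamma = b3$dgamma, beta = b3$dbeta))
}

# -- SGD with Nesterov momentum ----------------------------------------------

# params/grads are nested lists of numeric arrays with identical structure;
# velocity is carried alongside. Update: v <- mu*v + g; w <- w - lr*(g + mu*v).
sgd_update <- function(params, grads, vel, lr, mu) {
  step <- function(p, g, v) {
    if (is.list(p)) {
      out_p <- p; out_v <- v
      for (nm in names(g)) {
        r <- step(p[[nm]], g[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_v[[nm]] <- r$v
      }
      list(p = out_p, v = out_v)
    } else {
      v2 <- mu * v + g
      list(p = p - lr * (g + mu * v2), v = v2)
    }
  }
  step(params, grads, vel)
}

zeros_like <- function(p) {
  if (is.list(p)) lapply(p, zeros_like) else p * 0
}

#' Learning-rate schedule
#'
#' Geometric decay: `lr * decay^(epoch %/% every)` with `epoch` counted from
#' zero. With the defaults (`lr = 1e-5`, `decay = 0.9`, `every = 10`) the
#' rate at epoch 25 is `1e-5 * 0.9^2`.
#'
#' @param cfg a [train_config()].
#' @param epoch 0-based epoch index.
#' @return The learning rate at that epoch.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  cfg$lr * cfg$lr_decay^(epoch %/% cfg$decay_every)
}

#' Training configuration
#'
#' Hyperparameters of the SGD training used for both networks: learning rate
#' `1e-5` decaying geometrically (x0.9) every 10 epochs, Nesterov momentum
#' 0.9, dropout 0.5, Gaussian init with standard deviation 0.2, and early
#' stopping on a held-out fraction of the training signals.
#'
#' @param lr initial learning rate.
#' @param lr_decay geometric decay factor.
#' @param decay_every epochs between decays.
#' @param momentum Nesterov momentum coefficient.
#' @param dropout dropout probability in `[0, 1)`.
#' @param init_std standard deviation of the Gaussian weight initialisation.
#' @param batch_size minibatch size.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param max_epochs maximum number of epochs.
#' @param val_fraction fraction of the training set held out for early
#'   stopping.
#' @param input_len canonical input length in samples (10 s at 100 Hz).
#' @param seed integer seed governing initialisation, batching and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 1e-5, lr_decay = 0.9, decay_every = 10L,
                         momentum = 0.9, dropout = 0.5, init_std = 0.2,
                         batch_size = 16L, patience = 20L, max_epochs = 500L,
                         val_fraction = 0.2, input_len = 1000L, seed = 1L) {
  stopifnot(lr > 0, lr_decay > 0, momentum >= 0, dropout >= 0, dropout < 1,
            init_std > 0, batch_size >= 1, max_epochs >= 1, input_len >= 60)
  structure(list(lr = lr, lr_decay = lr_decay, decay_every = decay_every,
                 momentum = momentum, dropout = dropout, init_std = init_std,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 val_fraction = val_fraction,
                 input_len = as.integer(input_len), seed = as.integer(seed)),
            class = "train_config")
}
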