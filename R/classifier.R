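# The activity classifier: the three conv/BatchNorm blocks transferred from
# the trained step-proposal network (frozen, including BatchNorm running
# statistics) followed by a conv(8 -> 1, kernel 5) + ReLU, maxpool of size 5,
# and fully connected layers 18 -> 64 -> 16 -> 1 with a sigmoid output. The
# output is the probability that the signal was produced by medical staff
# (label y = 1 for staff, 0 for elderly), trained with binary cross-entropy.

HEAD_KERNEL <- 5L
POOL_SIZE <- 5L

# Shape chain for an input of length T:
#   T_f = floor((T - 60) / 10) + 1   (trunk output)
#   T_c = T_f - 5 + 1                (head convolution)
#   T_p = floor(T_c / 5)             (maxpool; flatten dimension)
head_flat_dim <- function(input_len) {
  Tf <- (as.integer(input_len) - SPN_KERNEL) %/% SPN_STRIDE + 1L
  (Tf - HEAD_KERNEL + 1L) %/% POOL_SIZE
}

#' Pad or crop an embedded signal to a canonical length
#'
#' Shorter signals are zero-padded symmetrically (the extra sample going to
#' the right), longer signals centre-cropped. 1000 samples (10 s at 100 Hz,
#' the average event duration) is the canonical classifier input.
#'
#' @param x an [embedded_signal()] or channel matrix.
#' @param target_len target length in samples (default 1000, >= 60).
#' @return Same type as `x`, with exactly `target_len` columns.
#' @export
pad_or_crop <- function(x, target_len = 1000L) {
  target_len <- as.integer(target_len)
  if (target_len < SPN_KERNEL) stop("`target_len` must be >= 60",
                                    call. = FALSE)
  ch <- if (inherits(x, "embedded_signal")) x$channels else as.matrix(x)
  Tn <- ncol(ch)
  if (Tn > target_len) {
    off <- (Tn - target_len) %/% 2L
    ch <- ch[, (off + 1L):(off + target_len), drop = FALSE]
  } else if (Tn < target_len) {
    left <- (target_len - Tn) %/% 2L
    right <- target_len - Tn - left
    ch <- cbind(matrix(0, nrow(ch), left), ch, matrix(0, nrow(ch), right))
  }
  if (inherits(x, "embedded_signal"))
    embedded_signal(ch, x$rate_hz, x$source_id)
  else ch
}

#' Build the activity classifier
#'
#' When `spn` is supplied its three conv/BatchNorm blocks (weights and
#' BatchNorm running statistics) are copied in and frozen; the remaining
#' head parameters are drawn i.i.d. centred Gaussian with standard
#' deviation `cfg$init_std`. Without `spn` the whole network is
#' Gaussian-initialised and trainable (the from-scratch ablations).
#'
#' @param spn a trained [spn_init()] model, or `NULL`.
#' @param cfg a [train_config()].
#' @param in_ch input channels (3 for embedded input, 1 for raw); taken
#'   from `spn` when given.
#' @param seed seed for the head initialisation (default `cfg$seed`).
#' @return An object of class `activity_net`.
#' @export
build_activity_net <- function(spn = NULL, cfg = train_config(),
                               in_ch = 3L, seed = NULL) {
  seed <- seed %||% cfg$seed
  sd <- cfg$init_std
  flat <- head_flat_dim(cfg$input_len)
  if (!is.null(spn)) {
    stopifnot(inherits(spn, "spn_model"))
    in_ch <- spn$in_ch
    blocks <- spn$params[c("conv1", "bn1", "conv2", "bn2", "conv3", "bn3")]
    frozen <- TRUE
  } else {
    blocks <- with_seed(derive_seed(seed, 3L), blocks_init(in_ch, sd))
    frozen <- FALSE
  }
  head <- with_seed(seed, list(
    conv5 = conv_init(8L * HEAD_KERNEL, 1L, sd),
    fc1 = conv_init(flat, 64L, sd),
    fc2 = conv_init(64L, 16L, sd),
    fc3 = conv_init(16L, 1L, sd)))
  structure(list(params = c(blocks, head), in_ch = as.integer(in_ch),
                 frozen = frozen, input_len = cfg$input_len,
                 flat_dim = flat),
            class = "activity_net")
}

#' @export
print.activity_net <- function(x, ...) {
  cat(sprintf(paste0("<activity_net> in_ch=%d, trunk %s, conv(5)+maxpool(5)",
                     " -> %d -> 64 -> 16 -> 1\n"),
              x$in_ch, if (x$frozen) "frozen" else "trainable", x$flat_dim))
  invisible(x)
}

# Head forward from trunk features H (rows x 8, per-signal blocks of equal
# length). Returns per-signal probabilities and caches for backprop.
head_forward <- function(net, H, n_sig, training = FALSE, dropout_p = 0) {
  p <- net$params
  Tf <- nrow(H) / n_sig
  Z5 <- vector("list", n_sig)
  for (i in seq_len(n_sig)) {
    rows <- ((i - 1L) * Tf + 1L):(i * Tf)
    Z5[[i]] <- im2col_feat(H[rows, , drop = FALSE], HEAD_KERNEL)
  }
  Z5 <- do.call(rbind, Z5)
  a5 <- affine(Z5, p$conv5$W, p$conv5$b)
  r5 <- pmax(a5, 0)
  Tc <- Tf - HEAD_KERNEL + 1L
  Tp <- Tc %/% POOL_SIZE
  flat <- matrix(0, n_sig, Tp)
  amax <- matrix(0L, n_sig, Tp)
  for (i in seq_len(n_sig)) {
    v <- r5[((i - 1L) * Tc + 1L):(i * Tc), 1L]
    gm <- matrix(v[seq_len(Tp * POOL_SIZE)], POOL_SIZE, Tp)
    j <- max.col(t(gm), ties.method = "first")
    flat[i, ] <- gm[cbind(j, seq_len(Tp))]
    amax[i, ] <- (seq_len(Tp) - 1L) * POOL_SIZE + j
  }
  a1 <- affine(flat, p$fc1$W, p$fc1$b); h1 <- pmax(a1, 0)
  d1 <- dropout_forward(h1, dropout_p, training)
  a2 <- affine(d1$y, p$fc2$W, p$fc2$b); h2 <- pmax(a2, 0)
  d2 <- dropout_forward(h2, dropout_p, training)
  a3 <- affine(d2$y, p$fc3$W, p$fc3$b)
  yhat <- as.numeric(sigmoid(a3))
  list(yhat = yhat,
       cache = list(Z5 = Z5, a5 = a5, Tf = Tf, Tc = Tc, Tp = Tp, amax = amax,
                    flat = flat, h1 = h1, m1 = d1$mask, x1 = d1$y,
                    h2 = h2, m2 = d2$mask, x2 = d2$y, n_sig = n_sig))
}

# Backward from dz3 = dL/d(logit). Returns head gradients and dH (gradient
# w.r.t. the trunk features), the latter only when requested.
head_backward <- function(net, cache, dz3, need_dH = FALSE) {
  p <- net$params
  dz3 <- matrix(dz3, ncol = 1L)
  g_fc3 <- list(W = crossprod(cache$x2, dz3), b = colSums(dz3))
  dx2 <- dz3 %*% t(p$fc3$W)
  if (!is.null(cache$m2)) dx2 <- dx2 * cache$m2
  dh2 <- dx2 * (cache$h2 > 0)
  g_fc2 <- list(W = crossprod(cache$x1, dh2), b = colSums(dh2))
  dx1 <- dh2 %*% t(p$fc2$W)
  if (!is.null(cache$m1)) dx1 <- dx1 * cache$m1
  dh1 <- dx1 * (cache$h1 > 0)
  g_fc1 <- list(W = crossprod(cache$flat, dh1), b = colSums(dh1))
  dflat <- dh1 %*% t(p$fc1$W)
  # unpool to the conv map, then through ReLU
  n_sig <- cache$n_sig; Tc <- cache$Tc; Tp <- cache$Tp
  dr5 <- matrix(0, n_sig * Tc, 1L)
  for (i in seq_len(n_sig)) {
    off <- (i - 1L) * Tc
    dr5[off + cache$amax[i, ], 1L] <- dflat[i, ]
  }
  da5 <- dr5 * (cache$a5 > 0)
  g_conv5 <- list(W = crossprod(cache$Z5, da5), b = colSums(da5))
  grads <- list(conv5 = g_conv5, fc1 = g_fc1, fc2 = g_fc2, fc3 = g_fc3)
  dH <- NULL
  if (need_dH) {
    dpatch <- da5 %*% t(p$conv5$W)
    Tf <- cache$Tf
    dH <- do.call(rbind, lapply(seq_len(n_sig), function(i) {
      rows <- ((i - 1L) * Tc + 1L):(i * Tc)
      col2im_feat(dpatch[rows, , drop = FALSE], Tf, 8L, HEAD_KERNEL)
    }))
  }
  list(grads = grads, dH = dH)
}

#' Binary cross-entropy loss
#'
#' `-(sum_i [ y_i log(yhat_i) + (1 - y_i) log(1 - yhat_i) ])` with
#' probabilities clamped to `[1e-7, 1 - 1e-7]`; y = 1 for staff, 0 for
#' elderly activity.
#'
#' @param y_hat predicted probabilities.
#' @param y 0/1 labels of the same length.
#' @return The loss (scalar >= 0).
#' @export
bce_loss <- function(y_hat, y) {
  if (length(y_hat) != length(y)) stop("length mismatch", call. = FALSE)
  p <- clamp(y_hat, NN_EPS, 1 - NN_EPS)
  -sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Classify activity scores at a threshold
#'
#' A signal is classified as staff iff its score is greater than or equal
#' to `tau` (inclusive).
#'
#' @param y_hat probabilities in `[0, 1]`.
#' @param tau threshold in `[0, 1]` (default 0.4).
#' @return Character vector over `c("staff", "elderly")`.
#' @export
classify_scores <- function(y_hat, tau = 0.4) {
  if (tau < 0 || tau > 1) stop("`tau` must be in [0, 1]", call. = FALSE)
  ifelse(y_hat >= tau, "staff", "elderly")
}

as_input_matrix <- function(x, net) {
  ch <- if (inherits(x, "embedded_signal")) x$channels
        else if (inherits(x, "mono_signal")) matrix(x$s, nrow = 1L)
        else as.matrix(x)
  if (nrow(ch) != net$in_ch)
    stop(sprintf("expected %d input channels, got %d", net$in_ch, nrow(ch)),
         call. = FALSE)
  if (ncol(ch) != net$input_len)
    ch <- pad_or_crop(ch, net$input_len)
  ch
}

#' Score signals with the activity classifier
#'
#' Inference mode (BatchNorm running statistics, no dropout). The returned
#' scores are probabilities that each signal is medical-staff activity.
#'
#' @param net an [build_activity_net()] model.
#' @param inputs list of [embedded_signal()]s (or channel matrices; mono
#'   signals for a 1-channel net). Signals are padded/cropped to the net's
#'   input length.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_activity <- function(net, inputs) {
  if (!is.list(inputs) || inherits(inputs, "embedded_signal"))
    inputs <- list(inputs)
  chans <- lapply(inputs, as_input_matrix, net = net)
  Z <- do.call(rbind, lapply(chans, im2col_signal, k = SPN_KERNEL,
                             stride = SPN_STRIDE))
  fb <- blocks_forward(Z, net$params, training = FALSE)
  head_forward(net, fb$H, length(chans))$yhat
}

#' Train the activity classifier
#'
#' Binary cross-entropy (summed over the batch) optimised by SGD with
#' Nesterov momentum under the geometric learning-rate schedule, dropout
#' 0.5 after each fully connected layer except the last, early stopping on
#' a stratified validation split. Frozen trunk blocks are excluded from the
#' optimiser and from BatchNorm statistic updates, so they are returned
#' bitwise unchanged. Deterministic given `cfg$seed`.
#'
#' @param net an [build_activity_net()] model.
#' @param inputs list of input signals (see [predict_activity()]).
#' @param y 0/1 labels (1 = staff).
#' @param cfg a [train_config()].
#' @return The trained `activity_net`, with a `history` element.
#' @export
train_activity_net <- function(net, inputs, y, cfg = train_config()) {
  if (!length(inputs)) stop("empty training set", call. = FALSE)
  if (length(unique(y)) < 2L)
    warning("single-class training set", call. = FALSE)
  chans <- lapply(inputs, as_input_matrix, net = net)
  Zs <- lapply(chans, im2col_signal, k = SPN_KERNEL, stride = SPN_STRIDE)
  n <- length(Zs)
  y <- as.numeric(y)

  # With a frozen trunk the block features are constant: compute them once.
  feat <- NULL
  if (net$frozen) {
    Zall <- do.call(rbind, Zs)
    feat <- blocks_forward(Zall, net$params, training = FALSE)$H
    Tf <- nrow(feat) / n
    feat <- lapply(seq_len(n), function(i)
      feat[((i - 1L) * Tf + 1L):(i * Tf), , drop = FALSE])
  }

  forward_eval <- function(net, idx) {
    if (net$frozen) {
      H <- do.call(rbind, feat[idx])
    } else {
      Z <- do.call(rbind, Zs[idx])
      H <- blocks_forward(Z, net$params, training = FALSE)$H
    }
    head_forward(net, H, length(idx))$yhat
  }

  with_seed(derive_seed(cfg$seed, 29L), {
    # stratified validation split
    n_val <- max(1L, round(cfg$val_fraction * n))
    if (n_val >= n) n_val <- n - 1L
    val_idx <- integer(0)
    for (cls in unique(y)) {
      ci <- which(y == cls)
      k <- max(if (length(ci) > 1L) 1L else 0L,
               round(length(ci) * cfg$val_fraction))
      k <- min(k, length(ci) - 1L)
      if (k > 0L) val_idx <- c(val_idx, sample(ci, k))
    }
    if (!length(val_idx)) val_idx <- sample(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)

    vel <- zeros_like(net$params)
    best_val <- bce_loss(forward_eval(net, val_idx), y[val_idx])
    loss0_train <- bce_loss(forward_eval(net, tr_idx), y[tr_idx])
    best_params <- net$params
    best_epoch <- -1L   # -1 = the initial weights
    wait <- 0L
    history <- data.frame(epoch = integer(), train = numeric(),
                          val = numeric())
    frozen_names <- c("conv1", "bn1", "conv2", "bn2", "conv3", "bn3")

    for (epoch in seq_len(cfg$max_epochs) - 1L) {
      lr <- lr_at_epoch(cfg, epoch)
      ord <- sample(tr_idx)
      for (b0 in seq(1L, length(ord), by = cfg$batch_size)) {
        bi <- ord[b0:min(b0 + cfg$batch_size - 1L, length(ord))]
        if (net$frozen) {
          H <- do.call(rbind, feat[bi])
          cache_blocks <- NULL
        } else {
          Z <- do.call(rbind, Zs[bi])
          fb <- blocks_forward(Z, net$params, training = TRUE)
          net$params[frozen_names] <- fb$p[frozen_names]  # BN running stats
          H <- fb$H
          cache_blocks <- fb$cache
        }
        hf <- head_forward(net, H, length(bi), training = TRUE,
                           dropout_p = cfg$dropout)
        dz3 <- hf$yhat - y[bi]
        hb <- head_backward(net, hf$cache, dz3, need_dH = !net$frozen)
        grads <- hb$grads
        if (!net$frozen)
          grads <- c(blocks_backward(hb$dH, net$params, cache_blocks), grads)
        up <- sgd_update(net$params[names(grads)], grads,
                         vel[names(grads)], lr, cfg$momentum)
        net$params[names(grads)] <- up$p
        vel[names(grads)] <- up$v
      }
      tr_loss <- bce_loss(forward_eval(net, tr_idx), y[tr_idx])
      val_loss <- bce_loss(forward_eval(net, val_idx), y[val_idx])
      history <- rbind(history, data.frame(epoch = epoch, train = tr_loss,
                                           val = val_loss))
      if (val_loss < best_val - 1e-10) {
        best_val <- val_loss
        best_params <- net$params
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait > cfg$patience) break
      }
    }
    net$params <- best_params
    net$history <- history
    net$best_epoch <- best_epoch
    net$loss0_train <- loss0_train
    net$best_train_loss <- if (best_epoch >= 0L)
      history$train[history$epoch == best_epoch] else loss0_train
  })
  net
}
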