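# Step Proposal Network (SPN): a fully convolutional 1D network that scores,
# at every position of its stride-10 feature grid, three anchor boxes (20,
# 30 and 40 raw samples -- typical step durations at 100 Hz) for the
# probability of containing a footstep. Anchors with intersection-over-union
# above 0.7 against a ground-truth step box are positive training instances,
# below 0.3 negative, in between neutral (excluded from the loss). Its three
# conv/BatchNorm blocks are later transferred, frozen, into the activity
# classifier.

SPN_KERNEL <- 60L
SPN_STRIDE <- 10L
SPN_BOX_SIZES <- c(20L, 30L, 40L)

#' Anchor grid for a signal length
#'
#' Anchor `(i, k)` (0-based grid index i) covers raw samples
#' `[i * 10, i * 10 + size_k)` with sizes 20, 30, 40. The grid length is
#' `floor((T - 60) / 10) + 1`, matching the stride-10, kernel-60 first
#' convolution of the network.
#'
#' @param T_len signal length in samples (>= 60).
#' @return An object of class `anchor_grid`.
#' @export
anchor_grid <- function(T_len) {
  T_len <- as.integer(T_len)
  if (T_len < SPN_KERNEL) stop("signal shorter than 60 samples", call. = FALSE)
  structure(list(stride = SPN_STRIDE, box_sizes = SPN_BOX_SIZES,
                 feature_len = (T_len - SPN_KERNEL) %/% SPN_STRIDE + 1L,
                 T_len = T_len),
            class = "anchor_grid")
}

# All anchors of a grid as a (T_f * 3) x 2 matrix of [start, end) intervals.
grid_anchors <- function(grid) {
  starts <- rep((seq_len(grid$feature_len) - 1L) * grid$stride, times = 3L)
  sizes <- rep(grid$box_sizes, each = grid$feature_len)
  cbind(start = starts, end = starts + sizes)
}

#' Intersection over union of a candidate box against ground truth
#'
#' `max_j |b_j intersect b| / |b_j union b|` over the ground-truth boxes,
#' counting integer samples of the half-open intervals; 0 when the ground
#' truth is empty.
#'
#' @param candidate length-2 vector `c(start, end)` (0-based, half-open) or
#'   a [step_boxes()] row.
#' @param ground_truth a [step_boxes()] matrix (possibly empty).
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(candidate, ground_truth) {
  if (is.null(ground_truth) || nrow(ground_truth) == 0L) return(0)
  s <- candidate[1]; e <- candidate[2]
  inter <- pmax(0L, pmin(e, ground_truth[, 2]) - pmax(s, ground_truth[, 1]))
  uni <- (e - s) + (ground_truth[, 2] - ground_truth[, 1]) - inter
  max(inter / uni)
}

# Vectorised IoU of many anchors against one ground-truth set.
anchors_iou <- function(anchors, gt) {
  if (is.null(gt) || nrow(gt) == 0L) return(rep(0, nrow(anchors)))
  apply(anchors, 1, box_iou, ground_truth = gt)
}

#' Assign positive/negative/neutral labels to anchors
#'
#' Anchors with IoU above `hi` against the ground-truth step boxes are
#' positive, below `lo` negative, all others neutral (excluded from the
#' training loss). With no ground-truth boxes every anchor is negative.
#'
#' @param grid an [anchor_grid()].
#' @param gt a [step_boxes()] matrix.
#' @param hi,lo thresholds (defaults 0.7 / 0.3), `lo < hi`.
#' @return A T_f x 3 character matrix over
#'   `c("positive", "negative", "neutral")`.
#' @export
assign_anchors <- function(grid, gt, hi = 0.7, lo = 0.3) {
  if (lo >= hi) stop("`lo` must be below `hi`", call. = FALSE)
  iou <- anchors_iou(grid_anchors(grid), gt)
  lab <- ifelse(iou > hi, "positive", ifelse(iou < lo, "negative", "neutral"))
  matrix(lab, grid$feature_len, 3L)
}

label_targets <- function(labels) {
  list(target = matrix(as.numeric(labels == "positive"), nrow(labels)),
       mask = matrix(as.numeric(labels != "neutral"), nrow(labels)))
}

#' Initialise step-proposal network weights
#'
#' Three conv/BatchNorm/tanh blocks (32 filters of size 60 with stride 10,
#' then 1x1 convolutions to 16 and 8 channels) topped by a 1x1 convolution
#' to 3 sigmoid outputs, one per anchor size. All weights i.i.d. centred
#' Gaussian with standard deviation `init_std`.
#'
#' @param in_ch input channel count (3 for dictionary-embedded signals).
#' @param init_std Gaussian init standard deviation (default 0.2).
#' @param seed integer seed.
#' @return An object of class `spn_model`.
#' @export
spn_init <- function(in_ch = 3L, init_std = 0.2, seed = 1L) {
  params <- with_seed(seed, {
    p <- blocks_init(in_ch, init_std)
    p$conv4 <- conv_init(8L, 3L, init_std)
    p
  })
  structure(list(params = params, in_ch = as.integer(in_ch)),
            class = "spn_model")
}

#' @export
print.spn_model <- function(x, ...) {
  cat(sprintf("<spn_model> in_ch=%d, conv(60,s10)x32 -> 16 -> 8 -> 3 anchors\n",
              x$in_ch))
  invisible(x)
}

spn_forward_batch <- function(model, Z, training = FALSE, dropout_p = 0) {
  fb <- blocks_forward(Z, model$params, training, dropout_p)
  A4 <- affine(fb$H, fb$p$conv4$W, fb$p$conv4$b)
  W <- sigmoid(A4)
  list(W = W, H = fb$H, p = fb$p, cache = fb$cache)
}

#' Score anchor boxes with the step-proposal network
#'
#' Runs the network in inference mode (BatchNorm running statistics, no
#' dropout) on one embedded signal.
#'
#' @param x an [embedded_signal()] (or channel matrix) with the model's
#'   input channel count and length >= 60.
#' @param model an [spn_model()].
#' @return A T_f x 3 matrix of step probabilities in (0, 1).
#' @export
spn_forward <- function(x, model) {
  ch <- if (inherits(x, "embedded_signal")) x$channels else as.matrix(x)
  if (nrow(ch) != model$in_ch)
    stop(sprintf("expected %d input channels, got %d", model$in_ch, nrow(ch)),
         call. = FALSE)
  Z <- im2col_signal(ch, SPN_KERNEL, SPN_STRIDE)
  spn_forward_batch(model, Z)$W
}

#' Anchor-box training loss
#'
#' The negated log-likelihood of the anchor labels:
#' `-(sum over positive anchors log W + sum over negative anchors log(1-W))`,
#' neutral anchors contributing nothing. Probabilities are clamped to
#' `[1e-7, 1 - 1e-7]`.
#'
#' @param W T_f x 3 matrix of anchor probabilities.
#' @param labels T_f x 3 label matrix from [assign_anchors()].
#' @return The loss (scalar >= 0).
#' @export
spn_loss <- function(W, labels) {
  if (!all(dim(W) == dim(labels))) stop("shape mismatch", call. = FALSE)
  tg <- label_targets(labels)
  Wc <- clamp(W, NN_EPS, 1 - NN_EPS)
  -sum(tg$mask * (tg$target * log(Wc) + (1 - tg$target) * log(1 - Wc)))
}

#' Train the step-proposal network
#'
#' Trains on embedded walk signals with ground-truth step boxes: SGD with
#' Nesterov momentum, learning rate `1e-5` decaying geometrically (x0.9)
#' every 10 epochs, dropout 0.5 after each BatchNorm, early stopping on a
#' held-out validation fraction. The per-signal loss is the raw sum of
#' [spn_loss()] over that signal's anchors; the batch loss is the mean over
#' the signals in the batch. Signals without a single positive anchor are
#' skipped with a warning. Deterministic given `cfg$seed`.
#'
#' @param walks list of [embedded_signal()]s.
#' @param boxes list of [step_boxes()] matrices, parallel to `walks`.
#' @param cfg a [train_config()].
#' @return A trained [spn_init()] model with a `history` element (per-epoch
#'   train/validation losses).
#' @export
train_spn <- function(walks, boxes, cfg = train_config()) {
  if (!length(walks)) stop("empty training set", call. = FALSE)
  chans <- lapply(walks, function(w)
    if (inherits(w, "embedded_signal")) w$channels else as.matrix(w))
  in_ch <- nrow(chans[[1]])
  Zs <- lapply(chans, im2col_signal, k = SPN_KERNEL, stride = SPN_STRIDE)
  tgs <- vector("list", length(walks))
  keep <- logical(length(walks))
  for (i in seq_along(walks)) {
    grid <- anchor_grid(ncol(chans[[i]]))
    lab <- assign_anchors(grid, boxes[[i]])
    tgs[[i]] <- label_targets(lab)
    keep[i] <- any(tgs[[i]]$target * tgs[[i]]$mask > 0)
  }
  if (!all(keep))
    warning(sprintf("%d signal(s) without a positive anchor were skipped",
                    sum(!keep)), call. = FALSE)
  if (!any(keep)) stop("no trainable signals", call. = FALSE)
  Zs <- Zs[keep]; tgs <- tgs[keep]
  n <- length(Zs)

  model <- spn_init(in_ch, cfg$init_std, cfg$seed)

  eval_loss <- function(model, idx) {
    tot <- 0
    for (i in idx) {
      W <- spn_forward_batch(model, Zs[[i]])$W
      Wc <- clamp(W, NN_EPS, 1 - NN_EPS)
      t <- tgs[[i]]
      tot <- tot - sum(t$mask * (t$target * log(Wc) +
                                   (1 - t$target) * log(1 - Wc)))
    }
    tot / length(idx)
  }

  with_seed(derive_seed(cfg$seed, 17L), {
    n_val <- max(1L, round(cfg$val_fraction * n))
    if (n_val >= n) n_val <- n - 1L
    val_idx <- if (n_val > 0L) sample(n, n_val) else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (!length(val_idx)) val_idx <- tr_idx   # degenerate tiny sets

    vel <- zeros_like(model$params)
    loss0_train <- eval_loss(model, tr_idx)
    best_val <- eval_loss(model, val_idx)
    best_params <- model$params
    best_epoch <- -1L   # -1 = the initial weights
    wait <- 0L
    history <- data.frame(epoch = integer(), train = numeric(),
                          val = numeric())

    for (epoch in seq_len(cfg$max_epochs) - 1L) {
      lr <- lr_at_epoch(cfg, epoch)
      ord <- sample(tr_idx)
      for (b0 in seq(1L, length(ord), by = cfg$batch_size)) {
        bi <- ord[b0:min(b0 + cfg$batch_size - 1L, length(ord))]
        Z <- do.call(rbind, Zs[bi])
        rows <- vapply(Zs[bi], nrow, 0L)
        fw <- spn_forward_batch(model, Z, training = TRUE,
                                dropout_p = cfg$dropout)
        model$params <- fw$p   # BatchNorm running statistics
        target <- do.call(rbind, lapply(tgs[bi], `[[`, "target"))
        mask <- do.call(rbind, lapply(tgs[bi], `[[`, "mask"))
        wgt <- rep(1 / length(bi), sum(rows))
        dA4 <- (fw$W - target) * mask * wgt
        g4 <- list(W = crossprod(fw$H, dA4), b = colSums(dA4))
        dH <- dA4 %*% t(model$params$conv4$W)
        gb <- blocks_backward(dH, model$params, fw$cache)
        grads <- c(gb, list(conv4 = g4))
        up <- sgd_update(model$params[names(grads)], grads,
                         vel[names(grads)], lr, cfg$momentum)
        model$params[names(grads)] <- up$p
        vel[names(grads)] <- up$v
      }
      tr_loss <- eval_loss(model, tr_idx)
      val_loss <- eval_loss(model, val_idx)
      history <- rbind(history, data.frame(epoch = epoch, train = tr_loss,
                                           val = val_loss))
      if (val_loss < best_val - 1e-10) {
        best_val <- val_loss
        best_params <- model$params
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait > cfg$patience) break
      }
    }
    model$params <- best_params
    model$history <- history
    model$best_epoch <- best_epoch
    model$loss0_train <- loss0_train
    model$best_train_loss <- if (best_epoch >= 0L)
      history$train[history$epoch == best_epoch] else loss0_train
  })
  model
}

#' Decode anchor scores into step boxes
#'
#' Keeps anchors scoring at least `score_min`, greedily in descending score
#' order, suppressing any anchor whose IoU with an already kept box exceeds
#' `nms_iou` (non-maximum suppression). Boxes are reported in raw-sample
#' coordinates.
#'
#' @param W T_f x 3 score matrix from [spn_forward()].
#' @param grid the matching [anchor_grid()].
#' @param score_min score threshold (default 0.5).
#' @param nms_iou suppression threshold (default 0.5).
#' @return A data frame with columns `start`, `end`, `score`, ordered by
#'   decreasing score.
#' @export
decode_boxes <- function(W, grid, score_min = 0.5, nms_iou = 0.5) {
  anchors <- grid_anchors(grid)
  scores <- as.vector(W)
  keep <- which(scores >= score_min)
  if (!length(keep))
    return(data.frame(start = integer(), end = integer(), score = numeric()))
  keep <- keep[order(scores[keep], decreasing = TRUE)]
  chosen <- integer(0)
  for (i in keep) {
    if (!length(chosen)) { chosen <- i; next }
    ious <- vapply(chosen, function(j)
      box_iou(anchors[i, ], anchors[j, , drop = FALSE]), 0)
    if (all(ious <= nms_iou)) chosen <- c(chosen, i)
  }
  data.frame(start = anchors[chosen, 1], end = anchors[chosen, 2],
             score = scores[chosen])
}

#' Average precision of step-box predictions
#'
#' Predictions from all signals are pooled and ranked by decreasing score; a
#' prediction is a true positive if it matches a not-yet-matched
#' ground-truth box of its own signal with IoU at least `iou_thresh`
#' (greedy, best-IoU match). AP is the area under the resulting
#' precision-recall curve (all-point, non-interpolated).
#'
#' @param predictions list (one per signal) of data frames with `start`,
#'   `end`, `score` columns (as from [decode_boxes()]).
#' @param gt list of [step_boxes()] matrices, parallel to `predictions`.
#' @param iou_thresh matching threshold in (0, 1].
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(predictions, gt, iou_thresh = 0.5) {
  n_gt <- sum(vapply(gt, nrow, 0L))
  if (n_gt == 0L) stop("no ground-truth boxes", call. = FALSE)
  pool <- do.call(rbind, lapply(seq_along(predictions), function(i) {
    p <- predictions[[i]]
    if (is.null(p) || !nrow(p)) return(NULL)
    data.frame(sig = i, start = p$start, end = p$end, score = p$score)
  }))
  if (is.null(pool) || !nrow(pool)) return(0)
  pool <- pool[order(-pool$score), , drop = FALSE]
  matched <- lapply(gt, function(g) rep(FALSE, nrow(g)))
  tp <- logical(nrow(pool))
  for (r in seq_len(nrow(pool))) {
    i <- pool$sig[r]
    g <- gt[[i]]
    if (!nrow(g)) next
    inter <- pmax(0L, pmin(pool$end[r], g[, 2]) - pmax(pool$start[r], g[, 1]))
    uni <- (pool$end[r] - pool$start[r]) + (g[, 2] - g[, 1]) - inter
    ious <- inter / uni
    ious[matched[[i]]] <- -1
    j <- which.max(ious)
    if (length(j) && ious[j] >= iou_thresh) {
      tp[r] <- TRUE
      matched[[i]][j] <- TRUE
    }
  }
  tps <- cumsum(tp)
  prec <- tps / seq_along(tp)
  sum(prec[tp]) / n_gt
}

#' Evaluate the step-proposal network by average precision
#'
#' Decodes boxes on each signal (with a low score floor so the whole
#' precision-recall curve is swept) and computes [average_precision()].
#'
#' @param model an [spn_model()].
#' @param walks list of [embedded_signal()]s.
#' @param boxes list of ground-truth [step_boxes()].
#' @param iou_thresh AP matching threshold (default 0.5).
#' @param score_min decode floor (default 0.05).
#' @param nms_iou suppression threshold (default 0.5).
#' @return AP in `[0, 1]`.
#' @export
spn_average_precision <- function(model, walks, boxes, iou_thresh = 0.5,
                                  score_min = 0.05, nms_iou = 0.5) {
  preds <- lapply(walks, function(w) {
    ch <- if (inherits(w, "embedded_signal")) w$channels else as.matrix(w)
    W <- spn_forward(ch, model)
    decode_boxes(W, anchor_grid(ncol(ch)), score_min, nms_iou)
  })
  average_precision(preds, boxes, iou_thresh)
}
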