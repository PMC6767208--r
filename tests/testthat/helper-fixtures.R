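# Shared fixtures, built in code at test time.

# A small random recording with annotation.
make_recording <- function(K = 3L, T_len = 200L, seed = 1L,
                           event_class = "walk_single", status = "staff",
                           boxes = step_boxes(c(20L, 80L), c(45L, 110L))) {
  withr::with_seed(seed, {
    ch <- matrix(stats::rnorm(K * T_len), K, T_len)
    recording(ch, rate_hz = 100, id = sprintf("fix-%d", seed),
              annotation = event_annotation(event_class, status,
                                            n_persons = if (event_class == "walk_multi") 2L else 1L,
                                            step_boxes = boxes))
  })
}

# A dataset with a given per-stratum composition (counts named by
# "<event_class>.<status>").
make_dataset <- function(comp, T_len = 150L, seed = 1L) {
  recs <- list()
  i <- 0L
  for (nm in names(comp)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    for (j in seq_len(comp[[nm]])) {
      i <- i + 1L
      recs[[i]] <- make_recording(K = 2L, T_len = T_len, seed = i,
                                  event_class = parts[1], status = parts[2],
                                  boxes = step_boxes())
    }
  }
  floor_dataset(recs)
}

# Planted-atom signals: a fixed unit-norm 70-sample bump convolved with
# sparse spike trains plus Gaussian noise.
planted_atom <- function() {
  u <- seq(0, 1, length.out = 70)
  a <- exp(-((u - 0.4) / 0.15)^2) + 0.5 * exp(-((u - 0.75) / 0.1)^2)
  a / sqrt(sum(a^2))
}

planted_signals <- function(n_signals = 20L, T_len = 1000L, density = 0.01,
                            noise_sd = 0.01, seed = 42L, amp = 1) {
  atom <- planted_atom()
  withr::with_seed(seed, lapply(seq_len(n_signals), function(i) {
    spikes <- stats::rbinom(T_len, 1, density) * amp *
      sample(c(-1, 1), T_len, replace = TRUE)
    s <- Re(stats::fft(stats::fft(spikes) *
                         stats::fft(c(atom, rep(0, T_len - 70))),
                       inverse = TRUE)) / T_len
    s + stats::rnorm(T_len, sd = noise_sd)
  }))
}

# Best normalised cross-correlation between two equal-support atoms over
# circular shifts and sign.
atom_ncc <- function(a, b) {
  stopifnot(length(a) == length(b))
  cc <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE)) /
    length(a)
  max(abs(cc)) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

# Brute-force oracles -------------------------------------------------------

# Sample-counting IoU oracle over explicit integer sample sets.
iou_oracle <- function(candidate, gt) {
  if (nrow(gt) == 0L) return(0)
  cand <- seq(candidate[1], candidate[2] - 1L)
  max(vapply(seq_len(nrow(gt)), function(j) {
    g <- seq(gt[j, 1], gt[j, 2] - 1L)
    length(intersect(cand, g)) / length(union(cand, g))
  }, 0))
}

# Pairwise-concordance AUC oracle.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Precision-recall enumeration oracle for average precision: predictions are
# pooled over signals and ranked by score, matched greedily to unmatched
# ground-truth boxes (best IoU >= threshold).
ap_oracle <- function(predictions, gt, iou_thresh) {
  pool <- do.call(rbind, lapply(seq_along(predictions), function(i) {
    p <- predictions[[i]]
    if (is.null(p) || !nrow(p)) return(NULL)
    cbind(i, p$start, p$end, p$score)
  }))
  n_gt <- sum(vapply(gt, nrow, 0L))
  if (is.null(pool)) return(0)
  pool <- pool[order(-pool[, 4]), , drop = FALSE]
  used <- lapply(gt, function(g) rep(FALSE, nrow(g)))
  tp <- integer(0)
  for (r in seq_len(nrow(pool))) {
    i <- pool[r, 1]
    best <- 0; best_j <- 0L
    g <- gt[[i]]
    for (j in seq_len(nrow(g))) {
      if (used[[i]][j]) next
      v <- iou_oracle(pool[r, 2:3], g[j, , drop = FALSE])
      if (v > best) { best <- v; best_j <- j }
    }
    if (best_j > 0L && best >= iou_thresh) {
      tp <- c(tp, 1L); used[[i]][best_j] <- TRUE
    } else tp <- c(tp, 0L)
  }
  cum <- cumsum(tp)
  ap <- 0
  for (r in seq_along(tp))
    if (tp[r] == 1L) ap <- ap + (cum[r] / r) / n_gt
  ap
}
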