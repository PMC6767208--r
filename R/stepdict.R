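# Convolutional dictionary learning of footstep atoms.
#
# The model: a preprocessed mono signal s is approximated as a sparse sum of
# shifted copies of m short waveform atoms d_m,
#     s ~ sum_m x_m * d_m,
# learned by minimising the convolutional basis pursuit denoising objective
#     sum_signals [ 1/2 || sum_m x_m * d_m - s ||_2^2 + lambda sum_m ||x_m||_1 ]
# over both the activation signals x_m and the unit-norm atoms d_m. The
# solver alternates single ADMM steps of sparse coding (x update) and of the
# consensus-form dictionary update (d update), with all linear systems solved
# in the frequency domain via rank-one (Sherman-Morrison) inversions.
# Convolutions inside the solver are circular at the signal length; the
# user-facing embedding uses linear "same" convolution so the embedded
# channels stay aligned with the raw time axis.

#' Step-atom dictionary
#'
#' @param atoms L x m numeric matrix, one unit-norm atom per column.
#' @param rate_hz sampling frequency (default 100).
#' @param lambda_used sparsity weight the atoms were learned with.
#' @param iters_used iterations used.
#' @param seed_used seed used.
#' @return An object of class `step_dictionary`.
#' @export
step_dictionary <- function(atoms, rate_hz = 100, lambda_used = NA_real_,
                            iters_used = NA_integer_, seed_used = NA_integer_) {
  atoms <- as.matrix(atoms)
  structure(list(atoms = atoms, rate_hz = rate_hz, m = ncol(atoms),
                 atom_len = nrow(atoms), lambda_used = lambda_used,
                 iters_used = iters_used, seed_used = seed_used),
            class = "step_dictionary")
}

#' @export
print.step_dictionary <- function(x, ...) {
  cat(sprintf("<step_dictionary> %d atoms of %d samples (%.2f s), lambda=%s\n",
              x$m, x$atom_len, x$atom_len / x$rate_hz,
              format(x$lambda_used)))
  invisible(x)
}

as_signal_vector <- function(s) {
  if (inherits(s, "mono_signal")) s$s else as.numeric(s)
}

# FFT of atoms zero-padded to length n: n x m complex matrix.
atom_fft <- function(atoms, n) {
  L <- nrow(atoms)
  padded <- rbind(atoms, matrix(0, n - L, ncol(atoms)))
  stats::mvfft(padded)
}

# Circular reconstruction sum_m x_m (*) d_m for one signal.
circ_reconstruct <- function(codes, atoms) {
  n <- nrow(codes)
  Dh <- atom_fft(atoms, n)
  Xh <- stats::mvfft(codes)
  Re(stats::fft(rowSums(Xh * Dh), inverse = TRUE)) / n
}

#' Convolutional basis pursuit denoising objective
#'
#' `sum_signals [ 1/2 ||sum_m x_m * d_m - s||_2^2 + lambda sum_m ||x_m||_1 ]`,
#' with circular convolution at each signal's length (the solver's
#' convention).
#'
#' @param signals list of [mono_signal()]s or numeric vectors.
#' @param dict a [step_dictionary()].
#' @param codes list (one per signal) of T x m activation matrices.
#' @param lam sparsity weight lambda >= 0.
#' @return The objective value (scalar).
#' @export
cdl_objective <- function(signals, dict, codes, lam) {
  if (!is.list(signals)) signals <- list(signals)
  if (is.matrix(codes)) codes <- list(codes)
  if (length(signals) != length(codes))
    stop("`signals` and `codes` must have equal length", call. = FALSE)
  total <- 0
  for (i in seq_along(signals)) {
    s <- as_signal_vector(signals[[i]])
    x <- as.matrix(codes[[i]])
    if (nrow(x) != length(s) || ncol(x) != dict$m)
      stop("code/signal shape mismatch", call. = FALSE)
    r <- circ_reconstruct(x, dict$atoms) - s
    total <- total + 0.5 * sum(r^2) + lam * sum(abs(x))
  }
  total
}

# One ADMM state per signal for the sparse-coding subproblem.
new_code_state <- function(n, m) list(y = matrix(0, n, m), u = matrix(0, n, m))

# One ADMM x/y/u sweep of convolutional basis pursuit denoising for a single
# signal, given the current dictionary (frequency domain, rank-one solve).
cbpdn_step <- function(state, Sh, Dh, dd, lam, rho) {
  n <- nrow(state$y)
  bf <- Conj(Dh) * Sh + rho * stats::mvfft(state$y - state$u)
  xf <- (bf - Conj(Dh) * (rowSums(Dh * bf) / (rho + dd))) / rho
  x <- Re(stats::mvfft(xf, inverse = TRUE)) / n
  y <- soft_threshold(x + state$u, lam / rho)
  u <- state$u + x - y
  list(y = y, u = u, x = x)
}

#' Sparse-code a signal against a fixed dictionary
#'
#' Solves the convolutional basis pursuit denoising problem in the codes
#' only (dictionary held fixed) by ADMM.
#'
#' @param s a [mono_signal()] or numeric vector.
#' @param dict a [step_dictionary()].
#' @param lam sparsity weight.
#' @param iters ADMM iterations (default 100).
#' @param rho ADMM penalty parameter (default `10 * lam + 1`).
#' @return T x m matrix of activations.
#' @export
sparse_code <- function(s, dict, lam, iters = 100L, rho = NULL) {
  s <- as_signal_vector(s)
  n <- length(s)
  if (n < dict$atom_len) stop("signal shorter than atom", call. = FALSE)
  rho <- rho %||% (10 * lam + 1)
  Dh <- atom_fft(dict$atoms, n)
  dd <- rowSums(Mod(Dh)^2)
  Sh <- stats::fft(s)
  st <- new_code_state(n, dict$m)
  for (it in seq_len(iters)) st <- cbpdn_step(st, Sh, Dh, dd, lam, rho)
  st$y
}

# Projection onto the dictionary constraint set: support limited to the
# first L samples, per-atom Euclidean norm at most 1.
proj_dict <- function(d_full, L) {
  g <- d_full[seq_len(L), , drop = FALSE]
  nrm <- sqrt(colSums(g^2))
  scale <- ifelse(nrm > 1, 1 / nrm, 1)
  sweep(g, 2, scale, `*`)
}

#' Learn a step dictionary by convolutional dictionary learning
#'
#' Alternates ADMM steps of sparse coding and of the consensus-form
#' dictionary update until `iters` alternations have run, then normalises
#' the atoms to exactly unit norm and re-codes the signals against the final
#' dictionary. Deterministic given `seed` (random atom initialisation).
#'
#' @param signals list of [mono_signal()]s (or numeric vectors); typically
#'   the preprocessed walks of a single person, selected so the training
#'   material is almost entirely walk related.
#' @param m number of atoms (default 3).
#' @param atom_sec atom duration in seconds (default 0.7, an upper bound on
#'   the step duration of a healthy adult).
#' @param lam sparsity weight lambda (default 5).
#' @param iters alternation count (default 2000).
#' @param seed integer seed for the atom initialisation.
#' @param rate_hz sampling frequency (default 100).
#' @param rho,sigma ADMM penalty parameters for the coding and dictionary
#'   subproblems (defaults `10 * lam + 1` and the number of signals).
#' @return A list with `dictionary` (a [step_dictionary()]) and `codes`
#'   (list of T x m activation matrices, one per signal).
#' @export
learn_dictionary <- function(signals, m = 3L, atom_sec = 0.7, lam = 5,
                             iters = 2000L, seed = 1L, rate_hz = 100,
                             rho = NULL, sigma = NULL) {
  if (!is.list(signals)) signals <- list(signals)
  xs <- lapply(signals, as_signal_vector)
  ns <- lengths(xs)
  L <- as.integer(round(atom_sec * rate_hz))
  if (m < 1L || lam < 0 || iters < 1L) stop("invalid CDL parameters",
                                            call. = FALSE)
  if (L > min(ns)) stop("atom longer than shortest signal", call. = FALSE)
  S <- length(xs)
  rho <- rho %||% (10 * lam + 1)
  sigma <- sigma %||% S

  G <- with_seed(seed, {
    g0 <- matrix(stats::rnorm(L * m), L, m)
    sweep(g0, 2, sqrt(colSums(g0^2)), `/`)
  })

  Sh <- lapply(xs, stats::fft)
  code_st <- lapply(ns, new_code_state, m = m)
  h <- lapply(ns, function(n) matrix(0, n, m))   # consensus duals
  d_loc <- lapply(ns, function(n) matrix(0, n, m))

  pad_global <- function(G, n) rbind(G, matrix(0, n - L, m))

  for (it in seq_len(iters)) {
    Dh <- NULL
    for (i in seq_len(S)) {
      n <- ns[i]
      Dh_i <- atom_fft(G, n)
      dd_i <- rowSums(Mod(Dh_i)^2)
      code_st[[i]] <- cbpdn_step(code_st[[i]], Sh[[i]], Dh_i, dd_i, lam, rho)
    }
    # dictionary update: per-signal local solve, then consensus projection
    acc <- matrix(0, L, m)
    Xh <- vector("list", S)
    for (i in seq_len(S)) {
      n <- ns[i]
      Xh[[i]] <- stats::mvfft(code_st[[i]]$y)
      xx <- rowSums(Mod(Xh[[i]])^2)
      Gp <- pad_global(G, n)
      bf <- Conj(Xh[[i]]) * Sh[[i]] + sigma * stats::mvfft(Gp - h[[i]])
      df <- (bf - Conj(Xh[[i]]) * (rowSums(Xh[[i]] * bf) / (sigma + xx))) /
        sigma
      d_loc[[i]] <- Re(stats::mvfft(df, inverse = TRUE)) / n
      acc <- acc + (d_loc[[i]] + h[[i]])[seq_len(L), , drop = FALSE]
    }
    G <- proj_dict(acc / S, L)
    for (i in seq_len(S)) {
      n <- ns[i]
      h[[i]] <- h[[i]] + d_loc[[i]] - pad_global(G, n)
    }
  }

  nrm <- sqrt(colSums(G^2))
  nrm[nrm < 1e-12] <- 1
  G <- sweep(G, 2, nrm, `/`)
  dict <- step_dictionary(G, rate_hz = rate_hz, lambda_used = lam,
                          iters_used = iters, seed_used = seed)
  codes <- lapply(xs, sparse_code, dict = dict, lam = lam,
                  iters = min(iters, 100L), rho = rho)
  list(dictionary = dict, codes = codes)
}

#' Choose the number of atoms by cross-validation
#'
#' For each candidate m, dictionaries are learned on the training folds and
#' the held-out signals are sparse-coded against them; the score is the mean
#' relative reconstruction error plus the number of active coefficients per
#' signal sample (a non-sparsity penalty), so the selected m trades
#' reconstruction quality against sparsity. Ties go to the smallest m.
#'
#' @param signals list of signals.
#' @param candidate_ms candidate atom counts.
#' @param folds number of CV folds (>= 2).
#' @param lam,iters,atom_sec,rate_hz passed to [learn_dictionary()].
#' @param seed integer seed (fold assignment and initialisations).
#' @param sparsity_weight weight of the non-sparsity penalty (default 1).
#' @return The selected number of atoms (integer).
#' @export
select_num_atoms <- function(signals, candidate_ms = 1:4, folds = 3L,
                             lam = 5, iters = 100L, atom_sec = 0.7,
                             rate_hz = 100, seed = 1L, sparsity_weight = 1) {
  if (!length(candidate_ms)) stop("no candidate atom counts", call. = FALSE)
  S <- length(signals)
  if (S < folds) stop("fewer signals than folds", call. = FALSE)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), S)))
  fold_scores <- sapply(candidate_ms, function(m) {
    vapply(seq_len(folds), function(f) {
      tr <- signals[fold_id != f]
      va <- signals[fold_id == f]
      fit <- learn_dictionary(tr, m = m, atom_sec = atom_sec, lam = lam,
                              iters = iters, seed = derive_seed(seed, m),
                              rate_hz = rate_hz)
      errs <- vapply(va, function(s) {
        sv <- as_signal_vector(s)
        x <- sparse_code(sv, fit$dictionary, lam, iters = 100L)
        rec <- circ_reconstruct(x, fit$dictionary$atoms)
        rel <- sum((rec - sv)^2) / max(sum(sv^2), .Machine$double.eps)
        # active coefficients per signal sample: the total description
        # length, so duplicated atoms (which split/spread activations)
        # are penalised rather than rewarded
        act <- sum(abs(x) > 1e-6) / length(sv)
        rel + sparsity_weight * act
      }, 0)
      mean(errs)
    }, 0)
  })
  fold_scores <- matrix(fold_scores, nrow = folds)
  means <- colMeans(fold_scores)
  ses <- apply(fold_scores, 2, stats::sd) / sqrt(folds)
  # one-standard-error parsimony rule: the smallest m whose mean CV score
  # is within one SE of the best (ties therefore resolve to the smallest m)
  best <- which.min(means)
  ok <- which(means <= means[best] + ses[best])
  as.integer(candidate_ms[min(ok)])
}

#' Embedded signal
#'
#' The m-channel image of a mono signal under convolution with the
#' dictionary atoms; the network input.
#'
#' @param channels m x T numeric matrix.
#' @param rate_hz sampling frequency.
#' @param source_id identifier of the source signal.
#' @return An object of class `embedded_signal`.
#' @export
embedded_signal <- function(channels, rate_hz = 100, source_id = "sig") {
  structure(list(channels = as.matrix(channels), rate_hz = rate_hz,
                 source_id = source_id), class = "embedded_signal")
}

#' @export
print.embedded_signal <- function(x, ...) {
  cat(sprintf("<embedded_signal '%s'> %d channels x %d samples\n",
              x$source_id, nrow(x$channels), ncol(x$channels)))
  invisible(x)
}

# Linear "same" convolution (zero padding) of x with kernel k, centred on
# element floor(L/2)+1 of the kernel.
conv_same <- function(x, k) {
  Tn <- length(x); L <- length(k)
  n <- Tn + L - 1L
  X <- stats::fft(c(x, rep(0, n - Tn)))
  K <- stats::fft(c(k, rep(0, n - L)))
  full <- Re(stats::fft(X * K, inverse = TRUE)) / n
  c0 <- L %/% 2L + 1L
  full[c0:(c0 + Tn - 1L)]
}

#' Embed a signal with the dictionary atoms
#'
#' Each embedded channel is the linear "same"-length convolution of the mono
#' signal with one atom, so the m channels stay aligned with the raw time
#' axis. Sparsity plays no role here: this is plain convolution.
#'
#' @param s a [mono_signal()] or numeric vector.
#' @param dict a [step_dictionary()].
#' @return An [embedded_signal()] with m rows and T columns.
#' @export
embed_signal <- function(s, dict) {
  id <- if (inherits(s, "mono_signal")) s$id else "sig"
  sv <- as_signal_vector(s)
  if (length(sv) < dict$atom_len)
    stop("signal shorter than atom", call. = FALSE)
  ch <- t(vapply(seq_len(dict$m),
                 function(j) conv_same(sv, dict$atoms[, j]),
                 numeric(length(sv))))
  embedded_signal(ch, rate_hz = dict$rate_hz, source_id = id)
}
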