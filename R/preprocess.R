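#' Zero-lag low-pass Butterworth filter
#'
#' Zero-phase low-pass filtering with the squared Butterworth magnitude
#' response `|H(f)|^2 = 1 / (1 + (f / cutoff)^(2 * order))` -- the
#' equivalent of one forward and one backward pass of the order-`order`
#' Butterworth filter, with exactly zero phase shift at every frequency.
#' It is applied in the frequency domain (so the analog magnitude response
#' holds exactly, without bilinear frequency warping), after odd-reflection
#' edge padding of `3 * (order + 1)` samples to limit edge transients.
#'
#' @param x numeric vector (one channel).
#' @param rate_hz sampling frequency.
#' @param cutoff_hz cutoff frequency; must be below the Nyquist frequency.
#' @param order filter order (default 5).
#' @return Filtered vector of the same length.
#' @export
lowpass_zero_lag <- function(x, rate_hz = 100, cutoff_hz = 10, order = 5L) {
  if (cutoff_hz >= rate_hz / 2)
    stop("`cutoff_hz` must be below the Nyquist frequency", call. = FALSE)
  pad <- 3L * (order + 1L)
  n <- length(x)
  if (n <= pad)
    stop(sprintf("signal too short for order-%d zero-lag filtering (need > %d samples)",
                 order, pad), call. = FALSE)
  # An affine signal is in the filter's passband (all its energy at DC):
  # remove the endpoint-matching line, filter the residual, and add the
  # line back. This keeps affine inputs exactly invariant and removes the
  # spectral leakage their wrap discontinuity would otherwise cause.
  line <- seq(x[1], x[n], length.out = n)
  r <- x - line
  # odd reflection: 2*x[edge] - x[mirror], as in standard filtfilt padding
  front <- 2 * r[1] - r[(pad + 1L):2L]
  back <- 2 * r[n] - r[(n - 1L):(n - pad)]
  rp <- c(front, r, back)
  np <- length(rp)
  f <- pmin(seq_len(np) - 1L, np - (seq_len(np) - 1L)) * rate_hz / np
  H2 <- 1 / (1 + (f / cutoff_hz)^(2 * order))
  y <- Re(stats::fft(stats::fft(rp) * H2, inverse = TRUE)) / np
  y[(pad + 1L):(pad + n)] + line
}

#' Least-squares linear detrend
#'
#' Removes the least-squares affine fit `a*t + b` from a channel; the result
#' is orthogonal to both the constant and the linear ramp.
#'
#' @param x numeric vector of length >= 2.
#' @return Detrended vector.
#' @export
detrend_ls <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples to detrend", call. = FALSE)
  t <- seq_len(n)
  fit <- stats::.lm.fit(cbind(1, t), x)
  as.numeric(fit$residuals)
}

#' Zero out quiet channels
#'
#' A channel is replaced by zeros iff its maximum absolute amplitude is below
#' `rel_threshold` times the loudest channel's maximum absolute amplitude;
#' such channels are assumed to carry only noise. An all-zero input is
#' returned unchanged.
#'
#' @param channels K x T numeric matrix.
#' @param rel_threshold relative threshold in (0, 1), default 0.05.
#' @return K x T matrix with quiet channels zeroed.
#' @export
zero_quiet_channels <- function(channels, rel_threshold = 0.05) {
  if (rel_threshold <= 0 || rel_threshold >= 1)
    stop("`rel_threshold` must be in (0, 1)", call. = FALSE)
  channels <- as.matrix(channels)
  mx <- apply(abs(channels), 1, max)
  top <- max(mx)
  if (top == 0) return(channels)
  channels[mx < rel_threshold * top, ] <- 0
  channels
}

#' Mono signal
#'
#' The single-channel signal obtained by preprocessing a recording
#' (filtering, detrending, quiet-channel zeroing, channel summation).
#'
#' @param s numeric vector.
#' @param rate_hz sampling frequency.
#' @param id source recording identifier.
#' @return An object of class `mono_signal`.
#' @export
mono_signal <- function(s, rate_hz = 100, id = "sig") {
  structure(list(s = as.numeric(s), rate_hz = rate_hz, id = id),
            class = "mono_signal")
}

#' @export
print.mono_signal <- function(x, ...) {
  cat(sprintf("<mono_signal '%s'> %d samples @ %g Hz\n", x$id, length(x$s),
              x$rate_hz))
  invisible(x)
}

#' Preprocess a recording into a mono signal
#'
#' The four preprocessing steps, in order: (1) zero-lag low-pass Butterworth
#' filtering of each channel (10 Hz cutoff, fifth order by default -- the
#' reference band for gait signals); (2) least-squares linear detrend of each
#' channel; (3) zeroing of quiet channels (relative amplitude below
#' `rel_threshold`); (4) summation of all channels into one mono signal.
#'
#' @param rec a [recording()].
#' @param cutoff_hz,order Butterworth parameters (defaults 10 Hz, order 5).
#' @param rel_threshold quiet-channel threshold, relative to the loudest
#'   channel (default 0.05); set to 0-excluded values in (0,1).
#' @param quiet_rule apply step (3)? Mainly for linearity checks.
#' @return A [mono_signal()] of the same length as the recording.
#' @export
preprocess_recording <- function(rec, cutoff_hz = 10, order = 5L,
                                 rel_threshold = 0.05, quiet_rule = TRUE) {
  stopifnot(inherits(rec, "recording"))
  ch <- rec$channels
  for (k in seq_len(nrow(ch))) {
    ch[k, ] <- lowpass_zero_lag(ch[k, ], rec$rate_hz, cutoff_hz, order)
    ch[k, ] <- detrend_ls(ch[k, ])
  }
  if (quiet_rule) ch <- zero_quiet_channels(ch, rel_threshold)
  mono_signal(colSums(ch), rate_hz = rec$rate_hz, id = rec$id)
}
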