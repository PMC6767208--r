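# Synthetic floor-sensor data generator. Emulates the statistical structure
# of nursing-home piezoelectric recordings: 5-channel, 100 Hz, ~10 s events;
# staff walks with high amplitude and regular cadence (~20 dB SNR), elderly
# walks with lower amplitude and irregular cadence; multi-walker
# superpositions; and non-gait events (wheelchair, pushed wheelchair, cart,
# other transients). Ground-truth step boxes are produced at the 10 ms (one
# sample) resolution. The step pulse is a stand-in waveform (asymmetric
# heel-strike/toe-off double bump with damped ringing) aiming at statistical,
# not biomechanical, fidelity.

#' Walker profile
#'
#' Generative parameters of one walker class. Defaults: staff walk with
#' amplitude 1.0 (CV 0.1), cadence 0.55 s (jitter CV 0.05); elderly walk
#' with amplitude 0.4 (CV 0.3), cadence 0.8 s (jitter CV 0.2) -- smaller and
#' less regular, reproducing the qualitative staff/elderly contrast. Step
#' durations stay within 0.2-0.4 s (typical step support; the atoms' 0.7 s
#' is an upper bound).
#'
#' @param status `"staff"` or `"elderly"`.
#' @param step_amplitude mean peak amplitude (amplifier units).
#' @param amplitude_cv coefficient of variation of the amplitude.
#' @param cadence_sec mean time between consecutive steps (s).
#' @param cadence_cv coefficient of variation of the cadence.
#' @param step_duration_sec mean step duration (s), within (0.2, 0.4).
#' @param duration_cv coefficient of variation of the duration.
#' @param rise_frac position of the heel-strike peak within the step (0-1).
#' @param ringing damped-ringing coefficient added to the double bump.
#' @return An object of class `person_profile`.
#' @export
person_profile <- function(status = c("staff", "elderly"),
                           step_amplitude = NULL, amplitude_cv = NULL,
                           cadence_sec = NULL, cadence_cv = NULL,
                           step_duration_sec = NULL, duration_cv = NULL,
                           rise_frac = 0.3, ringing = 0.15) {
  status <- match.arg(status)
  dft <- if (status == "staff")
    list(amp = 1.0, acv = 0.1, cad = 0.55, ccv = 0.05, dur = 0.30,
         dcv = 0.08)
  else
    list(amp = 0.4, acv = 0.3, cad = 0.80, ccv = 0.20, dur = 0.32,
         dcv = 0.12)
  p <- list(status = status,
            step_amplitude = step_amplitude %||% dft$amp,
            amplitude_cv = amplitude_cv %||% dft$acv,
            cadence_sec = cadence_sec %||% dft$cad,
            cadence_cv = cadence_cv %||% dft$ccv,
            step_duration_sec = step_duration_sec %||% dft$dur,
            duration_cv = duration_cv %||% dft$dcv,
            rise_frac = rise_frac, ringing = ringing)
  stopifnot(p$step_amplitude > 0, p$cadence_sec > 0,
            p$step_duration_sec > 0, p$step_duration_sec <= 0.7)
  structure(p, class = "person_profile")
}

#' Synthesise one footstep pulse
#'
#' Draws a step duration and amplitude from the profile and returns the
#' pressure pulse (heel-strike bump, toe-off bump, damped ringing) together
#' with its ground-truth box: the samples where the pulse exceeds 5% of its
#' peak. Under the default profiles the box width lies in [20, 40] samples.
#' Uses the current RNG stream.
#'
#' @param profile a [person_profile()].
#' @param t0 0-based sample index at which the pulse starts.
#' @param rate_hz sampling frequency (default 100).
#' @return A list with `pulse` (numeric vector) and `box` (a one-row
#'   [step_boxes()], in absolute coordinates from `t0`).
#' @export
synth_step <- function(profile, t0 = 0L, rate_hz = 100) {
  dur <- stats::rnorm(1, profile$step_duration_sec,
                      profile$step_duration_sec * profile$duration_cv)
  dur <- clamp(dur, 0.23, 0.39)
  amp <- stats::rnorm(1, profile$step_amplitude,
                      profile$step_amplitude * profile$amplitude_cv)
  amp <- max(amp, 0.05 * profile$step_amplitude)
  n <- max(4L, as.integer(round(dur * rate_hz)))
  u <- seq(0, 1, length.out = n)
  heel <- exp(-((u - profile$rise_frac) / 0.10)^2)
  toe <- 0.8 * exp(-((u - 0.72) / 0.09)^2)
  ring <- profile$ringing * sin(2 * pi * 5 * u) * exp(-3 * u)
  p <- heel + toe + ring
  p <- p / max(abs(p)) * amp
  above <- which(abs(p) > 0.05 * max(abs(p)))
  box <- step_boxes(t0 + above[1] - 1L, t0 + above[length(above)])
  list(pulse = p, box = box)
}

#' Synthesise a walk event
#'
#' Places steps at cadence intervals with jitter; each step's energy is
#' spread over the channels by a smooth spatial mixing emulating a walker
#' moving along the sensor bands (Gaussian channel weights following a
#' linear trajectory, normalised to sum 1 so the channel sum preserves the
#' pulse). Boxes are disjoint and sorted. Uses the current RNG stream.
#'
#' @param profile a [person_profile()].
#' @param duration_sec event duration in seconds (must cover >= 2 steps).
#' @param n_channels number of channels K (default 5).
#' @param rate_hz sampling frequency (default 100).
#' @return A list with `channels` (K x T matrix) and `boxes`
#'   (a [step_boxes()]).
#' @export
synth_walk <- function(profile, duration_sec = 10, n_channels = 5L,
                       rate_hz = 100) {
  Tn <- as.integer(round(duration_sec * rate_hz))
  if (duration_sec < 2 * profile$cadence_sec)
    stop("duration must cover at least 2 steps", call. = FALSE)
  ch <- matrix(0, n_channels, Tn)
  path0 <- stats::runif(1, 1, n_channels)
  path1 <- stats::runif(1, 1, n_channels)
  t_sec <- stats::runif(1, 0.2, 0.4)
  starts <- integer(0); ends <- integer(0)
  prev_end <- -1L
  while (TRUE) {
    t0 <- max(as.integer(round(t_sec * rate_hz)), prev_end + 2L)
    st <- synth_step(profile, t0, rate_hz)
    n <- length(st$pulse)
    if (t0 + n > Tn) break
    pos <- path0 + (path1 - path0) * (t0 / Tn)
    w <- exp(-((seq_len(n_channels) - pos)^2) / (2 * 0.8^2))
    w <- w / sum(w)
    idx <- (t0 + 1L):(t0 + n)
    ch[, idx] <- ch[, idx] + outer(w, st$pulse)
    starts <- c(starts, st$box[1, 1]); ends <- c(ends, st$box[1, 2])
    prev_end <- st$box[1, 2]
    gap <- profile$cadence_sec *
      (1 + profile$cadence_cv * stats::rnorm(1))
    t_sec <- t_sec + max(gap, (n + 2L) / rate_hz)
  }
  list(channels = ch, boxes = step_boxes(starts, ends))
}

# Merge overlapping/adjacent boxes into a disjoint sorted set.
merge_boxes <- function(bx) {
  if (nrow(bx) <= 1L) return(bx)
  o <- order(bx[, 1])
  s <- bx[o, 1]; e <- bx[o, 2]
  ms <- s[1]; me <- e[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me) me <- max(me, e[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- s[i]; me <- e[i] }
  }
  step_boxes(c(out_s, ms), c(out_e, me))
}

smooth_noise <- function(Tn, cutoff_hz = 2, rate_hz = 100) {
  x <- stats::rnorm(Tn)
  lowpass_zero_lag(x, rate_hz, cutoff_hz, 2L)
}

#' Synthesise one event of a given class
#'
#' Class-characteristic clean signals: `walk_single` and `walk_multi` are
#' walks (two independent same-status walkers for multi); `wheelchair` is a
#' continuous low-frequency rolling load traversing the bands;
#' `wheelchair_pushed` adds the pusher's steps; `cart_walk` is a walk with
#' a periodic wheel-bump component; `other` is a handful of random
#' transients. Walk-bearing classes carry step boxes for the walker(s)
#' only. Uses the current RNG stream.
#'
#' @param event_class one of the six event classes.
#' @param status person status driving the gait profile.
#' @param duration_sec event duration (default 10).
#' @param n_channels,rate_hz geometry (defaults 5 channels, 100 Hz).
#' @return A list with `channels` and `boxes`.
#' @export
synth_event <- function(event_class, status = "staff", duration_sec = 10,
                        n_channels = 5L, rate_hz = 100) {
  event_class <- match.arg(event_class, EVENT_CLASSES)
  Tn <- as.integer(round(duration_sec * rate_hz))
  prof <- person_profile(status)
  rolling <- function(amp) {
    f <- stats::runif(1, 0.8, 1.5)
    env <- sin(pi * seq(0, 1, length.out = Tn))^2
    base <- amp * env *
      (0.5 * sin(2 * pi * f * seq_len(Tn) / rate_hz +
                   stats::runif(1, 0, 2 * pi)) +
         smooth_noise(Tn, 2, rate_hz))
    pos <- seq(stats::runif(1, 1, n_channels), stats::runif(1, 1, n_channels),
               length.out = Tn)
    W <- vapply(seq_len(n_channels), function(k)
      exp(-(k - pos)^2 / (2 * 0.8^2)), numeric(Tn))   # Tn x K
    W <- W / rowSums(W)
    t(W * base)
  }
  if (event_class == "walk_single") {
    w <- synth_walk(prof, duration_sec, n_channels, rate_hz)
    list(channels = w$channels, boxes = w$boxes)
  } else if (event_class == "walk_multi") {
    w1 <- synth_walk(prof, duration_sec, n_channels, rate_hz)
    w2 <- synth_walk(prof, duration_sec, n_channels, rate_hz)
    list(channels = w1$channels + w2$channels,
         boxes = merge_boxes(step_boxes(c(w1$boxes[, 1], w2$boxes[, 1]),
                                        c(w1$boxes[, 2], w2$boxes[, 2]))))
  } else if (event_class == "wheelchair") {
    list(channels = rolling(0.5), boxes = empty_boxes())
  } else if (event_class == "wheelchair_pushed") {
    pusher <- synth_walk(person_profile("staff"), duration_sec, n_channels,
                         rate_hz)
    list(channels = rolling(0.5) + 0.8 * pusher$channels,
         boxes = pusher$boxes)
  } else if (event_class == "cart_walk") {
    w <- synth_walk(prof, duration_sec, n_channels, rate_hz)
    period <- as.integer(round(stats::runif(1, 0.35, 0.5) * rate_hz))
    bumps <- rep(0, Tn)
    at <- seq(as.integer(stats::runif(1, 10, 40)), Tn - 5L, by = period)
    for (t0 in at) bumps[t0:(t0 + 4L)] <- bumps[t0:(t0 + 4L)] +
      0.3 * c(0.4, 1, 0.8, 0.4, 0.15)
    k <- sample(n_channels, 1)
    w$channels[k, ] <- w$channels[k, ] + bumps
    list(channels = w$channels, boxes = w$boxes)
  } else {                       # other: random transients
    ch <- matrix(0, n_channels, Tn)
    for (j in seq_len(sample(1:4, 1))) {
      width <- sample(10:80, 1)
      amp <- stats::runif(1, 0.2, 1.5)
      t0 <- sample(Tn - width, 1)
      pulse <- amp * sin(pi * seq(0, 1, length.out = width))^2
      k <- sample(n_channels, 1)
      ch[k, t0:(t0 + width - 1L)] <- ch[k, t0:(t0 + width - 1L)] + pulse
    }
    list(channels = ch, boxes = empty_boxes())
  }
}

#' Add measurement noise and per-channel linear trends
#'
#' White Gaussian noise is scaled so the whole-record signal-to-noise ratio
#' `10*log10(P_signal / P_noise)` matches `snr_db` (within sampling
#' fluctuation, well inside +/- 0.5 dB at these record lengths), unless an
#' explicit noise standard deviation `sigma` is given. Each channel also
#' receives a random affine trend with endpoint magnitudes at most
#' `trend_amp` (removed later by the preprocessing detrend). Uses the
#' current RNG stream.
#'
#' @param clean K x T clean signal matrix (not identically zero when
#'   `snr_db` is finite and `sigma` is NULL).
#' @param snr_db target SNR in dB; `Inf` adds no noise.
#' @param trend_amp maximal endpoint amplitude of the affine trend.
#' @param sigma optional explicit noise standard deviation overriding the
#'   SNR calibration.
#' @param components return the clean/noise/trend decomposition?
#' @return The noisy K x T matrix, or (with `components = TRUE`) a list
#'   with `channels`, `clean`, `noise`, `trend`, `sigma`.
#' @export
add_noise_and_trend <- function(clean, snr_db = 20, trend_amp = 0.2,
                                sigma = NULL, components = FALSE) {
  clean <- as.matrix(clean)
  K <- nrow(clean); Tn <- ncol(clean)
  if (is.null(sigma)) {
    if (is.infinite(snr_db)) {
      sigma <- 0
    } else {
      P <- mean(clean^2)
      if (P == 0) stop("zero clean signal with finite snr_db", call. = FALSE)
      sigma <- sqrt(P / 10^(snr_db / 10))
    }
  }
  noise <- if (sigma > 0) matrix(stats::rnorm(K * Tn, sd = sigma), K, Tn)
           else matrix(0, K, Tn)
  trend <- t(vapply(seq_len(K), function(k) {
    a <- stats::runif(1, -trend_amp, trend_amp)
    b <- stats::runif(1, -trend_amp, trend_amp)
    seq(a, b, length.out = Tn)
  }, numeric(Tn)))
  if (trend_amp == 0) trend <- matrix(0, K, Tn)
  out <- clean + noise + trend
  if (components)
    list(channels = out, clean = clean, noise = noise, trend = trend,
         sigma = sigma)
  else out
}

#' Default dataset composition
#'
#' 93 events: 42 staff + 16 elderly single walks, 8 staff + 3 elderly
#' multi-walks, and 24 non-walk events (9 wheelchair + 5 pushed wheelchair
#' elderly, 5 staff cart walks, 2 staff + 3 elderly other transients),
#' giving 7 staff / 17 elderly in the pooled "other" stratum.
#'
#' @return Data frame with columns `event_class`, `person_status`, `count`.
#' @export
default_composition <- function() {
  data.frame(
    event_class = c("walk_single", "walk_single", "walk_multi", "walk_multi",
                    "wheelchair", "wheelchair_pushed", "cart_walk",
                    "other", "other"),
    person_status = c("staff", "elderly", "staff", "elderly",
                      "elderly", "elderly", "staff", "staff", "elderly"),
    count = c(42L, 16L, 8L, 3L, 9L, 5L, 5L, 2L, 3L),
    stringsAsFactors = FALSE)
}

#' Synthetic dataset configuration
#'
#' @param n_channels number of sensor channels (default 5).
#' @param rate_hz sampling frequency (default 100).
#' @param duration_sec nominal event duration; actual durations are drawn
#'   uniformly within +/- 10% (default 10 s).
#' @param composition manifest data frame (`event_class`, `person_status`,
#'   `count`); default [default_composition()].
#' @param snr_db SNR calibrated on staff walks (default 20 dB); all other
#'   events reuse the same noise power, so lower-amplitude events (e.g.
#'   elderly walks) have proportionally lower SNR.
#' @param trend_amp per-channel affine trend amplitude (default 0.2).
#' @param profiles named list with `staff` and `elderly`
#'   [person_profile()]s (defaults used when omitted).
#' @param seed integer seed; the dataset is a pure function of the config.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_channels = 5L, rate_hz = 100,
                             duration_sec = 10, composition = NULL,
                             snr_db = 20, trend_amp = 0.2, profiles = NULL,
                             seed = 1L) {
  comp <- composition %||% default_composition()
  stopifnot(all(c("event_class", "person_status", "count") %in% names(comp)),
            all(comp$count >= 0), is.finite(snr_db) || is.infinite(snr_db))
  profs <- profiles %||% list(staff = person_profile("staff"),
                              elderly = person_profile("elderly"))
  structure(list(n_channels = as.integer(n_channels), rate_hz = rate_hz,
                 duration_sec = duration_sec, composition = comp,
                 snr_db = snr_db, trend_amp = trend_amp, profiles = profs,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Clean event + annotation for one manifest entry. Uses current RNG.
synth_clean_recording <- function(event_class, status, cfg) {
  dur <- cfg$duration_sec * stats::runif(1, 0.9, 1.1)
  ev <- synth_event(event_class, status, dur, cfg$n_channels, cfg$rate_hz)
  n_persons <- switch(event_class, walk_multi = 2L, wheelchair_pushed = 2L, 1L)
  list(channels = ev$channels, boxes = ev$boxes, n_persons = n_persons)
}

#' Generate a synthetic floor-sensor dataset
#'
#' One recording per manifest entry, fully reproducible from `cfg$seed`.
#' Noise is calibrated per staff-walk recording to `cfg$snr_db`; all other
#' recordings reuse the mean staff-walk noise power (fixed sensor noise), so
#' their SNR emerges from their amplitudes.
#'
#' @param cfg a [synthetic_config()].
#' @return A [floor_dataset()] whose manifest equals `cfg$composition`.
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  comp <- cfg$composition[cfg$composition$count > 0, ]
  recs <- list()
  with_seed(cfg$seed, {
    entries <- comp[rep(seq_len(nrow(comp)), comp$count), 1:2]
    cleans <- vector("list", nrow(entries))
    for (i in seq_len(nrow(entries)))
      cleans[[i]] <- synth_clean_recording(entries$event_class[i],
                                           entries$person_status[i], cfg)
    staff_walk <- entries$event_class %in% c("walk_single", "walk_multi") &
      entries$person_status == "staff"
    sigmas <- vapply(seq_len(nrow(entries)), function(i) {
      if (!staff_walk[i]) return(NA_real_)
      sqrt(mean(cleans[[i]]$channels^2) / 10^(cfg$snr_db / 10))
    }, 0)
    sigma_ref <- if (any(staff_walk)) mean(sigmas, na.rm = TRUE) else {
      sqrt(mean(vapply(cleans, function(cl) mean(cl$channels^2), 0)) /
             10^(cfg$snr_db / 10))
    }
    for (i in seq_len(nrow(entries))) {
      cl <- cleans[[i]]
      sg <- if (staff_walk[i]) sigmas[i] else sigma_ref
      noisy <- add_noise_and_trend(cl$channels, snr_db = cfg$snr_db,
                                   trend_amp = cfg$trend_amp, sigma = sg)
      ann <- event_annotation(entries$event_class[i],
                              entries$person_status[i],
                              n_persons = cl$n_persons,
                              step_boxes = cl$boxes)
      recs[[i]] <- recording(noisy, rate_hz = cfg$rate_hz,
                             id = sprintf("synt-%03d", i), annotation = ann)
    }
  })
  floor_dataset(recs)
}

#' Measure the realised SNR of synthetic staff walks
#'
#' Generates `n` seeded staff single-walk recordings at the configured noise
#' setting and returns, for each, the realised
#' `10*log10(P_signal / P_noise)` computed from the known clean and noise
#' components.
#'
#' @param cfg a [synthetic_config()].
#' @param n number of recordings (default 50).
#' @return Numeric vector of `n` SNR values in dB.
#' @export
measure_staff_walk_snr <- function(cfg = synthetic_config(), n = 50L) {
  with_seed(derive_seed(cfg$seed, 97L), {
    vapply(seq_len(n), function(i) {
      cl <- synth_clean_recording("walk_single", "staff", cfg)
      parts <- add_noise_and_trend(cl$channels, snr_db = cfg$snr_db,
                                   trend_amp = cfg$trend_amp,
                                   components = TRUE)
      10 * log10(mean(parts$clean^2) / mean(parts$noise^2))
    }, 0)
  })
}
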