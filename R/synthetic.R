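# Synthetic two-device routine-EEG session generator.
#
# One latent multichannel source process is synthesized at a high internal
# rate (1000 Hz, at least twice the fastest device), then anti-alias
# filtered and decimated to each device's rate and contaminated with
# device-specific noise — so both devices record "the same brain", as a
# paired validation protocol requires. Every component is additive and the
# generator can retain the full component ledger for oracle tests.
#
# Amplitude defaults are calibration constants chosen to be physiologically
# plausible (10 uV rms pink background, occipital alpha tripling on eye
# closure, moderate photic driving), not values taken from any particular
# recording.

#' Parameterize a synthetic two-device session
#'
#' Defaults encode the routine-EEG protocol: 60 s baseline, a 4-minute eye
#' open/close test of alternating 10 s states, 180 s hyperventilation, and
#' the 12-step photic schedule (1-30 Hz, 10 s each); a 16-channel wearable
#' device sampling at 125 Hz with higher out-of-band noise (powerline,
#' baseline drift) and a 21-channel clinical device at 500 Hz with lower
#' noise. The seed fully determines the output.
#'
#' @param seed Integer RNG seed.
#' @param baseline_dur,hv_dur Segment durations in seconds.
#' @param eoc_cycles,eoc_interval Eye open/close cycles and seconds per
#'   state.
#' @param ps_sched Photic schedule tibble ([photic_schedule()]).
#' @param latent_fs Internal latent sampling rate in Hz.
#' @param devices List of device definitions: `name`, `fs`, `channels`,
#'   `powerline_amp` (uV), `drift_amp` (uV rms), `white_rms` (uV).
#' @param background `gamma` (1/f exponent), `rms` (uV), `common_mode`
#'   (relative gain of a shared term mimicking reference-montage
#'   correlation).
#' @param alpha Occipital alpha rhythm: `center`, `bw` (Hz), `base_rms`
#'   (uV), `closed_gain` (amplitude multiplier while eyes are closed).
#' @param hv Hyperventilation slowing: band edges `f_lo`, `f_hi` (Hz) and
#'   `peak_rms` (uV) reached at the end of a linear ramp.
#' @param photic Driving response: `amp` (uV) and `harmonic_gain`
#'   (relative second-harmonic amplitude).
#' @param blinks Frontal blink artifacts: `rate_per_min`, `amp` (uV),
#'   `duration` (s).
#' @param powerline_freq Mains frequency in Hz (50 by default).
#' @return A `session_spec` list.
#' @export
session_spec <- function(seed = 1,
                         baseline_dur = 60,
                         eoc_cycles = 12, eoc_interval = 10,
                         hv_dur = 180,
                         ps_sched = photic_schedule(),
                         latent_fs = 1000,
                         devices = list(
                           list(name = "wearable", fs = 125,
                                channels = montage_channels("wearable"),
                                powerline_amp = 8, drift_amp = 20,
                                white_rms = 0.3),
                           list(name = "clinical", fs = 500,
                                channels = montage_channels("clinical"),
                                powerline_amp = 2, drift_amp = 8,
                                white_rms = 0.3)),
                         background = list(gamma = 1, rms = 10,
                                           common_mode = 0.2),
                         alpha = list(center = 10, bw = 4, base_rms = 2,
                                      closed_gain = 3),
                         hv = list(f_lo = 2, f_hi = 7, peak_rms = 10),
                         photic = list(amp = 6, harmonic_gain = 0.3),
                         blinks = list(rate_per_min = 10, amp = 80,
                                       duration = 0.3),
                         powerline_freq = 50) {
  for (d in devices) {
    if (latent_fs %% d$fs != 0) {
      stop("latent_fs must be an integer multiple of device rate ", d$fs)
    }
    if (latent_fs < 2 * d$fs) stop("latent_fs must be >= 2x device rate")
    if (d$powerline_amp < 0 || d$drift_amp < 0 || d$white_rms < 0) {
      stop("device noise amplitudes must be nonnegative")
    }
  }
  names(devices) <- vapply(devices, `[[`, character(1), "name")
  spec <- list(seed = as.integer(seed), baseline_dur = baseline_dur,
               eoc_cycles = eoc_cycles, eoc_interval = eoc_interval,
               hv_dur = hv_dur, ps_sched = ps_sched, latent_fs = latent_fs,
               devices = devices, background = background, alpha = alpha,
               hv = hv, photic = photic, blinks = blinks,
               powerline_freq = powerline_freq)
  class(spec) <- "session_spec"
  spec
}

#' Create an empty additive signal buffer
#'
#' A buffer holds a set of additive signal components on a common time
#' base; component generators ([make_background()], [add_alpha_bursts()],
#' ...) add named components. With `ledger = TRUE` every component is
#' retained separately (and their sum is the composite, exactly); with
#' `ledger = FALSE` they are accumulated in place to save memory.
#'
#' @param duration Seconds.
#' @param fs Sampling rate in Hz.
#' @param channels Channel labels.
#' @param ledger Keep per-component matrices.
#' @return A `signal_buffer`.
#' @export
signal_buffer <- function(duration, fs, channels, ledger = TRUE) {
  n <- round(duration * fs)
  structure(list(n = n, fs = fs, duration = duration,
                 channels = as.character(channels),
                 ledger = ledger, components = list()),
            class = "signal_buffer")
}

.add_component <- function(buf, name, mat) {
  stopifnot(nrow(mat) == buf$n, ncol(mat) == length(buf$channels))
  if (buf$ledger) {
    buf$components[[name]] <- if (is.null(buf$components[[name]]))
      mat else buf$components[[name]] + mat
  } else {
    buf$components[["composite"]] <- if (is.null(buf$components$composite))
      mat else buf$components$composite + mat
  }
  buf
}

#' Composite signal of a buffer
#' @param buf A `signal_buffer`.
#' @return Matrix: the exact sum of all components.
#' @export
buffer_composite <- function(buf) {
  if (length(buf$components) == 0) {
    return(matrix(0, buf$n, length(buf$channels),
                  dimnames = list(NULL, buf$channels)))
  }
  out <- Reduce(`+`, buf$components)
  colnames(out) <- buf$channels
  out
}

# Spectrally shaped Gaussian noise scaled to an exact sample RMS.
# shape(f) gives the amplitude profile over positive frequencies.
.shaped_noise <- function(n, fs, shape, rms) {
  z <- stats::fft(stats::rnorm(n))
  f <- (0:(n - 1)) * fs / n
  f[f > fs / 2] <- fs - f[f > fs / 2]   # fold to physical frequency
  amp <- shape(f)
  amp[1] <- 0                           # no DC
  x <- Re(stats::fft(z * amp, inverse = TRUE)) / n
  r <- sqrt(mean(x^2))
  if (r == 0) return(numeric(n))
  x * (rms / r)
}

.pink_shape <- function(gamma, f_floor = 0.1) {
  function(f) {
    fc <- pmax(f, f_floor)
    fc^(-gamma / 2)
  }
}

.band_shape <- function(f_lo, f_hi) {
  function(f) as.numeric(f >= f_lo & f <= f_hi)
}

# Per-channel spatial weights from a named list with a default.
.channel_weights <- function(channels, named, default = 0) {
  w <- rep(default, length(channels))
  names(w) <- channels
  for (nm in names(named)) if (nm %in% channels) w[nm] <- named[[nm]]
  w
}

# Smooth a 0/1-style envelope with a short raised-cosine ramp.
.smooth_envelope <- function(env, fs, ramp = 0.25) {
  k <- max(1, round(ramp * fs))
  w <- 0.5 * (1 - cos(2 * pi * seq_len(k) / (k + 1)))
  w <- w / sum(w)
  as.numeric(stats::filter(c(rep(env[1], k), env, rep(env[length(env)], k)),
                           w, sides = 2))[(k + 1):(k + length(env))]
}

#' Add a 1/f background to a buffer
#'
#' Independent spectrally shaped Gaussian noise per channel (power spectral
#' density proportional to `f^-gamma`, flattened below 0.1 Hz) plus a
#' shared common-mode term that mimics the channel correlation induced by a
#' reference montage.
#'
#' @param buf A [signal_buffer()].
#' @param gamma Spectral exponent (PSD slope).
#' @param rms Per-channel RMS in microvolts.
#' @param common_mode Relative amplitude of the shared term.
#' @return The buffer with a `background` component added.
#' @export
make_background <- function(buf, gamma = 1, rms = 10, common_mode = 0.2) {
  if (rms < 0 || common_mode < 0) stop("amplitudes must be nonnegative")
  shape <- .pink_shape(gamma)
  nch <- length(buf$channels)
  mat <- matrix(0, buf$n, nch)
  for (j in seq_len(nch)) {
    mat[, j] <- .shaped_noise(buf$n, buf$fs, shape, rms)
  }
  if (common_mode > 0) {
    cm <- .shaped_noise(buf$n, buf$fs, shape, rms * common_mode)
    mat <- mat + cm
  }
  .add_component(buf, "background", mat)
}

#' Add an eye-state reactive occipital alpha rhythm
#'
#' A narrowband (center +/- bw/2) noise source, occipitally weighted, whose
#' amplitude is multiplied by `closed_gain` during the scheduled eyes-closed
#' intervals (0.25 s raised-cosine transitions).
#'
#' @param buf A [signal_buffer()].
#' @param closed_intervals Data frame with `t_start`, `t_end` (seconds on
#'   the buffer time base) of eyes-closed intervals; may be empty.
#' @param center,bw Band center and width in Hz.
#' @param base_rms Eyes-open RMS in microvolts.
#' @param closed_gain Amplitude multiplier while closed (>= 0).
#' @param weights Named per-channel gains (unlisted channels get 0.1).
#' @return The buffer with an `alpha` component added.
#' @export
add_alpha_bursts <- function(buf, closed_intervals,
                             center = 10, bw = 4, base_rms = 2,
                             closed_gain = 3,
                             weights = list(O1 = 1, O2 = 1, T5 = 0.5,
                                            T6 = 0.5, P3 = 0.5, P4 = 0.5,
                                            Pz = 0.5)) {
  if (base_rms < 0 || closed_gain < 0) stop("amplitudes must be nonnegative")
  src <- .shaped_noise(buf$n, buf$fs,
                       .band_shape(center - bw / 2, center + bw / 2), 1)
  env <- rep(1, buf$n)
  for (i in seq_len(NROW(closed_intervals))) {
    i0 <- round(closed_intervals$t_start[i] * buf$fs) + 1
    i1 <- round(closed_intervals$t_end[i] * buf$fs)
    env[i0:i1] <- closed_gain
  }
  env <- .smooth_envelope(env, buf$fs)
  w <- .channel_weights(buf$channels, weights, default = 0.1)
  .add_component(buf, "alpha", (base_rms * env * src) %o% w)
}

#' Add hyperventilation delta/theta slowing
#'
#' A narrowband slow source whose RMS ramps linearly from 0 to `peak_rms`
#' across the HV interval, with bifrontal preponderance but widespread
#' distribution.
#'
#' @param buf A [signal_buffer()].
#' @param interval List or row with `t_start`, `t_end` in seconds.
#' @param f_lo,f_hi Slowing band in Hz.
#' @param peak_rms RMS reached at the end of the ramp (uV).
#' @param weights Named per-channel gains (unlisted channels get 0.6).
#' @return The buffer with an `hv_slowing` component added.
#' @export
add_hv_slowing <- function(buf, interval, f_lo = 2, f_hi = 7,
                           peak_rms = 10,
                           weights = list(Fp1 = 1, Fp2 = 1, F3 = 1, F4 = 1,
                                          F7 = 1, F8 = 1, Fz = 1)) {
  if (peak_rms < 0) stop("amplitudes must be nonnegative")
  src <- .shaped_noise(buf$n, buf$fs, .band_shape(f_lo, f_hi), 1)
  env <- numeric(buf$n)
  i0 <- round(interval$t_start * buf$fs) + 1
  i1 <- round(interval$t_end * buf$fs)
  env[i0:i1] <- seq(0, 1, length.out = i1 - i0 + 1)
  w <- .channel_weights(buf$channels, weights, default = 0.6)
  .add_component(buf, "hv_slowing", (peak_rms * env * src) %o% w)
}

#' Add a photic driving response
#'
#' For each schedule step, an occipitally weighted sinusoid at the stimulus
#' frequency (plus an optional second harmonic) with 0.2 s on/off ramps.
#'
#' @param buf A [signal_buffer()].
#' @param schedule Photic schedule ([photic_schedule()]).
#' @param t_start Seconds at which the first step begins.
#' @param amp Driving amplitude in microvolts (0 adds nothing).
#' @param harmonic_gain Relative second-harmonic amplitude.
#' @param weights Named per-channel gains (unlisted channels get 0.1).
#' @return The buffer with a `photic` component added.
#' @export
add_photic_response <- function(buf, schedule, t_start, amp = 6,
                                harmonic_gain = 0.3,
                                weights = list(O1 = 1, O2 = 1, P3 = 0.4,
                                               P4 = 0.4, Pz = 0.4,
                                               T5 = 0.4, T6 = 0.4)) {
  if (amp < 0 || harmonic_gain < 0) stop("amplitudes must be nonnegative")
  sig <- numeric(buf$n)
  t0 <- t_start + cumsum(c(0, schedule$duration[-nrow(schedule)]))
  for (i in seq_len(nrow(schedule))) {
    i0 <- round(t0[i] * buf$fs) + 1
    i1 <- round((t0[i] + schedule$duration[i]) * buf$fs)
    tt <- (0:(i1 - i0)) / buf$fs
    f0 <- schedule$freq[i]
    wave <- sin(2 * pi * f0 * tt) +
      harmonic_gain * sin(2 * pi * 2 * f0 * tt)
    nr <- min(length(tt), round(0.2 * buf$fs))
    ramp <- rep(1, length(tt))
    ramp[1:nr] <- 0.5 * (1 - cos(pi * (0:(nr - 1)) / nr))
    ramp[(length(tt) - nr + 1):length(tt)] <- rev(ramp[1:nr])
    sig[i0:i1] <- wave * ramp
  }
  w <- .channel_weights(buf$channels, weights, default = 0.1)
  .add_component(buf, "photic", (amp * sig) %o% w)
}

#' Add frontal eye-blink artifacts
#'
#' Stylized biphasic 300 ms raised-cosine pulses at Poisson-distributed
#' times on the frontal channels — a documented stand-in for real blink
#' morphology, not a physiological model.
#'
#' @param buf A [signal_buffer()].
#' @param rate_per_min Mean blink rate.
#' @param amp Peak amplitude in microvolts.
#' @param duration Pulse duration in seconds.
#' @param weights Named per-channel gains (unlisted channels get 0).
#' @return The buffer with a `blinks` component added.
#' @export
add_blinks <- function(buf, rate_per_min = 10, amp = 80, duration = 0.3,
                       weights = list(Fp1 = 1, Fp2 = 1, F7 = 0.3, F3 = 0.3,
                                      F4 = 0.3, F8 = 0.3, Fz = 0.3)) {
  if (rate_per_min < 0 || amp < 0) stop("amplitudes must be nonnegative")
  n_blinks <- stats::rpois(1, rate_per_min * buf$duration / 60)
  sig <- numeric(buf$n)
  if (n_blinks > 0) {
    times <- sort(stats::runif(n_blinks, 0, buf$duration - duration))
    np <- round(duration * buf$fs)
    tau <- (0:(np - 1)) / np
    pulse <- sin(2 * pi * tau) * 0.5 * (1 - cos(2 * pi * tau))
    pulse <- pulse / max(abs(pulse))
    for (tb in times) {
      i0 <- round(tb * buf$fs) + 1
      jit <- stats::runif(1, 0.8, 1.2)
      sig[i0:(i0 + np - 1)] <- sig[i0:(i0 + np - 1)] + amp * jit * pulse
    }
  }
  w <- .channel_weights(buf$channels, weights, default = 0)
  .add_component(buf, "blinks", sig %o% w)
}

#' Add mains powerline interference
#'
#' A coherent sinusoid at the mains frequency with a random phase, equal on
#' all channels. Its total per-channel power is `amp^2 / 2`.
#'
#' @param buf A [signal_buffer()].
#' @param f0 Mains frequency in Hz (must lie below Nyquist).
#' @param amp Amplitude in microvolts.
#' @return The buffer with a `powerline` component added.
#' @export
add_powerline <- function(buf, f0 = 50, amp = 1) {
  if (amp < 0) stop("amplitudes must be nonnegative")
  if (f0 >= buf$fs / 2) stop("powerline frequency above Nyquist")
  phase <- stats::runif(1, 0, 2 * pi)
  tt <- (0:(buf$n - 1)) / buf$fs
  sig <- amp * sin(2 * pi * f0 * tt + phase)
  .add_component(buf, "powerline",
                 sig %o% rep(1, length(buf$channels)))
}

#' Add sub-0.5 Hz baseline wander
#'
#' Independent narrowband (0.02-0.4 Hz) drift per channel.
#'
#' @param buf A [signal_buffer()].
#' @param amp RMS amplitude in microvolts.
#' @return The buffer with a `drift` component added.
#' @export
add_drift <- function(buf, amp = 20) {
  if (amp < 0) stop("amplitudes must be nonnegative")
  nch <- length(buf$channels)
  mat <- matrix(0, buf$n, nch)
  if (amp > 0) {
    for (j in seq_len(nch)) {
      mat[, j] <- .shaped_noise(buf$n, buf$fs, .band_shape(0.02, 0.4), amp)
    }
  }
  .add_component(buf, "drift", mat)
}

#' Add white measurement noise
#'
#' @param buf A [signal_buffer()].
#' @param rms RMS amplitude in microvolts.
#' @return The buffer with a `white` component added.
#' @export
add_white_noise <- function(buf, rms = 0.3) {
  if (rms < 0) stop("amplitudes must be nonnegative")
  mat <- matrix(stats::rnorm(buf$n * length(buf$channels), sd = rms),
                buf$n, length(buf$channels))
  .add_component(buf, "white", mat)
}

# Zero-phase FIR anti-alias filtering + integer decimation of a matrix.
# Linear-phase FIR (513 taps) applied by FFT convolution; the exact integer
# group delay is removed so components decimate linearly and in phase.
.decimate_matrix <- function(x, from_fs, to_fs) {
  r <- from_fs / to_fs
  if (r != round(r)) stop("non-integer decimation factor")
  if (r == 1) return(x)
  ntap <- 513
  b <- signal::fir1(ntap - 1, 0.9 * (to_fs / 2) / (from_fs / 2))
  n <- nrow(x)
  pad <- ntap
  n_ext <- n + 2 * pad
  nfft <- stats::nextn(n_ext + ntap, c(2, 3, 5))
  bf <- stats::fft(c(b, rep(0, nfft - ntap)))
  out <- matrix(0, ceiling(n / r), ncol(x))
  gd <- (ntap - 1) / 2
  keep <- seq(1, n, by = r)
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    xe <- c(2 * col[1] - col[(pad + 1):2], col,
            2 * col[n] - col[(n - 1):(n - pad)])
    xf <- stats::fft(c(xe, rep(0, nfft - n_ext)))
    y <- Re(stats::fft(xf * bf, inverse = TRUE)) / nfft
    y <- y[(pad + gd + 1):(pad + gd + n)]
    out[, j] <- y[keep]
  }
  colnames(out) <- colnames(x)
  out
}

#' Simulate a two-device routine-EEG session
#'
#' Builds the protocol timeline (baseline, eye open/close, hyperventilation,
#' photic stimulation), synthesizes the latent source process at the
#' internal rate, then derives each device's recording by anti-alias
#' decimation of the shared composite plus device-specific powerline,
#' drift, and white measurement noise. Output is fully determined by
#' `spec$seed`.
#'
#' @param spec A [session_spec()].
#' @param keep_components Retain the full additive component ledger (latent
#'   and per-device); disable to reduce memory.
#' @return List with `spec`, `protocol` (annotations and schedules),
#'   `latent` (the latent `signal_buffer`), and `devices`: per device a
#'   list with `recording` (`eeg_recording`), `annotations`, and `buffer`
#'   (the device-rate `signal_buffer` whose composite is the recording).
#' @export
simulate_session <- function(spec = session_spec(), keep_components = TRUE) {
  stopifnot(inherits(spec, "session_spec"))
  set.seed(spec$seed)

  eoc_dur <- 2 * spec$eoc_cycles * spec$eoc_interval
  ps_dur <- sum(spec$ps_sched$duration)
  t_eoc <- spec$baseline_dur
  t_hv <- t_eoc + eoc_dur
  t_ps <- t_hv + spec$hv_dur
  total <- t_ps + ps_dur
  ann <- new_annotations(
    label = c("BASELINE", "EOC", "HV", "PS"),
    t_start = c(0, t_eoc, t_hv, t_ps),
    t_end = c(t_eoc, t_hv, t_ps, total),
    photic_schedule = list(NULL, NULL, NULL, spec$ps_sched))
  eoc_sched <- eoc_schedule(spec$eoc_cycles, spec$eoc_interval)

  latent_channels <- montage_channels("clinical")
  buf <- signal_buffer(total, spec$latent_fs, latent_channels,
                       ledger = keep_components)
  buf <- make_background(buf, spec$background$gamma, spec$background$rms,
                         spec$background$common_mode)
  closed_abs <- eoc_sched[eoc_sched$state == "closed", ]
  closed_abs$t_start <- closed_abs$t_start + t_eoc
  closed_abs$t_end <- closed_abs$t_end + t_eoc
  buf <- add_alpha_bursts(buf, closed_abs, spec$alpha$center,
                          spec$alpha$bw, spec$alpha$base_rms,
                          spec$alpha$closed_gain)
  buf <- add_hv_slowing(buf, list(t_start = t_hv, t_end = t_ps),
                        spec$hv$f_lo, spec$hv$f_hi, spec$hv$peak_rms)
  buf <- add_photic_response(buf, spec$ps_sched, t_ps, spec$photic$amp,
                             spec$photic$harmonic_gain)
  buf <- add_blinks(buf, spec$blinks$rate_per_min, spec$blinks$amp,
                    spec$blinks$duration)
  latent_composite <- buffer_composite(buf)

  devices <- lapply(spec$devices, function(d) {
    dec <- .decimate_matrix(latent_composite[, d$channels, drop = FALSE],
                            spec$latent_fs, d$fs)
    dbuf <- signal_buffer(total, d$fs, d$channels, ledger = keep_components)
    dbuf <- .add_component(dbuf, "latent", dec)
    dbuf <- add_powerline(dbuf, spec$powerline_freq, d$powerline_amp)
    dbuf <- add_drift(dbuf, d$drift_amp)
    dbuf <- add_white_noise(dbuf, d$white_rms)
    rec <- new_recording(buffer_composite(dbuf), fs = d$fs,
                         channels = d$channels, device = d$name)
    list(recording = rec, annotations = ann,
         buffer = if (keep_components) dbuf else NULL)
  })

  list(spec = spec,
       protocol = list(annotations = ann, eoc_schedule = eoc_sched,
                       eoc_t_start = t_eoc, ps_schedule = spec$ps_sched,
                       ps_t_start = t_ps, total_duration = total),
       latent = if (keep_components) buf else NULL,
       devices = devices)
}
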