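# Pre-processing: segmentation, Butterworth band-pass, normalization.
#
# Stages move strictly raw -> filtered -> normalized; sample counts are
# unchanged by filtering and normalization.

#' Band-pass filter specification
#'
#' Order-5 Butterworth band-pass between 0.5 and 40 Hz by default — the
#' standard clinical EEG passband that removes sub-0.5 Hz baseline wander
#' and high-frequency noise. Zero-phase (forward-backward) application is
#' the default so waveform morphology is preserved; note the effective
#' magnitude response is then the square of the single-pass response.
#'
#' @param order Filter order (>= 1).
#' @param f_low,f_high Band edges in Hz.
#' @param zero_phase Apply forward-backward (`TRUE`, default) or single
#'   causal pass (`FALSE`).
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(order = 5, f_low = 0.5, f_high = 40,
                        zero_phase = TRUE) {
  stopifnot(order >= 1, f_low > 0, f_high > f_low)
  structure(list(order = order, f_low = f_low, f_high = f_high,
                 design = "butterworth", zero_phase = zero_phase),
            class = "filter_spec")
}

.new_segment <- function(samples, fs, label, stage, device, channels,
                         t_start = 0, scale = NULL, center = NULL,
                         subject = NA_character_) {
  colnames(samples) <- channels
  structure(list(samples = samples, fs = fs, label = label, stage = stage,
                 device = device, channels = channels, t_start = t_start,
                 scale = scale, center = center, subject = subject),
            class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> %s/%s stage=%s fs=%g Hz, %d ch, %d samples\n",
              x$device, x$label, x$stage, x$fs, length(x$channels),
              nrow(x$samples)))
  invisible(x)
}

#' Cut a recording into test segments
#'
#' One raw-stage segment per annotation; the samples are the half-open slice
#' `[round(t_start * fs), round(t_end * fs))`.
#'
#' @param rec An `eeg_recording`.
#' @param ann An `eeg_annotations` tibble.
#' @param subject Optional subject identifier carried into metrics.
#' @return Named list of `eeg_segment` objects (names = test labels).
#' @export
segment_recording <- function(rec, ann, subject = NA_character_) {
  validate_annotations(ann, duration = duration_seconds(rec))
  out <- lapply(seq_len(nrow(ann)), function(i) {
    i0 <- round(ann$t_start[i] * rec$fs)
    i1 <- round(ann$t_end[i] * rec$fs)
    .new_segment(rec$samples[(i0 + 1):i1, , drop = FALSE], rec$fs,
                 ann$label[i], "raw", rec$device, rec$channels,
                 t_start = ann$t_start[i], subject = subject)
  })
  names(out) <- ann$label
  out
}

# Zero-phase filtering with odd-reflection edge padding (3x the filter
# length), applied forward then backward so the net phase is zero. Each
# pass is initialized at the steady state the filter would reach under a
# constant input equal to the first padded sample, which suppresses the
# startup transient; by linearity that initialization is equivalent to
# filtering the offset-removed sequence and adding back the DC gain
# response.
.filtfilt_pad <- function(b, a, x) {
  npad <- 3 * max(length(a), length(b))
  n <- length(x)
  npad <- min(npad, n - 1)
  head_ext <- 2 * x[1] - x[(npad + 1):2]
  tail_ext <- 2 * x[n] - x[(n - 1):(n - npad)]
  xe <- c(head_ext, x, tail_ext)
  k_dc <- sum(b) / sum(a)
  pass <- function(v) {
    as.numeric(signal::filter(b, a, v - v[1])) + v[1] * k_dc
  }
  y <- rev(pass(rev(pass(xe))))
  y[(npad + 1):(npad + n)]
}

#' Apply the band-pass filter to a segment
#'
#' Each channel is filtered independently with the Butterworth design in
#' `spec`. Requires `f_high < fs / 2`.
#'
#' @param segment A raw-stage `eeg_segment`.
#' @param spec A [filter_spec()].
#' @return The segment with `stage = "filtered"`.
#' @export
bandpass <- function(segment, spec = filter_spec()) {
  stopifnot(inherits(segment, "eeg_segment"))
  if (segment$stage != "raw") {
    stop("bandpass expects a raw-stage segment, got stage=", segment$stage)
  }
  fs <- segment$fs
  if (spec$f_high >= fs / 2) {
    stop(sprintf("design error: f_high = %g Hz must be below Nyquist %g Hz",
                 spec$f_high, fs / 2))
  }
  bt <- signal::butter(spec$order, c(spec$f_low, spec$f_high) / (fs / 2),
                       type = "pass")
  y <- segment$samples
  for (j in seq_len(ncol(y))) {
    y[, j] <- if (spec$zero_phase) {
      .filtfilt_pad(bt$b, bt$a, segment$samples[, j])
    } else {
      as.numeric(signal::filter(bt$b, bt$a, segment$samples[, j]))
    }
  }
  out <- segment
  out$samples <- y
  out$stage <- "filtered"
  out
}

#' Normalize a filtered segment
#'
#' `peak_unit` (default) divides each channel by its maximum absolute value
#' so the peak of the cleaned signal is exactly 1 — the convention that
#' makes the PSNR peak term equal 1. `zscore` subtracts the mean and divides
#' by the sample standard deviation (n - 1). The affine factors are retained
#' (`scale`, `center`) so the raw signal can be brought onto the cleaned
#' scale for noise bookkeeping.
#'
#' @param segment A filtered-stage `eeg_segment`.
#' @param method `"peak_unit"` or `"zscore"`.
#' @return The segment with `stage = "normalized"`.
#' @export
normalize_segment <- function(segment, method = c("peak_unit", "zscore")) {
  method <- match.arg(method)
  stopifnot(inherits(segment, "eeg_segment"))
  if (segment$stage != "filtered") {
    stop("normalize expects a filtered-stage segment, got stage=",
         segment$stage)
  }
  x <- segment$samples
  nch <- ncol(x)
  scale <- numeric(nch); center <- numeric(nch)
  for (j in seq_len(nch)) {
    if (method == "peak_unit") {
      m <- max(abs(x[, j]))
      if (m == 0) {
        stop("degenerate all-zero channel: ", segment$channels[j])
      }
      center[j] <- 0; scale[j] <- 1 / m
    } else {
      s <- stats::sd(x[, j])
      if (s == 0) {
        stop("degenerate constant channel: ", segment$channels[j])
      }
      center[j] <- mean(x[, j]); scale[j] <- 1 / s
    }
    x[, j] <- (x[, j] - center[j]) * scale[j]
  }
  out <- segment
  out$samples <- x
  out$stage <- "normalized"
  out$scale <- scale
  out$center <- center
  out$norm_method <- method
  out
}

#' Run segmentation, filtering and normalization in one call
#'
#' @param rec An `eeg_recording`.
#' @param ann Annotations.
#' @param spec A [filter_spec()].
#' @param method Normalization method, see [normalize_segment()].
#' @param subject Optional subject id.
#' @return List with `raw` and `clean` lists of segments (parallel order).
#' @export
preprocess_recording <- function(rec, ann, spec = filter_spec(),
                                 method = "peak_unit",
                                 subject = NA_character_) {
  raw <- segment_recording(rec, ann, subject = subject)
  clean <- lapply(raw, function(s) normalize_segment(bandpass(s, spec),
                                                     method = method))
  list(raw = raw, clean = clean)
}
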