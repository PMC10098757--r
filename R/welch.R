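# Welch power spectral density estimate (Hann window, 50% overlap).

#' Welch PSD estimate
#'
#' Averaged modified periodograms with a Hann window. Default 2-second
#' windows with 50% overlap give 0.5 Hz resolution, which matches the
#' +/- 0.5 Hz matching window used by the photic driving score.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param window_sec Window length in seconds.
#' @param overlap Fractional overlap between windows (0 to < 1).
#' @return Tibble with columns `freq` (Hz) and `psd` (power density,
#'   units^2/Hz, one-sided).
#' @export
welch_psd <- function(x, fs, window_sec = 2, overlap = 0.5) {
  nw <- round(window_sec * fs)
  if (nw < 4) stop("window too short")
  if (length(x) < nw) stop("signal shorter than one Welch window")
  step <- max(1, round(nw * (1 - overlap)))
  starts <- seq(1, length(x) - nw + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(nw - 1)) / nw))     # periodic Hann
  u <- sum(w^2)
  acc <- numeric(nw %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nw - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- Mod(stats::fft(seg))^2
    acc <- acc + sp[1:(nw %/% 2 + 1)]
  }
  psd <- acc / (length(starts) * u * fs)
  # one-sided: double everything except DC (and Nyquist when nw even)
  two <- rep(2, length(psd)); two[1] <- 1
  if (nw %% 2 == 0) two[length(psd)] <- 1
  tibble::tibble(freq = (0:(nw %/% 2)) * fs / nw, psd = psd * two)
}

# Integrated band power from a Welch PSD (inclusive bin range).
.band_power <- function(psd, f_lo, f_hi) {
  sel <- psd$freq >= f_lo - 1e-9 & psd$freq <= f_hi + 1e-9
  df <- psd$freq[2] - psd$freq[1]
  sum(psd$psd[sel]) * df
}

# Welch PSD averaged over a set of channels of a segment.
.segment_psd <- function(segment, channels, window_sec = 2, overlap = 0.5,
                         rows = NULL) {
  missing <- setdiff(channels, segment$channels)
  if (length(missing) > 0) {
    stop("channel(s) absent from segment: ", paste(missing, collapse = ", "))
  }
  acc <- NULL
  for (ch in channels) {
    x <- segment$samples[, ch]
    if (!is.null(rows)) x <- x[rows]
    p <- welch_psd(x, segment$fs, window_sec, overlap)
    acc <- if (is.null(acc)) p else
      tibble::tibble(freq = p$freq, psd = acc$psd + p$psd)
  }
  acc$psd <- acc$psd / length(channels)
  acc
}
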