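# Independent oracles used across the suite.

# Analytic squared magnitude of the bilinear-designed digital Butterworth
# band-pass: prewarp the evaluation and edge frequencies to the analog
# domain and evaluate the analog band-pass prototype response. Independent
# of the signal-domain filtering path under test.
butter_bp_mag2 <- function(f, fs, order = 5, f1 = 0.5, f2 = 40) {
  warp <- function(g) 2 * fs * tan(pi * g / fs)
  W <- warp(f); W1 <- warp(f1); W2 <- warp(f2)
  W0sq <- W1 * W2
  B <- W2 - W1
  ifelse(W == 0, 0, 1 / (1 + ((W^2 - W0sq) / (B * W))^(2 * order)))
}

# Periodogram band energy (inclusive of f_lo, exclusive of f_hi, matching
# the dyadic band convention). Total over all bands equals sum(x^2).
fft_band_energy <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  f <- (0:(n - 1)) * fs / n
  f[f > fs / 2] <- fs - f[f > fs / 2]
  sel <- f >= f_lo & f < f_hi
  sum(p[sel])
}

# Which dyadic band an FFT oracle assigns a pure tone to.
fft_dominant_band <- function(x, fs, scheme) {
  bands <- rbind(scheme$bands, scheme$unassigned)
  e <- vapply(seq_len(nrow(bands)), function(i) {
    fft_band_energy(x, fs, bands$f_lo[i], bands$f_hi[i])
  }, numeric(1))
  bands$band[which.max(e)]
}

sine_at <- function(f0, fs, dur, amp = 1, phase = 0) {
  amp * sin(2 * pi * f0 * (0:(round(dur * fs) - 1)) / fs + phase)
}

# Build a segment directly from a sample matrix (bypassing a recording).
make_segment <- function(x, fs, label = "EOC", device = "dev",
                         channels = NULL, stage = "raw") {
  x <- as.matrix(x)
  if (is.null(channels)) {
    channels <- if (!is.null(colnames(x))) colnames(x)
    else paste0("ch", seq_len(ncol(x)))
  }
  eegqc:::.new_segment(x, fs, label, stage, device, channels)
}

# A small two-device session spec used by scaled-down end-to-end tests.
tiny_session_spec <- function(seed = 1) {
  session_spec(seed = seed, baseline_dur = 20, eoc_cycles = 3, hv_dur = 40,
               ps_sched = photic_schedule(c(8, 12), 8))
}
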