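# Signal-quality metrics under the power-frequency noise model.
#
# The cleaned signal b is the band-passed, normalized segment; noise is the
# content the 0.5-40 Hz band-pass removed: baseline wander below 0.5 Hz and
# high-frequency noise above 40 Hz. Computing N as the residual a - b (with
# the raw signal a brought onto b's normalization scale) captures exactly
# that removed content and makes the power bookkeeping
# P_a = P_b + P_N + cross-term explicit and testable.

#' Noise component of a raw/cleaned channel pair
#'
#' @param a_scaled Raw channel brought onto the cleaned signal's
#'   normalization scale (same affine factors as applied to `b`).
#' @param b Cleaned channel (filtered + normalized), same length.
#' @return The residual series `a_scaled - b`.
#' @export
noise_component <- function(a_scaled, b) {
  if (length(a_scaled) != length(b)) {
    stop("length mismatch: ", length(a_scaled), " vs ", length(b))
  }
  a_scaled - b
}

#' Signal-to-noise ratio in decibels
#'
#' `10 * log10(P_a / P_N)` where `P_a` is the mean squared amplitude of the
#' (scaled) original signal and `P_N` that of the noise component. A zero
#' noise power yields `+Inf` (flagged downstream and excluded from
#' averages); a zero signal power is a degenerate-signal error.
#'
#' @param p_a,p_n Nonnegative powers.
#' @return Decibels.
#' @export
snr_db <- function(p_a, p_n) {
  if (any(p_a < 0) || any(p_n < 0)) stop("powers must be nonnegative")
  if (any(p_a == 0)) stop("degenerate signal: P_a == 0")
  ifelse(p_n == 0, Inf, 10 * log10(p_a / p_n))
}

#' Mean squared error between two equal-length series
#'
#' @param a,b Numeric vectors of equal positive length.
#' @return `mean((a - b)^2)`.
#' @export
mse <- function(a, b) {
  if (length(a) == 0) stop("empty input")
  if (length(a) != length(b)) {
    stop("length mismatch: ", length(a), " vs ", length(b))
  }
  mean((a - b)^2)
}

#' Peak signal-to-noise ratio in decibels
#'
#' Computed as `20 * log10(MAX_f / MSE)` with the mean squared error itself
#' in the denominator — the form used by this pipeline's quality model.
#' `literature = TRUE` instead uses the conventional
#' `20 * log10(MAX_f / sqrt(MSE))` for comparison with image/signal
#' processing references.
#'
#' @param max_f Peak absolute value of the cleaned signal (> 0).
#' @param mse_value Mean squared error (>= 0; 0 yields `+Inf`, flagged).
#' @param literature Use the RMSE-denominator convention.
#' @return Decibels.
#' @export
psnr_db <- function(max_f, mse_value, literature = FALSE) {
  if (any(max_f <= 0)) stop("MAX_f must be positive")
  if (any(mse_value < 0)) stop("MSE must be nonnegative")
  denom <- if (literature) sqrt(mse_value) else mse_value
  ifelse(mse_value == 0, Inf, 20 * log10(max_f / denom))
}

#' Per-channel quality metrics for one segment
#'
#' Assembles, per channel, the raw signal scaled onto the cleaned signal's
#' normalization, the residual noise component, and the SNR/PSNR/MSE triple.
#'
#' @param raw_segment Raw-stage `eeg_segment`.
#' @param cleaned_segment The matching normalized-stage segment (same
#'   channels, same length).
#' @param literature_psnr Also report the RMSE-convention PSNR column.
#' @return Tibble with one row per channel: `device`, `test`, `subject`,
#'   `channel`, `snr_db`, `psnr_db`, `mse`, `max_f`, `p_a`, `p_n`,
#'   `infinite` flag (and `psnr_db_literature` if requested).
#' @export
segment_metrics <- function(raw_segment, cleaned_segment,
                            literature_psnr = FALSE) {
  stopifnot(inherits(raw_segment, "eeg_segment"),
            inherits(cleaned_segment, "eeg_segment"))
  if (raw_segment$stage != "raw" || cleaned_segment$stage != "normalized") {
    stop("expected a raw-stage and a normalized-stage segment")
  }
  if (!identical(raw_segment$channels, cleaned_segment$channels)) {
    stop("channel mismatch between raw and cleaned segments")
  }
  if (nrow(raw_segment$samples) != nrow(cleaned_segment$samples)) {
    stop("sample-count mismatch between raw and cleaned segments")
  }
  nch <- length(raw_segment$channels)
  rows <- lapply(seq_len(nch), function(j) {
    a <- raw_segment$samples[, j]
    b <- cleaned_segment$samples[, j]
    a_scaled <- (a - cleaned_segment$center[j]) * cleaned_segment$scale[j]
    n <- noise_component(a_scaled, b)
    p_a <- mean(a_scaled^2)
    p_n <- mean(n^2)
    m <- mse(a_scaled, b)
    max_f <- max(abs(b))
    tibble::tibble(
      device = raw_segment$device, test = raw_segment$label,
      subject = raw_segment$subject, channel = raw_segment$channels[j],
      snr_db = snr_db(p_a, p_n), psnr_db = psnr_db(max_f, m),
      mse = m, max_f = max_f, p_a = p_a, p_n = p_n,
      infinite = !is.finite(snr_db(p_a, p_n)) || m == 0)
  })
  out <- dplyr::bind_rows(rows)
  if (literature_psnr) {
    out$psnr_db_literature <- psnr_db(out$max_f, out$mse, literature = TRUE)
  }
  out
}

#' Aggregate quality metrics across channels and subjects
#'
#' For each subject the metrics are first averaged over channels, then the
#' mean and sample standard deviation (n - 1) are taken across subjects for
#' every device x test combination. Infinite (flagged) channel values are
#' excluded from the channel averages with a warning stating how many were
#' dropped; a cell with a single subject reports `NA` for the standard
#' deviation rather than 0.
#'
#' @param metrics A tibble as returned by [segment_metrics()] (rows from
#'   several segments/subjects bound together), or a list of such tibbles.
#' @return Tidy tibble: `device`, `test`, `metric`, `mean`, `sd`,
#'   `n_subjects`.
#' @export
summarize_metrics <- function(metrics) {
  if (is.list(metrics) && !is.data.frame(metrics)) {
    metrics <- dplyr::bind_rows(metrics)
  }
  n_inf <- sum(metrics$infinite)
  if (n_inf > 0) {
    warning(n_inf, " channel value(s) with infinite SNR/PSNR excluded ",
            "from averages")
    metrics <- metrics[!metrics$infinite, , drop = FALSE]
  }
  long <- tidyr::pivot_longer(
    metrics[, c("device", "test", "subject", "channel",
                "snr_db", "psnr_db", "mse")],
    cols = c("snr_db", "psnr_db", "mse"),
    names_to = "metric", values_to = "value")
  per_subject <- dplyr::summarise(
    dplyr::group_by(long, .data$device, .data$test, .data$subject,
                    .data$metric),
    value = mean(.data$value), .groups = "drop")
  out <- dplyr::summarise(
    dplyr::group_by(per_subject, .data$device, .data$test, .data$metric),
    mean = mean(.data$value),
    sd = if (dplyr::n() > 1) stats::sd(.data$value) else NA_real_,
    n_subjects = dplyr::n(), .groups = "drop")
  out$metric <- factor(out$metric, levels = c("snr_db", "psnr_db", "mse"))
  dplyr::arrange(out, .data$device, .data$test, .data$metric)
}

#' Write a metrics summary table to CSV
#'
#' Layout mirrors the device x test quality-summary table: one row per
#' device x test x metric with mean and standard deviation. The first line
#' is a schema/provenance comment.
#'
#' @param summary Output of [summarize_metrics()].
#' @param path Output CSV path.
#' @param config_hash Optional provenance hash included in the header line.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summary, path, config_hash = NA) {
  hdr <- sprintf("# eegqc metrics summary schema v1 config=%s", config_hash)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(summary), con, row.names = FALSE)
  invisible(path)
}
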