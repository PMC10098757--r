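# Stimulus-response indices for the routine-EEG activation protocols.
#
# These indices quantify responses that clinical review assesses visually:
# occipital alpha blocking on eye opening, hyperventilation-induced
# delta/theta slowing, and photic driving at the flicker frequency. They
# are derived observables defined by this package, not standard clinical
# statistics, and reports label them as such. All three are ratios of
# band powers, hence invariant to scaling the whole recording.

#' Alternating eye open/close schedule
#'
#' @param n_cycles Number of open+close cycles.
#' @param interval Seconds per state (default 10 s, alternating, starting
#'   with eyes open).
#' @return Tibble `state` (`"open"`/`"closed"`), `t_start`, `t_end` in
#'   seconds from segment start.
#' @export
eoc_schedule <- function(n_cycles = 12, interval = 10) {
  k <- 0:(2 * n_cycles - 1)
  tibble::tibble(state = rep(c("open", "closed"), n_cycles),
                 t_start = k * interval, t_end = (k + 1) * interval)
}

#' Standard photic stimulation schedule
#'
#' The routine-test flicker sequence: 1, 3, 6, 8, 10, 12, 14, 16, 18, 20,
#' 25, 30 Hz for 10 s each.
#'
#' @param freqs Stimulus frequencies in Hz.
#' @param duration Seconds per stimulus step.
#' @return Tibble `freq`, `duration`.
#' @export
photic_schedule <- function(freqs = c(1, 3, 6, 8, 10, 12, 14, 16, 18,
                                      20, 25, 30),
                            duration = 10) {
  tibble::tibble(freq = freqs, duration = rep(duration, length(freqs)))
}

#' Alpha reactivity of an eye open/close segment
#'
#' Mean occipital alpha band power during eyes-closed intervals divided by
#' the same during eyes-open intervals. A ratio above 1 indicates alpha
#' blocking on eye opening (the normal finding).
#'
#' @param eoc_segment An `eeg_segment` of the EOC test (filtered or raw).
#' @param schedule Open/close schedule relative to segment start, see
#'   [eoc_schedule()]. Must lie within the segment and contain both states.
#' @param channels Channels to average (default occipital O1, O2).
#' @param alpha_band Alpha band edges in Hz.
#' @return List with `ratio`, `per_channel` (named vector) and
#'   `per_interval` tibble.
#' @export
alpha_reactivity <- function(eoc_segment, schedule,
                             channels = c("O1", "O2"),
                             alpha_band = c(8, 13)) {
  stopifnot(inherits(eoc_segment, "eeg_segment"))
  dur <- nrow(eoc_segment$samples) / eoc_segment$fs
  if (any(schedule$t_end > dur + 1e-9) || any(schedule$t_start < 0)) {
    stop("schedule does not fit within the segment (duration ", dur, " s)")
  }
  if (!all(c("open", "closed") %in% schedule$state)) {
    stop("schedule must contain both open and closed intervals")
  }
  fs <- eeg_fs(eoc_segment)
  per_interval <- dplyr::bind_rows(lapply(seq_len(nrow(schedule)),
                                          function(i) {
    rows <- (round(schedule$t_start[i] * fs) + 1):round(schedule$t_end[i] * fs)
    pw <- vapply(channels, function(ch) {
      p <- welch_psd(eoc_segment$samples[rows, ch], fs)
      .band_power(p, alpha_band[1], alpha_band[2])
    }, numeric(1))
    tibble::tibble(state = schedule$state[i], interval = i,
                   channel = channels, alpha_power = pw)
  }))
  per_channel <- vapply(channels, function(ch) {
    d <- per_interval[per_interval$channel == ch, ]
    mean(d$alpha_power[d$state == "closed"]) /
      mean(d$alpha_power[d$state == "open"])
  }, numeric(1))
  closed <- mean(per_interval$alpha_power[per_interval$state == "closed"])
  open <- mean(per_interval$alpha_power[per_interval$state == "open"])
  list(ratio = closed / open, per_channel = per_channel,
       per_interval = per_interval)
}

# internal accessor kept for symmetry with recordings
eeg_fs <- function(seg) seg$fs

#' Hyperventilation slowing index
#'
#' Ratio of the slow-to-fast band-energy ratio during hyperventilation to
#' the same ratio at baseline, using DWT band energies:
#' `[(delta + theta) / (alpha + beta)]_HV / [(delta + theta) / (alpha + beta)]_baseline`.
#' An index above 1 indicates rhythmic slowing during HV.
#'
#' @param baseline_segment,hv_segment Segments from the same device with
#'   the same channels.
#' @param channels Channels to average over.
#' @param wavelet Passed to [dwt_band_energies()].
#' @return List with `index` and `per_segment` band-energy tibble.
#' @export
hv_slowing_index <- function(baseline_segment, hv_segment,
                             channels = c("O1", "O2"), wavelet = "db10") {
  if (baseline_segment$device != hv_segment$device) {
    stop("baseline and HV segments must come from the same device")
  }
  ratio_of <- function(seg) {
    missing <- setdiff(channels, seg$channels)
    if (length(missing) > 0) {
      stop("channel(s) absent: ", paste(missing, collapse = ", "))
    }
    scheme <- make_scheme(seg$fs)
    e <- Reduce(`+`, lapply(channels, function(ch) {
      be <- dwt_band_energies(seg$samples[, ch], scheme, wavelet)
      stats::setNames(be$energy_abs, be$band)[c("delta", "theta",
                                                "alpha", "beta")]
    })) / length(channels)
    if (anyNA(e)) stop("missing band energies")
    (e[["delta"]] + e[["theta"]]) / (e[["alpha"]] + e[["beta"]])
  }
  r_hv <- ratio_of(hv_segment)
  r_base <- ratio_of(baseline_segment)
  list(index = r_hv / r_base, hv_ratio = r_hv, baseline_ratio = r_base)
}

#' Photic driving scores per stimulus frequency
#'
#' For each schedule step the occipital Welch spectrum (2 s Hann windows,
#' 50% overlap) is evaluated; the driving score is the spectral power in a
#' +/- 0.5 Hz window at the stimulus frequency (plus, optionally, at its
#' second harmonic when it lies at or below 40 Hz) divided by the median
#' broadband power over 1-40 Hz. The detected dominant frequency is the
#' spectral argmax within 1-40 Hz. Steps shorter than two stimulus cycles
#' are flagged low-confidence with a warning.
#'
#' @param ps_segment An `eeg_segment` of the photic test.
#' @param schedule Photic schedule ([photic_schedule()]); steps are laid
#'   out consecutively from `offset` seconds into the segment.
#' @param channels Channels to average (default O1, O2).
#' @param harmonic Include the second harmonic in the score.
#' @param offset Seconds from segment start to the first step.
#' @return Tibble: `freq`, `score`, `detected_freq`, `low_confidence`.
#' @export
photic_driving_score <- function(ps_segment, schedule,
                                 channels = c("O1", "O2"),
                                 harmonic = TRUE, offset = 0) {
  stopifnot(inherits(ps_segment, "eeg_segment"))
  fs <- ps_segment$fs
  t0 <- offset + cumsum(c(0, schedule$duration[-nrow(schedule)]))
  dur_seg <- nrow(ps_segment$samples) / fs
  if (any(t0 + schedule$duration > dur_seg + 1e-9)) {
    stop("photic schedule extends beyond the segment")
  }
  rows_list <- lapply(seq_len(nrow(schedule)), function(i) {
    (round(t0[i] * fs) + 1):round((t0[i] + schedule$duration[i]) * fs)
  })
  out <- lapply(seq_len(nrow(schedule)), function(i) {
    f0 <- schedule$freq[i]
    low_conf <- schedule$duration[i] * f0 < 2
    if (low_conf) {
      warning(sprintf("photic step %g Hz shorter than 2 cycles; ", f0),
              "score marked low-confidence")
    }
    psd <- .segment_psd(ps_segment, channels,
                        window_sec = min(2, schedule$duration[i]),
                        rows = rows_list[[i]])
    broad <- psd[psd$freq >= 1 & psd$freq <= 40, ]
    med <- stats::median(broad$psd)
    stim <- .band_power(psd, f0 - 0.5, f0 + 0.5)
    if (harmonic && 2 * f0 <= 40) {
      stim <- stim + .band_power(psd, 2 * f0 - 0.5, 2 * f0 + 0.5)
    }
    df <- psd$freq[2] - psd$freq[1]
    tibble::tibble(freq = f0, score = stim / (med * df),
                   detected_freq = broad$freq[which.max(broad$psd)],
                   low_confidence = low_conf)
  })
  dplyr::bind_rows(out)
}

#' Full response report for one device session
#'
#' Bundles the three indices into one serializable report, labelled as
#' derived observables.
#'
#' @param segments Named list of raw or filtered segments containing at
#'   least `EOC`, `HV`, `PS` and `BASELINE` entries.
#' @param eoc_sched,ps_sched Protocol schedules relative to the respective
#'   segment starts.
#' @param channels Channels for all three indices.
#' @return List ready for JSON serialization.
#' @export
response_report <- function(segments, eoc_sched = eoc_schedule(),
                            ps_sched = photic_schedule(),
                            channels = c("O1", "O2")) {
  ar <- alpha_reactivity(segments$EOC, eoc_sched, channels)
  hv <- hv_slowing_index(segments$BASELINE, segments$HV, channels)
  ps <- photic_driving_score(segments$PS, ps_sched, channels)
  list(
    note = paste("alpha_reactivity, hv_slowing_index and photic_driving",
                 "are derived observables defined by this package"),
    device = segments$EOC$device,
    alpha_reactivity = ar$ratio,
    alpha_reactivity_per_channel = as.list(ar$per_channel),
    hv_slowing_index = hv$index,
    photic_driving = ps)
}
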