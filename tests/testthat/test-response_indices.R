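# Segments here are built from the generator's component primitives at
# 125 Hz so each index is checked against its construction ground truth.

make_eoc_segment <- function(seed, closed_gain, dur = 120, fs = 125) {
  set.seed(seed)
  sched <- eoc_schedule(n_cycles = dur / 20)
  buf <- signal_buffer(dur, fs, c("O1", "O2", "Fp1"))
  buf <- make_background(buf, gamma = 1, rms = 10)
  buf <- add_alpha_bursts(buf, sched[sched$state == "closed", ],
                          base_rms = 2, closed_gain = closed_gain)
  list(seg = make_segment(buffer_composite(buf), fs, label = "EOC",
                          channels = c("O1", "O2", "Fp1")),
       sched = sched)
}

test_that("alpha reactivity exceeds 2 when closed-eye alpha is tripled, and is ~1 under symmetry", {
  e <- make_eoc_segment(seed = 21, closed_gain = 3)
  ar <- alpha_reactivity(e$seg, e$sched)
  expect_gt(ar$ratio, 2)
  expect_length(ar$per_channel, 2)
  expect_true(all(ar$per_channel > 1.5))

  flat <- make_eoc_segment(seed = 22, closed_gain = 1)
  ar0 <- alpha_reactivity(flat$seg, flat$sched)
  expect_equal(ar0$ratio, 1, tolerance = 0.35)
})

test_that("alpha reactivity enforces its schedule contracts", {
  e <- make_eoc_segment(seed = 23, closed_gain = 2, dur = 40)
  open_only <- e$sched[e$sched$state == "open", ]
  expect_error(alpha_reactivity(e$seg, open_only),
               "both open and closed")
  too_long <- eoc_schedule(n_cycles = 10)
  expect_error(alpha_reactivity(e$seg, too_long), "does not fit")
})

# Same seed for both members: the HV segment is the baseline background
# plus the ramped slow-wave component, exactly. Indices are computed on
# band-passed segments, as in the pipeline.
make_hv_pair <- function(seed, peak_rms, dur = 60, fs = 125) {
  mk <- function(with_hv) {
    set.seed(seed)
    buf <- signal_buffer(dur, fs, c("O1", "O2"))
    buf <- make_background(buf, gamma = 1, rms = 10)
    if (with_hv) {
      buf <- add_hv_slowing(buf, list(t_start = 0, t_end = dur),
                            peak_rms = peak_rms,
                            weights = list(O1 = 1, O2 = 1))
    }
    bandpass(make_segment(buffer_composite(buf), fs,
                          label = if (with_hv) "HV" else "BASELINE"))
  }
  list(base = mk(FALSE), hv = mk(TRUE))
}

test_that("the HV slowing index exceeds 1.5 for a ramped slow-wave burden and is 1 under identity", {
  p <- make_hv_pair(seed = 31, peak_rms = 10)
  hv <- hv_slowing_index(p$base, p$hv, channels = c("O1", "O2"))
  expect_gt(hv$index, 1.5)

  p0 <- make_hv_pair(seed = 32, peak_rms = 0)
  hv0 <- hv_slowing_index(p0$base, p0$hv, channels = c("O1", "O2"))
  expect_equal(hv0$index, 1, tolerance = 1e-12)  # identical construction
})

test_that("the HV slowing index grows monotonically with the slowing gain", {
  set.seed(33)
  fs <- 125; dur <- 60
  buf <- signal_buffer(dur, fs, c("O1", "O2"))
  buf <- make_background(buf, gamma = 1, rms = 10)
  base_mat <- buffer_composite(buf)
  slow_buf <- add_hv_slowing(signal_buffer(dur, fs, c("O1", "O2")),
                             list(t_start = 0, t_end = dur), peak_rms = 1,
                             weights = list(O1 = 1, O2 = 1))
  slow_mat <- buffer_composite(slow_buf)
  base_seg <- make_segment(base_mat, fs, label = "BASELINE")
  idx <- vapply(c(0, 4, 8, 16), function(g) {
    hv_seg <- make_segment(base_mat + g * slow_mat, fs, label = "HV")
    hv_slowing_index(base_seg, hv_seg, channels = c("O1", "O2"))$index
  }, numeric(1))
  expect_true(all(diff(idx) > 0))
})

make_ps_segment <- function(seed, amp, sched, fs = 125,
                            harmonic_gain = 0) {
  set.seed(seed)
  dur <- sum(sched$duration)
  buf <- signal_buffer(dur, fs, c("O1", "O2"))
  buf <- make_background(buf, gamma = 1, rms = 10)
  buf <- add_photic_response(buf, sched, t_start = 0, amp = amp,
                             harmonic_gain = harmonic_gain,
                             weights = list(O1 = 1, O2 = 1))
  make_segment(buffer_composite(buf), fs, label = "PS")
}

test_that("photic driving is detected at the stimulus frequency with scores above the null", {
  sched <- photic_schedule()
  seg <- make_ps_segment(seed = 41, amp = 6, sched = sched)
  ps <- photic_driving_score(seg, sched)
  hits <- sum(abs(ps$detected_freq - ps$freq) <= 0.5)
  expect_gte(hits, 10)

  null_seg <- make_ps_segment(seed = 42, amp = 0, sched = sched)
  ps0 <- photic_driving_score(null_seg, sched)
  expect_gt(stats::median(ps$score), 5 * stats::median(ps0$score))
})

test_that("an enabled second harmonic elevates power at twice the stimulus frequency", {
  sched <- photic_schedule(6, duration = 60)
  seg <- make_ps_segment(seed = 43, amp = 6, sched = sched,
                         harmonic_gain = 0.5)
  null_seg <- make_ps_segment(seed = 43, amp = 0, sched = sched)
  p_h <- welch_psd(seg$samples[, "O1"], 125)
  p_0 <- welch_psd(null_seg$samples[, "O1"], 125)
  at12 <- function(p) sum(p$psd[p$freq >= 11.5 & p$freq <= 12.5])
  at6 <- function(p) sum(p$psd[p$freq >= 5.5 & p$freq <= 6.5])
  expect_gt(at6(p_h), 5 * at6(p_0))
  expect_gt(at12(p_h), 2 * at12(p_0))
})

test_that("steps shorter than two stimulus cycles are flagged low-confidence", {
  sched <- tibble::tibble(freq = 1, duration = 1.5)
  seg <- make_ps_segment(seed = 44, amp = 6, sched = sched)
  expect_warning(ps <- photic_driving_score(seg, sched,
                                            harmonic = FALSE),
                 "low-confidence")
  expect_true(ps$low_confidence)
})

test_that("all three indices are invariant to a positive rescaling of the recording", {
  e <- make_eoc_segment(seed = 51, closed_gain = 3, dur = 40)
  scaled <- e$seg; scaled$samples <- scaled$samples * 3.7
  expect_equal(alpha_reactivity(scaled, e$sched)$ratio,
               alpha_reactivity(e$seg, e$sched)$ratio)

  p <- make_hv_pair(seed = 52, peak_rms = 8)
  hv1 <- hv_slowing_index(p$base, p$hv, channels = c("O1", "O2"))$index
  sb <- p$base; sb$samples <- sb$samples * 3.7
  sh <- p$hv; sh$samples <- sh$samples * 3.7
  expect_equal(hv_slowing_index(sb, sh, channels = c("O1", "O2"))$index, hv1)

  sched <- photic_schedule(c(8, 12), 10)
  seg <- make_ps_segment(seed = 53, amp = 6, sched = sched)
  s2 <- seg; s2$samples <- s2$samples * 3.7
  expect_equal(photic_driving_score(s2, sched)$score,
               photic_driving_score(seg, sched)$score)
})
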