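test_that("the same seed reproduces a session bit-identically", {
  s1 <- simulate_session(tiny_session_spec(seed = 5))
  s2 <- simulate_session(tiny_session_spec(seed = 5))
  for (nm in names(s1$devices)) {
    expect_identical(s1$devices[[nm]]$recording$samples,
                     s2$devices[[nm]]$recording$samples)
  }
  s3 <- simulate_session(tiny_session_spec(seed = 6))
  expect_false(identical(s1$devices[[1]]$recording$samples,
                         s3$devices[[1]]$recording$samples))
})

test_that("the component ledger sums to the composite exactly, at both rates", {
  sess <- simulate_session(tiny_session_spec(seed = 8))
  lat <- sess$latent
  expect_setequal(names(lat$components),
                  c("background", "alpha", "hv_slowing", "photic", "blinks"))
  expect_identical(unname(Reduce(`+`, lat$components)),
                   unname(buffer_composite(lat)))
  for (nm in names(sess$devices)) {
    d <- sess$devices[[nm]]
    expect_setequal(names(d$buffer$components),
                    c("latent", "powerline", "drift", "white"))
    expect_equal(unname(d$recording$samples),
                 unname(Reduce(`+`, d$buffer$components)))
  }
})

test_that("with all response gains zero the background is 1/f with the configured exponent", {
  slopes <- vapply(1:3, function(seed) {
    set.seed(seed)
    buf <- signal_buffer(120, 500, c("O1", "Cz"))
    buf <- make_background(buf, gamma = 1, rms = 10, common_mode = 0)
    p <- welch_psd(buffer_composite(buf)[, 1], 500, window_sec = 4)
    sel <- p$freq >= 1 & p$freq <= 30
    stats::coef(stats::lm(log(p$psd[sel]) ~ log(p$freq[sel])))[2]
  }, numeric(1))
  expect_equal(mean(slopes), -1, tolerance = 0.2)
})

test_that("occipital channels carry at least twice the frontal alpha power while eyes are closed", {
  sess <- simulate_session(tiny_session_spec(seed = 13))
  rec <- sess$devices$clinical$recording
  closed <- sess$protocol$eoc_schedule
  closed <- closed[closed$state == "closed", ]
  fs <- rec$fs
  pw <- function(ch) {
    mean(vapply(seq_len(nrow(closed)), function(i) {
      t0 <- sess$protocol$eoc_t_start + closed$t_start[i]
      rows <- (round(t0 * fs) + 1):round((t0 + 10) * fs)
      p <- welch_psd(rec$samples[rows, ch], fs)
      sum(p$psd[p$freq >= 7.8 & p$freq <= 15.6])
    }, numeric(1)))
  }
  expect_gt((pw("O1") + pw("O2")) / (pw("Fp1") + pw("Fp2")), 2)
})

test_that("component generators obey their analytic contracts", {
  set.seed(99)
  buf <- signal_buffer(60, 125, c("O1", "Fp1"))
  # powerline adds a^2/2 power per channel
  buf2 <- add_powerline(buf, 50, amp = 4)
  expect_equal(mean(buf2$components$powerline[, 1]^2), 8, tolerance = 0.01)
  # blinks touch only the weighted (frontal) channels
  buf3 <- add_blinks(buf, rate_per_min = 30,
                     weights = list(Fp1 = 1))
  expect_true(all(buf3$components$blinks[, "O1"] == 0))
  expect_gt(max(abs(buf3$components$blinks[, "Fp1"])), 0)
  # photic with zero amplitude is the additive identity
  sched <- photic_schedule(8, 10)
  buf4 <- add_photic_response(buf, sched, t_start = 0, amp = 0)
  expect_true(all(buf4$components$photic == 0))
  # negative amplitudes are rejected
  expect_error(add_powerline(buf, 50, amp = -1), "nonnegative")
  expect_error(add_drift(buf, amp = -1), "nonnegative")
  expect_error(make_background(buf, rms = -1), "nonnegative")
})

test_that("powerline interference ends up in the noise component, not the cleaned signal", {
  sess <- simulate_session(tiny_session_spec(seed = 17))
  hum <- sess$devices$wearable$buffer$components$powerline
  seg <- make_segment(hum[seq_len(125 * 30), 1, drop = FALSE], 125)
  filtered <- bandpass(seg)
  # steady-state view away from the finite-segment filter edges
  core <- (2 * 125):(28 * 125)
  expect_lt(sum(filtered$samples[core, 1]^2) / sum(seg$samples[core, 1]^2),
            0.01)
})

test_that("decimation preserves the shared latent content across device rates", {
  sess <- simulate_session(tiny_session_spec(seed = 19))
  lw <- sess$devices$wearable$buffer$components$latent[, "O1", drop = FALSE]
  lc <- sess$devices$clinical$buffer$components$latent[, "O1", drop = FALSE]
  # clinical at 500 Hz holds 4x the samples
  expect_equal(nrow(lc), 4 * nrow(lw))
  # after the common 0.5-40 Hz band-pass both devices hold the same latent
  # content; zero-phase filtering keeps them sample-aligned
  fw <- bandpass(make_segment(lw, 125, channels = "O1"))$samples[, 1]
  fc <- bandpass(make_segment(lc, 500, channels = "O1"))$samples[, 1]
  expect_gt(stats::cor(fw, fc[seq(1, length(fc), by = 4)]), 0.98)
})

test_that("session specs validate device rate compatibility", {
  expect_error(session_spec(latent_fs = 300), "integer multiple")
  expect_error(session_spec(devices = list(
    list(name = "bad", fs = 125, channels = "O1", powerline_amp = -2,
         drift_amp = 0, white_rms = 0))), "nonnegative")
})
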