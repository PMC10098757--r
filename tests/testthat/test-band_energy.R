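test_that("dyadic band schemes reproduce the device-specific edges and depths", {
  s125 <- make_scheme(125)
  expect_equal(s125$depth, 4)
  expect_equal(s125$bands$band, c("delta", "theta", "alpha", "beta", "gamma"))
  expect_equal(s125$bands$f_hi, 62.5 / 2^(4:0))
  expect_equal(s125$bands$component[1], "approximation 4")
  s500 <- make_scheme(500)
  expect_equal(s500$depth, s125$depth + 2)
  # same clinical band edges, two extra halvings of depth
  expect_equal(s500$bands$f_hi, s125$bands$f_hi)
  expect_equal(s500$bands$component[1], "approximation 6")
  expect_equal(s500$unassigned$f_lo, c(62.5, 125))
  # legacy (+1 offset) level labelling for report reproduction
  leg <- make_scheme(125, level_convention = "legacy")
  expect_equal(leg$bands$component,
               c("approximation 5", "detail 5", "detail 4", "detail 3",
                 "detail 2"))
  expect_error(make_scheme(60), "unsupported rate")
})

test_that("the periodized DWT reconstructs perfectly with exactly additive energies", {
  set.seed(11)
  x <- rnorm(2^10)
  for (wv in c("db2", "db4", "db10")) {
    dec <- dwt_periodic(x, 4, wv)
    parts <- c(list(dwt_reconstruct_component(dec, "approx")),
               lapply(1:4, function(l)
                 dwt_reconstruct_component(dec, "detail", l)))
    expect_lt(max(abs(Reduce(`+`, parts) - x)), 1e-10)
    e_rec <- sum(vapply(parts, function(p) sum(p^2), numeric(1)))
    e_coef <- sum(dec$approx^2) + sum(unlist(lapply(dec$details,
                                                    function(d) sum(d^2))))
    expect_equal(e_rec, sum(x^2), tolerance = 1e-12)
    expect_equal(e_coef, sum(x^2), tolerance = 1e-12)
  }
  expect_error(dwt_periodic(rnorm(100), 4), "multiple of 2\\^depth")
  expect_error(daubechies_filters("db99"), "unknown wavelet")
})

test_that("pure tones land in the FFT-oracle band: dominant on a 1-45 Hz grid, >=90% mid-band", {
  for (fs in c(125, 500)) {
    scheme <- make_scheme(fs)
    edges <- scheme$bands$f_hi[1:4]
    grid <- setdiff(1:45, unlist(lapply(edges, function(e)
      which(abs(1:45 - e) / e < 0.1))))
    for (f0 in grid) {
      x <- sine_at(f0, fs, 30)
      be <- dwt_band_energies(x, scheme)
      oracle <- fft_dominant_band(x[seq_len(attr(be, "n_used"))], fs, scheme)
      expect_equal(be$band[which.max(be$energy_abs)], oracle,
                   label = sprintf("dominant band at %d Hz, fs=%d", f0, fs))
    }
    # canonical mid-band tones concentrate >= 90% in their own octave
    a10 <- dwt_band_energies(sine_at(10, fs, 60), scheme)
    expect_gte(a10$energy_rel[a10$band == "alpha"], 0.9)
    d2 <- dwt_band_energies(sine_at(2, fs, 60), scheme)
    expect_gte(d2$energy_rel[d2$band == "delta"], 0.9)
  }
})

test_that("five-band energies satisfy Parseval within tolerance on 60 s segments", {
  set.seed(2)
  for (fs in c(125, 500)) {
    # band-limited content (as after the 0.5-40 Hz band-pass)
    raw <- make_segment(cbind(rnorm(60 * fs)), fs)
    x <- bandpass(raw)$samples[, 1]
    be <- dwt_band_energies(x, make_scheme(fs))
    named <- be[!grepl("unassigned", be$band), ]
    expect_equal(sum(named$energy_abs) / sum(x^2), 1, tolerance = 0.02)
    expect_equal(sum(named$energy_rel), 1, tolerance = 0.02)
  }
})

test_that("band energy is invariant to circular time-shift of a periodic input", {
  fs <- 125
  x <- sine_at(5, fs, 32) + 0.5 * sine_at(20, fs, 32)
  n <- (length(x) %/% 2^4) * 2^4
  x <- x[1:n]
  e1 <- dwt_band_energies(x, make_scheme(fs))$energy_abs
  xs <- c(x[101:n], x[1:100])
  e2 <- dwt_band_energies(xs, make_scheme(fs))$energy_abs
  expect_equal(e2, e1, tolerance = 0.01)
})

test_that("white-noise band energies match the bandwidth fractions of a flat spectrum", {
  fracs <- c(delta = 0.0625, theta = 0.0625, alpha = 0.125,
             beta = 0.25, gamma = 0.5)
  acc <- rep(0, 5)
  for (seed in 1:5) {
    set.seed(seed)
    be <- dwt_band_energies(rnorm(120 * 125), make_scheme(125))
    acc <- acc + be$energy_rel[match(names(fracs), be$band)]
  }
  expect_equal(acc / 5, unname(fracs), tolerance = 0.15)
})

test_that("band profiles detect alpha bursts against baseline and enforce channel contracts", {
  set.seed(9)
  fs <- 125; dur <- 64
  buf <- signal_buffer(dur, fs, c("O1", "O2"))
  buf <- make_background(buf, gamma = 1, rms = 10)
  base <- buffer_composite(buf)
  buf <- add_alpha_bursts(buf, data.frame(t_start = 0, t_end = dur),
                          base_rms = 2, closed_gain = 3,
                          weights = list(O1 = 1, O2 = 1))
  burst <- buffer_composite(buf)
  segs <- list(make_segment(base, fs, label = "BASELINE", device = "dev"),
               make_segment(burst, fs, label = "EOC", device = "dev"))
  prof <- band_energy_profile(segs, channels = c("O1", "O2"))
  alpha <- prof[prof$band == "alpha", ]
  expect_gt(alpha$energy_rel[alpha$test == "EOC"],
            alpha$energy_rel[alpha$test == "BASELINE"])
  expect_error(band_energy_profile(segs, channels = c("O1", "Oz")), "Oz")
  expect_error(band_energy_profile(segs, channels = character(0)),
               "empty channel list")
})

test_that("segments shorter than the decomposition support are rejected with the minimum stated", {
  expect_error(dwt_band_energies(rnorm(100), make_scheme(125)),
               "at least \\d+ samples")
})
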