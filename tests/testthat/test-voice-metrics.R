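test_that("domain-averaged PSD finds the oscillation and conserves variance", {
  # uniform field oscillating at 150 Hz
  fs <- 5000; nt <- fs
  t <- (seq_len(nt) - 1L) / fs
  osc <- 1 + 0.5 * sin(2 * pi * 150 * t)
  u <- array(rep(osc, times = 16), dim = c(nt, 4, 4))
  f <- make_field(u, array(0, dim(u)), fs = fs)
  sp <- averaged_velocity_psd(f)
  expect_equal(sp$frequencies[which.max(sp$psd[sp$frequencies > 0])
                              + sum(sp$frequencies <= 0)], 150,
               tolerance = sp$resolution)
  expect_equal(extract_fundamental(sp), 150, tolerance = sp$resolution)

  # Parseval: PSD integral approximates the signal variance
  expect_equal(sum(sp$psd) * sp$resolution, stats::var(osc), tolerance = 0.05)

  # white-noise field: spectrum flat between band averages
  set.seed(77)
  un <- array(stats::rnorm(nt * 4), dim = c(nt, 2, 2))
  spn <- averaged_velocity_psd(make_field(un, array(0, dim(un)), fs = fs))
  b1 <- mean(spn$psd[spn$frequencies > 300 & spn$frequencies < 1000])
  b2 <- mean(spn$psd[spn$frequencies > 1500 & spn$frequencies < 2200])
  expect_equal(b1 / b2, 1, tolerance = 0.25)

  expect_error(averaged_velocity_psd(f, seg_len = 10 * nt), "longer")
})

test_that("fundamental extraction picks the strongest in-band peak", {
  fs <- 5000; nt <- 2 * fs
  t <- (seq_len(nt) - 1L) / fs
  two <- 1.0 * sin(2 * pi * 225.7 * t) + 0.6 * sin(2 * pi * 150.5 * t)
  u <- array(rep(two, times = 9), dim = c(nt, 3, 3))
  sp <- averaged_velocity_psd(make_field(u, array(0, dim(u)), fs = fs))
  expect_equal(extract_fundamental(sp), 225.7, tolerance = sp$resolution)
  expect_error(extract_fundamental(sp, 2600, 3000), "empty")
})

test_that("subharmonic detection reports the fo/3 family and nothing else", {
  s <- generate_acoustic_signal(acoustic_config(fo = 225.7, duration = 1.5,
                                                subharmonic_fraction = 0.4,
                                                noise_level_db = -25, seed = 13L))
  w <- phonocouple:::welch_psd(s$samples, s$sample_rate, 16384L)
  sp <- phonocouple:::new_spectrum(w$frequencies, w$psd, w$resolution)
  det <- detect_subharmonics(sp, 225.7)
  expect_gt(nrow(det$subharmonics), 0L)
  # detections sit at 75.2 and 150.5 Hz within the bin width
  expect_true(any(abs(det$subharmonics[, "freq"] - 75.2) < 2 * sp$resolution))
  expect_true(any(abs(det$subharmonics[, "freq"] - 150.5) < 2 * sp$resolution))
  # every detection is an m fo / 3 with m not divisible by 3
  m <- round(3 * det$subharmonics[, "freq"] / 225.7)
  expect_true(all(m %% 3 != 0))

  # infinite prominence: nothing qualifies
  det_inf <- detect_subharmonics(sp, 225.7, prominence_db = Inf)
  expect_equal(nrow(det_inf$subharmonics), 0L)
})

test_that("SPL reproduces its closed forms and incoherent +3 dB addition", {
  fs <- 44100
  sq <- acoustic_signal(rep(c(1, -1), fs / 2), fs)     # p_rms = 1 Pa
  expect_equal(spl(sq), 20 * log10(1 / 20e-6), tolerance = 1e-10)
  expect_equal(spl(sq), 93.9794, tolerance = 1e-4)

  t <- (seq_len(fs) - 1L) / fs
  sine <- acoustic_signal(sin(2 * pi * 441 * t), fs)   # p_rms = 1/sqrt(2)
  expect_equal(spl(sine), 20 * log10(1 / sqrt(2) / 20e-6), tolerance = 1e-6)
  expect_equal(spl(sine), 90.9691, tolerance = 1e-3)

  # two incoherent equal-SPL noises add to +3.01 dB
  set.seed(99)
  a <- stats::rnorm(fs); b <- stats::rnorm(fs)
  gain <- spl(acoustic_signal(a + b, fs)) - spl(acoustic_signal(a, fs))
  expect_equal(gain, 3.01, tolerance = 0.1)
})

test_that("SNR and HNR recover configured ratios and cap on clean signals", {
  clean <- generate_acoustic_signal(acoustic_config(fo = 151.3, duration = 1,
                                                    noise_level_db = -Inf))
  r <- snr_hnr(clean, fo = 151.3)
  expect_equal(r$snr_db, 60)
  expect_equal(r$hnr_db, 60)

  for (ratio in c(0, 10, 20)) {
    s <- generate_acoustic_signal(acoustic_config(fo = 151.3, duration = 1.5,
                                                  noise_level_db = -ratio,
                                                  seed = 40L + ratio))
    r <- snr_hnr(s, fo = 151.3)
    expect_equal(r$snr_db, ratio, tolerance = 1)
    expect_equal(r$hnr_db, ratio, tolerance = 1)
  }
  expect_error(snr_hnr(clean, fo = 8000), "band")
})

test_that("cepstral analysis locates the voice period and tracks noise", {
  fs <- 44100
  t <- (seq_len(fs) - 1L) / fs
  pulses <- as.numeric((round(t * 150 * 1000) %% 1000) == 0)
  r <- cpp(acoustic_signal(pulses, fs))
  expect_equal(r$peak_quefrency, 1 / 150, tolerance = 2e-4)

  set.seed(3)
  wn <- acoustic_signal(stats::rnorm(fs), fs)
  expect_lt(cpp(wn)$cpp_db, 3)

  vals <- vapply(c(-30, -15, 0), function(nl) {
    s <- generate_acoustic_signal(acoustic_config(fo = 151.3, duration = 1,
                                                  noise_level_db = nl, seed = 7L))
    cpp(s)$cpp_db
  }, numeric(1))
  expect_true(all(diff(vals) < 0))

  short <- acoustic_signal(stats::rnorm(100), fs)
  expect_error(cpp(short), "too short")
})

test_that("vocal efficiency follows its spreading and power scalings", {
  expect_equal(vocal_efficiency(0, 1, 4208, 2e-3), 0)
  v1 <- vocal_efficiency(0.5, 1, 4208, 2e-3)
  expect_equal(vocal_efficiency(0.5, 2, 4208, 2e-3), 4 * v1)
  expect_equal(vocal_efficiency(0.5, 1, 4208, 4e-3), v1 / 2)
  expect_equal(vocal_efficiency(0.5, 1, 4208, 2e-3, spreading = "hemisphere"),
               v1 / 2)
  expect_error(vocal_efficiency(0.5, 1, 0, 2e-3), "positive")
})
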