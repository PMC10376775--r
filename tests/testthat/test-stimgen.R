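test_that("ERB bandwidth follows the Glasberg-Moore line", {
  expect_equal(erb_bandwidth(0), 24.7)
  expect_equal(erb_bandwidth(1), 132.639)
  expect_equal(erb_bandwidth(2.924), 24.7 * (4.37 * 2.924 + 1))
  expect_error(erb_bandwidth(-0.1), "non-negative")
})

test_that("masker frequencies are log-spaced with the closed-form count", {
  spec <- masker_spec(11)
  f <- masker_frequencies(spec)
  expect_length(f, floor(32 * log2(5000 / 239)) + 1)  # 141
  expect_length(f, 141)
  expect_equal(diff(log2(f)), rep(1 / 32, length(f) - 1))
  expect_true(all(f >= 239 & f <= 5000))

  oct <- spec
  oct$fpo <- 1; oct$freq_lo <- 250; oct$freq_hi <- 1000
  expect_equal(masker_frequencies(oct), c(250, 500, 1000))
})

test_that("density labels carry the printed miti/fpo pairings", {
  tab <- data.frame(d = c(11, 20, 28, 36), miti = c(200, 400, 600, 800),
                    fpo = c(32, 64, 96, 128))
  for (i in 1:4) {
    sp <- masker_spec(tab$d[i])
    expect_equal(sp$miti, tab$miti[i])
    expect_equal(sp$fpo, tab$fpo[i])
    expect_equal(sp$interval_max, 2 * sp$miti - sp$interval_min)
  }
  expect_error(masker_spec(15), "must be one of")
})

test_that("tone tracks are renewal processes with the configured mean gap", {
  spec <- masker_spec(11)
  spec$fpo <- 0.1  # single-frequency track
  set.seed(42)
  tones <- sample_tone_sequence(spec, trial_duration = 2100)
  expect_equal(length(unique(tones$frequency)), 1)
  gaps <- diff(tones$onset) * 1000
  expect_gt(length(gaps), 9000)
  expect_lt(abs(mean(gaps) - spec$miti), 3)           # law of large numbers
  expect_true(all(gaps >= spec$interval_min - 1e-9))
  expect_true(all(gaps <= spec$interval_max + 1e-9))
  expect_true(all(tones$onset + tones$duration_ms / 1000 <= 2100))
})

test_that("a degenerate uniform gives a strictly periodic track", {
  spec <- masker_spec(11)
  spec$fpo <- 0.1
  spec$interval_min <- spec$interval_max <- 200
  set.seed(1)
  tones <- sample_tone_sequence(spec, trial_duration = 20)
  expect_equal(diff(tones$onset), rep(0.2, nrow(tones) - 1))
  spec$interval_max <- 50
  expect_error(sample_tone_sequence(spec), "interval_max")
})

test_that("stimulus synthesis is reproducible under a seed", {
  t1 <- build_trial_stimulus(density = 20, seed = 7)
  t2 <- build_trial_stimulus(density = 20, seed = 7)
  expect_identical(t1$masker, t2$masker)
  expect_identical(render_waveform(t1), render_waveform(t2))
})

test_that("the protected region removes a closed two-ERB band", {
  tones <- tibble::tibble(onset = 0, frequency = c(800, 867.4, 867.3, 1000,
                                                   1132.6, 1132.7, 1200),
                          duration_ms = 20, ramp_ms = 10, amplitude = 1)
  erb <- erb_bandwidth(1)  # 132.639 -> band [867.361, 1132.639]
  kept <- apply_protected_region(tones, 1000)
  expect_true(all(kept$frequency < 1000 - erb | kept$frequency > 1000 + erb))
  expect_true(867.3 %in% kept$frequency)    # just outside
  expect_false(867.4 %in% kept$frequency)   # inside, removed
  expect_false(1000 %in% kept$frequency)
  # boundary tone exactly at the edge is removed (closed interval)
  edge <- tibble::tibble(onset = 0, frequency = 1000 + erb, duration_ms = 20,
                         ramp_ms = 10, amplitude = 1)
  expect_equal(nrow(apply_protected_region(edge, 1000)), 0)
  expect_equal(nrow(apply_protected_region(tones[0, ], 1000)), 0)
})

test_that("rendering produces ramped sines of the right support", {
  tone <- tibble::tibble(onset = 0.1, frequency = 1000, duration_ms = 100,
                         ramp_ms = 10, amplitude = 1)
  x <- render_waveform(tone, sr = 44100, duration = 0.5)
  nz <- which(x != 0)
  expect_equal(nz[length(nz)] - nz[1] + 1, 4410, tolerance = 2e-3)
  expect_equal(max(abs(x)), 10^(-1 / 20))
  # silence renders as zeros
  expect_equal(render_waveform(tone[0, ], sr = 44100, duration = 0.2),
               numeric(8820))
  # spectral peak sits at the tone frequency
  spec <- Mod(fft(x))^2
  f_axis <- (seq_along(spec) - 1) / length(spec) * 44100
  expect_equal(f_axis[which.max(spec[1:(length(spec) / 2)])], 1000,
               tolerance = 5)
})

test_that("no masker energy falls within one ERB of the target", {
  trial <- build_trial_stimulus(density = 36, target = target_spec(1000),
                                seed = 3)
  erb <- erb_bandwidth(1)
  expect_true(all(trial$masker$frequency < 1000 - erb |
                    trial$masker$frequency > 1000 + erb))
  # periodogram check on the rendered masker alone: the protected band holds
  # far less power density than the masker band average
  x <- render_waveform(trial$masker, sr = 44100, duration = 10)
  p <- Mod(fft(x))^2
  f_axis <- (seq_along(p) - 1) / length(p) * 44100
  inside <- f_axis > 1000 - erb + 30 & f_axis < 1000 + erb - 30
  outside <- (f_axis > 300 & f_axis < 1000 - erb - 30) |
    (f_axis > 1000 + erb + 30 & f_axis < 4800)
  expect_lt(mean(p[inside]), 0.05 * mean(p[outside]))
})

test_that("WAV round trip preserves samples to quantisation accuracy", {
  x <- render_waveform(build_trial_stimulus(seed = 1), duration = 0.4)
  f <- tempfile(fileext = ".wav")
  write_wav(x, f, sr = 44100)
  back <- read_wav(f)
  expect_equal(back$sr, 44100)
  expect_lt(max(abs(back$x - x)), 1 / 32000)
  sidecar <- tempfile(fileext = ".json")
  write_trial_sidecar(build_trial_stimulus(seed = 1), sidecar)
  meta <- jsonlite::read_json(sidecar)
  expect_equal(meta$seed, 1)
  unlink(c(f, sidecar))
})
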