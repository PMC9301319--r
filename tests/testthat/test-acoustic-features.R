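test_that("STFT frames satisfy the basic spectral contracts", {
  tone <- make_tone(1000, 0.3)
  fr <- analyze_frames(tone)
  binw <- tone$sample_rate / fr$nfft
  peak_freq <- fr$freq[apply(fr$mag, 2, which.max)]
  expect_true(all(abs(peak_freq - 1000) <= binw))
  # energy-probability rows sum to one
  P <- energy_probability(fr)
  expect_equal(unname(colSums(P)), rep(1, ncol(P)), tolerance = 1e-9)
  # appended silence gives near-zero-energy frames
  padded <- audio_stimulus(c(tone$samples, rep(0, 22050)), 44100)
  fr2 <- analyze_frames(padded)
  tail_frames <- fr2$times > 0.35
  expect_lt(max(fr2$rms[tail_frames]), 1e-6)
  expect_error(analyze_frames(audio_stimulus(rnorm(100), 44100)), "window")
})

test_that("Parseval: spectral energy matches windowed time-domain energy", {
  a <- make_noise(0.1, seed = 61)
  fr <- analyze_frames(a)
  # reconstruct one frame by hand
  x <- a$samples[1:fr$win_len] * fr$window
  spec_energy <- sum(Mod(fft(c(x, rep(0, fr$nfft - fr$win_len))))^2) / fr$nfft
  expect_equal(spec_energy, sum(x^2), tolerance = 1e-9)
})

test_that("pure tone: centroid and roll-off at the tone, tiny flatness", {
  tone <- make_tone(440, 0.5)
  fr <- analyze_frames(tone)
  sp <- spectral_descriptors(fr)
  binw <- 44100 / fr$nfft
  mid <- fr$times > 0.1 & fr$times < 0.4
  expect_lt(abs(mean(sp$spectral_centroid[mid]) - 440), binw)
  expect_lt(abs(mean(sp$spectral_rolloff[mid]) - 440), binw)
  expect_lte(mean(sp$spectral_flatness[mid]), 0.1)
})

test_that("white noise: high flatness, low crest relative to a tone", {
  noise <- make_noise(0.5, seed = 62)
  spn <- spectral_descriptors(analyze_frames(noise))
  spt <- spectral_descriptors(analyze_frames(make_tone(440, 0.5)))
  expect_gte(mean(spn$spectral_flatness), 0.9)
  expect_lt(mean(spn$spectral_crest), mean(spt$spectral_crest))
})

test_that("two equal-power tones have their centroid at the midpoint", {
  t <- (0:22049) / 44100
  two <- audio_stimulus(sin(2 * pi * 400 * t) + sin(2 * pi * 800 * t), 44100)
  fr <- analyze_frames(two)
  sp <- spectral_descriptors(fr)
  binw <- 44100 / fr$nfft
  expect_lt(abs(mean(sp$spectral_centroid, na.rm = TRUE) - 600), binw)
})

test_that("shape descriptors are scale invariant, energies quadratic", {
  a <- synth_dyad(dyad_spec(noise_fraction = 0.2, duration_s = 0.3,
                            seed = 63))
  b <- a
  b$samples <- 0.25 * a$samples
  fa <- analyze_frames(a); fb <- analyze_frames(b)
  sa <- spectral_descriptors(fa); sb <- spectral_descriptors(fb)
  for (col in c("spectral_centroid", "spectral_flatness",
                "spectral_rolloff", "spectral_skewness",
                "spectral_kurtosis", "spectral_crest", "spectral_flux"))
    expect_equal(sa[[col]], sb[[col]], tolerance = 1e-8)
  expect_equal(sb$rms_energy, 0.25 * sa$rms_energy, tolerance = 1e-10)
  ha <- harmonic_descriptors(fa); hb <- harmonic_descriptors(fb)
  expect_equal(hb$noisiness, ha$noisiness, tolerance = 1e-6)
  expect_equal(hb$harmonic_energy, 0.0625 * ha$harmonic_energy,
               tolerance = 1e-6)
  ta <- temporal_descriptors(a); tb <- temporal_descriptors(b)
  expect_equal(ta$series$zero_crossing_rate, tb$series$zero_crossing_rate)
  expect_equal(ta$scalars[["attack_time"]], tb$scalars[["attack_time"]])
})

test_that("roll-off is nondecreasing in the energy threshold", {
  a <- synth_dyad(dyad_spec(noise_fraction = 0.3, duration_s = 0.3,
                            seed = 64))
  fr <- analyze_frames(a)
  r85 <- spectral_descriptors(fr, rolloff_threshold = 0.85)$spectral_rolloff
  r95 <- spectral_descriptors(fr, rolloff_threshold = 0.95)$spectral_rolloff
  r99 <- spectral_descriptors(fr, rolloff_threshold = 0.99)$spectral_rolloff
  expect_true(all(r85 <= r95 & r95 <= r99))
})

test_that("duller synthesis slopes strictly lower the mean centroid", {
  cms <- sapply(c(0.5, 1, 1.5, 2, 2.5), function(sl) {
    a <- synth_dyad(dyad_spec(spectral_slope_a = sl, spectral_slope_b = sl,
                              duration_s = 0.3, seed = 65))
    mean(spectral_descriptors(analyze_frames(a))$spectral_centroid,
         na.rm = TRUE)
  })
  expect_true(all(diff(cms) < 0))
})

test_that("harmonic/noise split tracks the synthesized noise fraction", {
  for (nf in c(0, 0.25, 0.5)) {
    a <- synth_dyad(dyad_spec(noise_fraction = nf, duration_s = 1,
                              seed = 66))
    fr <- analyze_frames(a)
    h <- harmonic_descriptors(fr)
    sus <- fr$times > 0.2 & fr$times < 0.8
    expect_lt(abs(mean(h$noisiness[sus]) - nf), 0.05)
  }
})

test_that("energy split is conservative and noisiness bounded", {
  a <- synth_dyad(dyad_spec(noise_fraction = 0.4, duration_s = 0.3,
                            seed = 67))
  fr <- analyze_frames(a)
  h <- harmonic_descriptors(fr)
  tot <- colSums(fr$mag^2)
  ok <- tot > 0
  expect_equal(h$harmonic_energy[ok] + h$noisiness_energy[ok], tot[ok],
               tolerance = 1e-9)
  expect_true(all(h$noisiness[ok] >= 0 & h$noisiness[ok] <= 1))
})

test_that("single-partial voice gives the degenerate tristimulus", {
  a <- synth_dyad(dyad_spec(f0_a = 440, f0_b = 440, n_harmonics = 1,
                            duration_s = 0.3, seed = 68))
  fr <- analyze_frames(a)
  h <- harmonic_descriptors(fr)
  mid <- fr$times > 0.1 & fr$times < 0.25
  expect_equal(mean(h$tristimulus[mid]), 1, tolerance = 1e-6)
  expect_equal(mean(h$tristimulus3[mid]), 0, tolerance = 1e-9)
  # no even partial -> odd/even undefined
  expect_true(all(is.na(h$odd_even_ratio[mid])))
})

test_that("pure noise yields no partials and noisiness near one", {
  noise <- make_noise(0.3, seed = 69)
  h <- harmonic_descriptors(analyze_frames(noise))
  expect_gt(mean(h$noisiness), 0.85)
  expect_lt(mean(h$n_partials), 3)
})

test_that("temporal descriptors match their threshold definitions", {
  # 100 Hz sine: 200 crossings/s
  td <- temporal_descriptors(make_tone(100, 1))
  expect_equal(unname(td$global["zero_crossing_rate"]), 200,
               tolerance = 0.02)
  expect_equal(mean(td$series$zero_crossing_rate), 200, tolerance = 0.02)
  # 100 ms linear attack ramp: 10->90% spans 80 ms
  t <- (0:44099) / 44100
  ramp <- audio_stimulus(pmin(t / 0.1, 1) * sin(2 * pi * 500 * t), 44100)
  tdr <- temporal_descriptors(ramp)
  expect_lt(abs(tdr$scalars[["attack_time"]] - 0.08), 0.01)
  expect_equal(tdr$scalars[["log_attack_time"]],
               log10(tdr$scalars[["attack_time"]]))
  # rectangular 2 s envelope: effective duration 2 s
  rect <- make_tone(300, 2)
  expect_lt(abs(temporal_descriptors(rect)$scalars[["effective_duration"]]
                - 2), 0.05)
  expect_error(temporal_descriptors(audio_stimulus(rep(0, 1000), 44100)),
               "silent")
})

test_that("feature vector has exactly the 45 canonical statistics", {
  expect_length(feature_names(), 45)
  expect_equal(anyDuplicated(feature_names()), 0L)
  a <- synth_dyad(dyad_spec(noise_fraction = 0.2, duration_s = 0.3,
                            seed = 70))
  fv <- extract_features(a)
  expect_length(fv, 45)
  expect_named(fv, feature_names())
  expect_true(all(is.finite(unclass(fv))))
  expect_true(fv[["noisiness_mean"]] >= 0 && fv[["noisiness_mean"]] <= 1)
  expect_true(all(fv[grep("_iqr$", names(fv))] >= 0))
})

test_that("summary statistics follow the fixed quartile convention", {
  spec <- data.frame(time = 1:100)
  for (pn in timbrefuse:::FRAME_PARAMS) spec[[pn]] <- 1:100
  spectral_cols <- c("spectral_centroid", "spectral_spread",
                     "spectral_skewness", "spectral_kurtosis",
                     "spectral_decrease", "spectral_rolloff",
                     "spectral_flatness", "spectral_crest",
                     "spectral_flux", "rms_energy")
  sp <- spec[c("time", spectral_cols)]
  harm <- spec[c("time", "harmonic_energy", "noisiness_energy",
                 "tristimulus", "harmonic_spectral_deviation",
                 "odd_even_ratio", "noisiness")]
  temporal <- list(
    series = spec[c("time", "temporal_centroid", "zero_crossing_rate")],
    scalars = setNames(as.numeric(1:9), timbrefuse:::NOTE_PARAMS))
  fv <- summarize_features(sp, harm, temporal)
  expect_equal(unname(fv[["spectral_centroid_mean"]]), 50.5)
  expect_equal(unname(fv[["spectral_centroid_iqr"]]), 49.5)
  # constant series: IQR 0, mean the constant
  harm2 <- harm
  harm2$noisiness <- 0.3
  fv2 <- summarize_features(sp, harm2, temporal)
  expect_equal(unname(fv2[["noisiness_mean"]]), 0.3)
  expect_equal(unname(fv2[["noisiness_iqr"]]), 0)
})

test_that("screening reproduces the 216 -> 54 -> 45 rule", {
  a <- synth_dyad(dyad_spec(noise_fraction = 0.1, duration_s = 0.25,
                            seed = 71))
  full <- extract_features(a, full = TRUE)
  expect_length(full, 216)
  set.seed(72)
  stats216 <- matrix(rnorm(40 * 216), 40, 216,
                     dimnames = list(NULL, names(full)))
  target <- rnorm(40)
  stats216[, "harmonic_energy__mean"] <- target     # perfect predictor
  out <- suppressWarnings(screen_features(stats216, target))
  expect_length(out$retained_54, 54)
  expect_length(out$retained_45, 45)
  expect_equal(out$ranking$statistic[1], "harmonic_energy__mean")
  expect_equal(out$ranking$abs_r[1], 1)
  # the 45 are the 54 minus the per-note IQRs
  expect_setequal(setdiff(out$retained_54, out$retained_45),
                  paste0(timbrefuse:::NOTE_PARAMS, "__iqr"))
})

test_that("noise-only candidates rarely correlate with the target", {
  set.seed(73)
  x <- matrix(rnorm(500 * 100), 500, 100,
              dimnames = list(NULL, paste0("p", 1:100, "__mean")))
  out <- screen_features(x, rnorm(500))
  expect_gte(mean(out$ranking$abs_r < 0.1), 0.95)
})
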