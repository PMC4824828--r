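test_that("cue parameter draws respect the stressed/unstressed contracts", {
  withr::local_seed(11)
  for (i in 1:50) {
    u <- draw_cue_params(stressed = FALSE)
    expect_equal(u$f0_start, 194)
    expect_equal(u$f0_peak, 194)
    expect_true(u$duration >= 0.3 && u$duration <= 0.4)
    expect_true(u$rms_target >= 0.0316 && u$rms_target <= 0.0447)
    expect_equal(u$vowel_mode, "reduced")
    s <- draw_cue_params(stressed = TRUE)
    expect_equal(s$f0_start, 194)
    expect_true(s$f0_peak >= 230 && s$f0_peak <= 280)
    expect_equal(s$duration, 0.5)
    expect_equal(s$rms_target, 0.1)
    expect_equal(s$vowel_mode, "full")
  }
})

test_that("random cue values are uniform over their printed intervals", {
  withr::local_seed(21)
  dur <- replicate(1e4, draw_cue_params(FALSE)$duration)
  expect_gte(min(dur), 0.3)
  expect_lte(max(dur), 0.4)
  ks <- suppressWarnings(stats::ks.test(dur, "punif", 0.3, 0.4))
  expect_gt(ks$p.value, 0.01)
  peaks <- replicate(1e3, draw_cue_params(TRUE)$f0_peak)
  ks2 <- suppressWarnings(stats::ks.test(peaks, "punif", 230, 280))
  expect_gt(ks2$p.value, 0.01)
})

test_that("cue removal neutralizes exactly the targeted cues", {
  withr::local_seed(3)
  s <- draw_cue_params(TRUE)
  u <- draw_cue_params(FALSE)
  pr <- apply_manipulation(s, u, "pitch_removed")
  expect_equal(pr$stressed$f0_peak, 194)
  expect_equal(pr$unstressed$f0_peak, 194)
  expect_equal(pr$stressed$duration, s$duration)     # other cues intact
  expect_equal(pr$stressed$rms_target, s$rms_target)
  expect_equal(pr$unstressed$vowel_mode, "reduced")
  dr <- apply_manipulation(s, u, "duration_removed")
  expect_equal(dr$stressed$duration, 0.5)
  expect_equal(dr$unstressed$duration, 0.5)
  ar <- apply_manipulation(s, u, "amplitude_removed")
  expect_equal(ar$unstressed$rms_target, 0.1)
  vr <- apply_manipulation(s, u, "vowel_removed")
  expect_equal(vr$unstressed$vowel_mode, "full")
  # identity
  none <- apply_manipulation(s, u, "none")
  expect_identical(none$stressed, s)
  expect_identical(none$unstressed, u)
  expect_error(apply_manipulation(s, u, "loudness_removed"))
})

test_that("X_only equals composing the three complementary removals", {
  withr::local_seed(4)
  s <- draw_cue_params(TRUE)
  u <- draw_cue_params(FALSE)
  only <- apply_manipulation(s, u, "amplitude_only")
  step <- apply_manipulation(s, u, "vowel_removed")
  step <- apply_manipulation(step$stressed, step$unstressed,
                             "pitch_removed")
  step <- apply_manipulation(step$stressed, step$unstressed,
                             "duration_removed")
  expect_identical(only, step)
})

test_that("manipulations are idempotent and commute across distinct cues", {
  withr::local_seed(5)
  s <- draw_cue_params(TRUE)
  u <- draw_cue_params(FALSE)
  singles <- c("pitch_removed", "duration_removed", "amplitude_removed",
               "vowel_removed")
  for (m in manipulation_labels()) {
    once <- apply_manipulation(s, u, m)
    twice <- apply_manipulation(once$stressed, once$unstressed, m)
    expect_identical(twice, once)
  }
  for (a in singles) {
    for (b in setdiff(singles, a)) {
      ab <- apply_manipulation(s, u, a)
      ab <- apply_manipulation(ab$stressed, ab$unstressed, b)
      ba <- apply_manipulation(s, u, b)
      ba <- apply_manipulation(ba$stressed, ba$unstressed, a)
      expect_identical(ab, ba)
    }
  }
})

test_that("RMS and attenuation measures match closed forms", {
  sr <- 44100
  expect_equal(measure_rms(waveform(rep(0.1, 1000), sr)), 0.1)
  t <- seq(0, 1, length.out = sr)
  expect_equal(measure_rms(waveform(sin(2 * pi * 100 * t), sr)),
               1 / sqrt(2), tolerance = 1e-3)
  expect_error(measure_rms(waveform(numeric(0), sr)), "empty")
  expect_equal(rms_to_db_attenuation(0.1, 0.1), 0)
  expect_equal(rms_to_db_attenuation(0.1, 0.0316), 10, tolerance = 0.005)
  expect_equal(rms_to_db_attenuation(0.1, 0.0447), 7, tolerance = 0.007)
  expect_error(rms_to_db_attenuation(0, 0.1), "positive")
})

test_that("f0 tracker recovers a known tone and flags silence", {
  sr <- 44100
  t <- seq(0, 0.5, length.out = sr / 2)
  tone <- waveform(0.5 * sin(2 * pi * 194 * t), sr)
  f <- estimate_f0(tone)
  expect_true(all(f$voiced))
  expect_true(all(abs(f$f0 - 194) < 1))
  sil <- estimate_f0(waveform(numeric(sr / 4), sr))
  expect_false(any(sil$voiced))
})

test_that("synthesized syllables honour duration, RMS and pitch contracts", {
  withr::local_seed(6)
  sr <- 44100
  for (syl in c("pu", "na", "zi", "ke", "to", "ji", "lu", "de")) {
    s <- draw_cue_params(TRUE)
    w <- synthesize_syllable(syl, s, sr)
    expect_equal(length(w$samples), round(0.5 * sr))
    expect_equal(measure_rms(w), 0.1, tolerance = 0.01)
    expect_lt(max(abs(w$samples)), 1)
    u <- draw_cue_params(FALSE)
    wu <- synthesize_syllable(syl, u, sr)
    expect_equal(length(wu$samples), round(u$duration * sr))
    expect_equal(measure_rms(wu), u$rms_target, tolerance = 0.01)
    f <- estimate_f0(wu, frame_s = 0.02)
    expect_equal(median(f$f0[f$voiced]), 194, tolerance = 2)
  }
})

test_that("stressed pitch ramps to its drawn peak at syllable end", {
  withr::local_seed(7)
  for (i in 1:5) {
    s <- draw_cue_params(TRUE)
    w <- synthesize_syllable("vo", s)
    f <- estimate_f0(w, frame_s = 0.02)
    fv <- f$f0[f$voiced]
    terminal <- fv[length(fv)]
    expect_gt(terminal, 230 - 3)
    expect_lt(terminal, 280 + 3)
    expect_equal(terminal, s$f0_peak, tolerance = 5 / s$f0_peak)
    # contour starts near the 194 Hz baseline
    expect_lt(min(fv), 205)
  }
})

test_that("too-short durations for the consonant onset are rejected", {
  p <- stress_cue_params(194, 194, 0.05, 0.05, "reduced")
  expect_error(synthesize_syllable("pu", p), "too short")
})

test_that("word synthesis concatenates syllables with no silence", {
  withr::local_seed(8)
  sr <- 44100
  st <- synthesize_word("puvo", "trochaic")
  u_dur <- st$syllable_params[[2]]$duration
  expect_true(u_dur >= 0.3 && u_dur <= 0.4)
  expect_equal(length(st$audio$samples), round(0.5 * sr) + round(u_dur * sr))
  # duration removed forces both syllables to 0.5 s
  di <- synthesize_word("puvo", "iambic", "duration_removed")
  expect_equal(length(di$audio$samples), sr, tolerance = 2 / sr)
  # identical parameter draws land in swapped slots under the two patterns
  params <- list(stressed = draw_cue_params(TRUE),
                 unstressed = draw_cue_params(FALSE))
  tro <- synthesize_word("puvo", "trochaic", params = params)
  iam <- synthesize_word("puvo", "iambic", params = params)
  expect_identical(tro$syllable_params[[1]], iam$syllable_params[[2]])
  expect_identical(tro$syllable_params[[2]], iam$syllable_params[[1]])
})

test_that("WAV files round-trip through the PCM writer", {
  withr::local_seed(9)
  w <- synthesize_syllable("mi", draw_cue_params(FALSE))
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(w, path)
  back <- read_wav(path)
  expect_equal(back$sample_rate, 44100)
  expect_equal(length(back$samples), length(w$samples))
  expect_lt(max(abs(back$samples - w$samples)), 1e-4)  # 16-bit step
})

test_that("seeded banks are bit-identical and match their manifests", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  man1 <- write_stimulus_bank(training_sets[[1]], seed = 7, dir = d1)
  man2 <- write_stimulus_bank(training_sets[[1]], seed = 7, dir = d2)
  expect_equal(nrow(man1), 24L)  # 12 words x 2 patterns
  expect_identical(man1, man2)
  sums1 <- tools::md5sum(file.path(d1, man1$filename))
  sums2 <- tools::md5sum(file.path(d2, man2$filename))
  expect_identical(unname(sums1), unname(sums2))
  # parameter recovery on a subset of files
  for (i in c(1L, 7L, 13L, 24L)) {
    w <- read_wav(file.path(d1, man1$filename[i]))
    expect_equal(length(w$samples),
                 round(man1$duration1[i] * 44100) +
                   round(man1$duration2[i] * 44100))
    n1 <- round(man1$duration1[i] * 44100)
    s1 <- waveform(w$samples[1:n1], 44100)
    s2 <- waveform(w$samples[(n1 + 1):length(w$samples)], 44100)
    expect_equal(measure_rms(s1), man1$rms1[i], tolerance = 0.011)
    expect_equal(measure_rms(s2), man1$rms2[i], tolerance = 0.011)
  }
})

test_that("cue probe bank holds 3 exemplars per manipulation per pattern", {
  withr::local_seed(10)
  bank <- cue_probe_bank(training_sets[[1]])
  expect_equal(nrow(bank), 48L)
  counts <- table(bank$manipulation, bank$pattern)
  expect_true(all(counts == 3L))
  expect_setequal(rownames(counts),
                  setdiff(manipulation_labels(), "none"))
  expect_false(anyDuplicated(bank$stimulus_id) > 0)
})
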