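test_that("autocorrelation tracking recovers a known F0 within 1 Hz", {
  w <- audio_from_spec(2, 0, f0_mean = 120, seed = 1, noise_rms = 0)
  fr <- analyze_frames(w$samples, w$sample_rate)
  expect_gt(mean(fr$voiced), 0.9)
  expect_lt(max(abs(fr$f0_hz[fr$voiced] - 120)), 1)
})

test_that("silence and noise are not voiced", {
  fr <- analyze_frames(rep(0, 16000), 16000)
  expect_true(fr$no_speech)
  expect_equal(sum(fr$voiced), 0)

  set.seed(4)
  frn <- analyze_frames(rnorm(32000) * 0.1, 16000)
  expect_lt(mean(frn$voiced), 0.10)
})

test_that("an F0 glide spans its endpoints", {
  # rising pulse rate: pulse times from integrating f(t) = 100 + 50 t over 2 s
  sr <- 16000
  tk <- 0; times <- c()
  while (tk < 2) { times <- c(times, tk); tk <- tk + 1 / (100 + 50 * tk) }
  x <- numeric(2 * sr)
  pt <- (0:63) / sr
  shape <- exp(-pt / 0.0016) * sin(2 * pi * 500 * pt)
  for (tt in times) {
    i0 <- ceiling(tt * sr) + 1
    idx <- i0:min(length(x), i0 + 63)
    x[idx] <- x[idx] + 0.4 * shape[seq_along(idx)]
  }
  fr <- analyze_frames(x, sr)
  f0 <- fr$f0_hz[fr$voiced]
  expect_lt(abs(min(f0) - 100), 5)
  expect_lt(abs(max(f0) - 200), 5)
})

test_that("timing features reproduce constructed pause arithmetic", {
  # 10 s span: frames 1..1000, pauses at frames 201-350 and 601-750 (3 s)
  db <- rep(-20, 1000)
  db[c(201:350, 601:750)] <- -60
  tm <- timing_features(make_frames(db))
  expect_equal(tm$speaking_duration_s, 10)
  expect_equal(tm$ppt_pct, 30)
  expect_equal(tm$articulation_duration_s, 7)

  # no sub-threshold run of >= 0.2 s: ppt 0
  db2 <- rep(-20, 1000)
  db2[seq(100, 900, by = 50)] <- -60  # isolated silent frames
  expect_equal(timing_features(make_frames(db2))$ppt_pct, 0)
})

test_that("percent pause time is invariant to pause placement", {
  set.seed(7)
  base_ppt <- NULL
  for (rep in 1:5) {
    # 4 pauses of 0.5 s each in a 20 s stream, random non-adjacent starts
    db <- rep(-20, 2000)
    starts <- sort(sample(seq(100, 1800, by = 120), 4))
    for (s in starts) db[s:(s + 49)] <- -60
    ppt <- timing_features(make_frames(db))$ppt_pct
    if (is.null(base_ppt)) base_ppt <- ppt
    expect_equal(ppt, base_ppt, tolerance = 1e-9)
  }
  expect_equal(base_ppt, 100 * 2 / 20, tolerance = 0.11)
})

test_that("local jitter matches its hand-computed definition", {
  # perfectly periodic: zero jitter
  expect_equal(jitter_local(rep(0.008, 50)), 0)
  # alternating 8.0 / 8.4 ms periods
  p <- rep(c(0.0080, 0.0084), 25)
  expect_equal(jitter_local(p), 100 * 0.0004 / 0.0082, tolerance = 1e-6)
  # reversal symmetry
  set.seed(1)
  q <- 0.008 * (1 + 0.02 * rnorm(40))
  expect_equal(jitter_local(q), jitter_local(rev(q)))
  # region boundaries: no differences across regions
  expect_equal(jitter_local(list(rep(0.008, 10), rep(0.009, 10))),
               0, tolerance = 1e-9)
})

test_that("frequency features go missing below the voiced-frame floor", {
  w <- audio_from_spec(0.08, 0, f0_mean = 150, seed = 2, noise_rms = 0)
  fr <- analyze_frames(w$samples, w$sample_rate)
  expect_lt(sum(fr$voiced), 10)
  fq <- frequency_features(fr)
  expect_true(all(is.na(unlist(fq))))
})

test_that("shimmer, HNR and SNR behave on constructed signals", {
  # constant-amplitude periodic signal: shimmer ~ 0
  w <- audio_from_spec(2, 0, f0_mean = 140, seed = 3, noise_rms = 0)
  fr <- analyze_frames(w$samples, w$sample_rate)
  eq <- energy_quality_features(fr)
  expect_lt(eq$shimmer_pct, 0.1)
  # noiseless harmonic signal: high HNR
  expect_gte(eq$hnr_db, 30)
  # no pauses: SNR missing
  expect_true(is.na(eq$snr_db))

  # speech power 100x pause power by construction -> SNR = 20 dB
  db <- rep(10 * log10(0.01), 1000)          # speech frame power 0.01
  db[301:500] <- 10 * log10(0.0001)          # pause frame power 0.0001
  cfg <- acoustic_config(silence_db = 15)
  fr2 <- make_frames(db, voiced = c(rep(TRUE, 300), rep(FALSE, 200),
                                    rep(TRUE, 500)))
  fr2$r_peak <- ifelse(fr2$voiced, 0.9, NA)
  eq2 <- energy_quality_features(fr2, cfg)
  expect_equal(eq2$snr_db, 20, tolerance = 1e-9)
})

test_that("scale and reversal invariances hold for the acoustic measures", {
  w <- audio_from_spec(3, 0.3, f0_mean = 150, jitter_pct = 1.5,
                       shimmer_pct = 4, seed = 5)
  a <- speech_features(w$samples, w$sample_rate)
  b <- speech_features(w$samples * 0.2, w$sample_rate)
  for (m in c("ppt", "jitter", "shimmer", "hnr", "snr")) {
    expect_equal(unname(a[m]), unname(b[m]), tolerance = 1e-6, label = m)
  }
})

test_that("estimates recover generator settings within 5% on 20 vowels", {
  set.seed(42)
  for (i in 1:20) {
    f0 <- runif(1, 100, 220)
    j <- runif(1, 0.5, 3)
    s <- runif(1, 2, 8)
    w <- audio_from_spec(3, 0, f0_mean = f0, jitter_pct = j,
                         shimmer_pct = s, seed = i, noise_rms = 0)
    fr <- analyze_frames(w$samples, w$sample_rate)
    fq <- frequency_features(fr)
    eq <- energy_quality_features(fr)
    expect_lt(abs(fq$f0_mean_hz - f0) / f0, 0.05)
    expect_lt(abs(fq$jitter_pct - j) / j, 0.05)
    expect_lt(abs(eq$shimmer_pct - s) / s, 0.05)
  }
})

test_that("per-task speech featurization handles absent and silent audio", {
  dir <- withr::local_tempdir()
  rows <- manifest_row("P1", "S1")
  w <- audio_from_spec(4, 0.3, f0_mean = 180, seed = 6)
  dir.create(file.path(dir, "s"))
  write_wav(w$samples, w$sample_rate, file.path(dir, "s", "hope.wav"))
  rows$hope_audio <- "s/hope.wav"
  write_manifest_fixture(dir, rows)
  cohort <- read_cohort(file.path(dir, "manifest.csv"))
  fm <- featurize_speech(cohort)
  expect_s3_class(fm, "feature_matrix")
  expect_false(is.na(fm$values["S1", "hope.ppt"]))
  # all other tasks are missing
  expect_true(all(is.na(fm$values["S1", grep("^fear", fm$feature_names)])))
})
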