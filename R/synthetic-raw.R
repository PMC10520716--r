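#' Configuration for the raw synthetic-cohort generator
#'
#' Defaults emulate the study conditions of a dialog-system interview
#' cohort: 68 participants of whom 5 return for a second session (73
#' sessions), session-level case prevalences 15/73, 21/73 and 26/73 for
#' depression, anxiety and suicide risk, a heavily female sample, seven
#' interview tasks totalling about 9.3 minutes, and roughly 925 transcript
#' words per session. Group effects are planted at the generator-parameter
#' level: depressed and at-risk speakers pause more, anxious speakers move
#' the lower face less.
#'
#' @param n_participants,n_repeat Cohort size and repeat-session count.
#' @param prevalence Session-level case prevalences (named).
#' @param sex_prob Probabilities for female/male/unreported.
#' @param task_durations Named mean response durations in seconds (defaults
#'   total 558 s = 9.3 min; the read sentence and warm-up are short).
#' @param words_per_second Transcript word rate (defaults to ~925 words per
#'   9.3 min session).
#' @param sample_rate Audio sampling rate (Hz).
#' @param frame_rate Landmark frame rate (Hz).
#' @param pause_fraction Baseline pause fraction of a response.
#' @param pause_shift_depression,pause_shift_suicide Added pause fraction
#'   for cases (planted speech effect).
#' @param amplitude_mult_anxiety Multiplier on articulation amplitude for
#'   anxiety cases (planted facial effect; < 1 = reduced movement).
#' @param vocab_odds Odds multiplier for condition-specific case terms in
#'   case transcripts.
#' @param task_skip_prob Probability a task is skipped entirely (drives
#'   feature missingness).
#' @param seed Random seed.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 68, n_repeat = 5,
                          prevalence = c(depression = 15 / 73,
                                         anxiety = 21 / 73,
                                         suicide_risk = 26 / 73),
                          sex_prob = c(female = 0.765, male = 0.22,
                                       unreported = 0.015),
                          task_durations = c(sit = 6, warmup = 40,
                                             hope = 102, secrets = 102,
                                             anger = 103, fear = 103,
                                             emotional_pain = 102),
                          words_per_second = 925 / 558,
                          sample_rate = 16000, frame_rate = 30,
                          pause_fraction = 0.25,
                          pause_shift_depression = 0.08,
                          pause_shift_suicide = 0.06,
                          amplitude_mult_anxiety = 0.7,
                          vocab_odds = 3,
                          task_skip_prob = 0.02,
                          seed = 1L) {
  stopifnot(all(prevalence > 0 & prevalence < 1),
            all(task_durations > 0), pause_fraction < 1)
  structure(as.list(environment()), class = "cohort_config")
}

#' Synthesize a speech-like waveform with known acoustic properties
#'
#' Source-filter surrogate for a spoken response: a glottal pulse train
#' (damped-sinusoid pulses at a slowly modulated F0) interrupted by pauses,
#' plus a low noise floor. Jitter and shimmer are planted as alternating
#' period/amplitude perturbations sized so the realized local jitter and
#' shimmer equal the requested percentages. F0 modulation is sinusoidal
#' with SD `f0_sd`. Responses begin and end with speech; every pause is
#' long enough to be detectable.
#'
#' @param duration_s Total response duration (s).
#' @param pause_fraction Fraction of the response spent in pauses `[0, 1)`.
#' @param f0_mean,f0_sd Fundamental frequency mean and SD (Hz).
#' @param jitter_pct,shimmer_pct Planted local jitter/shimmer (%).
#' @param sample_rate Sampling rate (Hz).
#' @param noise_rms RMS of additive noise during speech (0 = noiseless).
#' @param pause_noise_rms Noise floor during pauses.
#' @param seed Optional seed (set it for reproducible phase/noise).
#' @return List: `samples`, `sample_rate`.
#' @export
audio_from_spec <- function(duration_s, pause_fraction = 0.25,
                            f0_mean = 160, f0_sd = 0, jitter_pct = 0,
                            shimmer_pct = 0, sample_rate = 16000,
                            noise_rms = 1e-4, pause_noise_rms = 1e-3,
                            seed = NULL) {
  if (pause_fraction >= 1) stop("pause_fraction must be < 1")
  stopifnot(duration_s > 0, f0_mean > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * sample_rate)
  x <- numeric(n)
  # speech/pause layout: pauses of ~0.8 s interleaved between speech runs
  pause_total <- pause_fraction * duration_s
  n_pause <- if (pause_total > 0) max(1L, round(pause_total / 0.8)) else 0L
  speech_total <- duration_s - pause_total
  n_speech <- n_pause + 1L
  seg_lens <- numeric(0)
  seg_speech <- logical(0)
  for (i in seq_len(n_speech)) {
    seg_lens <- c(seg_lens, speech_total / n_speech)
    seg_speech <- c(seg_speech, TRUE)
    if (i <= n_pause) {
      seg_lens <- c(seg_lens, pause_total / n_pause)
      seg_speech <- c(seg_speech, FALSE)
    }
  }
  seg_start <- cumsum(c(0, seg_lens[-length(seg_lens)]))
  f_mod <- 0.4
  phase <- stats::runif(1, 0, 2 * pi)
  f0_at <- function(t) f0_mean + f0_sd * sqrt(2) * sin(2 * pi * f_mod * t + phase)
  # jitter/shimmer are planted as a deterministic period-4 perturbation
  # cycle (+1, +1, -1, -1): the realized local jitter/shimmer equal the
  # requested percentages exactly (mean |consecutive difference| equals the
  # cycle amplitude), consecutive periods misalign less than periods two
  # apart (so pitch tracking prefers T over 2T), and the 4T subharmonic
  # lies outside the F0 search range for vowel F0.
  cyc <- c(1, 1, -1, -1)
  dj <- jitter_pct / 100
  ds <- shimmer_pct / 100
  fc <- 500; tau <- 0.0016
  # truncate each pulse well below one period (smooth fade on the last
  # 20%) so pulse tails neither reach the next pulse peak nor leak
  # period-dependent energy into per-cycle amplitude windows
  pulse_dur <- min(0.008, 0.55 / (f0_mean + 1.6 * f0_sd))
  pulse_len <- max(8L, round(pulse_dur * sample_rate))
  pt <- (seq_len(pulse_len) - 1) / sample_rate
  fade <- rep(1, pulse_len)
  ramp <- seq_len(max(2L, round(0.2 * pulse_len)))
  fade[pulse_len - rev(ramp) + 1L] <-
    0.5 * (1 + cos(pi * ramp / length(ramp)))
  k <- 0L
  for (s in which(seg_speech)) {
    t0 <- seg_start[s]; t1 <- t0 + seg_lens[s]
    tk <- t0 + 0.002
    while (tk < t1 - 0.004) {
      ck <- cyc[k %% 4L + 1L]
      amp <- 0.4 * (1 + ck * ds)
      # render the pulse at fractional-sample precision, starting at the
      # first sample grid point at or after the pulse onset
      i0 <- ceiling(tk * sample_rate) + 1L
      offset <- (i0 - 1) / sample_rate - tk
      shape <- exp(-(pt + offset) / tau) * sin(2 * pi * fc * (pt + offset)) * fade
      idx <- i0:min(n, i0 + pulse_len - 1L)
      x[idx] <- x[idx] + amp * shape[seq_along(idx)]
      period <- (1 / f0_at(tk)) * (1 + ck * dj)
      tk <- tk + period
      k <- k + 1L
    }
  }
  if (noise_rms > 0 || pause_noise_rms > 0) {
    noise <- stats::rnorm(n)
    lvl <- rep(noise_rms, n)
    for (s in which(!seg_speech)) {
      i0 <- max(1L, floor(seg_start[s] * sample_rate) + 1L)
      i1 <- min(n, floor((seg_start[s] + seg_lens[s]) * sample_rate))
      lvl[i0:i1] <- pause_noise_rms
    }
    x <- x + noise * lvl
  }
  list(samples = x, sample_rate = sample_rate)
}

# smoothed (band-limited) standard noise of length n, unit SD
bandlimited_noise <- function(n, frame_rate, cutoff_hz = 3) {
  w <- max(1L, round(frame_rate / (2 * cutoff_hz)))
  z <- stats::rnorm(n + 2 * w)
  sm <- stats::filter(z, rep(1 / (2 * w + 1), 2 * w + 1), sides = 2)
  sm <- as.numeric(sm)[(w + 1):(w + n)]
  sm[is.na(sm)] <- 0
  s <- stats::sd(sm)
  if (is.na(s) || s == 0) rep(0, n) else sm / s
}

#' Synthesize a facial landmark track with known motion properties
#'
#' Builds a pixel-coordinate 14-keypoint track over a plausible face: a
#' constant geometry plus mild global translation drift and slow zoom (to
#' exercise canthal normalization), band-limited lower-lip/jaw motion
#' scaled by `articulation_amplitude` (normalized units of vertical
#' excursion SD), `round(blink_rate * duration)` scheduled blinks (eyelid
#' dips of ~0.2 s at jittered regular times), and a slow eyebrow raise
#' cycle.
#'
#' @param duration_s Track duration (s).
#' @param frame_rate Frames per second (>= 15).
#' @param articulation_amplitude SD of lower-lip vertical motion in
#'   inter-canthal units (0 = static articulators).
#' @param blink_rate Blinks per second.
#' @param eyebrow_amplitude Eyebrow raise amplitude (normalized units).
#' @param point_noise_px Per-frame white jitter on every keypoint (pixels).
#' @param seed Optional seed.
#' @return A [landmark_track()] in pixel coordinates.
#' @export
landmarks_from_spec <- function(duration_s, frame_rate = 30,
                                articulation_amplitude = 0.05,
                                blink_rate = 0.3,
                                eyebrow_amplitude = 0.02,
                                point_noise_px = 0.3, seed = NULL) {
  stopifnot(frame_rate >= 15, duration_s > 0)
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration_s, by = 1 / frame_rate)
  nf <- length(t)
  icd <- 66  # pixel inter-canthal distance at zoom 1
  base <- list(
    right_inner_canthus = c(-33, 0), left_inner_canthus = c(33, 0),
    right_upper_eyelid = c(-45, -6), right_lower_eyelid = c(-45, 6),
    left_upper_eyelid = c(45, -6), left_lower_eyelid = c(45, 6),
    right_eyebrow_center = c(-45, -25), left_eyebrow_center = c(45, -25),
    mouth_corner_right = c(-25, 60), mouth_corner_left = c(25, 60),
    upper_lip_center = c(0, 52), lower_lip_center = c(0, 68),
    jaw_center = c(0, 85), chin_base = c(0, 100))
  # mild global drift: translation (slow, small) + zoom about the center
  drift_x <- 3 * sin(2 * pi * 0.02 * t)
  drift_y <- 3 * cos(2 * pi * 0.017 * t)
  zoom <- 1 + 0.05 * sin(2 * pi * 0.03 * t)
  lip_dy <- articulation_amplitude * icd * bandlimited_noise(nf, frame_rate)
  jaw_dy <- 0.6 * lip_dy +
    0.2 * articulation_amplitude * icd * bandlimited_noise(nf, frame_rate)
  upper_dy <- -0.2 * lip_dy
  brow_dy <- -eyebrow_amplitude * icd *
    (0.5 + 0.5 * sin(2 * pi * 0.1 * t))
  # blink profile: cosine dips to 10% opening over ~0.2 s
  blink_scale <- rep(1, nf)
  n_blinks <- round(blink_rate * duration_s)
  if (n_blinks > 0) {
    centers <- (seq_len(n_blinks) - 0.5) / n_blinks * duration_s +
      stats::runif(n_blinks, -0.2, 0.2)
    half <- 0.1
    for (bc in centers) {
      idx <- which(abs(t - bc) <= half)
      blink_scale[idx] <- pmin(blink_scale[idx],
                               0.1 + 0.9 * (abs(t[idx] - bc) / half)^2)
    }
  }
  xy <- matrix(0, nf, 28, dimnames = list(NULL, track_columns()))
  for (role in names(base)) {
    px <- base[[role]][1]
    py <- rep(base[[role]][2], nf)
    if (role == "lower_lip_center") py <- py + lip_dy
    if (role == "upper_lip_center") py <- py + upper_dy
    if (role == "jaw_center") py <- py + jaw_dy
    if (role == "chin_base") py <- py + 0.8 * jaw_dy
    if (role %in% c("right_eyebrow_center", "left_eyebrow_center")) {
      py <- py + brow_dy
    }
    if (role %in% c("right_upper_eyelid", "left_upper_eyelid")) {
      py <- 0 - 6 * blink_scale
    }
    if (role %in% c("right_lower_eyelid", "left_lower_eyelid")) {
      py <- 0 + 6 * blink_scale
    }
    xy[, role_x(role)] <- px * zoom + drift_x +
      stats::rnorm(nf, 0, point_noise_px)
    xy[, role_y(role)] <- py * zoom + drift_y +
      stats::rnorm(nf, 0, point_noise_px)
  }
  landmark_track(t, xy)
}

# condition-specific vocabulary for transcript synthesis
synthetic_vocabulary <- function() {
  base <- c("i", "you", "the", "a", "and", "to", "of", "it", "that", "is",
            "was", "my", "me", "have", "had", "feel", "felt", "think",
            "know", "like", "just", "really", "about", "when", "with",
            "for", "not", "but", "so", "im", "its", "dont", "on", "in",
            "they", "them", "things", "people", "time", "day", "week",
            "work", "home", "family", "friends", "life", "good", "bad",
            "better", "hard", "lot", "little", "sometimes", "always",
            "never", "maybe", "because", "would", "could", "want", "need",
            "talk", "said", "say", "going", "been", "get", "got", "make",
            "much", "more", "still", "even", "now", "then", "school",
            "money", "year", "well", "right", "some", "this", "very",
            "one", "her", "his", "at", "these", "those", "keep", "told")
  list(base = base,
       depression = c("tired", "empty", "sad", "hopeless", "heavy",
                      "alone", "nothing", "sleep", "numb", "unable"),
       anxiety = c("anxious", "worry", "nervous", "heart", "racing",
                   "panic", "tense", "overwhelmed", "mad", "sensitive"),
       suicide_risk = c("pain", "escape", "burden", "fear", "end",
                        "secret", "trapped", "worthless", "cry", "loss"))
}

sample_transcript <- function(n_words, case_states, vocab_odds) {
  v <- synthetic_vocabulary()
  words <- c(v$base, v$depression, v$anxiety, v$suicide_risk)
  w <- c(2 / seq_along(v$base) + 0.3, rep(0.3, 30))
  for (cond in names(case_states)) {
    if (isTRUE(case_states[[cond]])) {
      idx <- match(v[[cond]], words)
      w[idx] <- w[idx] * vocab_odds
    }
  }
  paste(sample(words, n_words, TRUE, prob = w), collapse = " ")
}

#' Generate a complete synthetic cohort directory
#'
#' Writes a full on-disk cohort in the layout the readers expect:
#' `manifest.csv`, per-session task WAVs ([audio_from_spec()]), landmark
#' CSVs ([landmarks_from_spec()]) and transcripts, plus
#' `ground_truth.json` with the per-participant condition states and
#' generator parameters for recovery tests. Group effects: depression and
#' suicide-risk cases get a higher pause fraction; anxiety cases get
#' reduced articulation amplitude; case transcripts over-sample
#' condition-specific terms. Output is byte-deterministic given
#' `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created; must not already contain a
#'   manifest).
#' @return The cohort directory path, invisibly; side effect: files.
#' @export
generate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "cohort_config"))
  sim <- simulate_feature_cohort(
    n_participants = config$n_participants, n_repeat = config$n_repeat,
    prevalence = config$prevalence,
    n_features = c(speech = 1, facial = 1),  # metadata only; raw files below
    missing_rate = 0, seed = config$seed)
  sessions <- sim$sessions
  sessions$sex <- NULL
  # resample sex with configured probabilities (participant level)
  set.seed(config$seed + 1L)
  pid <- unique(sessions$participant_id)
  sex_pp <- sample(names(config$sex_prob), length(pid), TRUE,
                   prob = config$sex_prob)
  sessions$sex <- sex_pp[match(sessions$participant_id, pid)]
  labels <- sim$labels
  dir.create(file.path(out_dir, "sessions"), recursive = TRUE,
             showWarnings = FALSE)
  tasks <- names(config$task_durations)
  for (kind in c("audio", "landmarks", "transcript")) {
    for (task in tasks) sessions[[paste(task, kind, sep = "_")]] <- ""
  }
  f0_base <- ifelse(sex_pp == "male", 120, 200)
  names(f0_base) <- pid
  for (i in seq_len(nrow(sessions))) {
    sid <- sessions$session_id[i]
    sdir <- file.path(out_dir, "sessions", sid)
    dir.create(sdir, showWarnings = FALSE)
    st <- list(depression = labels$depression[i],
               anxiety = labels$anxiety[i],
               suicide_risk = labels$suicide_risk[i])
    pf <- config$pause_fraction +
      config$pause_shift_depression * st$depression +
      config$pause_shift_suicide * st$suicide_risk
    amp <- 0.05 * ifelse(st$anxiety, config$amplitude_mult_anxiety, 1)
    f0 <- f0_base[sessions$participant_id[i]] + stats::rnorm(1, 0, 10)
    for (task in tasks) {
      if (stats::runif(1) < config$task_skip_prob) next
      dur <- max(3, stats::rnorm(1, config$task_durations[[task]],
                                 0.15 * config$task_durations[[task]]))
      wav <- audio_from_spec(dur, pause_fraction = min(pf, 0.6),
                             f0_mean = f0, f0_sd = 8, jitter_pct = 1,
                             shimmer_pct = 5,
                             sample_rate = config$sample_rate)
      apath <- file.path("sessions", sid, paste0(task, "_audio.wav"))
      write_wav(wav$samples, wav$sample_rate, file.path(out_dir, apath))
      sessions[[paste0(task, "_audio")]][i] <- apath
      track <- landmarks_from_spec(dur, frame_rate = config$frame_rate,
                                   articulation_amplitude = amp,
                                   blink_rate = 0.3)
      lpath <- file.path("sessions", sid, paste0(task, "_landmarks.csv"))
      write_landmark_track(track, file.path(out_dir, lpath))
      sessions[[paste0(task, "_landmarks")]][i] <- lpath
      n_words <- max(5, round(dur * config$words_per_second *
                                stats::runif(1, 0.85, 1.15)))
      tpath <- file.path("sessions", sid, paste0(task, "_transcript.txt"))
      writeLines(sample_transcript(n_words, st, config$vocab_odds),
                 file.path(out_dir, tpath))
      sessions[[paste0(task, "_transcript")]][i] <- tpath
    }
  }
  write_cohort(sessions, file.path(out_dir, "manifest.csv"))
  gt <- list(
    participant_state = lapply(sim$ground_truth$participant_state,
                               function(s) pid[s]),
    generator = list(pause_fraction = config$pause_fraction,
                     pause_shift_depression = config$pause_shift_depression,
                     pause_shift_suicide = config$pause_shift_suicide,
                     amplitude_mult_anxiety = config$amplitude_mult_anxiety,
                     vocab_odds = config$vocab_odds,
                     case_terms = synthetic_vocabulary()[
                       c("depression", "anxiety", "suicide_risk")],
                     seed = config$seed))
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
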