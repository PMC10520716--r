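#' Acoustic analysis configuration
#'
#' Extraction settings for the clinical-voice featurizer. Defaults follow
#' common clinical-voice conventions: 10 ms frame step, analysis window of
#' three longest pitch periods, F0 search range 75-500 Hz, pause threshold
#' 25 dB below the task median intensity, 200 ms minimum pause.
#'
#' @param step Frame step in seconds.
#' @param window Analysis window length in seconds (default `3 / f0_min`).
#' @param f0_min,f0_max F0 search range in Hz.
#' @param voicing_threshold Minimum normalized autocorrelation peak for a
#'   frame to count as voiced.
#' @param silence_db A frame is silent if its intensity is more than this
#'   many dB below the task median intensity.
#' @param min_pause_s Minimum duration of a sub-threshold interval to count
#'   as a pause.
#' @param min_voiced_frames Minimum voiced frames required before F0
#'   statistics are reported (fewer: features are returned missing).
#' @return List of class `acoustic_config`.
#' @export
acoustic_config <- function(step = 0.010, window = NULL,
                            f0_min = 75, f0_max = 500,
                            voicing_threshold = 0.45,
                            silence_db = 25, min_pause_s = 0.2,
                            min_voiced_frames = 10) {
  if (is.null(window)) window <- 3 / f0_min
  stopifnot(step > 0, window > 0, f0_min > 0, f0_max > f0_min,
            silence_db > 0, min_pause_s > 0)
  structure(list(step = step, window = window, f0_min = f0_min,
                 f0_max = f0_max, voicing_threshold = voicing_threshold,
                 silence_db = silence_db, min_pause_s = min_pause_s,
                 min_voiced_frames = min_voiced_frames),
            class = "acoustic_config")
}

# normalized autocorrelation of one (mean-subtracted) frame over a lag range.
# r(tau) = sum x[1:(N-tau)] x[(tau+1):N] / sqrt(sum x[1:(N-tau)]^2 sum x[(tau+1):N]^2)
frame_autocorr <- function(x, lag_min, lag_max) {
  n <- length(x)
  lag_max <- min(lag_max, n - 2L)
  n2 <- stats::nextn(2L * n, 2)
  f <- stats::fft(c(x, rep(0, n2 - n)))
  ac <- Re(stats::fft(Mod(f)^2, inverse = TRUE)) / n2
  cs <- cumsum(x^2)
  lags <- lag_min:lag_max
  denom <- sqrt(cs[n - lags] * (cs[n] - cs[lags]))
  r <- ifelse(denom > 0, ac[lags + 1] / denom, 0)
  list(lags = lags, r = r)
}

#' Frame-level acoustic analysis
#'
#' Segments a mono waveform into overlapping frames and computes per-frame
#' RMS intensity, a voicing decision and fundamental frequency by the
#' normalized-autocorrelation method (peak location refined by parabolic
#' interpolation), then locates glottal pulse peaks inside voiced regions to
#' obtain the period and per-period peak-amplitude sequences used for
#' jitter, shimmer and HNR.
#'
#' @param samples Numeric waveform in `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz (>= 16000 recommended).
#' @param cfg An [acoustic_config()].
#' @return Object of class `speech_frames`: `frame_times` (frame centers,
#'   s), `intensity_db`, `voiced`, `f0_hz` (NA where unvoiced), `r_peak`
#'   (autocorrelation at the pitch lag), `pulses` (list per voiced region of
#'   `times` and `amps`), `step`, `sample_rate`, and `no_speech` (TRUE for
#'   empty or all-silent input — returned instead of an error).
#' @export
analyze_frames <- function(samples, sample_rate, cfg = acoustic_config()) {
  stopifnot(is.numeric(samples), sample_rate > 0)
  win_n <- max(16L, round(cfg$window * sample_rate))
  step_n <- max(1L, round(cfg$step * sample_rate))
  n <- length(samples)
  empty <- function() {
    structure(list(frame_times = numeric(0), intensity_db = numeric(0),
                   voiced = logical(0), f0_hz = numeric(0),
                   r_peak = numeric(0), pulses = list(), step = cfg$step,
                   sample_rate = sample_rate, no_speech = TRUE),
              class = "speech_frames")
  }
  if (n < win_n) return(empty())
  starts <- seq.int(1L, n - win_n + 1L, by = step_n)
  centers <- (starts - 1 + win_n / 2) / sample_rate
  lag_min <- max(2L, floor(sample_rate / cfg$f0_max))
  lag_max <- ceiling(sample_rate / cfg$f0_min)
  nf <- length(starts)
  rms <- numeric(nf); f0 <- rep(NA_real_, nf); rpk <- rep(NA_real_, nf)
  voiced <- logical(nf)
  for (i in seq_len(nf)) {
    xf <- samples[starts[i]:(starts[i] + win_n - 1L)]
    rms[i] <- sqrt(mean(xf^2))
    if (rms[i] <= 0) next
    xf <- xf - mean(xf)
    if (sum(xf^2) <= 0) next
    acr <- frame_autocorr(xf, lag_min - 1L, lag_max + 1L)
    interior <- which(acr$lags >= lag_min & acr$lags <= lag_max)
    rmax <- max(acr$r[interior])
    # octave preference: among near-maximal lags take the shortest, so an
    # exactly periodic signal resolves to its fundamental, not a multiple
    j <- interior[which(acr$r[interior] >= rmax - 0.015)[1]]
    r0 <- acr$r[j]
    if (is.finite(r0) && r0 > cfg$voicing_threshold) {
      rm1 <- acr$r[j - 1L]; rp1 <- acr$r[j + 1L]
      denom <- rm1 - 2 * r0 + rp1
      d <- if (is.finite(denom) && abs(denom) > 1e-12) {
        max(-0.5, min(0.5, 0.5 * (rm1 - rp1) / denom))
      } else 0
      lag_star <- acr$lags[j] + d
      voiced[i] <- TRUE
      f0[i] <- sample_rate / lag_star
      rpk[i] <- min(r0 - 0.25 * (rm1 - rp1) * d, 1 - 1e-6)
    }
  }
  # amplitude gate: voiced frames must carry signal (relative floor keeps
  # the analysis scale-invariant; digital silence stays unvoiced)
  floor_rms <- 1e-4 * max(rms)
  voiced <- voiced & rms > floor_rms
  f0[!voiced] <- NA_real_
  rpk[!voiced] <- NA_real_
  if (!any(rms > 0)) return(empty())
  intensity_db <- 20 * log10(pmax(rms, 1e-10))
  pulses <- find_pulses(samples, sample_rate, centers, voiced, f0, cfg)
  structure(list(frame_times = centers, intensity_db = intensity_db,
                 voiced = voiced, f0_hz = f0, r_peak = rpk,
                 pulses = pulses, step = cfg$step,
                 sample_rate = sample_rate, no_speech = !any(voiced)),
            class = "speech_frames")
}

#' @export
print.speech_frames <- function(x, ...) {
  cat(sprintf("speech_frames: %d frames (%.2f s), %.0f%% voiced%s\n",
              length(x$frame_times),
              if (length(x$frame_times)) max(x$frame_times) else 0,
              100 * mean(x$voiced), if (x$no_speech) " [no speech]" else ""))
  invisible(x)
}

# pulse picking: within each voiced run, walk outward from the strongest
# |sample|, stepping by the local pitch period and snapping to the local
# extremum. Returns a list per region of pulse times and peak amplitudes.
find_pulses <- function(samples, sample_rate, centers, voiced, f0, cfg) {
  runs <- rle(voiced)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  min_run <- 3L
  for (k in which(runs$values & runs$lengths >= min_run)) {
    fr <- starts[k]:ends[k]
    t0 <- centers[fr[1]] - cfg$window / 2
    t1 <- centers[fr[length(fr)]] + cfg$window / 2
    a <- max(1L, floor(t0 * sample_rate) + 1L)
    b <- min(length(samples), ceiling(t1 * sample_rate))
    if (b - a < 8L) next
    seg <- samples[a:b]
    period_at <- function(tt) {
      f <- stats::approx(centers[fr], f0[fr], xout = tt, rule = 2)$y
      1 / f
    }
    seed <- which.max(abs(seg))
    walk <- function(from, dir) {
      pk <- integer(0)
      cur <- from
      repeat {
        tp <- period_at((a + cur - 2) / sample_rate) * sample_rate
        lo <- round(cur + dir * 0.7 * tp)
        hi <- round(cur + dir * 1.3 * tp)
        if (dir < 0) { tmp <- lo; lo <- hi; hi <- tmp }
        if (lo < 1L || hi > length(seg)) break
        nxt <- (lo:hi)[which.max(abs(seg[lo:hi]))]
        pk <- c(pk, nxt)
        cur <- nxt
      }
      pk
    }
    idx <- sort(unique(c(rev(walk(seed, -1L)), seed, walk(seed, 1L))))
    if (length(idx) < 3L) next
    cyc <- cycle_measures(seg, idx)
    out[[length(out) + 1L]] <- list(times = (a + idx - 2) / sample_rate,
                                    periods = cyc$periods / sample_rate,
                                    amps = cyc$amps)
  }
  out
}

# per-cycle period and amplitude measurement by waveform matching: the
# period between pulses k and k+1 is the lag maximizing the
# cross-correlation of a one-period window around pulse k with itself
# shifted (parabolic sub-sample refinement); the per-period amplitude is
# the RMS of that window. Both are nearly insensitive to where the sample
# grid falls within the cycle, unlike raw peak picking.
cycle_measures <- function(seg, idx) {
  n <- length(seg)
  # discard spurious picks (weak tail/noise peaks, typically at region
  # edges): amplitude far below the typical pulse peak
  amp0 <- abs(seg[idx])
  idx <- idx[amp0 >= 0.3 * stats::median(amp0)]
  if (length(idx) < 3L) return(list(periods = numeric(0), amps = numeric(0)))
  med_lag <- stats::median(diff(idx))
  k <- length(idx) - 1L
  periods <- rep(NA_real_, k)
  amps <- rep(NA_real_, length(idx))
  # fixed window half-width across the region: a varying window would let
  # period fluctuations bleed into the RMS amplitudes
  m <- max(4L, floor(0.45 * stats::median(diff(idx))))
  for (i in seq_len(k)) {
    lag0 <- idx[i + 1L] - idx[i]
    if (lag0 < 0.7 * med_lag || lag0 > 1.3 * med_lag) next
    lo <- idx[i] - m; hi <- idx[i] + m
    if (lo < 1L || hi + lag0 + 2L > n) next
    w <- seg[lo:hi]
    cc <- vapply(-2:2, function(d) sum(w * seg[(lo + lag0 + d):(hi + lag0 + d)]),
                 numeric(1))
    j <- which.max(cc)
    d <- 0
    if (j > 1 && j < 5) {
      den <- cc[j - 1] - 2 * cc[j] + cc[j + 1]
      if (is.finite(den) && abs(den) > 1e-300) {
        d <- max(-0.5, min(0.5, 0.5 * (cc[j - 1] - cc[j + 1]) / den))
      }
    }
    periods[i] <- lag0 + (-2:2)[j] + d
    amps[i] <- sqrt(mean(w^2))
  }
  # amplitude for the final pulse
  lo <- idx[length(idx)] - m; hi <- min(n, idx[length(idx)] + m)
  if (lo >= 1L) amps[length(idx)] <- sqrt(mean(seg[lo:hi]^2))
  list(periods = periods[!is.na(periods)], amps = amps[!is.na(amps)])
}

# pause segmentation shared by timing and SNR: silent frames are those more
# than cfg$silence_db below the median frame intensity; pauses are silent
# runs of at least min_pause_s inside the response span.
segment_pauses <- function(frames, cfg) {
  db <- frames$intensity_db
  nf <- length(db)
  if (nf == 0) stop("empty task")
  thr <- stats::median(db) - cfg$silence_db
  silent <- db < thr
  active <- which(!silent)
  if (length(active) == 0) stop("empty task")
  span_idx <- active[1]:active[length(active)]
  min_frames <- max(1L, round(cfg$min_pause_s / frames$step))
  in_pause <- logical(nf)
  runs <- rle(silent[span_idx])
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  for (k in which(runs$values & runs$lengths >= min_frames)) {
    in_pause[span_idx[starts[k]:ends[k]]] <- TRUE
  }
  span_s <- (length(span_idx)) * frames$step
  list(silent = silent, in_pause = in_pause, span_idx = span_idx,
       speaking_duration_s = span_s,
       pause_s = sum(in_pause) * frames$step)
}

#' Timing features: speaking duration, articulation duration, percent pause time
#'
#' Speech/pause segmentation by intensity threshold. The response span
#' (first to last supra-threshold frame) is the speaking duration; pauses
#' are sub-threshold intervals of at least `min_pause_s` inside the span;
#' articulation duration is speaking duration minus total pause time; PPT is
#' the pause share of the speaking duration in percent, so PPT and the
#' articulated fraction sum to 100%.
#'
#' @param frames A [analyze_frames()] result.
#' @param cfg An [acoustic_config()].
#' @return Named list: `speaking_duration_s`, `articulation_duration_s`,
#'   `ppt_pct`.
#' @export
timing_features <- function(frames, cfg = acoustic_config()) {
  if (frames$no_speech && length(frames$frame_times) == 0) stop("empty task")
  seg <- segment_pauses(frames, cfg)
  sp <- seg$speaking_duration_s
  pa <- seg$pause_s
  list(speaking_duration_s = sp,
       articulation_duration_s = sp - pa,
       ppt_pct = 100 * pa / sp)
}

#' Local jitter of a period sequence
#'
#' `100 * mean(|T_i - T_(i-1)|) / mean(T_i)` over consecutive glottal
#' periods. Accepts a numeric vector or a list of vectors (periods from
#' separate voiced regions; differences are never taken across regions).
#'
#' @param periods Numeric vector or list of numeric vectors (seconds).
#' @return Jitter in percent (NA if fewer than 2 periods).
#' @export
jitter_local <- function(periods) {
  if (!is.list(periods)) periods <- list(periods)
  periods <- lapply(periods, function(p) p[is.finite(p) & p > 0])
  diffs <- unlist(lapply(periods, function(p) if (length(p) > 1) abs(diff(p))))
  all_p <- unlist(periods)
  if (length(diffs) == 0 || length(all_p) == 0) return(NA_real_)
  100 * mean(diffs) / mean(all_p)
}

#' Local shimmer of a peak-amplitude sequence
#'
#' `100 * mean(|A_i - A_(i-1)|) / mean(A_i)` over consecutive period peak
#' amplitudes (same convention as [jitter_local()]).
#'
#' @param amps Numeric vector or list of numeric vectors (linear amplitude).
#' @return Shimmer in percent (NA if fewer than 2 amplitudes).
#' @export
shimmer_local <- function(amps) jitter_local(amps)

#' Frequency-domain features: F0 statistics and jitter
#'
#' F0 mean/max/min/standard deviation over voiced frames and local jitter
#' from the pulse period sequence. If fewer than `cfg$min_voiced_frames`
#' frames are voiced all outputs are NA (missing), to be handled by the
#' missing-data policy downstream.
#'
#' @inheritParams timing_features
#' @return Named list: `f0_mean_hz`, `f0_max_hz`, `f0_min_hz`, `f0_std_hz`,
#'   `jitter_pct`.
#' @export
frequency_features <- function(frames, cfg = acoustic_config()) {
  f0 <- frames$f0_hz[frames$voiced]
  if (length(f0) < cfg$min_voiced_frames) {
    return(list(f0_mean_hz = NA_real_, f0_max_hz = NA_real_,
                f0_min_hz = NA_real_, f0_std_hz = NA_real_,
                jitter_pct = NA_real_))
  }
  periods <- lapply(frames$pulses, function(p) p$periods)
  list(f0_mean_hz = mean(f0), f0_max_hz = max(f0), f0_min_hz = min(f0),
       f0_std_hz = stats::sd(f0), jitter_pct = jitter_local(periods))
}

#' Energy and voice-quality features: shimmer, HNR, SNR
#'
#' Local shimmer from per-period peak amplitudes; harmonics-to-noise ratio
#' as `10 log10(r / (1 - r))` with `r` the normalized autocorrelation at the
#' pitch-period lag, averaged over voiced frames; SNR as
#' `10 log10(speech power / pause power)` over the intensity-based
#' speech/pause segmentation. SNR is NA when no pause is detected.
#'
#' @inheritParams timing_features
#' @return Named list: `shimmer_pct`, `hnr_db`, `snr_db`.
#' @export
energy_quality_features <- function(frames, cfg = acoustic_config()) {
  if (!any(frames$voiced)) {
    return(list(shimmer_pct = NA_real_, hnr_db = NA_real_, snr_db = NA_real_))
  }
  amps <- lapply(frames$pulses, function(p) p$amps)
  r <- pmin(pmax(frames$r_peak[frames$voiced], 1e-6), 1 - 1e-6)
  hnr <- mean(10 * log10(r / (1 - r)))
  seg <- segment_pauses(frames, cfg)
  pow <- 10^(frames$intensity_db / 10)  # frame power up to a constant
  speech_frames <- seq_along(pow) %in% seg$span_idx & !seg$in_pause
  snr <- if (any(seg$in_pause)) {
    10 * log10(mean(pow[speech_frames]) / mean(pow[seg$in_pause]))
  } else NA_real_
  list(shimmer_pct = shimmer_local(amps), hnr_db = hnr, snr_db = snr)
}

speech_measures <- function() {
  c("speaking_duration", "articulation_duration", "ppt",
    "f0_mean", "f0_max", "f0_min", "f0_sd", "jitter",
    "shimmer", "hnr", "snr")
}

#' All speech features for one task response
#'
#' @param samples Mono waveform.
#' @param sample_rate Sampling rate (Hz).
#' @param cfg An [acoustic_config()].
#' @return Named numeric vector over [speech_measures()]; all NA when the
#'   response contains no speech.
#' @export
speech_features <- function(samples, sample_rate, cfg = acoustic_config()) {
  out <- stats::setNames(rep(NA_real_, length(speech_measures())),
                         speech_measures())
  frames <- analyze_frames(samples, sample_rate, cfg)
  if (frames$no_speech) return(out)
  tm <- timing_features(frames, cfg)
  fq <- frequency_features(frames, cfg)
  eq <- energy_quality_features(frames, cfg)
  out["speaking_duration"] <- tm$speaking_duration_s
  out["articulation_duration"] <- tm$articulation_duration_s
  out["ppt"] <- tm$ppt_pct
  out["f0_mean"] <- fq$f0_mean_hz
  out["f0_max"] <- fq$f0_max_hz
  out["f0_min"] <- fq$f0_min_hz
  out["f0_sd"] <- fq$f0_std_hz
  out["jitter"] <- fq$jitter_pct
  out["shimmer"] <- eq$shimmer_pct
  out["hnr"] <- eq$hnr_db
  out["snr"] <- eq$snr_db
  out
}

#' Speech feature matrix for a cohort
#'
#' Reads each session's per-task WAV files and assembles the
#' sessions-by-features speech matrix; absent files or failed extractions
#' become missing entries.
#'
#' @param cohort An `mhs_cohort` from [read_cohort()].
#' @param cfg An [acoustic_config()].
#' @param tasks Tasks to featurize (default all canonical tasks).
#' @return A [feature_matrix()] with modality `"speech"` and feature names
#'   `<task>.<measure>`.
#' @export
featurize_speech <- function(cohort, cfg = acoustic_config(),
                             tasks = canonical_tasks()) {
  sessions <- cohort$sessions
  feats <- as.vector(t(outer(tasks, speech_measures(), paste, sep = ".")))
  values <- matrix(NA_real_, nrow(sessions), length(feats),
                   dimnames = list(sessions$session_id, feats))
  for (i in seq_len(nrow(sessions))) {
    for (task in tasks) {
      p <- sessions[[paste0(task, "_audio")]][i]
      if (is.na(p) || !nzchar(p) || !file.exists(p)) next
      wav <- read_wav(p)
      v <- speech_features(wav$samples, wav$sample_rate, cfg)
      values[i, paste(task, names(v), sep = ".")] <- v
    }
  }
  feature_matrix(values, sessions$session_id, feats, "speech")
}
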