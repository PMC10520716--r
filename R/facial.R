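#' Facial analysis configuration
#'
#' @param blink_fraction A blink candidate frame has eye opening below this
#'   fraction of the rolling-median opening.
#' @param min_blink_frames Minimum frames for a dip to count as a blink.
#' @param max_blink_s Maximum blink duration in seconds.
#' @param median_window_s Rolling-median window for the blink baseline.
#' @param max_gap_frames Derivatives are not computed across gaps of more
#'   than this many invalid frames; the track is segmented instead.
#' @param smooth_window Optional moving-average window (frames) applied to
#'   coordinates before differentiation; 0 disables smoothing. Jerk from raw
#'   30 fps landmarks amplifies noise, so real-data analyses may want 3-5.
#' @return List of class `facial_config`.
#' @export
facial_config <- function(blink_fraction = 0.5, min_blink_frames = 2L,
                          max_blink_s = 0.5, median_window_s = 2,
                          max_gap_frames = 5L, smooth_window = 0L) {
  structure(list(blink_fraction = blink_fraction,
                 min_blink_frames = as.integer(min_blink_frames),
                 max_blink_s = max_blink_s,
                 median_window_s = median_window_s,
                 max_gap_frames = as.integer(max_gap_frames),
                 smooth_window = as.integer(smooth_window)),
            class = "facial_config")
}

#' Normalize a landmark track by the inter-canthal distance
#'
#' Divides every coordinate, per frame, by the Euclidean distance between
#' the right and left inner canthus, removing variability due to position
#' and distance from the camera. After normalization the inter-canthal
#' distance is identically 1. Frames with a degenerate canthal distance are
#' masked invalid.
#'
#' @param track A [landmark_track()] in pixel coordinates.
#' @param eps Degeneracy threshold on the canthal distance.
#' @return The normalized track (`normalized = TRUE`).
#' @export
normalize_track <- function(track, eps = 1e-9) {
  icd <- point_dist(role_point(track, "right_inner_canthus"),
                    role_point(track, "left_inner_canthus"))
  bad <- !is.finite(icd) | icd < eps
  icd[bad] <- 1
  track$xy <- track$xy / icd
  track$valid <- track$valid & !bad
  track$normalized <- TRUE
  track
}

# shoelace area of a polygon given vertex matrices (n_frames x 2 each),
# vectorized over frames; returns signed area
shoelace_signed <- function(...) {
  pts <- list(...)
  k <- length(pts)
  s <- 0
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    s <- s + pts[[i]][, 1] * pts[[j]][, 2] - pts[[j]][, 1] * pts[[i]][, 2]
  }
  s / 2
}

#' Per-frame mouth geometry
#'
#' Computes, on a canthal-normalized track: lip aperture (upper to lower
#' lip center distance), lip width (corner to corner), mouth surface area
#' (shoelace area of the quadrilateral left corner - upper center - right
#' corner - lower center), the left/right half areas obtained by splitting
#' that quadrilateral along the upper-lower lip-center segment, and the
#' left/right half-area symmetry ratio. Frames where the quadrilateral is
#' self-intersecting (the two triangle areas do not add up to the total, a
#' landmark glitch) are masked.
#'
#' @param track A normalized [landmark_track()].
#' @return data.frame per frame: `t`, `lip_aperture`, `lip_width`,
#'   `mouth_area`, `half_area_left`, `half_area_right`, `symmetry`, `valid`.
#' @export
mouth_geometry <- function(track) {
  if (!track$normalized) track <- normalize_track(track)
  up <- role_point(track, "upper_lip_center")
  lo <- role_point(track, "lower_lip_center")
  cl <- role_point(track, "mouth_corner_left")
  cr <- role_point(track, "mouth_corner_right")
  aperture <- point_dist(up, lo)
  width <- point_dist(cl, cr)
  area <- abs(shoelace_signed(cl, up, cr, lo))
  half_l <- abs(shoelace_signed(cl, up, lo))
  half_r <- abs(shoelace_signed(cr, up, lo))
  consistent <- abs(area - (half_l + half_r)) <= 1e-9 + 1e-6 * pmax(area, 1e-12)
  degenerate <- area <= 1e-12  # closed mouth: area 0, symmetry undefined
  valid <- track$valid & (consistent | degenerate)
  symmetry <- ifelse(half_r > 1e-12, half_l / half_r, NA_real_)
  data.frame(t = track$t, lip_aperture = aperture, lip_width = width,
             mouth_area = area, half_area_left = half_l,
             half_area_right = half_r, symmetry = symmetry, valid = valid)
}

# split valid frames into runs not interrupted by > max_gap invalid frames
valid_segments <- function(valid, max_gap) {
  idx <- which(valid)
  if (length(idx) == 0) return(list())
  brk <- c(0L, which(diff(idx) > max_gap + 1L), length(idx))
  lapply(seq_len(length(brk) - 1L),
         function(k) idx[(brk[k] + 1L):brk[k + 1L]])
}

central_diff <- function(t, p) {
  n <- length(t)
  if (n < 3) return(list(t = numeric(0), d = matrix(numeric(0), 0, ncol(p))))
  i <- 2:(n - 1)
  dt <- t[i + 1] - t[i - 1]
  list(t = t[i], d = (p[i + 1, , drop = FALSE] - p[i - 1, , drop = FALSE]) / dt)
}

#' Articulator kinematics
#'
#' Velocity, acceleration and jerk of a tracked keypoint (lower lip center
#' or jaw center) by repeated central finite differences over the actual
#' timestamps, segmented at gaps. The vertical channel is split into
#' downward (increasing y in image coordinates) and upward components.
#'
#' @param track A normalized [landmark_track()].
#' @param role Keypoint role, typically `"lower_lip_center"` or
#'   `"jaw_center"`.
#' @param cfg A [facial_config()].
#' @return Object of class `kinematic_series`: `segments` (per contiguous
#'   run: `t_v`, `v`, `t_a`, `a`, `t_j`, `j`) and `summary`, a named vector
#'   with `speed_mean`, `vel_up_max`, `vel_down_max`, `acc_mean`,
#'   `acc_up_max`, `acc_down_max`, `acc_absmax`, `jerk_mean`, `jerk_up_max`,
#'   `jerk_down_max`, `jerk_absmax` (units: normalized units /s, /s^2, /s^3).
#'   Summaries of an empty or constant series are 0.
#' @export
articulator_kinematics <- function(track, role = "lower_lip_center",
                                   cfg = facial_config()) {
  if (!track$normalized) track <- normalize_track(track)
  p_all <- role_point(track, role)
  if (cfg$smooth_window > 1) {
    w <- rep(1 / cfg$smooth_window, cfg$smooth_window)
    p_all <- apply(p_all, 2, function(col) {
      as.numeric(stats::filter(col, w, sides = 2))
    })
  }
  segs <- valid_segments(track$valid & stats::complete.cases(p_all),
                         cfg$max_gap_frames)
  out_segs <- list()
  vy <- ay <- jy <- numeric(0)
  speed <- acc_mag <- jerk_mag <- numeric(0)
  for (idx in segs) {
    if (length(idx) < 4) next
    t <- track$t[idx]
    p <- p_all[idx, , drop = FALSE]
    dv <- central_diff(t, p)
    da <- central_diff(dv$t, dv$d)
    dj <- central_diff(da$t, da$d)
    out_segs[[length(out_segs) + 1L]] <-
      list(t_v = dv$t, v = dv$d, t_a = da$t, a = da$d, t_j = dj$t, j = dj$d)
    speed <- c(speed, sqrt(rowSums(dv$d^2)))
    vy <- c(vy, dv$d[, 2])
    if (nrow(da$d) > 0) {
      acc_mag <- c(acc_mag, sqrt(rowSums(da$d^2)))
      ay <- c(ay, da$d[, 2])
    }
    if (nrow(dj$d) > 0) {
      jerk_mag <- c(jerk_mag, sqrt(rowSums(dj$d^2)))
      jy <- c(jy, dj$d[, 2])
    }
  }
  mx <- function(x) if (length(x) == 0) 0 else max(x)
  dirmax <- function(x, sign) mx(sign * x[sign * x > 0])
  summary <- c(
    speed_mean = if (length(speed)) mean(speed) else 0,
    vel_up_max = dirmax(vy, -1), vel_down_max = dirmax(vy, 1),
    acc_mean = if (length(acc_mag)) mean(acc_mag) else 0,
    acc_up_max = dirmax(ay, -1), acc_down_max = dirmax(ay, 1),
    acc_absmax = mx(abs(ay)),
    jerk_mean = if (length(jerk_mag)) mean(jerk_mag) else 0,
    jerk_up_max = dirmax(jy, -1), jerk_down_max = dirmax(jy, 1),
    jerk_absmax = mx(abs(jy)))
  structure(list(segments = out_segs, summary = summary),
            class = "kinematic_series")
}

# per-frame eye opening, averaged over the two eyes (normalized units)
eye_opening_series <- function(track) {
  r <- point_dist(role_point(track, "right_upper_eyelid"),
                  role_point(track, "right_lower_eyelid"))
  l <- point_dist(role_point(track, "left_upper_eyelid"),
                  role_point(track, "left_lower_eyelid"))
  (r + l) / 2
}

#' Blink rate
#'
#' Eye opening is the eyelid distance averaged over both eyes on the
#' normalized track. A blink is a maximal run of frames where the opening
#' falls below `blink_fraction` times the rolling-median opening, lasting at
#' least `min_blink_frames` frames and at most `max_blink_s` seconds. The
#' rate is blinks per second over the track span.
#'
#' @param track A normalized [landmark_track()].
#' @param cfg A [facial_config()].
#' @return Blinks per second (NA with less than 1 s of valid eye data).
#' @export
blink_rate <- function(track, cfg = facial_config()) {
  if (!track$normalized) track <- normalize_track(track)
  opening <- eye_opening_series(track)
  ok <- track$valid & is.finite(opening)
  if (sum(ok) < 2) return(NA_real_)
  span <- diff(range(track$t[ok]))
  if (span <= 1) return(NA_real_)
  op <- opening[ok]
  k <- round(cfg$median_window_s * track$frame_rate)
  k <- max(3L, min(as.integer(k) %/% 2L * 2L + 1L, length(op) - 1 + length(op) %% 2))
  if (k > length(op)) k <- max(3L, length(op) - (1 - length(op) %% 2))
  baseline <- stats::runmed(op, k)
  low <- op < cfg$blink_fraction * baseline
  runs <- rle(low)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  t_ok <- track$t[ok]
  n_blinks <- 0L
  for (i in which(runs$values)) {
    len <- runs$lengths[i]
    dur <- t_ok[ends[i]] - t_ok[starts[i]] + 1 / track$frame_rate
    if (len >= cfg$min_blink_frames && dur <= cfg$max_blink_s) {
      n_blinks <- n_blinks + 1L
    }
  }
  n_blinks / span
}

#' Vertical eyebrow displacement
#'
#' Per-frame vertical distance between each eyebrow center and the
#' ipsilateral inner canthus (normalized units; eyebrows sit above the
#' canthi, so the distance is canthus y minus eyebrow y in image
#' coordinates), averaged over the two eyes.
#'
#' @param track A normalized [landmark_track()].
#' @return Numeric vector, one value per frame (NA on invalid frames).
#' @export
eyebrow_displacement <- function(track) {
  if (!track$normalized) track <- normalize_track(track)
  r <- role_point(track, "right_inner_canthus")[, 2] -
    role_point(track, "right_eyebrow_center")[, 2]
  l <- role_point(track, "left_inner_canthus")[, 2] -
    role_point(track, "left_eyebrow_center")[, 2]
  out <- (r + l) / 2
  out[!track$valid] <- NA_real_
  out
}

facial_measures <- function() {
  kin <- c("speed_mean", "vel_up_max", "vel_down_max", "acc_mean",
           "acc_up_max", "acc_down_max", "acc_absmax", "jerk_mean",
           "jerk_up_max", "jerk_down_max", "jerk_absmax")
  c("lip_aperture_mean", "lip_aperture_max", "lip_width_mean",
    "lip_width_max", "mouth_area_mean", "mouth_area_max",
    "half_mouth_area_left_mean", "half_mouth_area_left_max",
    "half_mouth_area_right_mean", "half_mouth_area_right_max",
    "mouth_symmetry_mean",
    paste0("lower_lip_", kin), paste0("jaw_", kin),
    "blink_rate", "eye_opening_mean", "eyebrow_displacement_mean")
}

#' All facial features for one task response
#'
#' @param track A [landmark_track()] (pixel coordinates; normalization is
#'   applied internally).
#' @param cfg A [facial_config()].
#' @return Named numeric vector over [facial_measures()]; NA where a
#'   feature could not be computed.
#' @export
facial_features <- function(track, cfg = facial_config()) {
  out <- stats::setNames(rep(NA_real_, length(facial_measures())),
                         facial_measures())
  track <- normalize_track(track)
  geom <- mouth_geometry(track)
  g <- geom[geom$valid, , drop = FALSE]
  if (nrow(g) > 0) {
    out["lip_aperture_mean"] <- mean(g$lip_aperture)
    out["lip_aperture_max"] <- max(g$lip_aperture)
    out["lip_width_mean"] <- mean(g$lip_width)
    out["lip_width_max"] <- max(g$lip_width)
    out["mouth_area_mean"] <- mean(g$mouth_area)
    out["mouth_area_max"] <- max(g$mouth_area)
    out["half_mouth_area_left_mean"] <- mean(g$half_area_left)
    out["half_mouth_area_left_max"] <- max(g$half_area_left)
    out["half_mouth_area_right_mean"] <- mean(g$half_area_right)
    out["half_mouth_area_right_max"] <- max(g$half_area_right)
    out["mouth_symmetry_mean"] <- mean(g$symmetry, na.rm = TRUE)
  }
  for (art in c(lower_lip = "lower_lip_center", jaw = "jaw_center")) {
    prefix <- names(which(c(lower_lip = "lower_lip_center",
                            jaw = "jaw_center") == art))
    kin <- articulator_kinematics(track, art, cfg)
    out[paste0(prefix, "_", names(kin$summary))] <- kin$summary
  }
  out["blink_rate"] <- blink_rate(track, cfg)
  opening <- eye_opening_series(track)[track$valid]
  if (length(opening) > 0) out["eye_opening_mean"] <- mean(opening)
  disp <- eyebrow_displacement(track)
  if (any(is.finite(disp))) {
    out["eyebrow_displacement_mean"] <- mean(disp, na.rm = TRUE)
  }
  out
}

#' Facial feature matrix for a cohort
#'
#' @param cohort An `mhs_cohort` from [read_cohort()].
#' @param cfg A [facial_config()].
#' @param tasks Tasks to featurize.
#' @return A [feature_matrix()] with modality `"facial"`.
#' @export
featurize_facial <- function(cohort, cfg = facial_config(),
                             tasks = canonical_tasks()) {
  sessions <- cohort$sessions
  feats <- as.vector(t(outer(tasks, facial_measures(), paste, sep = ".")))
  values <- matrix(NA_real_, nrow(sessions), length(feats),
                   dimnames = list(sessions$session_id, feats))
  for (i in seq_len(nrow(sessions))) {
    for (task in tasks) {
      p <- sessions[[paste0(task, "_landmarks")]][i]
      if (is.na(p) || !nzchar(p) || !file.exists(p)) next
      track <- read_landmark_track(p)
      v <- facial_features(track, cfg)
      values[i, paste(task, names(v), sep = ".")] <- v
    }
  }
  feature_matrix(values, sessions$session_id, feats, "facial")
}
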