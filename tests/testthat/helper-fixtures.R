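# shared fixture builders (all fixtures are generated in code)

# neutral face geometry used by landmark fixtures (pixel coordinates,
# y increasing downward); inter-canthal distance 66 px
base_face <- function() {
  list(
    right_inner_canthus = c(-33, 0), left_inner_canthus = c(33, 0),
    right_upper_eyelid = c(-45, -6), right_lower_eyelid = c(-45, 6),
    left_upper_eyelid = c(45, -6), left_lower_eyelid = c(45, 6),
    right_eyebrow_center = c(-45, -25), left_eyebrow_center = c(45, -25),
    mouth_corner_right = c(-25, 60), mouth_corner_left = c(25, 60),
    upper_lip_center = c(0, 52), lower_lip_center = c(0, 68),
    jaw_center = c(0, 85), chin_base = c(0, 100))
}

# landmark track with every keypoint static except per-role overrides;
# overrides are functions t -> c(x, y) or t -> y offset matrices
make_track <- function(n_frames = 60, frame_rate = 30, overrides = list()) {
  t <- (seq_len(n_frames) - 1) / frame_rate
  face <- base_face()
  cols <- as.vector(t(outer(names(face), c("x", "y"), paste, sep = "_")))
  xy <- matrix(0, n_frames, length(cols), dimnames = list(NULL, cols))
  for (role in names(face)) {
    xy[, paste0(role, "_x")] <- face[[role]][1]
    xy[, paste0(role, "_y")] <- face[[role]][2]
  }
  for (role in names(overrides)) {
    o <- overrides[[role]](t)
    xy[, paste0(role, "_x")] <- o[, 1]
    xy[, paste0(role, "_y")] <- o[, 2]
  }
  landmark_track(t, xy)
}

# minimal speech_frames object built directly from an intensity pattern
# (dB) for timing/SNR arithmetic tests
make_frames <- function(intensity_db, step = 0.01, voiced = NULL,
                        f0 = NULL, sample_rate = 16000) {
  nf <- length(intensity_db)
  if (is.null(voiced)) voiced <- rep(FALSE, nf)
  if (is.null(f0)) f0 <- rep(NA_real_, nf)
  structure(list(frame_times = (seq_len(nf) - 0.5) * step,
                 intensity_db = intensity_db, voiced = voiced, f0_hz = f0,
                 r_peak = rep(NA_real_, nf), pulses = list(), step = step,
                 sample_rate = sample_rate, no_speech = !any(voiced)),
            class = "speech_frames")
}

# tiny cohort manifest on disk (sessions written task-file-free)
write_manifest_fixture <- function(dir, rows) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(rows, path, row.names = FALSE)
  path
}

manifest_row <- function(participant_id, session_id, sex = "female",
                         age = 40L, phq9 = 0L, gad7 = 0L, cssrs = "None") {
  data.frame(participant_id = participant_id, session_id = session_id,
             sex = sex, age = age, phq9_total = phq9, gad7_total = gad7,
             cssrs_risk = cssrs, stringsAsFactors = FALSE)
}

# brute-force tie-corrected two-group Kruskal-Wallis statistic and p-value
# (independent oracle for the screening implementation)
kw_brute <- function(x1, x2) {
  x <- c(x1, x2)
  g <- rep(c(1, 2), c(length(x1), length(x2)))
  n <- length(x)
  r <- rank(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (n + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- h / corr
  list(statistic = h, p = stats::pchisq(h, 1, lower.tail = FALSE))
}

# brute-force AUC by concordant-pair counting (ties count 1/2)
auc_brute <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}
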