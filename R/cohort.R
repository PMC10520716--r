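#' @keywords internal
"_PACKAGE"

#' Canonical interview tasks
#'
#' The seven tasks of a structured mental-health interview session: a read
#' speech-intelligibility-test sentence, a warm-up question, and five
#' open-ended topics (hope, secrets, anger, fear, emotional pain).
#'
#' @return Character vector of task names, in canonical order.
#' @export
canonical_tasks <- function() {
  c("sit", "warmup", "hope", "secrets", "anger", "fear", "emotional_pain")
}

#' Canonical 14-keypoint facial landmark roles
#'
#' Role names for the 14 tracked facial keypoints consumed by the facial
#' featurizer: the two inner canthi (the normalization reference), upper and
#' lower eyelids, eyebrow centers, mouth corners, upper and lower lip
#' centers, jaw center and chin base. Features reference these roles, so an
#' alternative landmark source can be adapted by renaming columns.
#'
#' @return Character vector of 14 role names.
#' @export
landmark_roles <- function() {
  c("right_inner_canthus", "left_inner_canthus",
    "right_upper_eyelid", "right_lower_eyelid",
    "left_upper_eyelid", "left_lower_eyelid",
    "right_eyebrow_center", "left_eyebrow_center",
    "mouth_corner_right", "mouth_corner_left",
    "upper_lip_center", "lower_lip_center",
    "jaw_center", "chin_base")
}

cssrs_levels <- function() c("None", "Low", "Moderate", "High")

# column layout of a cohort manifest CSV
manifest_columns <- function() {
  base <- c("participant_id", "session_id", "sex", "age",
            "phq9_total", "gad7_total", "cssrs_risk")
  task_cols <- as.vector(t(outer(canonical_tasks(),
                                 c("audio", "landmarks", "transcript"),
                                 paste, sep = "_")))
  c(base, task_cols)
}

#' Read and validate a cohort manifest
#'
#' The manifest is a UTF-8 CSV with one row per interview session and
#' columns `participant_id`, `session_id`, `sex` (`male`/`female`/
#' `unreported`), `age`, `phq9_total` (0-27), `gad7_total` (0-21),
#' `cssrs_risk` (`None` < `Low` < `Moderate` < `High`) plus, for each task,
#' `<task>_audio`, `<task>_landmarks` and `<task>_transcript` path columns
#' (empty string = modality not recorded for that task). Relative paths are
#' resolved against the manifest's directory.
#'
#' @param manifest_path Path to the manifest CSV.
#' @return An object of class `mhs_cohort`: a list with `participants`
#'   (data.frame: `participant_id`, `sex`, `age`, `n_sessions`, `repeat_participant`)
#'   and `sessions` (data.frame, one row per session with scores and resolved
#'   task file paths).
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  df <- utils::read.csv(manifest_path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("participant_id", "session_id", "sex", "age",
                "phq9_total", "gad7_total", "cssrs_risk")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("manifest schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  df$age <- as.integer(df$age)
  df$phq9_total <- as.integer(df$phq9_total)
  df$gad7_total <- as.integer(df$gad7_total)
  validate_sessions(df)
  root <- dirname(normalizePath(manifest_path))
  for (task in canonical_tasks()) {
    for (kind in c("audio", "landmarks", "transcript")) {
      col <- paste(task, kind, sep = "_")
      if (!col %in% names(df)) {
        df[[col]] <- ""
      } else {
        rel <- !is.na(df[[col]]) & nzchar(df[[col]]) &
          !grepl("^(/|[A-Za-z]:)", df[[col]])
        df[[col]][rel] <- file.path(root, df[[col]][rel])
      }
    }
  }
  new_cohort(df)
}

validate_sessions <- function(df) {
  if (anyDuplicated(df$session_id)) {
    stop("validation error: duplicate session_id: ",
         paste(unique(df$session_id[duplicated(df$session_id)]),
               collapse = ", "))
  }
  bad_sex <- !df$sex %in% c("male", "female", "unreported")
  if (any(bad_sex)) {
    stop("validation error: invalid sex in session ",
         df$session_id[which(bad_sex)[1]])
  }
  check_range <- function(x, lo, hi, what) {
    bad <- is.na(x) | x < lo | x > hi
    if (any(bad)) {
      stop("validation error: ", what, " out of range [", lo, ",", hi,
           "] in session ", df$session_id[which(bad)[1]])
    }
  }
  check_range(df$age, 18L, 120L, "age")
  check_range(df$phq9_total, 0L, 27L, "phq9_total")
  check_range(df$gad7_total, 0L, 21L, "gad7_total")
  bad_risk <- !df$cssrs_risk %in% cssrs_levels()
  if (any(bad_risk)) {
    stop("validation error: invalid cssrs_risk in session ",
         df$session_id[which(bad_risk)[1]])
  }
  invisible(TRUE)
}

new_cohort <- function(sessions) {
  tab <- table(sessions$participant_id)
  first <- !duplicated(sessions$participant_id)
  participants <- data.frame(
    participant_id = sessions$participant_id[first],
    sex = sessions$sex[first],
    age = sessions$age[first],
    stringsAsFactors = FALSE
  )
  participants$n_sessions <- as.integer(tab[participants$participant_id])
  participants$repeat_participant <- participants$n_sessions > 1L
  structure(list(participants = participants, sessions = sessions),
            class = "mhs_cohort")
}

#' @export
print.mhs_cohort <- function(x, ...) {
  cat("Interview cohort:", nrow(x$participants), "participants,",
      nrow(x$sessions), "sessions\n")
  lab <- derive_labels(x$sessions)
  cat(sprintf("  cases: depression %d, anxiety %d, suicide risk %d\n",
              sum(lab$depression), sum(lab$anxiety), sum(lab$suicide_risk)))
  n_rep <- sum(x$participants$repeat_participant)
  if (n_rep > 0) cat("  repeat participants:", n_rep, "\n")
  invisible(x)
}

#' Write a cohort manifest CSV
#'
#' Inverse of [read_cohort()]; paths are written as stored.
#'
#' @param cohort An `mhs_cohort` object (or a sessions data.frame).
#' @param manifest_path Output CSV path.
#' @return `manifest_path`, invisibly.
#' @export
write_cohort <- function(cohort, manifest_path) {
  sessions <- if (inherits(cohort, "mhs_cohort")) cohort$sessions else cohort
  cols <- intersect(manifest_columns(), names(sessions))
  utils::write.csv(sessions[, cols], manifest_path, row.names = FALSE,
                   quote = TRUE)
  invisible(manifest_path)
}

#' Derive binary case labels from assessment scores
#'
#' Case definitions follow the standard screening-instrument thresholds:
#' depression if PHQ-9 total >= 10, anxiety if GAD-7 total >= 10, suicide
#' risk if the C-SSRS screener level is Moderate or High.
#'
#' @param sessions A sessions data.frame (from an `mhs_cohort`) or a cohort.
#' @return data.frame with `session_id` and logical columns `depression`,
#'   `anxiety`, `suicide_risk`.
#' @export
derive_labels <- function(sessions) {
  if (inherits(sessions, "mhs_cohort")) sessions <- sessions$sessions
  risk <- match(sessions$cssrs_risk, cssrs_levels())
  if (anyNA(risk)) stop("invalid cssrs_risk value")
  data.frame(
    session_id = sessions$session_id,
    depression = sessions$phq9_total >= 10L,
    anxiety = sessions$gad7_total >= 10L,
    suicide_risk = risk >= 3L,
    stringsAsFactors = FALSE
  )
}

#' Validate a cohort directory
#'
#' Reads the manifest, checks score ranges and that every referenced task
#' file exists, and returns a schema report.
#'
#' @param dir Cohort directory containing `manifest.csv`.
#' @return data.frame report with one row per session file reference and a
#'   logical `exists` column; printed summary as a side effect if
#'   `verbose = TRUE`.
#' @param verbose Print a summary.
#' @export
validate_cohort <- function(dir, verbose = FALSE) {
  cohort <- read_cohort(file.path(dir, "manifest.csv"))
  rows <- list()
  for (i in seq_len(nrow(cohort$sessions))) {
    s <- cohort$sessions[i, ]
    for (task in canonical_tasks()) {
      for (kind in c("audio", "landmarks", "transcript")) {
        p <- s[[paste(task, kind, sep = "_")]]
        if (!is.na(p) && nzchar(p)) {
          rows[[length(rows) + 1L]] <- data.frame(
            session_id = s$session_id, task = task, kind = kind,
            path = p, exists = file.exists(p), stringsAsFactors = FALSE)
        }
      }
    }
  }
  report <- do.call(rbind, rows)
  if (verbose) {
    cat("cohort:", nrow(cohort$participants), "participants,",
        nrow(cohort$sessions), "sessions;",
        sum(!report$exists), "missing file(s) of", nrow(report), "\n")
  }
  invisible(report)
}
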