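# helpers for sampling assessment scores consistent with a case state
sample_scores <- function(state, n) {
  list(
    phq9 = ifelse(state$depression, sample(10:27, n, TRUE), sample(0:9, n, TRUE)),
    gad7 = ifelse(state$anxiety, sample(10:21, n, TRUE), sample(0:9, n, TRUE)),
    cssrs = ifelse(state$suicide_risk,
                   sample(c("Moderate", "High"), n, TRUE),
                   sample(c("None", "Low"), n, TRUE)))
}

# choose case participants so the summed session count hits `target` exactly
# (participants with 2 sessions can overshoot by one; fix by a swap)
assign_cases <- function(n_sessions_per_participant, target) {
  n <- length(n_sessions_per_participant)
  ord <- sample.int(n)
  case <- logical(n)
  total <- 0L
  for (i in ord) {
    if (total >= target) break
    if (total + n_sessions_per_participant[i] <= target) {
      case[i] <- TRUE
      total <- total + n_sessions_per_participant[i]
    }
  }
  if (total < target) {  # only 2-session participants left; swap one in
    cand <- which(!case & n_sessions_per_participant == (target - total))
    if (length(cand) > 0) case[cand[1]] <- TRUE
  }
  case
}

#' Simulate a cohort at the feature-matrix level
#'
#' Fast synthetic cohort for testing the screening and classification
#' stages without audio/video synthesis: standard-normal speech and facial
#' feature matrices with plantable case effects (Cohen's d shifts),
#' optional per-sex baseline shifts, controlled missingness, and assessment
#' scores drawn so the thresholded labels match the true states by
#' construction. Condition states live at the participant level, so repeat
#' sessions carry the same labels; case-session counts hit
#' `round(prevalence * n_sessions)` exactly.
#'
#' @param n_participants Number of participants (default 68).
#' @param n_repeat Participants contributing a second session (default 5).
#' @param prevalence Named session-level case prevalences for
#'   `depression`, `anxiety`, `suicide_risk` (defaults 15/73, 21/73,
#'   26/73).
#' @param sex_ratio_female Probability a participant is female (default
#'   0.765; 0.015 are unreported).
#' @param n_features Named counts of speech and facial features.
#' @param planted data.frame with columns `modality`, `feature`,
#'   `condition`, `d`: features whose case mean is shifted by `d` (unit SD
#'   base noise, so `d` is the population Cohen's d).
#' @param sex_shift Baseline mean shift added to female rows on every
#'   feature (default 0; set positive to exercise sex standardization).
#' @param exact_effects Realize each planted effect exactly in-sample by
#'   centering the noise within the case and control groups before adding
#'   the shift (default TRUE), so that recovery checks measure the
#'   pipeline's estimation fidelity rather than sampling noise of the
#'   generator. Set FALSE for population-level (noisy) effects.
#' @param missing_rate Probability an entry is missing (speech/facial).
#' @param seed Random seed (required; the generator sets it).
#' @return List: `sessions` (data.frame), `features` (list of
#'   [feature_matrix()]), `labels` (from [derive_labels()]),
#'   `ground_truth` (participant states and the planted table).
#' @export
simulate_feature_cohort <- function(n_participants = 68, n_repeat = 5,
                                    prevalence = c(depression = 15 / 73,
                                                   anxiety = 21 / 73,
                                                   suicide_risk = 26 / 73),
                                    sex_ratio_female = 0.765,
                                    n_features = c(speech = 40, facial = 40),
                                    planted = NULL, sex_shift = 0,
                                    exact_effects = TRUE,
                                    missing_rate = 0.01, seed = 1L) {
  set.seed(seed)
  stopifnot(n_repeat <= n_participants, all(prevalence > 0 & prevalence < 1))
  pid <- sprintf("P%03d", seq_len(n_participants))
  n_sess_pp <- rep(1L, n_participants)
  n_sess_pp[sample.int(n_participants, n_repeat)] <- 2L
  n_sessions <- sum(n_sess_pp)
  sex <- sample(c("female", "male", "unreported"), n_participants, TRUE,
                prob = c(sex_ratio_female, 1 - sex_ratio_female - 0.015, 0.015))
  state <- list()
  for (cond in c("depression", "anxiety", "suicide_risk")) {
    target <- round(prevalence[[cond]] * n_sessions)
    if (target < 2) stop("infeasible config: fewer than 2 case sessions for ", cond)
    state[[cond]] <- assign_cases(n_sess_pp, target)
  }
  age_pp <- pmin(85L, pmax(18L, as.integer(round(stats::rnorm(n_participants, 38.8, 14.7)))))
  part_row <- rep(seq_len(n_participants), n_sess_pp)
  n <- length(part_row)
  sess_state <- lapply(state, function(s) s[part_row])
  sc <- sample_scores(sess_state, n)
  sessions <- data.frame(
    participant_id = pid[part_row],
    session_id = sprintf("S%03d", seq_len(n)),
    sex = sex[part_row],
    age = age_pp[part_row],
    phq9_total = sc$phq9, gad7_total = sc$gad7, cssrs_risk = sc$cssrs,
    stringsAsFactors = FALSE)
  features <- list()
  for (m in names(n_features)) {
    p <- n_features[[m]]
    vals <- matrix(stats::rnorm(n * p), n, p)
    colnames(vals) <- sprintf("%s.feat_%02d", m, seq_len(p))
    if (!is.null(planted) && exact_effects) {
      pl <- planted[planted$modality == m, , drop = FALSE]
      for (r in seq_len(nrow(pl))) {
        j <- match(pl$feature[r], colnames(vals))
        if (is.na(j)) stop("unknown planted feature ", pl$feature[r])
        case <- sess_state[[pl$condition[r]]]
        vals[case, j] <- vals[case, j] - mean(vals[case, j])
        vals[!case, j] <- vals[!case, j] - mean(vals[!case, j])
      }
    }
    if (sex_shift != 0) {
      vals[sessions$sex == "female", ] <-
        vals[sessions$sex == "female", ] + sex_shift
    }
    if (!is.null(planted)) {
      pl <- planted[planted$modality == m, , drop = FALSE]
      for (r in seq_len(nrow(pl))) {
        j <- match(pl$feature[r], colnames(vals))
        case <- sess_state[[pl$condition[r]]]
        vals[case, j] <- vals[case, j] + pl$d[r]
      }
    }
    mask <- matrix(stats::runif(n * p) < missing_rate, n, p)
    vals[mask] <- NA_real_
    features[[m]] <- feature_matrix(vals, sessions$session_id,
                                    colnames(vals), m)
  }
  list(sessions = sessions, features = features,
       labels = derive_labels(sessions),
       ground_truth = list(participant_state = state, planted = planted))
}
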