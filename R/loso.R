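#' Leave-one-subject-out fold specification
#'
#' One fold per participant; all of a participant's sessions travel
#' together into that fold's test side, so the test sets partition the
#' sessions and no participant ever appears on both sides of a fold.
#'
#' @param sessions Sessions data.frame (needs `session_id`,
#'   `participant_id`) or an `mhs_cohort`.
#' @return List of folds, each `list(held_out_participant,
#'   train_session_ids, test_session_ids)`.
#' @export
make_loso_folds <- function(sessions) {
  if (inherits(sessions, "mhs_cohort")) sessions <- sessions$sessions
  participants <- unique(sessions$participant_id)
  if (length(participants) < 3) stop("need at least 3 participants for LOSO")
  lapply(participants, function(p) {
    test <- sessions$session_id[sessions$participant_id == p]
    list(held_out_participant = p,
         train_session_ids = sessions$session_id[sessions$participant_id != p],
         test_session_ids = test)
  })
}

#' Drop features missing in more than a fraction of sessions
#'
#' Applied cohort-wide once, before cross-validation: imputing a feature
#' absent from many sessions would manufacture information, so such
#' features are removed up front.
#'
#' @param fm A [feature_matrix()].
#' @param max_missing Maximum tolerated missing fraction (default 0.03).
#' @return The filtered [feature_matrix()].
#' @export
drop_high_missingness <- function(fm, max_missing = 0.03) {
  frac <- colMeans(fm$missing_mask)
  keep <- frac <= max_missing
  feature_matrix(fm$values[, keep, drop = FALSE], fm$session_ids,
                 fm$feature_names[keep], fm$modality,
                 fm$missing_mask[, keep, drop = FALSE])
}

# z-score columns within sex groups using supplied (training) statistics;
# stats = NULL fits them. Sessions of unreported sex, or of a sex absent
# from the training rows, fall back to pooled training statistics.
zscore_by_sex <- function(values, sex, stats = NULL) {
  if (is.null(stats)) {
    stats <- list(pooled = list(mean = colMeans(values, na.rm = TRUE),
                                sd = apply(values, 2, stats::sd, na.rm = TRUE)))
    for (s in c("male", "female")) {
      rows <- which(sex == s)
      if (length(rows) >= 2) {
        stats[[s]] <- list(
          mean = colMeans(values[rows, , drop = FALSE], na.rm = TRUE),
          sd = apply(values[rows, , drop = FALSE], 2, stats::sd, na.rm = TRUE))
      }
    }
  }
  out <- values
  for (i in seq_len(nrow(values))) {
    st <- stats[[sex[i]]]
    if (is.null(st)) st <- stats$pooled
    sd <- st$sd
    sd[!is.finite(sd) | sd < 1e-8] <- 1e-8
    out[i, ] <- (values[i, ] - st$mean) / sd
  }
  list(values = out, stats = stats)
}

#' Fold-nested preprocessing
#'
#' For speech and facial matrices: impute missing entries with the
#' training-fold feature mean, then z-score per sex with training-fold
#' per-sex statistics (pooled fallback for unreported or absent sex
#' groups). Text matrices pass through unchanged (TF-IDF refitting is
#' handled at tokenization level). Every fitted statistic is a function of
#' the training rows only.
#'
#' @param train_fm,test_fm [feature_matrix()] objects (same features).
#' @param sex_train,sex_test Character vectors aligned to rows (ignored for
#'   text).
#' @return List: `train`, `test` (numeric matrices), `impute_means`,
#'   `z_stats`.
#' @export
fold_preprocess <- function(train_fm, test_fm, sex_train = NULL,
                            sex_test = NULL) {
  tr <- train_fm$values
  te <- test_fm$values
  if (train_fm$modality == "text") {
    return(list(train = tr, test = te, impute_means = NULL, z_stats = NULL))
  }
  means <- colMeans(tr, na.rm = TRUE)
  means[!is.finite(means)] <- 0
  impute <- function(m) {
    for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- means[j]
    m
  }
  tr <- impute(tr); te <- impute(te)
  z_stats <- NULL
  if (!is.null(sex_train)) {
    z <- zscore_by_sex(tr, sex_train)
    tr <- z$values
    z_stats <- z$stats
    te <- zscore_by_sex(te, sex_test, stats = z_stats)$values
  }
  list(train = tr, test = te, impute_means = means, z_stats = z_stats)
}

# fast two-group Kruskal-Wallis p-values (tie-corrected), used inside CV
# folds where stats::kruskal.test's per-call overhead dominates; verified
# against kruskal.test in the test suite.
kw_pvalues_fast <- function(values, labels, min_group = 2L) {
  p <- stats::setNames(rep(NA_real_, ncol(values)), colnames(values))
  for (j in seq_len(ncol(values))) {
    x <- values[, j]
    ok <- !is.na(x)
    g <- labels[ok]
    n1 <- sum(g); n2 <- sum(!g)
    if (n1 < min_group || n2 < min_group) next
    x <- x[ok]
    n <- n1 + n2
    r <- rank(x)
    h <- 12 / (n * (n + 1)) *
      (sum(r[g])^2 / n1 + sum(r[!g])^2 / n2) - 3 * (n + 1)
    tie <- tabulate(match(x, unique(x)))
    corr <- 1 - sum(tie^3 - tie) / (n^3 - n)
    if (corr <= 0) { p[j] <- 1; next }
    p[j] <- stats::pchisq(h / corr, df = 1, lower.tail = FALSE)
  }
  p
}

#' Fold-level feature selection
#'
#' Ranks features by ascending Kruskal-Wallis p-value computed on training
#' rows only and returns the top `k` names; ties break lexicographically.
#' The number `k` comes from the full-sample screen (`k_mc`); the
#' identities are fold-specific, so no held-out information enters the
#' choice.
#'
#' @param train_values Numeric training matrix with column names.
#' @param labels Logical training labels.
#' @param k Number of features to keep.
#' @return Character vector of at most `k` feature names (all usable
#'   features, with a message, if fewer than `k` are testable).
#' @export
fold_select_features <- function(train_values, labels, k) {
  if (k <= 0) return(character(0))
  p <- kw_pvalues_fast(train_values, as.logical(labels))
  p <- p[!is.na(p)]
  if (length(p) < k) {
    message("fold_select_features: only ", length(p), " usable features for k = ", k)
    k <- length(p)
  }
  ord <- order(p, names(p))
  names(p)[ord][seq_len(k)]
}

#' Experiment gate: at least five significant features
#'
#' Classification experiments are only run (and reported) when the
#' full-sample screen found at least five significant features, guarding
#' against over-reliance on a handful of features or outliers.
#'
#' @param k_mc Significant-feature count from the full-sample screen.
#' @return TRUE iff `k_mc >= 5`.
#' @export
gate_experiment <- function(k_mc) {
  isTRUE(k_mc >= 5)
}

#' Fit a classifier on a training fold and score held-out sessions
#'
#' `"logistic"` is an L2-regularized logistic regression (unit-strength
#' penalty, matching the common default of a regularized LR) returning the
#' predicted case probability. `"linear_svm"` is a linear support vector
#' machine whose margins are mapped to `[0, 1]` by a sigmoid calibration
#' fit on the training margins; ranking metrics (AUC) are unaffected by the
#' calibration, which matters for the Brier score only.
#'
#' @param train_x,test_x Numeric matrices (columns = selected features).
#' @param train_y Logical training labels.
#' @param model_kind `"logistic"` or `"linear_svm"`.
#' @return Numeric test scores in `[0, 1]`.
#' @export
fit_score <- function(train_x, train_y, test_x,
                      model_kind = c("logistic", "linear_svm")) {
  model_kind <- match.arg(model_kind)
  train_y <- as.logical(train_y)
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  if (length(unique(train_y)) < 2 || ncol(train_x) == 0) {
    warning("degenerate training fold; returning constant score 0.5")
    return(rep(0.5, nrow(test_x)))
  }
  if (model_kind == "logistic") {
    tr <- train_x; te <- test_x
    if (ncol(tr) == 1) {  # ridge solver requires >= 2 columns; pad inert 0
      tr <- cbind(tr, `.pad` = 0)
      te <- cbind(te, `.pad` = 0)
    }
    fit <- withCallingHandlers(
      glmnet::glmnet(tr, as.numeric(train_y), family = "binomial",
                     alpha = 0, lambda = 1 / nrow(tr),
                     standardize = FALSE),
      # small minority classes are routine in tiny training folds; the
      # ridge fit itself is well-defined
      warning = function(w) {
        if (grepl("fewer than 8", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    as.numeric(stats::predict(fit, te, type = "response"))
  } else {
    fit <- e1071::svm(train_x, factor(train_y, levels = c(FALSE, TRUE)),
                      kernel = "linear", cost = 1, scale = FALSE)
    dv_train <- as.numeric(attr(stats::predict(fit, train_x,
                                               decision.values = TRUE),
                                "decision.values"))
    dv_test <- as.numeric(attr(stats::predict(fit, test_x,
                                              decision.values = TRUE),
                               "decision.values"))
    if (stats::sd(dv_train) == 0) return(rep(mean(train_y), nrow(test_x)))
    cal <- suppressWarnings(
      stats::glm(train_y ~ dv_train, family = stats::binomial()))
    as.numeric(stats::predict(cal, data.frame(dv_train = dv_test),
                              type = "response"))
  }
}

#' Linear SVM weights on a full dataset
#'
#' Fits a linear SVM to the whole (selected) text matrix and returns the
#' primal weight vector oriented so positive weights favor the case class;
#' feeds [top_weighted_terms()].
#'
#' @param x Numeric matrix with column names (terms).
#' @param y Logical labels.
#' @return Named numeric weight vector.
#' @export
svm_term_weights <- function(x, y) {
  y <- as.logical(y)
  fit <- e1071::svm(x, factor(y, levels = c(FALSE, TRUE)),
                    kernel = "linear", cost = 1, scale = FALSE)
  w <- crossprod(fit$SV, fit$coefs)[, 1]
  # the sign of e1071 decision values depends on label ordering; orient
  # empirically so positive weights lean toward the case class
  dv <- as.numeric(attr(stats::predict(fit, x, decision.values = TRUE),
                        "decision.values"))
  if (mean(dv[y]) < mean(dv[!y])) w <- -w
  stats::setNames(w, colnames(x))
}

#' Evaluate out-of-fold scores
#'
#' AUC by the Mann-Whitney identity (ties counted 1/2) with a 95% DeLong
#' confidence interval, and the Brier score (mean squared difference
#' between score and 0/1 label).
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param labels Logical labels.
#' @return List: `auc`, `auc_ci95`, `brier`, `n_case`, `n_control`.
#' @export
evaluate_scores <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) {
    stop("AUC undefined: only one class present")
  }
  roc <- pROC::roc(response = labels, predictor = scores,
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(roc, method = "delong")))
  list(auc = as.numeric(pROC::auc(roc)), auc_ci95 = ci[c(1, 3)],
       brier = mean((scores - as.numeric(labels))^2),
       n_case = sum(labels), n_control = sum(!labels))
}

#' Decision-level score fusion
#'
#' Element-wise combination of per-modality out-of-fold score vectors.
#'
#' @param score_list List of aligned numeric score vectors (>= 2).
#' @param rule `"min"`, `"max"`, or `"mean"`.
#' @return Fused numeric score vector.
#' @export
fuse_scores <- function(score_list, rule = c("min", "max", "mean")) {
  rule <- match.arg(rule)
  if (length(score_list) < 2) stop("decision fusion needs >= 2 score vectors")
  n <- unique(vapply(score_list, length, 1L))
  if (length(n) != 1) stop("alignment error: score vectors differ in length")
  m <- do.call(cbind, score_list)
  switch(rule,
         min = apply(m, 1, min),
         max = apply(m, 1, max),
         mean = rowMeans(m))
}
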