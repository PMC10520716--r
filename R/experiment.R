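#' Run a leave-one-subject-out classification experiment
#'
#' The package's central fitting routine. Given per-modality features,
#' session metadata and binary case labels for one condition, it:
#' \enumerate{
#'   \item drops features missing in more than `max_missing` of sessions
#'     (cohort-wide, once);
#'   \item determines `k_mc`, the number of significant features per
#'     modality, by a full-sample Kruskal-Wallis screen on one session per
#'     participant (sex-standardized for speech/facial);
#'   \item applies the at-least-five-significant-features gate;
#'   \item runs leave-one-subject-out cross-validation in which imputation,
#'     sex z-scoring, TF-IDF fitting and the selection of the top `k_mc`
#'     features are all re-fit on each training fold;
#'   \item scores held-out sessions with a logistic regression (speech,
#'     facial, feature fusion) or linear SVM (text), and evaluates AUC
#'     (DeLong 95% CI) and Brier score.
#' }
#' Feature-level fusion concatenates the independently preprocessed and
#' selected per-modality matrices before a logistic model; decision-level
#' fusion combines the per-modality out-of-fold scores element-wise under
#' the min/max/mean rules and reports all three.
#'
#' @param features Named list by modality (`speech`, `facial`, `text`).
#'   Each element is a [feature_matrix()], or for text alternatively a
#'   named list of token vectors (per session), in which case TF-IDF is
#'   refit inside every fold.
#' @param sessions Sessions data.frame with `session_id`, `participant_id`
#'   and optionally `sex`.
#' @param labels Logical case labels aligned to `sessions` rows.
#' @param condition Condition name for reporting.
#' @param modalities Modalities to use (default: all in `features`).
#' @param fusion `"none"` (single modality), `"feature"` or `"decision"`.
#' @param k Optional override of `k_mc` (single number or named by
#'   modality); used by [feature_count_sweep()]. When set, the full-sample
#'   screen is skipped and the gate only requires `k >= 1`.
#' @param alpha Significance level of the full-sample screen.
#' @param max_missing Cohort-wide missingness threshold (default 0.03).
#' @param enforce_gate Apply the five-feature gate (default TRUE).
#' @return Object of class `mhs_experiment`.
#' @export
run_experiment <- function(features, sessions, labels,
                           condition = "condition",
                           modalities = names(features),
                           fusion = c("none", "feature", "decision"),
                           k = NULL, alpha = 0.05, max_missing = 0.03,
                           enforce_gate = TRUE) {
  fusion <- match.arg(fusion)
  if (inherits(sessions, "mhs_cohort")) sessions <- sessions$sessions
  labels <- as.logical(labels)
  stopifnot(length(labels) == nrow(sessions))
  if (fusion == "none" && length(modalities) != 1) {
    stop("fusion = 'none' takes exactly one modality")
  }
  if (fusion != "none" && length(modalities) < 2) {
    stop("fusion needs at least 2 modalities")
  }
  sex <- if ("sex" %in% names(sessions)) sessions$sex else
    rep("unreported", nrow(sessions))
  ids <- sessions$session_id
  names(labels) <- ids

  # per-modality data, aligned to session order
  mods <- list()
  for (m in modalities) {
    x <- features[[m]]
    if (is.null(x)) stop("no features for modality ", m)
    if (inherits(x, "feature_matrix")) {
      x <- fm_subset(x, ids)
      if (x$modality != "text") x <- drop_high_missingness(x, max_missing)
      mods[[m]] <- list(kind = "matrix", fm = x)
    } else {
      if (!all(ids %in% names(x))) stop("token list misses sessions")
      mods[[m]] <- list(kind = "tokens", tokens = x[ids])
    }
  }

  # full-sample screen on primary sessions -> k_mc per modality
  primary <- select_primary_sessions(sessions)
  prim_idx <- match(primary, ids)
  k_mc <- stats::setNames(integer(length(modalities)), modalities)
  if (is.null(k)) {
    for (m in modalities) {
      md <- mods[[m]]
      if (md$kind == "matrix") {
        vals <- md$fm$values[prim_idx, , drop = FALSE]
        if (md$fm$modality != "text") {
          vals <- zscore_by_sex(vals, sex[prim_idx])$values
        }
        p <- kw_pvalues(vals, labels[prim_idx])
      } else {
        tf <- suppressWarnings(fit_tfidf(md$tokens[prim_idx]))
        keep <- match(tf$matrix$session_ids, primary)
        p <- kw_pvalues(tf$matrix$values, labels[primary][keep])
      }
      k_mc[m] <- sum(!is.na(p) & p < alpha)
    }
  } else {
    k_mc[] <- if (length(k) == 1) k else k[modalities]
  }
  gate <- if (is.null(k)) all(vapply(k_mc, gate_experiment, TRUE)) else
    all(k_mc >= 1)

  res <- structure(list(condition = condition, modalities = modalities,
                        fusion = fusion, k_mc = k_mc,
                        gate_passed = gate, session_ids = ids,
                        labels = labels, alpha = alpha),
                   class = "mhs_experiment")
  if (enforce_gate && !gate) {
    res$skipped <- TRUE
    return(res)
  }
  res$skipped <- FALSE

  model_for <- function(m) if (m == "text") "linear_svm" else "logistic"
  folds <- make_loso_folds(sessions)
  single_scores <- lapply(modalities, function(m) {
    stats::setNames(rep(NA_real_, length(ids)), ids)
  })
  names(single_scores) <- modalities
  fused_scores <- stats::setNames(rep(NA_real_, length(ids)), ids)
  fold_selected <- stats::setNames(
    lapply(modalities, function(m) vector("list", length(folds))), modalities)
  n_features_used <- matrix(0L, length(folds), length(modalities),
                            dimnames = list(NULL, modalities))

  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    tr_ids <- fold$train_session_ids
    te_ids <- fold$test_session_ids
    tr_idx <- match(tr_ids, ids); te_idx <- match(te_ids, ids)
    fused_tr <- NULL; fused_te <- NULL
    for (m in modalities) {
      md <- mods[[m]]
      if (md$kind == "matrix") {
        pp <- fold_preprocess(fm_subset(md$fm, tr_ids),
                              fm_subset(md$fm, te_ids),
                              if (md$fm$modality == "text") NULL else sex[tr_idx],
                              if (md$fm$modality == "text") NULL else sex[te_idx])
        tr_x <- pp$train; te_x <- pp$test
      } else {
        tf <- suppressWarnings(fit_tfidf(md$tokens[tr_ids]))
        tr_full <- transform_tfidf(tf$model, md$tokens[tr_ids])
        te_full <- transform_tfidf(tf$model, md$tokens[te_ids])
        tr_x <- tr_full$values; te_x <- te_full$values
      }
      sel <- fold_select_features(tr_x, labels[tr_idx], k_mc[m])
      fold_selected[[m]][[fi]] <- sel
      n_features_used[fi, m] <- length(sel)
      tr_s <- tr_x[, sel, drop = FALSE]
      te_s <- te_x[, sel, drop = FALSE]
      if (fusion %in% c("none", "decision")) {
        single_scores[[m]][te_ids] <-
          fit_score(tr_s, labels[tr_idx], te_s, model_for(m))
      }
      if (fusion == "feature") {
        colnames(tr_s) <- colnames(te_s) <- paste(m, sel, sep = ":")
        fused_tr <- cbind(fused_tr, tr_s)
        fused_te <- cbind(fused_te, te_s)
      }
    }
    if (fusion == "feature") {
      fused_scores[te_ids] <-
        fit_score(fused_tr, labels[tr_idx], fused_te, "logistic")
    }
  }

  res$fold_selected <- fold_selected
  res$n_features_used <- n_features_used
  if (fusion == "none") {
    m <- modalities[1]
    res$scores <- single_scores[[m]]
    res$evaluation <- evaluate_scores(res$scores, labels)
    res$label <- m
  } else if (fusion == "feature") {
    res$scores <- fused_scores
    res$evaluation <- evaluate_scores(fused_scores, labels)
    res$label <- paste0("feature_fusion(", paste(modalities, collapse = "+"), ")")
  } else {
    res$per_modality <- lapply(single_scores, function(s) {
      list(scores = s, evaluation = evaluate_scores(s, labels))
    })
    res$rules <- list()
    for (rule in c("min", "max", "mean")) {
      fs <- fuse_scores(single_scores, rule)
      names(fs) <- ids
      res$rules[[rule]] <- list(scores = fs,
                                evaluation = evaluate_scores(fs, labels))
    }
    aucs <- vapply(res$rules, function(r) r$evaluation$auc, 1)
    res$best_rule <- names(which.max(aucs))
    res$scores <- res$rules[[res$best_rule]]$scores
    res$evaluation <- res$rules[[res$best_rule]]$evaluation
    res$label <- paste0("decision_fusion(", res$best_rule, "; ",
                        paste(modalities, collapse = "+"), ")")
  }
  res
}

#' @export
print.mhs_experiment <- function(x, ...) {
  cat("LOSO experiment:", x$condition, "~",
      paste(x$modalities, collapse = "+"),
      if (x$fusion != "none") paste0("[", x$fusion, " fusion]") else "", "\n")
  cat("  k_mc:", paste(names(x$k_mc), x$k_mc, sep = "=", collapse = ", "),
      "| gate", if (x$gate_passed) "passed" else "FAILED", "\n")
  if (isTRUE(x$skipped)) {
    cat("  experiment skipped (fewer than 5 significant features)\n")
    return(invisible(x))
  }
  ev <- x$evaluation
  cat(sprintf("  %s: AUC = %.2f (95%% CI %.2f-%.2f), Brier = %.2f\n",
              x$label, ev$auc, ev$auc_ci95[1], ev$auc_ci95[2], ev$brier))
  invisible(x)
}

#' @export
summary.mhs_experiment <- function(object, ...) {
  if (isTRUE(object$skipped)) {
    return(data.frame(condition = object$condition,
                      label = "skipped", auc = NA, ci_lo = NA, ci_hi = NA,
                      brier = NA))
  }
  row <- function(label, ev) {
    data.frame(condition = object$condition, label = label, auc = ev$auc,
               ci_lo = ev$auc_ci95[1], ci_hi = ev$auc_ci95[2],
               brier = ev$brier, stringsAsFactors = FALSE)
  }
  out <- row(object$label, object$evaluation)
  if (object$fusion == "decision") {
    for (m in names(object$per_modality)) {
      out <- rbind(out, row(m, object$per_modality[[m]]$evaluation))
    }
    for (r in names(object$rules)) {
      out <- rbind(out, row(paste0("decision:", r),
                            object$rules[[r]]$evaluation))
    }
  }
  rownames(out) <- NULL
  out
}

#' ROC curve of an experiment
#'
#' @param x An `mhs_experiment`.
#' @param ... Passed to [pROC::plot.roc()].
#' @export
plot.mhs_experiment <- function(x, ...) {
  if (isTRUE(x$skipped)) stop("experiment was skipped; nothing to plot")
  roc <- pROC::roc(response = x$labels, predictor = x$scores,
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  pROC::plot.roc(roc, main = sprintf("%s ~ %s (AUC %.2f)", x$condition,
                                     x$label, x$evaluation$auc), ...)
  invisible(x)
}

#' Sweep the number of selected features
#'
#' Reruns the LOSO machinery with the per-fold selection size forced to
#' each `k` in `k_range` (overriding `k_mc`) and reports the AUC curve and
#' its argmax. `k = 0` rows are marked skipped (no features, gate fails);
#' `k` beyond the available feature count is truncated by the selector.
#'
#' @inheritParams run_experiment
#' @param k_range Integer vector of selection sizes.
#' @return Object of class `mhs_sweep`: data.frame `table` (k, auc, brier,
#'   skipped) and `best_k`.
#' @export
feature_count_sweep <- function(features, sessions, labels,
                                condition = "condition",
                                modalities = names(features),
                                k_range = 1:15,
                                fusion = if (length(modalities) > 1)
                                  "feature" else "none") {
  rows <- lapply(k_range, function(kk) {
    if (kk <= 0) {
      return(data.frame(k = kk, auc = NA_real_, brier = NA_real_,
                        skipped = TRUE))
    }
    ex <- run_experiment(features, sessions, labels, condition, modalities,
                         fusion = fusion, k = kk, enforce_gate = FALSE)
    data.frame(k = kk, auc = ex$evaluation$auc, brier = ex$evaluation$brier,
               skipped = FALSE)
  })
  tab <- do.call(rbind, rows)
  ok <- !tab$skipped
  structure(list(table = tab,
                 best_k = tab$k[ok][which.max(tab$auc[ok])],
                 condition = condition, modalities = modalities),
            class = "mhs_sweep")
}

#' @export
print.mhs_sweep <- function(x, ...) {
  cat("Feature-count sweep:", x$condition, "~",
      paste(x$modalities, collapse = "+"), "\n")
  print(x$table, row.names = FALSE)
  cat("best k:", x$best_k, "\n")
  invisible(x)
}
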