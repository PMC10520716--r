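#' Select one session per participant
#'
#' Full-sample feature screening weights each participant equally, so
#' repeat sessions are reduced to one per participant: the earliest by
#' session id order of appearance in the manifest (the manifest is written
#' in session order). The choice is deterministic and invariant to row
#' permutations of the input.
#'
#' @param sessions Sessions data.frame or `mhs_cohort`.
#' @return Character vector of retained session ids.
#' @export
select_primary_sessions <- function(sessions) {
  if (inherits(sessions, "mhs_cohort")) sessions <- sessions$sessions
  ord <- order(sessions$session_id)
  s <- sessions[ord, , drop = FALSE]
  s$session_id[!duplicated(s$participant_id)]
}

#' Kruskal-Wallis feature screen
#'
#' Runs a two-group Kruskal-Wallis rank test (with tie correction) per
#' feature between cases and controls, on primary sessions only, and counts
#' the number of features significant at `alpha`. That count, `k_mc`, is
#' the only quantity carried into cross-validated feature selection (the
#' identities are re-derived per fold to avoid leakage). No multiple-testing
#' correction is applied: `alpha` is a per-feature level.
#'
#' @param fm A [feature_matrix()].
#' @param labels Logical vector of case labels aligned to `fm` rows.
#' @param alpha Significance level (default 0.05).
#' @param min_group Minimum non-missing observations required per group.
#' @return List of class `kw_screen`: `p_values` (named; NA where a group
#'   was empty or the feature was excluded), `k_mc`, `significant`
#'   (character vector of significant feature names), `alpha`, `n_case`,
#'   `n_control`.
#' @export
kw_screen <- function(fm, labels, alpha = 0.05, min_group = 2L) {
  stopifnot(length(labels) == nrow(fm$values), alpha > 0, alpha < 1)
  labels <- as.logical(labels)
  p <- kw_pvalues(fm$values, labels, min_group)
  significant <- names(p)[!is.na(p) & p < alpha]
  structure(list(p_values = p, k_mc = length(significant),
                 significant = significant, alpha = alpha,
                 n_case = sum(labels), n_control = sum(!labels)),
            class = "kw_screen")
}

# per-column two-group KW p-values on a plain matrix (NA = missing)
kw_pvalues <- function(values, labels, min_group = 2L) {
  p <- stats::setNames(rep(NA_real_, ncol(values)), colnames(values))
  for (j in seq_len(ncol(values))) {
    x <- values[, j]
    ok <- !is.na(x)
    g <- labels[ok]
    if (sum(g) < min_group || sum(!g) < min_group) next
    xo <- x[ok]
    if (length(unique(xo)) == 1) { p[j] <- 1; next }
    p[j] <- stats::kruskal.test(xo, factor(g))$p.value
  }
  p
}

#' @export
print.kw_screen <- function(x, ...) {
  cat(sprintf(
    "Kruskal-Wallis screen: %d of %d features significant at alpha = %g (%d cases / %d controls)\n",
    x$k_mc, length(x$p_values), x$alpha, x$n_case, x$n_control))
  invisible(x)
}

#' Cohen's d with a 95% confidence interval
#'
#' Standardized mean difference, case minus control, divided by the pooled
#' standard deviation; positive values mean cases have the higher mean. The
#' 95% CI uses the normal approximation with
#' `Var(d) = (n1 + n2)/(n1 n2) + d^2 / (2 (n1 + n2 - 2))`.
#'
#' @param case_values,control_values Numeric vectors (NAs dropped), at
#'   least 2 values each.
#' @return Named list: `d`, `ci95` (length-2), `n_case`, `n_control`. A
#'   zero pooled SD gives `d = 0` for equal means and a signed `Inf`
#'   sentinel (with a warning) otherwise.
#' @export
cohens_d <- function(case_values, control_values) {
  x1 <- case_values[!is.na(case_values)]
  x2 <- control_values[!is.na(control_values)]
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 2 || n2 < 2) stop("need at least 2 values per group")
  s_pooled <- sqrt(((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) /
                     (n1 + n2 - 2))
  diff_means <- mean(x1) - mean(x2)
  if (s_pooled == 0) {
    if (diff_means == 0) {
      return(list(d = 0, ci95 = c(0, 0), n_case = n1, n_control = n2))
    }
    warning("zero pooled SD with unequal means; returning signed Inf")
    return(list(d = sign(diff_means) * Inf, ci95 = c(NA_real_, NA_real_),
                n_case = n1, n_control = n2))
  }
  d <- diff_means / s_pooled
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2 - 2)))
  list(d = d, ci95 = c(d - 1.96 * se, d + 1.96 * se),
       n_case = n1, n_control = n2)
}

#' Full-sample feature screen with effect sizes
#'
#' Combines the Kruskal-Wallis screen with per-feature Cohen's d (computed
#' on the same, optionally sex-standardized, values that enter modeling)
#' into a forest-plot-ready report for one modality and condition.
#'
#' @param fm A speech or facial [feature_matrix()].
#' @param labels Logical case labels aligned to rows.
#' @param condition Label for reporting (e.g. `"depression"`).
#' @param alpha Significance level.
#' @param sex Optional character vector (`male`/`female`/`unreported`)
#'   aligned to rows; when given, features are z-scored within sex before
#'   testing and effect-size computation.
#' @return Object of class `feature_screen`: `table` (data.frame: feature,
#'   d, ci_lo, ci_hi, p_kw, significant, n_case, n_control), `k_mc`,
#'   `condition`, `modality`, `alpha`.
#' @export
screen_features <- function(fm, labels, condition = "condition",
                            alpha = 0.05, sex = NULL) {
  values <- fm$values
  if (!is.null(sex) && fm$modality != "text") {
    values <- zscore_by_sex(values, sex)$values
  }
  zfm <- feature_matrix(values, fm$session_ids, fm$feature_names,
                        fm$modality,
                        if (fm$modality == "text") NULL else is.na(values))
  kw <- kw_screen(zfm, labels, alpha)
  labels <- as.logical(labels)
  rows <- lapply(seq_along(zfm$feature_names), function(j) {
    x <- values[, j]
    ok <- !is.na(x)
    if (sum(ok & labels) < 2 || sum(ok & !labels) < 2) return(NULL)
    es <- cohens_d(x[ok & labels], x[ok & !labels])
    data.frame(feature = zfm$feature_names[j], d = es$d,
               ci_lo = es$ci95[1], ci_hi = es$ci95[2],
               p_kw = kw$p_values[j],
               significant = !is.na(kw$p_values[j]) & kw$p_values[j] < alpha,
               n_case = es$n_case, n_control = es$n_control,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, k_mc = kw$k_mc, condition = condition,
                 modality = fm$modality, alpha = alpha),
            class = "feature_screen")
}

#' @export
print.feature_screen <- function(x, ...) {
  cat(sprintf("Feature screen [%s / %s]: k_mc = %d of %d at alpha = %g\n",
              x$modality, x$condition, x$k_mc, nrow(x$table), x$alpha))
  sig <- x$table[x$table$significant, , drop = FALSE]
  if (nrow(sig) > 0) {
    sig <- sig[order(-abs(sig$d)), ]
    cat("Top significant features by |d|:\n")
    print(utils::head(data.frame(feature = sig$feature,
                                 d = round(sig$d, 2),
                                 p = signif(sig$p_kw, 2)), 10),
          row.names = FALSE)
  }
  invisible(x)
}

#' Forest plot of significant effect sizes
#'
#' @param x A `feature_screen`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.feature_screen <- function(x, ...) {
  sig <- x$table[x$table$significant, , drop = FALSE]
  if (nrow(sig) == 0) {
    graphics::plot.new()
    graphics::title(main = "No significant features")
    return(invisible(x))
  }
  sig <- sig[order(sig$d), ]
  n <- nrow(sig)
  old <- graphics::par(mar = c(4, 14, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(sig$d, seq_len(n), xlim = range(c(sig$ci_lo, sig$ci_hi, 0)),
                 yaxt = "n", ylab = "", xlab = "Cohen's d (case - control)",
                 pch = 16, main = paste(x$modality, "/", x$condition), ...)
  graphics::segments(sig$ci_lo, seq_len(n), sig$ci_hi, seq_len(n))
  graphics::abline(v = 0, lty = 2, col = "grey50")
  graphics::axis(2, at = seq_len(n), labels = sig$feature, las = 1,
                 cex.axis = 0.6)
  invisible(x)
}

#' Pearson correlation screen against assessment totals
#'
#' Correlates each (speech or facial) feature with an assessment total
#' score; a feature is flagged when `|r| >= 0.2` and `p < 0.05` — a
#' deliberately permissive rule meant to surface weak but statistically
#' significant associations in an exploratory analysis.
#'
#' @param fm A [feature_matrix()].
#' @param totals Numeric assessment totals aligned to rows.
#' @param r_threshold,alpha Flagging rule parameters.
#' @return data.frame: `feature`, `r`, `p`, `n`, `flagged`, `note`.
#' @export
pearson_screen <- function(fm, totals, r_threshold = 0.2, alpha = 0.05) {
  stopifnot(length(totals) == nrow(fm$values))
  rows <- lapply(seq_along(fm$feature_names), function(j) {
    x <- fm$values[, j]
    ok <- !is.na(x) & !is.na(totals)
    note <- ""
    r <- NA_real_; p <- NA_real_; flagged <- FALSE
    if (sum(ok) < 3) {
      note <- "fewer than 3 paired observations"
    } else if (stats::sd(x[ok]) == 0) {
      note <- "constant feature; correlation undefined"
    } else {
      ct <- stats::cor.test(x[ok], totals[ok])
      r <- unname(ct$estimate); p <- ct$p.value
      flagged <- abs(r) >= r_threshold && p < alpha
    }
    data.frame(feature = fm$feature_names[j], r = r, p = p, n = sum(ok),
               flagged = flagged, note = note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stable features across the full sample and all CV folds
#'
#' Intersection of (a) features significant in the full-sample
#' Kruskal-Wallis screen and (b) features selected in every
#' cross-validation fold — the features robust to participant partitioning.
#'
#' @param full_sample_significant Character vector of significant features.
#' @param per_fold_selected List of character vectors, one per fold.
#' @return Character vector (subset of every input set).
#' @export
stable_features <- function(full_sample_significant, per_fold_selected) {
  out <- full_sample_significant
  for (sel in per_fold_selected) out <- intersect(out, sel)
  out
}

#' Stable-feature report with effect sizes
#'
#' Joins the stable-feature set (significant on the full sample and
#' selected in every CV fold) with the screen's effect-size table.
#'
#' @param screen A `feature_screen` from [screen_features()].
#' @param per_fold_selected List of per-fold selected feature names (from
#'   an `mhs_experiment`'s `fold_selected` entry).
#' @return data.frame subset of the screen table, ordered by |d|.
#' @export
stable_feature_report <- function(screen, per_fold_selected) {
  stopifnot(inherits(screen, "feature_screen"))
  stable <- stable_features(
    screen$table$feature[screen$table$significant], per_fold_selected)
  tab <- screen$table[screen$table$feature %in% stable, , drop = FALSE]
  tab[order(-abs(tab$d)), , drop = FALSE]
}
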