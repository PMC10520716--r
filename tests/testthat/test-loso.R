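test_that("LOSO folds partition sessions and group repeat sessions", {
  sim <- simulate_feature_cohort(20, 3, prevalence = c(depression = 0.4,
                                                       anxiety = 0.3,
                                                       suicide_risk = 0.3),
                                 seed = 2)
  folds <- make_loso_folds(sim$sessions)
  expect_length(folds, 20)
  test_ids <- unlist(lapply(folds, `[[`, "test_session_ids"))
  expect_setequal(test_ids, sim$sessions$session_id)
  expect_equal(anyDuplicated(test_ids), 0)
  for (f in folds) {
    own <- sim$sessions$session_id[
      sim$sessions$participant_id == f$held_out_participant]
    expect_setequal(f$test_session_ids, own)
    expect_length(intersect(f$train_session_ids, f$test_session_ids), 0)
  }
})

test_that("cohort-wide missingness filter drops features above 3%", {
  vals <- matrix(rnorm(300), 100, 3,
                 dimnames = list(NULL, c("ok", "borderline", "gappy")))
  vals[1:3, 2] <- NA   # exactly 3%: kept
  vals[1:4, 3] <- NA   # 4%: dropped
  fm <- feature_matrix(vals, sprintf("S%03d", 1:100), colnames(vals), "speech")
  kept <- drop_high_missingness(fm)
  expect_setequal(kept$feature_names, c("ok", "borderline"))
})

test_that("fold preprocessing imputes and sex-standardizes from training only", {
  set.seed(6)
  n <- 40
  vals <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("f1", "f2")))
  sex <- rep(c("male", "female"), each = n / 2)
  vals[sex == "female", ] <- vals[sex == "female", ] + 3  # sex offset
  vals[5, 1] <- NA
  ids <- sprintf("S%02d", seq_len(n))
  fm <- feature_matrix(vals, ids, c("f1", "f2"), "speech")
  tr_ids <- ids[1:30]; te_ids <- ids[31:40]
  pp <- fold_preprocess(mindmodal:::fm_subset(fm, tr_ids),
                        mindmodal:::fm_subset(fm, te_ids),
                        sex[1:30], sex[31:40])
  # imputation fills the training mean of the feature
  expect_false(anyNA(pp$train))
  expect_equal(pp$impute_means[["f1"]], mean(vals[1:30, 1], na.rm = TRUE))
  # after per-sex z-scoring the sex offset is gone from training rows
  p_sex <- stats::kruskal.test(pp$train[, 2], factor(sex[1:30]))$p.value
  expect_gt(p_sex, 0.05)
  # no missing values: imputation is the identity
  fm2 <- feature_matrix(vals[, 2, drop = FALSE], ids, "f2", "speech")
  pp2 <- fold_preprocess(mindmodal:::fm_subset(fm2, tr_ids),
                         mindmodal:::fm_subset(fm2, te_ids))
  expect_equal(pp2$train, fm2$values[1:30, , drop = FALSE])
})

test_that("fold feature selection recovers planted features from training rows", {
  set.seed(14)
  hits <- 0; folds <- 25
  for (i in seq_len(folds)) {
    n <- 60
    x <- matrix(rnorm(n * 50), n, 50,
                dimnames = list(NULL, sprintf("f%02d", 1:50)))
    y <- rep(c(TRUE, FALSE), each = n / 2)
    x[y, 1:5] <- x[y, 1:5] + 1.2
    sel <- fold_select_features(x, y, 5)
    expect_length(sel, 5)
    if (sum(sel %in% sprintf("f%02d", 1:5)) >= 4) hits <- hits + 1
  }
  expect_gte(hits, 0.8 * folds)
})

test_that("selection and preprocessing never look at held-out rows", {
  set.seed(25)
  sim <- simulate_feature_cohort(30, 0, prevalence = c(depression = 0.4,
                                                       anxiety = 0.3,
                                                       suicide_risk = 0.3),
                                 seed = 25)
  fm <- sim$features$speech
  ids <- fm$session_ids
  tr <- ids[1:24]; te <- ids[25:30]
  y_tr <- sim$labels$depression[1:24]
  sex <- sim$sessions$sex

  pp1 <- fold_preprocess(mindmodal:::fm_subset(fm, tr),
                         mindmodal:::fm_subset(fm, te),
                         sex[1:24], sex[25:30])
  sel1 <- fold_select_features(pp1$train, y_tr, 5)

  # mutate held-out rows wildly
  fm2 <- fm
  fm2$values[25:30, ] <- fm2$values[25:30, ] * 100 + 7
  pp2 <- fold_preprocess(mindmodal:::fm_subset(fm2, tr),
                         mindmodal:::fm_subset(fm2, te),
                         sex[1:24], sex[25:30])
  expect_identical(pp1$impute_means, pp2$impute_means)
  expect_identical(pp1$z_stats, pp2$z_stats)
  expect_identical(pp1$train, pp2$train)
  expect_identical(fold_select_features(pp2$train, y_tr, 5), sel1)

  # TF-IDF vocabulary is a function of training documents only
  toks <- lapply(1:10, function(i) sample(letters[1:6], 8, TRUE))
  names(toks) <- paste0("T", 1:10)
  v1 <- fit_tfidf(toks[1:8])$model$vocabulary
  toks[[9]] <- c("zebra", "quark")
  v2 <- fit_tfidf(toks[1:8])$model$vocabulary
  expect_identical(v1, v2)
})

test_that("the experiment gate requires at least five significant features", {
  expect_false(gate_experiment(1))
  expect_false(gate_experiment(4))
  expect_true(gate_experiment(5))
  expect_true(gate_experiment(24))
})

test_that("classifier scoring behaves on separable, degenerate and null data", {
  # separable toy set: the held-out case-side point scores above 0.5
  tr_x <- matrix(c(-2, -1.5, 1.5, 2), 4, 1)
  te_x <- matrix(3, 1, 1)
  y <- c(FALSE, FALSE, TRUE, TRUE)
  expect_gt(fit_score(tr_x, y, te_x, "logistic"), 0.5)
  expect_gt(fit_score(tr_x, y, te_x, "linear_svm"), 0.5)

  # single-class training fold: constant 0.5 with warning
  expect_warning(s <- fit_score(tr_x, rep(TRUE, 4), te_x, "logistic"),
                 "degenerate")
  expect_equal(s, 0.5)

  # duplicating every training row leaves SVM test ranks unchanged
  set.seed(41)
  xtr <- matrix(rnorm(40), 20, 2); ytr <- rep(c(TRUE, FALSE), 10)
  xte <- matrix(rnorm(10), 5, 2)
  s1 <- fit_score(xtr, ytr, xte, "linear_svm")
  s2 <- fit_score(rbind(xtr, xtr), c(ytr, ytr), xte, "linear_svm")
  expect_equal(order(s1), order(s2))
})

test_that("evaluation matches closed forms and the pair-counting oracle", {
  lab <- c(TRUE, TRUE, FALSE, FALSE)
  perfect <- evaluate_scores(c(0.9, 0.8, 0.2, 0.1), lab)
  expect_equal(perfect$auc, 1)
  expect_equal(evaluate_scores(as.numeric(lab), lab)$brier, 0)
  flat <- evaluate_scores(rep(0.5, 4), lab)
  expect_equal(flat$auc, 0.5)
  expect_equal(flat$brier, 0.25)
  expect_error(evaluate_scores(c(0.1, 0.2), c(TRUE, TRUE)), "one class")

  set.seed(50)
  for (i in 1:50) {
    n <- sample(6:25, 1)
    sc <- round(runif(n), 2)  # rounded: force ties
    lb <- sample(c(TRUE, FALSE), n, TRUE)
    if (sum(lb) < 2 || sum(!lb) < 2) next  # DeLong CI needs 2 per class
    ev <- evaluate_scores(sc, lb)
    expect_equal(ev$auc, auc_brute(sc, lb), tolerance = 1e-12)
    expect_true(ev$auc_ci95[1] <= ev$auc && ev$auc <= ev$auc_ci95[2])
  }
})

test_that("decision fusion rules are idempotent and match direct evaluation", {
  set.seed(51)
  s <- runif(20); lab <- rep(c(TRUE, FALSE), 10)
  for (rule in c("min", "max", "mean")) {
    expect_equal(fuse_scores(list(s, s, s), rule), s)
  }
  s2 <- runif(20)
  fused <- fuse_scores(list(s, s2), "min")
  expect_equal(evaluate_scores(fused, lab)$auc,
               auc_brute(pmin(s, s2), lab), tolerance = 1e-12)
  # mean rule is permutation-invariant in modality order
  expect_equal(fuse_scores(list(s, s2), "mean"), fuse_scores(list(s2, s), "mean"))
  expect_error(fuse_scores(list(s, s2[1:5]), "min"), "alignment")
})

test_that("run_experiment skips gated experiments and reports fold selections", {
  sim <- simulate_feature_cohort(24, 0, prevalence = c(depression = 0.4,
                                                       anxiety = 0.3,
                                                       suicide_risk = 0.3),
                                 n_features = c(speech = 10), seed = 33)
  # k override below the gate: with enforce_gate the experiment is skipped
  ex0 <- run_experiment(sim$features["speech"], sim$sessions,
                        sim$labels$depression, "depression", "speech",
                        k = 0)
  expect_true(ex0$skipped)
  ex <- run_experiment(sim$features["speech"], sim$sessions,
                       sim$labels$depression, "depression", "speech",
                       k = 3, enforce_gate = FALSE)
  expect_false(ex$skipped)
  expect_length(ex$fold_selected$speech, 24)
  expect_true(all(ex$n_features_used[, "speech"] == 3))
  expect_equal(sort(names(ex$scores)), sort(sim$sessions$session_id))
  expect_true(all(ex$scores >= 0 & ex$scores <= 1))
})

test_that("feature-count sweep rows reproduce standalone runs", {
  sim <- simulate_feature_cohort(
    24, 0, prevalence = c(depression = 0.4, anxiety = 0.3, suicide_risk = 0.3),
    n_features = c(speech = 12),
    planted = data.frame(modality = "speech",
                         feature = sprintf("speech.feat_%02d", 1:3),
                         condition = "depression", d = 1.3),
    seed = 44)
  sw <- feature_count_sweep(sim$features["speech"], sim$sessions,
                            sim$labels$depression, "depression", "speech",
                            k_range = c(0, 2, 4))
  expect_true(sw$table$skipped[sw$table$k == 0])
  ex4 <- run_experiment(sim$features["speech"], sim$sessions,
                        sim$labels$depression, "depression", "speech",
                        k = 4, enforce_gate = FALSE)
  expect_equal(sw$table$auc[sw$table$k == 4], ex4$evaluation$auc)
})
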