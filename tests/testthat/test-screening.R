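test_that("primary-session selection is deterministic and permutation-invariant", {
  s <- rbind(manifest_row("P1", "S1"), manifest_row("P1", "S5"),
             manifest_row("P2", "S2"), manifest_row("P3", "S3"))
  keep <- select_primary_sessions(s)
  expect_setequal(keep, c("S1", "S2", "S3"))
  set.seed(5)
  for (i in 1:5) {
    expect_setequal(select_primary_sessions(s[sample(nrow(s)), ]), keep)
  }
  # no repeats: identity
  s2 <- s[-2, ]
  expect_setequal(select_primary_sessions(s2), s2$session_id)
})

test_that("Kruskal-Wallis screen agrees with a brute-force rank oracle", {
  x1 <- c(1, 2, 3); x2 <- c(10, 11, 12)
  fm <- feature_matrix(matrix(c(x1, x2), ncol = 1), paste0("S", 1:6),
                       "f", "speech")
  scr <- kw_screen(fm, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  oracle <- kw_brute(x1, x2)
  expect_equal(unname(scr$p_values), oracle$p, tolerance = 1e-12)
  expect_lt(scr$p_values[1], 0.05)
  expect_equal(scr$k_mc, 1)

  # identical groups: H = 0, p = 1, not counted
  fm0 <- feature_matrix(matrix(rep(5, 8), ncol = 1), paste0("S", 1:8),
                        "f", "speech")
  scr0 <- kw_screen(fm0, rep(c(TRUE, FALSE), 4))
  expect_equal(unname(scr0$p_values), 1)
  expect_equal(scr0$k_mc, 0)

  # randomized instances with ties, vs kruskal.test and the fast CV path
  set.seed(13)
  for (i in 1:20) {
    n <- sample(8:20, 1)
    x <- sample(1:6, n, TRUE)  # heavy ties
    g <- sample(c(TRUE, FALSE), n, TRUE)
    if (sum(g) < 2 || sum(!g) < 2) next
    ref <- stats::kruskal.test(x, factor(g))$p.value
    fmx <- feature_matrix(matrix(x, ncol = 1), paste0("S", 1:n), "f", "speech")
    expect_equal(unname(kw_screen(fmx, g)$p_values), ref, tolerance = 1e-12)
    expect_equal(unname(mindmodal:::kw_pvalues_fast(fmx$values, g)), ref,
                 tolerance = 1e-12)
  }
})

test_that("screen p-values are invariant under monotone transforms", {
  set.seed(8)
  x <- rnorm(30)
  g <- rep(c(TRUE, FALSE), 15)
  p1 <- kw_screen(feature_matrix(matrix(x, ncol = 1), paste0("S", 1:30),
                                 "f", "speech"), g)$p_values
  p2 <- kw_screen(feature_matrix(matrix(exp(3 * x), ncol = 1),
                                 paste0("S", 1:30), "f", "speech"),
                  g)$p_values
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("Cohen's d follows its definition, sign convention, and CI", {
  same <- cohens_d(c(1, 2, 3, 4), c(4, 3, 2, 1))
  expect_equal(same$d, 0)

  a <- c(2, 4, 6); b <- c(1, 3, 5)
  es <- cohens_d(a, b)
  sp <- sqrt(((2) * var(a) + (2) * var(b)) / 4)
  expect_equal(es$d, (mean(a) - mean(b)) / sp, tolerance = 1e-12)
  # swapping roles negates d and mirrors the CI
  es2 <- cohens_d(b, a)
  expect_equal(es2$d, -es$d)
  expect_equal(es2$ci95, -rev(es$ci95))
  expect_true(es$ci95[1] <= es$d && es$d <= es$ci95[2])

  # zero pooled SD: 0 for equal means, signed Inf sentinel otherwise
  expect_equal(cohens_d(c(1, 1), c(1, 1))$d, 0)
  expect_warning(inf <- cohens_d(c(2, 2), c(1, 1))$d, "zero pooled SD")
  expect_identical(inf, Inf)
})

test_that("Cohen's d recovers a planted unit effect in simulation", {
  set.seed(99)
  es <- cohens_d(rnorm(200, 1), rnorm(200, 0))
  expect_lt(abs(es$d - 1), 0.15)
})

test_that("Pearson screen applies the |r| and p flagging rule", {
  set.seed(31)
  totals <- rnorm(60, 10, 5)
  vals <- cbind(exact = totals,
                noise = rnorm(60),
                konst = rep(2, 60))
  fm <- feature_matrix(vals, paste0("S", 1:60), colnames(vals), "speech")
  rep <- pearson_screen(fm, totals)
  expect_true(rep$flagged[rep$feature == "exact"])
  expect_equal(rep$r[rep$feature == "exact"], 1, tolerance = 1e-9)
  expect_false(rep$flagged[rep$feature == "konst"])
  expect_match(rep$note[rep$feature == "konst"], "constant")

  # r below 0.2 never flags regardless of p: force r ~ 0.19 with n large
  set.seed(32)
  n <- 5000
  t2 <- rnorm(n)
  x2 <- 0.19 * t2 + sqrt(1 - 0.19^2) * rnorm(n)
  r_emp <- cor(x2, t2)
  x2 <- x2 - (r_emp - 0.19) * t2  # nudge toward exactly r < 0.2
  fm2 <- feature_matrix(matrix(x2, ncol = 1), paste0("S", 1:n), "f", "speech")
  rep2 <- pearson_screen(fm2, t2)
  if (abs(rep2$r) < 0.2) expect_false(rep2$flagged)
  expect_lt(rep2$p, 0.05)
})

test_that("stable features are the intersection across folds and full sample", {
  full <- c("a", "b", "c")
  folds <- list(c("a", "b", "c"), c("a", "b", "c"))
  expect_setequal(stable_features(full, folds), full)
  folds2 <- list(c("a", "b"), c("a", "b", "c"))
  expect_setequal(stable_features(full, folds2), c("a", "b"))
  # subset property on random sets
  set.seed(17)
  for (i in 1:20) {
    full_s <- sample(letters, sample(5:15, 1))
    fs <- lapply(1:4, function(j) sample(letters, sample(5:15, 1)))
    out <- stable_features(full_s, fs)
    expect_true(all(out %in% full_s))
    for (f in fs) expect_true(all(out %in% f))
  }
})

test_that("screen_features ties the effect table to the significance count", {
  sim <- simulate_feature_cohort(
    50, 0, prevalence = c(depression = 0.4, anxiety = 0.3, suicide_risk = 0.3),
    planted = data.frame(modality = "speech", feature = "speech.feat_01",
                         condition = "depression", d = 1.5),
    seed = 5)
  scr <- screen_features(sim$features$speech, sim$labels$depression,
                         "depression", sex = sim$sessions$sex)
  expect_equal(scr$k_mc, sum(scr$table$significant))
  expect_true("speech.feat_01" %in%
                scr$table$feature[scr$table$significant])
  expect_gt(scr$table$d[scr$table$feature == "speech.feat_01"], 0)

  # stable-feature report restricts the table to the fold-stable subset
  sig <- scr$table$feature[scr$table$significant]
  folds <- list(sig, sig[1])
  rep <- stable_feature_report(scr, folds)
  expect_equal(rep$feature, sig[1])
})
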