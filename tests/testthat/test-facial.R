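test_that("canthal normalization removes zoom and fixes the unit distance", {
  tr <- make_track(40)
  tr2 <- tr
  tr2$xy <- tr$xy * 2  # uniform zoom
  n1 <- normalize_track(tr)
  n2 <- normalize_track(tr2)
  expect_equal(n1$xy, n2$xy, tolerance = 1e-12)
  icd <- sqrt(rowSums((n1$xy[, c("right_inner_canthus_x", "right_inner_canthus_y")] -
                         n1$xy[, c("left_inner_canthus_x", "left_inner_canthus_y")])^2))
  expect_equal(icd, rep(1, 40), tolerance = 1e-12)

  # degenerate canthal distance masks the frame
  tr3 <- tr
  tr3$xy[7, c("left_inner_canthus_x", "left_inner_canthus_y")] <-
    tr3$xy[7, c("right_inner_canthus_x", "right_inner_canthus_y")]
  expect_false(normalize_track(tr3)$valid[7])
})

test_that("distance features are invariant to translation and zoom", {
  tr <- make_track(60, overrides = list(
    lower_lip_center = function(t) cbind(0, 68 + 3 * sin(2 * pi * t))))
  f1 <- facial_features(tr)
  tr2 <- tr; tr2$xy <- tr$xy * 1.7 + 12.3
  f2 <- facial_features(tr2)
  keep <- !is.na(f1)
  expect_equal(f1[keep], f2[keep], tolerance = 1e-9)
})

test_that("mouth geometry matches hand-computed shoelace areas", {
  # rhombus with unit diagonals: area 1/2, symmetric halves 1/4 each
  tr <- make_track(5, overrides = list(
    mouth_corner_left = function(t) cbind(rep(33, length(t)), 60),
    mouth_corner_right = function(t) cbind(rep(-33, length(t)), 60),
    upper_lip_center = function(t) cbind(0, 60 - 33),
    lower_lip_center = function(t) cbind(0, 60 + 33)))
  g <- mouth_geometry(normalize_track(tr))
  expect_equal(g$mouth_area, rep(0.5, 5), tolerance = 1e-9)
  expect_equal(g$half_area_left, rep(0.25, 5), tolerance = 1e-9)
  expect_equal(g$symmetry, rep(1, 5), tolerance = 1e-9)
  expect_equal(g$lip_aperture, rep(1, 5), tolerance = 1e-9)
  expect_equal(g$lip_width, rep(1, 5), tolerance = 1e-9)

  # closed mouth: aperture and area collapse to zero
  trc <- make_track(3, overrides = list(
    lower_lip_center = function(t) cbind(0, rep(52, length(t)))))
  gc <- mouth_geometry(normalize_track(trc))
  expect_equal(gc$lip_aperture, rep(0, 3))
  expect_equal(gc$mouth_area, rep(0, 3))
})

test_that("mouth geometry arithmetic: 30 px lips over a 100 px canthal base", {
  tr <- make_track(3, overrides = list(
    right_inner_canthus = function(t) cbind(0, rep(0, length(t))),
    left_inner_canthus = function(t) cbind(100, rep(0, length(t))),
    upper_lip_center = function(t) cbind(50, 60),
    lower_lip_center = function(t) cbind(50, 90)))
  g <- mouth_geometry(normalize_track(tr))
  expect_equal(g$lip_aperture, rep(0.3, 3), tolerance = 1e-12)
})

test_that("kinematics satisfy polynomial differentiation identities", {
  tr_lin <- make_track(90, overrides = list(
    lower_lip_center = function(t) cbind(0, 0.1 * 66 * t)))
  # bypass normalization drift: canthi static, so normalization is /1 after
  k <- articulator_kinematics(normalize_track(tr_lin))
  v <- do.call(rbind, lapply(k$segments, function(s) s$v))
  expect_equal(v[, 2], rep(0.1, nrow(v)), tolerance = 1e-9)
  expect_equal(k$summary[["acc_absmax"]], 0, tolerance = 1e-8)
  expect_equal(k$summary[["jerk_absmax"]], 0, tolerance = 1e-7)

  tr_quad <- make_track(90, overrides = list(
    jaw_center = function(t) cbind(0, 66 * t^2)))
  k2 <- articulator_kinematics(normalize_track(tr_quad), "jaw_center")
  a <- do.call(rbind, lapply(k2$segments, function(s) s$a))
  expect_equal(a[, 2], rep(2, nrow(a)), tolerance = 1e-7)
  expect_equal(k2$summary[["jerk_absmax"]], 0, tolerance = 1e-6)
})

test_that("sinusoidal motion attains its closed-form peak velocity", {
  tr <- make_track(301, frame_rate = 100, overrides = list(
    lower_lip_center = function(t) cbind(0, 66 * sin(2 * pi * t))))
  k <- articulator_kinematics(normalize_track(tr))
  vmax <- max(abs(do.call(rbind, lapply(k$segments, function(s) s$v))[, 2]))
  expect_lt(abs(vmax - 2 * pi) / (2 * pi), 0.02)
})

test_that("kinematic summaries of a static face are exactly zero", {
  tr <- make_track(50)
  k <- articulator_kinematics(normalize_track(tr))
  expect_true(all(k$summary == 0))
})

test_that("absolute-maximum jerk dominates its directional components", {
  set.seed(11)
  for (i in 1:10) {
    tr <- landmarks_from_spec(6, 30, articulation_amplitude = runif(1, 0.01, 0.1),
                              blink_rate = 0.3, seed = i)
    k <- articulator_kinematics(normalize_track(tr))
    expect_gte(k$summary[["jerk_absmax"]],
               max(k$summary[["jerk_up_max"]], k$summary[["jerk_down_max"]]))
    expect_gte(k$summary[["acc_absmax"]],
               max(k$summary[["acc_up_max"]], k$summary[["acc_down_max"]]))
  }
})

test_that("blink detection counts constructed dips at the right rate", {
  # constant opening: no blinks
  expect_equal(blink_rate(normalize_track(make_track(90))), 0)

  # 10 dips of 4 frames in 20 s at 30 fps -> 0.5 blinks/s
  dip <- function(t) {
    y <- rep(-6, length(t))
    for (c0 in seq(1, 19, by = 2)) y[t >= c0 & t < c0 + 4 / 30] <- -0.5
    cbind(-45, y)
  }
  dip_lo <- function(t) {
    y <- rep(6, length(t))
    for (c0 in seq(1, 19, by = 2)) y[t >= c0 & t < c0 + 4 / 30] <- 0.5
    cbind(-45, y)
  }
  tr <- make_track(600, overrides = list(right_upper_eyelid = dip,
                                         right_lower_eyelid = dip_lo,
                                         left_upper_eyelid = function(t) {
                                           o <- dip(t); o[, 1] <- 45; o },
                                         left_lower_eyelid = function(t) {
                                           o <- dip_lo(t); o[, 1] <- 45; o }))
  rate <- blink_rate(normalize_track(tr))
  expect_equal(rate, 10 / (599 / 30), tolerance = 0.01)

  # dips shorter than min_blink_frames are not counted
  cfg <- facial_config(min_blink_frames = 5L)
  expect_equal(blink_rate(normalize_track(tr), cfg), 0)
})

test_that("eyebrow displacement reflects a mid-task raise", {
  tr <- make_track(200, overrides = list(
    right_eyebrow_center = function(t)
      cbind(-45, -25 - 66 * 0.1 * (t >= max(t) / 2)),
    left_eyebrow_center = function(t)
      cbind(45, -25 - 66 * 0.1 * (t >= max(t) / 2))))
  d <- eyebrow_displacement(normalize_track(tr))
  base <- 25 / 66
  expect_equal(mean(d), base + 0.05, tolerance = 0.002)
})

test_that("facial featurization survives gaps and missing eyes", {
  tr <- make_track(100, overrides = list(
    lower_lip_center = function(t) cbind(0, 68 + 2 * sin(4 * pi * t))))
  tr$xy[40:60, "lower_lip_center_y"] <- NA
  tr <- landmark_track(tr$t, tr$xy)
  f <- facial_features(tr)
  expect_false(is.na(f[["lower_lip_speed_mean"]]))
  # under 1 s of track: blink rate missing
  short <- make_track(20)
  expect_true(is.na(blink_rate(normalize_track(short))))
})
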