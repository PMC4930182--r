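test_that("joint angles match geometry and a dot-product oracle", {
  fs <- 30
  fr <- static_frames(4, fs)
  # place shoulder-elbow-wrist by hand: collinear, right angle, then random
  fr[joint_cols("shoulder_L")] <- matrix(c(0, 0, 0), 4, 3, byrow = TRUE)
  fr[joint_cols("elbow_L")] <- matrix(c(0, -0.3, 0), 4, 3, byrow = TRUE)
  wr <- rbind(c(0, -0.6, 0),    # straight arm: collinear -> 180
              c(0.3, -0.3, 0),  # perpendicular forearm -> 90
              c(0.1, -0.05, 0.2),
              c(-0.2, -0.5, 0.1))
  fr[joint_cols("wrist_L")] <- wr
  rec <- motion_recording(fr, "S", "left", "elbow_flexion", frame_rate = fs)
  ang <- joint_angle_series(rec, "shoulder_L", "elbow_L", "wrist_L")
  expect_equal(ang[1], 180)
  expect_equal(ang[2], 90)
  # independent oracle: arccos of normalized dot product, frame by frame
  for (i in 3:4) {
    u <- c(0, 0, 0) - c(0, -0.3, 0)
    v <- wr[i, ] - c(0, -0.3, 0)
    expect_equal(ang[i],
                 acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi)
  }
})

test_that("degenerate zero-length rays yield flagged NaN frames", {
  fr <- static_frames(3)
  fr[2, joint_cols("elbow_L")] <- fr[2, joint_cols("wrist_L")]
  rec <- motion_recording(fr, "S", "left", "elbow_flexion")
  ang <- joint_angle_series(rec, "shoulder_L", "wrist_L", "elbow_L")
  expect_true(is.nan(ang[2]))
  expect_equal(attr(ang, "n_degenerate"), 1L)
})

test_that("joint distances match a frame-by-frame brute-force loop", {
  rec <- synth_motion(motion_params("shoulder_flexion_0_90", 2L), seed = 3)
  d <- joint_distance_series(rec, "hand", "head")
  oracle <- vapply(seq_len(n_frames(rec)), function(i) {
    a <- as.numeric(rec$frames[i, joint_cols("hand_L")])
    b <- as.numeric(rec$frames[i, joint_cols("head")])
    sqrt(sum((a - b)^2))
  }, numeric(1))
  expect_equal(d, oracle)
  expect_equal(joint_distance_series(rec, "hand", "hand"),
               rep(0, n_frames(rec)))
  # static pose gives a constant series
  still <- hand_track_recording(rep(0, 20))
  expect_equal(diff(joint_distance_series(still, "hand", "head")),
               rep(0, 19))
})

test_that("series summaries match two-pass oracles and handle NaN", {
  expect_equal(unname(summarize_series(rep(3.5, 10))[c("range", "var", "mean")]),
               c(0, 0, 3.5))
  expect_equal(unname(summarize_series(c(0, 1))[c("range", "mean")]),
               c(1, 0.5))
  set.seed(8)
  x <- rnorm(200)
  s <- summarize_series(x)
  m <- sum(x) / length(x)                      # two-pass variance oracle
  expect_equal(unname(s["var"]), sum((x - m)^2) / (length(x) - 1))
  withnan <- c(x, NaN, NaN)
  s2 <- summarize_series(withnan)
  expect_equal(unname(s2["mean"]), m)
  expect_equal(attr(s2, "n_excluded"), 2L)
  expect_error(summarize_series(c(NaN, NaN)), "all-NaN")
})

test_that("feature extraction is deterministic, fixed-order and complete", {
  rec <- preprocess_recording(
    synth_motion(motion_params("elbow_flexion", 1L), seed = 21))$recording
  fv1 <- extract_features(rec)
  fv2 <- extract_features(rec)
  expect_identical(as.numeric(fv1), as.numeric(fv2))
  expect_identical(names(fv1), names(fv2))
  expect_length(fv1, 93L)
  expect_true(all(is.finite(fv1)))
  expect_identical(attr(fv1, "version"), FEATURE_ROSTER_VERSION)
  expect_true(all(c("normalized_jerk", "movement_duration",
                    "bbox_area_frontal") %in% names(fv1)))
  # unpreprocessed input is refused
  raw <- synth_motion(motion_params("elbow_flexion", 1L), seed = 21)
  expect_error(extract_features(raw), "clipped, pose-normalized")
})

test_that("larger-amplitude reaches have strictly larger displacement range", {
  for (seed in 1:5) {
    small <- preprocess_recording(synth_motion(
      motion_params("shoulder_abduction", 0L, amplitude_fraction = 0.1),
      seed = seed))$recording
    large <- preprocess_recording(synth_motion(
      motion_params("shoulder_abduction", 2L, amplitude_fraction = 0.9),
      seed = seed))$recording
    fs <- extract_features(small)
    fl <- extract_features(large)
    expect_gt(fl[["disp_hand_x.range"]], fs[["disp_hand_x.range"]])
    expect_gt(fl[["dist_hand_shoulder_center.range"]],
              fs[["dist_hand_shoulder_center.range"]])
  }
})

test_that("features are invariant to translation and scaling of raw input", {
  raw <- synth_motion(motion_params("elbow_flexion", 2L), seed = 31)
  fv0 <- extract_features(preprocess_recording(raw)$recording)
  moved <- transform_frames(raw, scale = 2.5, shift = c(-0.8, 0.4, 1.2))
  fv1 <- extract_features(preprocess_recording(moved)$recording)
  expect_equal(as.numeric(fv1), as.numeric(fv0), tolerance = 1e-8)
})

test_that("a no-motion attempt forced through yields zero-range features", {
  still <- hand_track_recording(rep(0, 40), clipped = TRUE)
  norm <- normalize_pose(still)
  # displacement ranges of noiseless still data are exactly zero; the jerk
  # statistic is undefined (no displacement), which is reported by name
  expect_error(extract_features(norm), "normalized_jerk")
  expect_equal(unname(summarize_series(
    joint_distance_series(norm, "hand", "head"))["range"]), 0)
})

test_that("feature matrices reject roster mismatches", {
  recs <- lapply(1:3, function(s) preprocess_recording(
    synth_motion(motion_params("elbow_flexion", 2L), seed = s))$recording)
  fvs <- lapply(recs, extract_features)
  M <- feature_matrix(fvs)
  expect_equal(dim(M), c(3L, 93L))
  broken <- fvs
  names(broken[[2]])[1] <- "renamed"
  expect_error(feature_matrix(broken), "mismatch")
})
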