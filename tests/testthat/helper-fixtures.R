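# shared fixture builders: all synthetic, constructed in code at test time

# frame table with every joint at a plausible static pose
static_frames <- function(n, fs = 30) {
  fr <- data.frame(t = (seq_len(n) - 1) / fs)
  pose <- list(
    head = c(0, 0.77, 2.3), shoulder_center = c(0, 0.55, 2.3),
    shoulder_L = c(0.18, 0.53, 2.3), shoulder_R = c(-0.18, 0.53, 2.3),
    elbow_L = c(0.21, 0.28, 2.41), elbow_R = c(-0.21, 0.28, 2.41),
    wrist_L = c(0.23, 0.33, 2.66), wrist_R = c(-0.23, 0.33, 2.66),
    hand_L = c(0.24, 0.35, 2.74), hand_R = c(-0.24, 0.35, 2.74))
  for (j in names(pose)) {
    fr[[paste0(j, ".x")]] <- pose[[j]][1]
    fr[[paste0(j, ".y")]] <- pose[[j]][2]
    fr[[paste0(j, ".z")]] <- pose[[j]][3]
  }
  fr
}

# recording whose left hand follows the given x-offset series, rest static
hand_track_recording <- function(dx, fs = 30, dy = NULL, dz = NULL,
                                 clipped = FALSE, side = "left") {
  fr <- static_frames(length(dx), fs)
  hand <- if (side == "left") "hand_L" else "hand_R"
  fr[[paste0(hand, ".x")]] <- fr[[paste0(hand, ".x")]] + dx
  if (!is.null(dy)) fr[[paste0(hand, ".y")]] <- fr[[paste0(hand, ".y")]] + dy
  if (!is.null(dz)) fr[[paste0(hand, ".z")]] <- fr[[paste0(hand, ".z")]] + dz
  motion_recording(fr, "T1", side, "elbow_flexion", frame_rate = fs,
                   clipped = clipped)
}

# still(pad)-move(move)-still(pad) minimum-jerk reach of the left hand
reach_recording <- function(D = 0.3, move_s = 2, pad_s = 1, fs = 30) {
  prof <- min_jerk_trajectory(D, move_s, fs)$x
  n_pad <- round(pad_s * fs)
  hand_track_recording(c(rep(0, n_pad), prof, rep(D, n_pad)), fs = fs)
}

# single-joint 1-D minimum-jerk recording for closed-form jerk checks
min_jerk_recording <- function(D = 0.3, T_total = 2, fs = 300) {
  hand_track_recording(min_jerk_trajectory(D, T_total, fs)$x, fs = fs,
                       clipped = TRUE)
}

# scale / translate every coordinate of a recording's frames
transform_frames <- function(rec, scale = 1, shift = c(0, 0, 0)) {
  fr <- rec$frames
  for (i in seq_along(c("x", "y", "z"))) {
    cols <- grep(paste0("\\.", c("x", "y", "z")[i], "$"), names(fr))
    fr[cols] <- fr[cols] * scale + shift[i]
  }
  rec$frames <- fr
  rec
}

# three well-separated Gaussian clusters in feature space, labels 0/1/2
separable_features <- function(n_per_class = 20, p = 12, seed = 99,
                               spread = 0.3) {
  set.seed(seed)
  centers <- rbind(rep(0, p), rep(4, p), c(rep(8, p %/% 2), rep(-4, p - p %/% 2)))
  X <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(n_per_class * p, sd = spread), ncol = p),
          2, centers[k, ], `+`)))
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = rep(0:2, each = n_per_class), centers = centers)
}

# valid 3-arm cohort data.frame
toy_cohort_df <- function() {
  df <- data.frame(subject_id = c("A", "B", "C"),
                   hemiplegic_side = c("left", "right", "left"),
                   brunnstrom_stage = c(3, 5, 2),
                   total_33 = c(30, 60, 12))
  for (it in fma_items()) df[[paste0("score_", it)]] <- c(1, 2, 0)
  df
}
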