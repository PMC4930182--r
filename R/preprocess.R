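#' Mirror a right-arm recording onto the left side
#'
#' To pool both arms in one learning problem, right-side recordings are
#' reflected about the subject's sagittal plane, approximated as the vertical
#' plane through the first-frame shoulder center with normal along the
#' camera x axis. Left/right joint labels are swapped so the moving arm is
#' always the left one. Left-side input is returned unchanged. The reflection
#' is an isometry: all inter-joint distances and all time stamps are
#' preserved.
#'
#' @param rec A [motion_recording()].
#' @return A `motion_recording` with `side == "left"`.
#' @export
mirror_to_left <- function(rec) {
  stopifnot(inherits(rec, "motion_recording"))
  if (rec$side == "left") return(rec)
  frames <- rec$frames
  x_sc <- frames[["shoulder_center.x"]][1L]
  x_cols <- grep("\\.x$", names(frames), value = TRUE)
  frames[x_cols] <- 2 * x_sc - frames[x_cols]
  # swap the _L / _R column blocks (coordinates already reflected)
  for (base in c("shoulder", "elbow", "wrist", "hand")) {
    l <- joint_cols(paste0(base, "_L"))
    r <- joint_cols(paste0(base, "_R"))
    tmp <- frames[l]
    frames[l] <- frames[r]
    frames[r] <- tmp
  }
  motion_recording(frames, rec$subject_id, "left", rec$item,
                   frame_rate = rec$frame_rate, normalized = rec$normalized,
                   clipped = rec$clipped)
}

#' Resample a recording to its nominal uniform rate
#'
#' Downstream derivative estimates assume uniform sampling; recordings whose
#' time stamps drift are linearly interpolated onto a uniform grid at the
#' nominal frame rate. Recordings already uniform to within `tol` of the
#' nominal interval are returned unchanged.
#'
#' @param rec A [motion_recording()].
#' @param tol Relative tolerance on the frame interval (default 1e-6).
#' @return A uniformly sampled `motion_recording`.
#' @export
resample_uniform <- function(rec, tol = 1e-6) {
  stopifnot(inherits(rec, "motion_recording"))
  t <- rec$frames$t
  dt <- 1 / rec$frame_rate
  if (all(abs(diff(t) - dt) <= tol * dt)) return(rec)
  grid <- seq(t[1L], t[length(t)], by = dt)
  frames <- data.frame(t = grid)
  for (cn in setdiff(recording_columns(), "t")) {
    frames[[cn]] <- stats::approx(t, rec$frames[[cn]], xout = grid)$y
  }
  replace_frames(rec, frames)
}

# body length L = |wrist-elbow| + |elbow-shoulder| + |shoulder-shoulder_center|
# on the moving side; "mean" averages over frames to damp sensor jitter
body_length <- function(rec, mode = c("mean", "first")) {
  mode <- match.arg(mode)
  sh <- joint_xyz(rec, "shoulder")
  el <- joint_xyz(rec, "elbow")
  wr <- joint_xyz(rec, "wrist")
  sc <- joint_xyz(rec, "shoulder_center")
  per_frame <- sqrt(rowSums((wr - el)^2)) + sqrt(rowSums((el - sh)^2)) +
    sqrt(rowSums((sh - sc)^2))
  if (mode == "first") per_frame[1L] else mean(per_frame)
}

#' Clip the still padding around a motion
#'
#' Recordings start and end with the subject at rest. The motion proper is
#' located by thresholding the per-frame displacement of the moving-side hand
#' joint, expressed in body-length-normalized units so the rule is invariant
#' to subject size and seating distance: the window runs from the first to
#' the last frame whose smoothed displacement exceeds `threshold`, extended
#' by `margin` frames on each side (clamped to the recording).
#'
#' @param rec A [motion_recording()] with at least 2 frames (resampled to a
#'   uniform rate if needed).
#' @param threshold Normalized displacement per frame; default 0.002 (0.2% of
#'   the summed arm-segment length per frame).
#' @param margin Frames retained on each side of the detected window
#'   (default 5).
#' @param smooth_window Width of the centered moving average applied to the
#'   displacement series before thresholding (default 5; 1 disables).
#' @param clip_joint `"hand"` (default) thresholds the hand joint's
#'   displacement; `"max"` the per-frame maximum over the six moving-side
#'   joints.
#' @return List with `$recording` (the clipped `motion_recording`) and
#'   `$window`, a `clip_window`: `start`/`end` (1-based inclusive frame
#'   indices into the input) and times `T1`/`T2`.
#' @export
clip_motion <- function(rec, threshold = 0.002, margin = 5L,
                        smooth_window = 5L, clip_joint = c("hand", "max")) {
  stopifnot(inherits(rec, "motion_recording"))
  clip_joint <- match.arg(clip_joint)
  rec <- resample_uniform(rec)
  n <- n_frames(rec)
  L <- body_length(rec)
  if (L < 1e-9) stop("degenerate skeleton: summed segment length ~ 0")
  disp <- if (clip_joint == "hand") {
    p <- joint_xyz(rec, "hand")
    c(0, sqrt(rowSums(diff(p)^2)))
  } else {
    P <- side_position_matrix(rec)
    d <- diff(P)
    c(0, apply(sqrt(d[, seq(1, 16, by = 3), drop = FALSE]^2 +
                    d[, seq(2, 17, by = 3), drop = FALSE]^2 +
                    d[, seq(3, 18, by = 3), drop = FALSE]^2), 1L, max))
  }
  disp <- disp / L
  if (smooth_window > 1L) {
    disp <- stats::filter(disp, rep(1 / smooth_window, smooth_window),
                          sides = 2L)
    disp[is.na(disp)] <- 0
  }
  active <- which(disp > threshold)
  if (length(active) == 0L) {
    stop("no motion detected: hand displacement never exceeds threshold ",
         threshold)
  }
  start <- max(1L, min(active) - as.integer(margin))
  end <- min(n, max(active) + as.integer(margin))
  out <- rec
  out$frames <- rec$frames[start:end, , drop = FALSE]
  rownames(out$frames) <- NULL
  out$clipped <- TRUE
  window <- structure(list(start = start, end = end,
                           T1 = rec$frames$t[start], T2 = rec$frames$t[end]),
                      class = "clip_window")
  list(recording = out, window = window)
}

#' Normalize pose for seating position and body size
#'
#' Joint positions are translated so the shoulder center of the first
#' (clipped) frame sits at the origin, then divided by the summed length of
#' the moving arm's segments (wrist--elbow + elbow--shoulder +
#' shoulder--shoulder center), making coordinates dimensionless. The output
#' is invariant under global translation and uniform scaling of the input.
#'
#' @param rec A clipped [motion_recording()].
#' @param length_mode `"mean"` (default) averages the segment sum over
#'   frames; `"first"` uses the first frame only.
#' @return A dimensionless `motion_recording` (`normalized = TRUE`).
#' @export
normalize_pose <- function(rec, length_mode = c("mean", "first")) {
  stopifnot(inherits(rec, "motion_recording"))
  L <- body_length(rec, match.arg(length_mode))
  if (L < 1e-9) stop("degenerate skeleton: summed segment length ~ 0")
  frames <- rec$frames
  origin <- as.numeric(frames[1L, joint_cols("shoulder_center")])
  for (a in c("x", "y", "z")) {
    cols <- grep(paste0("\\.", a, "$"), names(frames), value = TRUE)
    frames[cols] <- (frames[cols] - origin[match(a, c("x", "y", "z"))]) / L
  }
  out <- rec
  out$frames <- frames
  out$normalized <- TRUE
  out
}

#' Run the standard preprocessing chain on one recording
#'
#' Mirror (if right-sided), resample to the nominal rate, clip the still
#' padding, and pose-normalize. If no motion is detected at the clipping
#' threshold — as happens when the attempt's amplitude is essentially zero —
#' the whole recording is retained and flagged, since the absence of motion
#' is itself informative for scoring.
#'
#' @param rec A [motion_recording()].
#' @inheritParams clip_motion
#' @return List: `$recording` (clipped + normalized), `$window`
#'   ([clip_motion()] window), `$no_motion` (logical fallback flag).
#' @export
preprocess_recording <- function(rec, threshold = 0.002, margin = 5L,
                                 smooth_window = 5L) {
  rec <- resample_uniform(mirror_to_left(rec))
  clipped <- tryCatch(
    clip_motion(rec, threshold = threshold, margin = margin,
                smooth_window = smooth_window),
    error = function(e) {
      if (grepl("no motion detected", conditionMessage(e))) NULL
      else stop(e)
    })
  if (is.null(clipped)) {
    out <- rec
    out$clipped <- TRUE
    window <- structure(list(start = 1L, end = n_frames(rec),
                             T1 = rec$frames$t[1L],
                             T2 = rec$frames$t[n_frames(rec)]),
                        class = "clip_window")
    list(recording = normalize_pose(out), window = window, no_motion = TRUE)
  } else {
    list(recording = normalize_pose(clipped$recording),
         window = clipped$window, no_motion = FALSE)
  }
}
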