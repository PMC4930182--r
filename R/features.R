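#' Per-frame angle at a joint
#'
#' Angle at vertex `b` between the rays `b -> a` and `b -> c`, in degrees
#' within \[0, 180\]. Frames where either ray has (numerically) zero length
#' yield `NaN` and are counted in the `n_degenerate` attribute.
#'
#' @param rec A [motion_recording()].
#' @param a,b,c Joint names ([fma_joints()] or unsided, resolved against the
#'   recording's side).
#' @return Numeric vector of length `n_frames(rec)`.
#' @export
joint_angle_series <- function(rec, a, b, c) {
  u <- joint_xyz(rec, a) - joint_xyz(rec, b)
  v <- joint_xyz(rec, c) - joint_xyz(rec, b)
  nu <- sqrt(rowSums(u^2))
  nv <- sqrt(rowSums(v^2))
  cosang <- rowSums(u * v) / (nu * nv)
  bad <- nu < 1e-12 | nv < 1e-12
  cosang[bad] <- NaN
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  attr(ang, "n_degenerate") <- sum(bad)
  ang
}

#' Per-frame distance between two joints
#'
#' @inheritParams joint_angle_series
#' @return Numeric vector of Euclidean distances per frame.
#' @export
joint_distance_series <- function(rec, a, b) {
  d <- joint_xyz(rec, a) - joint_xyz(rec, b)
  sqrt(rowSums(d^2))
}

#' Summary statistics of a kinematic time series
#'
#' The motion's range grows with the FMA score, so each series is reduced to
#' bounding and dispersion summaries: min, max, range, variance and mean.
#' `NaN` values (degenerate frames) are excluded; their count is returned as
#' an attribute.
#'
#' @param s Numeric series with at least one non-`NaN` value.
#' @return Named numeric vector `c(min, max, range, var, mean)` with
#'   attribute `n_excluded`.
#' @export
summarize_series <- function(s) {
  keep <- !is.na(s)
  if (!any(keep)) stop("cannot summarize an all-NaN series")
  x <- s[keep]
  out <- c(min = min(x), max = max(x), range = max(x) - min(x),
           var = if (length(x) > 1L) stats::var(x) else 0,
           mean = mean(x))
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' @rdname extract_features
#' @format NULL
#' @export
FEATURE_ROSTER_VERSION <- "fmscore-features-1"

# the fixed series roster: 4 angles, 8 distances, 6 displacement components
feature_series <- function(rec) {
  contra_shoulder <- if (rec$side == "left") "shoulder_R" else "shoulder_L"
  hand <- joint_xyz(rec, "hand")
  wrist <- joint_xyz(rec, "wrist")
  list(
    ang_elbow = joint_angle_series(rec, "shoulder", "elbow", "wrist"),
    ang_shoulder = joint_angle_series(rec, "shoulder_center", "shoulder", "elbow"),
    ang_shoulder_wrist = joint_angle_series(rec, "shoulder_center", "shoulder", "wrist"),
    ang_trunk_hand = joint_angle_series(rec, "head", "shoulder_center", "hand"),
    dist_hand_shoulder = joint_distance_series(rec, "hand", "shoulder"),
    dist_hand_head = joint_distance_series(rec, "hand", "head"),
    dist_elbow_head = joint_distance_series(rec, "elbow", "head"),
    dist_hand_shoulder_center = joint_distance_series(rec, "hand", "shoulder_center"),
    dist_wrist_head = joint_distance_series(rec, "wrist", "head"),
    dist_hand_shoulder_contra = joint_distance_series(rec, "hand", contra_shoulder),
    dist_wrist_shoulder = joint_distance_series(rec, "wrist", "shoulder"),
    dist_elbow_shoulder_center = joint_distance_series(rec, "elbow", "shoulder_center"),
    disp_hand_x = hand[, "x"] - hand[1L, "x"],
    disp_hand_y = hand[, "y"] - hand[1L, "y"],
    disp_hand_z = hand[, "z"] - hand[1L, "z"],
    disp_wrist_x = wrist[, "x"] - wrist[1L, "x"],
    disp_wrist_y = wrist[, "y"] - wrist[1L, "y"],
    disp_wrist_z = wrist[, "z"] - wrist[1L, "z"])
}

#' Extract the kinematic feature vector of a recording
#'
#' Reduces one clipped, pose-normalized recording to the fixed, versioned
#' feature roster used for score prediction: five summaries
#' ([summarize_series()]) of each of 18 kinematic series (elbow/shoulder/trunk
#' angles, pairwise joint distances, per-axis hand and wrist displacement),
#' plus the dimensionless normalized jerk, the movement duration, and the
#' area of the hand trajectory's axis-aligned bounding rectangle in the
#' frontal (x--y) plane — 93 features in all, identically named and ordered
#' for every recording of an item.
#'
#' @param rec A clipped, normalized [motion_recording()] with >= 7 frames.
#' @param item FMA item the features describe; defaults to the recording's.
#' @return Named numeric `feature_vector` with attributes `item`, `version`
#'   and `provenance` (subject/side).
#' @export
extract_features <- function(rec, item = rec$item) {
  stopifnot(inherits(rec, "motion_recording"))
  item <- match_item(item)
  if (!rec$normalized || !rec$clipped) {
    stop("extract_features expects a clipped, pose-normalized recording; ",
         "run preprocess_recording() first")
  }
  series <- feature_series(rec)
  vals <- unlist(lapply(names(series), function(nm) {
    s <- tryCatch(summarize_series(series[[nm]]),
                  error = function(e) stop("feature '", nm, "' failed: ",
                                           conditionMessage(e)))
    names(s) <- paste(nm, names(s), sep = ".")
    s
  }))
  jr <- tryCatch(normalized_jerk(rec),
                 error = function(e) stop("feature 'normalized_jerk' failed: ",
                                          conditionMessage(e)))
  hand <- joint_xyz(rec, "hand")
  bbox <- diff(range(hand[, "x"])) * diff(range(hand[, "y"]))
  vals <- c(vals,
            normalized_jerk = jr$normalized_jerk,
            movement_duration = jr$duration,
            bbox_area_frontal = bbox)
  if (!all(is.finite(vals))) {
    bad <- names(vals)[!is.finite(vals)][1L]
    stop("feature '", bad, "' is non-finite")
  }
  structure(vals, class = "feature_vector", item = item,
            version = FEATURE_ROSTER_VERSION,
            provenance = paste(rec$subject_id, rec$side, sep = "/"))
}

#' Stack feature vectors into a matrix
#'
#' @param fvs List of [extract_features()] results for one item.
#' @return Numeric matrix, one row per recording, columns in roster order.
#' @export
feature_matrix <- function(fvs) {
  stopifnot(length(fvs) > 0L)
  nm <- names(fvs[[1L]])
  for (fv in fvs) {
    if (!identical(names(fv), nm)) stop("feature name/order mismatch in batch")
  }
  m <- do.call(rbind, lapply(fvs, as.numeric))
  colnames(m) <- nm
  rownames(m) <- vapply(fvs, function(f) attr(f, "provenance"), character(1))
  m
}
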