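#' Construct a motion recording
#'
#' A `motion_recording` holds one attempt at one FMA item: an ordered,
#' strictly time-increasing sequence of skeleton frames plus metadata. The
#' frame table has 31 columns (`t` in seconds, then x/y/z in meters for each
#' of the ten joints returned by [fma_joints()]).
#'
#' @param frames data.frame with the 31 columns of [fma_joints()] layout
#'   (`t`, then `<joint>.x`, `<joint>.y`, `<joint>.z`).
#' @param subject_id Opaque subject identifier.
#' @param side Which arm the recording captures, `"left"` or `"right"`.
#' @param item One of [fma_items()].
#' @param frame_rate Nominal sampling rate in Hz (default 30, the depth
#'   camera's native skeleton rate).
#' @param normalized Logical; `TRUE` once the recording has passed
#'   [normalize_pose()] and coordinates are dimensionless.
#' @param clipped Logical; `TRUE` once the still padding has been removed by
#'   [clip_motion()].
#' @return An object of class `motion_recording`.
#' @export
motion_recording <- function(frames, subject_id, side, item,
                             frame_rate = 30, normalized = FALSE,
                             clipped = FALSE) {
  side <- match_side(side)
  item <- match_item(item)
  frames <- as.data.frame(frames)
  cols <- recording_columns()
  missing <- setdiff(cols, names(frames))
  if (length(missing) > 0L) {
    stop("frame table is missing columns: ", paste(missing, collapse = ", "))
  }
  frames <- frames[, cols]
  if (nrow(frames) < 2L) {
    stop("a motion recording needs at least 2 frames, got ", nrow(frames))
  }
  if (!all(vapply(frames, is.numeric, logical(1)))) {
    stop("all 31 frame variables must be numeric")
  }
  if (!all(is.finite(as.matrix(frames)))) {
    stop("non-finite coordinate or time stamp in frame table")
  }
  if (any(diff(frames$t) <= 0)) {
    bad <- which(diff(frames$t) <= 0)[1L] + 1L
    stop("time stamps must be strictly increasing (violated at frame ", bad, ")")
  }
  if (!is.numeric(frame_rate) || frame_rate <= 0) {
    stop("frame_rate must be a positive number")
  }
  structure(
    list(subject_id = as.character(subject_id), side = side, item = item,
         frame_rate = frame_rate, frames = frames,
         normalized = isTRUE(normalized), clipped = isTRUE(clipped)),
    class = "motion_recording")
}

#' @export
print.motion_recording <- function(x, ...) {
  cat(sprintf(
    "<motion_recording> subject=%s side=%s item=%s\n  %d frames @ %g Hz, %.2f s%s%s\n",
    x$subject_id, x$side, x$item, nrow(x$frames), x$frame_rate,
    diff(range(x$frames$t)),
    if (x$clipped) ", clipped" else "",
    if (x$normalized) ", pose-normalized" else ""))
  invisible(x)
}

#' Number of frames in a recording
#' @param rec A `motion_recording`.
#' @return Integer frame count.
#' @export
n_frames <- function(rec) nrow(rec$frames)

#' Extract one joint's trajectory
#'
#' @param rec A `motion_recording`.
#' @param joint One of [fma_joints()], or an unsided name
#'   (`"hand"`, `"wrist"`, `"elbow"`, `"shoulder"`) resolved against
#'   `rec$side`.
#' @return Numeric matrix with `n_frames(rec)` rows and columns x, y, z.
#' @export
joint_xyz <- function(rec, joint) {
  joint <- resolve_joint(joint, rec$side)
  m <- as.matrix(rec$frames[, joint_cols(joint)])
  colnames(m) <- c("x", "y", "z")
  m
}

resolve_joint <- function(joint, side) {
  if (joint %in% fma_joints()) return(joint)
  if (joint %in% c("shoulder", "elbow", "wrist", "hand")) {
    return(paste(joint, if (side == "left") "L" else "R", sep = "_"))
  }
  stop("unknown joint: ", joint)
}

# stacked positions of the six moving-side joints: n x 18 matrix
side_position_matrix <- function(rec) {
  cols <- unlist(lapply(side_joints(rec$side), joint_cols))
  as.matrix(rec$frames[, cols])
}

replace_frames <- function(rec, frames) {
  motion_recording(frames, rec$subject_id, rec$side, rec$item,
                   frame_rate = rec$frame_rate, normalized = rec$normalized,
                   clipped = rec$clipped)
}
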