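#' Tracked upper-body joints
#'
#' The skeleton model carries ten named joints. Together with the time stamp,
#' each frame therefore holds 1 + 10 x 3 = 31 scalar values.
#'
#' @return Character vector of the ten joint names.
#' @export
fma_joints <- function() {
  c("head", "shoulder_center",
    "shoulder_L", "shoulder_R",
    "elbow_L", "elbow_R",
    "wrist_L", "wrist_R",
    "hand_L", "hand_R")
}

#' Implemented FMA upper-extremity items
#'
#' The thirteen upper-extremity motor items that can be scored from skeletal
#' tracking alone: the six flexor-synergy movements, the three
#' extensor-synergy movements, and four movements combining or leaving the
#' synergies. Each item is scored 0 (cannot perform), 1 (partial) or 2
#' (performs fully), so the thirteen-item sum ranges 0--26; the full 33-item
#' upper-extremity motor scale totals 66.
#'
#' @return Character vector of 13 item codes.
#' @export
fma_items <- function() {
  c("shoulder_retraction",
    "shoulder_elevation",
    "shoulder_abduction",
    "shoulder_external_rotation",
    "elbow_flexion",
    "forearm_supination",
    "shoulder_adduction_internal_rotation",
    "elbow_extension",
    "forearm_pronation",
    "hand_to_lumbar_spine",
    "shoulder_flexion_0_90",
    "shoulder_abduction_0_90",
    "shoulder_flexion_90_180")
}

#' @rdname fma_items
#' @format NULL
#' @export
FMA_ITEM_MAX_SCORE <- 2L

#' @rdname fma_items
#' @format NULL
#' @export
FMA_13_MAX_SUM <- 26L

#' @rdname fma_items
#' @format NULL
#' @export
FMA_UE_TOTAL_MAX <- 66L

# column names of the on-disk / in-memory frame table: t then x/y/z per joint
recording_columns <- function() {
  c("t", as.vector(t(outer(fma_joints(), c("x", "y", "z"),
                           function(j, a) paste(j, a, sep = ".")))))
}

joint_cols <- function(joint) paste(joint, c("x", "y", "z"), sep = ".")

# the six joints entering the 18-dimensional jerk vector for one side
side_joints <- function(side) {
  suffix <- if (side == "left") "L" else "R"
  c("head", "shoulder_center",
    paste(c("shoulder", "elbow", "wrist", "hand"), suffix, sep = "_"))
}

match_item <- function(item) match.arg(item, fma_items())

match_side <- function(side) match.arg(side, c("left", "right"))
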