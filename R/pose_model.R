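#' Keypoint model specification
#'
#' Describes one of the standard 2-D body-pose keypoint models fit by
#' OpenPose-style pose estimators: `"body25"` (25 body landmarks),
#' `"face"` (70 facial landmarks) or `"hand_left"`/`"hand_right"`
#' (21 landmarks per hand). The specification carries the point count,
#' point labels, and the name of the keypoint field inside per-frame
#' JSON documents.
#'
#' @param name Model name, one of `"body25"`, `"face"`, `"hand_left"`,
#'   `"hand_right"`. The bare `"hand"` is accepted as an alias for
#'   `"hand_right"` (the dominant hand in most stimulus material).
#' @return An object of class `pose_model` with fields `name`,
#'   `n_points`, `labels` (unique point names, length `n_points`) and
#'   `json_field` (the keypoint array name in frame JSON documents).
#' @examples
#' m <- pose_model("body25")
#' m$n_points          # 25
#' m$labels[3:5]       # right-arm chain: shoulder, elbow, wrist
#' @export
pose_model <- function(name = c("body25", "face", "hand_left", "hand_right", "hand")) {
  name <- match.arg(name)
  if (name == "hand") name <- "hand_right"
  labels <- switch(name,
    body25 = c(
      "Nose", "Neck",
      "RShoulder", "RElbow", "RWrist",
      "LShoulder", "LElbow", "LWrist",
      "MidHip",
      "RHip", "RKnee", "RAnkle",
      "LHip", "LKnee", "LAnkle",
      "REye", "LEye", "REar", "LEar",
      "LBigToe", "LSmallToe", "LHeel",
      "RBigToe", "RSmallToe", "RHeel"
    ),
    face = sprintf("Face%02d", 0:69),
    hand_left = hand_labels(),
    hand_right = hand_labels()
  )
  stopifnot(!anyDuplicated(labels))
  json_field <- switch(name,
    body25     = "pose_keypoints_2d",
    face       = "face_keypoints_2d",
    hand_left  = "hand_left_keypoints_2d",
    hand_right = "hand_right_keypoints_2d"
  )
  structure(
    list(name = name, n_points = length(labels), labels = labels,
         json_field = json_field),
    class = "pose_model"
  )
}

hand_labels <- function() {
  c("Wrist",
    paste0(rep(c("Thumb", "Index", "Middle", "Ring", "Pinky"), each = 4), 1:4))
}

#' @export
print.pose_model <- function(x, ...) {
  cat(sprintf("<pose_model> %s: %d points (%s, ...)\n",
              x$name, x$n_points, paste(utils::head(x$labels, 3), collapse = ", ")))
  invisible(x)
}

as_pose_model <- function(model) {
  if (inherits(model, "pose_model")) return(model)
  if (is.character(model) && length(model) == 1L) return(pose_model(model))
  stop("`model` must be a pose_model object or a model name", call. = FALSE)
}

# body25 arm keypoint chains, 0-based indices per the OpenPose convention.
# "Left"/"right" are anatomical: the actor's left arm appears on image right.
BODY25_RIGHT_ARM <- c(2L, 3L, 4L)
BODY25_LEFT_ARM  <- c(5L, 6L, 7L)
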