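#' Which arm(s) did the actor move?
#'
#' Classifies a body25 clip as `"left"`, `"right"`, `"both"` or `"none"`
#' from per-side motion: for each side the keypoint speeds
#' \eqn{\sqrt{v_x^2 + v_y^2}} are summed over all frame transitions and
#' over that side's arm chain (shoulder, elbow, wrist — 0-based body25
#' indices 2,3,4 on the right and 5,6,7 on the left, anatomical labels:
#' the actor's left arm appears on image right). The decision rule:
#' `"none"` if both side sums fall below an absolute floor; `"both"` if
#' the smaller side is at least `rel_threshold` of the larger; otherwise
#' the side with the larger sum. The rule and its constants are this
#' package's own heuristic; both thresholds are configurable.
#'
#' @param seq A cleaned body25 [pose_sequence()] with at least 2 frames.
#' @param rel_threshold Balance threshold in `(0, 1]`; default 0.5.
#' @param abs_floor Absolute per-side floor in summed pixels/second below
#'   which a side counts as not moving; default 1.
#' @return An object of class `laterality`: `label`, `left_motion`,
#'   `right_motion` (summed speeds, pixels/second) and `ratio`
#'   (smaller/larger side, in `[0, 1]`).
#' @export
det_hand <- function(seq, rel_threshold = 0.5, abs_floor = 1) {
  stopifnot(inherits(seq, "pose_sequence"))
  if (seq$model$name != "body25")
    stop(sprintf("laterality detection requires the body25 model, got '%s'",
                 seq$model$name), call. = FALSE)
  if (!is.numeric(rel_threshold) || length(rel_threshold) != 1L ||
      rel_threshold <= 0 || rel_threshold > 1)
    stop("rel_threshold must lie in (0, 1]", call. = FALSE)
  fld <- velocity(seq)
  speed <- sqrt(fld$vx^2 + fld$vy^2)
  right <- sum(speed[, BODY25_RIGHT_ARM + 1L])
  left  <- sum(speed[, BODY25_LEFT_ARM + 1L])
  hi <- max(left, right); lo <- min(left, right)
  ratio <- if (hi > 0) lo / hi else 1
  label <- if (hi < abs_floor) "none"
           else if (ratio >= rel_threshold) "both"
           else if (left > right) "left"
           else "right"
  structure(list(label = label, left_motion = left, right_motion = right,
                 ratio = ratio, rel_threshold = rel_threshold,
                 abs_floor = abs_floor),
            class = "laterality")
}

#' @export
print.laterality <- function(x, ...) {
  cat(sprintf("<laterality> %s  (left %.4g, right %.4g px/s; ratio %.3f)\n",
              x$label, x$left_motion, x$right_motion, x$ratio))
  invisible(x)
}
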