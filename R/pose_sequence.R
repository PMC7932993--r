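#' Construct a pose sequence
#'
#' A pose sequence is the in-memory form of a clip's motion-tracking data:
#' for every video frame and every keypoint of the governing model, an
#' `(x, y, confidence)` triplet in image pixel coordinates (origin top-left,
#' y increasing downward, as emitted by the pose estimator). Frames are
#' 0-based and consecutive; for a complete clip the frame count equals
#' clip duration times frame rate.
#'
#' @param x,y Numeric matrices, `n_frames x n_points`, pixel coordinates.
#' @param conf Numeric matrix of the same shape, per-keypoint detection
#'   confidence in `[0, 1]` (0 together with `x = y = 0` marks a failed fit).
#' @param model A [pose_model()] or model name; its `n_points` must match
#'   the column count.
#' @param fps Frame rate of the source clip in frames per second (default 25).
#' @param source_id Clip identifier, used as the output filename stem.
#' @return An object of class `pose_sequence`.
#' @export
pose_sequence <- function(x, y, conf, model = "body25", fps = 25,
                          source_id = "clip") {
  model <- as_pose_model(model)
  x <- as.matrix(x); y <- as.matrix(y); conf <- as.matrix(conf)
  if (!identical(dim(x), dim(y)) || !identical(dim(x), dim(conf)))
    stop("x, y and conf must have identical dimensions", call. = FALSE)
  if (ncol(x) != model$n_points)
    stop(sprintf("model '%s' has %d points but data has %d columns",
                 model$name, model$n_points, ncol(x)), call. = FALSE)
  if (nrow(x) > 0 && (min(conf) < 0 || max(conf) > 1))
    stop("confidence values must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("fps must be a single positive number", call. = FALSE)
  dimnames(x) <- dimnames(y) <- dimnames(conf) <- NULL
  structure(
    list(x = x, y = y, conf = conf, model = model, fps = fps,
         source_id = as.character(source_id)),
    class = "pose_sequence"
  )
}

#' Number of frames in a pose sequence
#' @param seq A [pose_sequence()].
#' @return Integer frame count.
#' @export
n_frames <- function(seq) {
  stopifnot(inherits(seq, "pose_sequence"))
  nrow(seq$x)
}

#' @export
print.pose_sequence <- function(x, ...) {
  cat(sprintf("<pose_sequence> '%s': %d frames x %d points (%s), %g fps (%.2f s)\n",
              x$source_id, nrow(x$x), x$model$n_points, x$model$name,
              x$fps, nrow(x$x) / x$fps))
  invisible(x)
}

#' @export
summary.pose_sequence <- function(object, cutoff = 0.3, ...) {
  inv <- find_invalid(object, cutoff = cutoff)
  out <- list(
    source_id = object$source_id,
    model = object$model$name,
    n_frames = nrow(object$x),
    n_points = object$model$n_points,
    fps = object$fps,
    duration = nrow(object$x) / object$fps,
    n_invalid = sum(inv),
    frac_invalid = if (length(inv)) mean(inv) else 0,
    cutoff = cutoff
  )
  class(out) <- "summary.pose_sequence"
  out
}

#' @export
print.summary.pose_sequence <- function(x, ...) {
  cat(sprintf("Pose sequence '%s' (%s model)\n", x$source_id, x$model))
  cat(sprintf("  %d frames x %d points at %g fps (%.2f s)\n",
              x$n_frames, x$n_points, x$fps, x$duration))
  cat(sprintf("  invalid observations (all-zero or conf < %g): %d (%.1f%%)\n",
              x$cutoff, x$n_invalid, 100 * x$frac_invalid))
  invisible(x)
}

#' @export
plot.pose_sequence <- function(x, ...) plot_frontal(x, ...)

# Single frame as a list of aligned vectors; internal working unit.
frame_pose <- function(x, y, conf, model) {
  model <- as_pose_model(model)
  stopifnot(length(x) == model$n_points,
            length(y) == model$n_points,
            length(conf) == model$n_points)
  list(x = as.numeric(x), y = as.numeric(y), conf = as.numeric(conf))
}
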