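#' Locate failed and low-confidence keypoint observations
#'
#' A keypoint observation is invalid when the pose estimator's fit failed —
#' signalled by an all-zero `(x, y, confidence)` triplet — or when its
#' confidence falls strictly below the cutoff (so `c = 0.30` is kept at the
#' default cutoff while `c = 0.29` is not). Such observations make points
#' appear to jump between frames and corrupt velocity and acceleration if
#' left in place.
#'
#' @param seq A [pose_sequence()].
#' @param cutoff Confidence threshold in `[0, 1]`; default 0.3.
#' @return A logical `n_frames x n_points` matrix, `TRUE` where the
#'   observation is invalid, with the cutoff attached as attribute
#'   `"cutoff"`.
#' @export
find_invalid <- function(seq, cutoff = 0.3) {
  stopifnot(inherits(seq, "pose_sequence"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff) ||
      cutoff < 0 || cutoff > 1)
    stop("cutoff must be a single value in [0, 1]", call. = FALSE)
  inv <- (seq$x == 0 & seq$y == 0 & seq$conf == 0) | seq$conf < cutoff
  attr(inv, "cutoff") <- cutoff
  inv
}

#' Impute invalid keypoint observations
#'
#' Replaces each invalid observation's x and y by interpolating from the
#' nearest valid neighbours of the same point: an isolated gap becomes the
#' mean of the previous and following valid frames; a run of consecutive
#' invalid frames is filled by linear interpolation between the bounding
#' valid frames; runs touching a clip boundary take the nearest valid
#' value. Valid observations are never modified, and confidences are left
#' untouched — provenance lives in the returned mask, not in-band.
#'
#' @param seq A [pose_sequence()].
#' @param invalid Logical mask from [find_invalid()] (recomputed with the
#'   default cutoff when omitted).
#' @return The imputed [pose_sequence()], with the mask attached as
#'   attribute `"imputed"`.
#' @export
impute_invalid <- function(seq, invalid = find_invalid(seq)) {
  stopifnot(inherits(seq, "pose_sequence"))
  if (!identical(dim(invalid), dim(seq$x)))
    stop("mask shape does not match the sequence", call. = FALSE)
  n <- nrow(seq$x)
  for (j in seq_len(ncol(seq$x))) {
    bad <- which(invalid[, j])
    if (length(bad) == 0L) next
    ok <- setdiff(seq_len(n), bad)
    if (length(ok) == 0L)
      stop(sprintf("point %d ('%s') has no valid observation in the clip",
                   j - 1L, seq$model$labels[j]), call. = FALSE)
    # rule = 2: constant extrapolation = nearest-valid fill at boundaries
    seq$x[bad, j] <- stats::approx(ok, seq$x[ok, j], xout = bad, rule = 2)$y
    seq$y[bad, j] <- stats::approx(ok, seq$y[ok, j], xout = bad, rule = 2)$y
  }
  attr(seq, "imputed") <- invalid
  seq
}

#' Clean a pose sequence
#'
#' Convenience composition of [find_invalid()] and [impute_invalid()].
#'
#' @inheritParams find_invalid
#' @return The cleaned [pose_sequence()] (mask in attribute `"imputed"`).
#' @export
clean_pose <- function(seq, cutoff = 0.3) {
  impute_invalid(seq, find_invalid(seq, cutoff = cutoff))
}

#' Clean a per-clip keypoint CSV file
#'
#' Reads a clip table in the package's tabular dialect, cleans it, and
#' writes the result. With `overwrite = FALSE` (the default) the output is
#' written next to the input as `<stem>_cleaned.csv`; with
#' `overwrite = TRUE` the input file is replaced.
#'
#' @param path Path to a CSV written by [write_pose_csv()]/[convert_clip()].
#' @param cutoff Confidence threshold in `[0, 1]`.
#' @param overwrite Replace the input file instead of writing a sibling.
#' @return The path of the cleaned file, invisibly.
#' @export
clean_file <- function(path, cutoff = 0.3, overwrite = FALSE) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff) ||
      cutoff < 0 || cutoff > 1)
    stop("cutoff must be a single value in [0, 1]", call. = FALSE)
  seq <- read_pose_csv(path)
  cleaned <- clean_pose(seq, cutoff = cutoff)
  out <- if (overwrite) path else
    file.path(dirname(path),
              paste0(tools::file_path_sans_ext(basename(path)), "_cleaned.csv"))
  if (!overwrite)
    cleaned$source_id <- paste0(cleaned$source_id, "_cleaned")
  write_pose_csv(cleaned, out)
  invisible(out)
}
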