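#' Per-point velocity by frame differencing
#'
#' For every keypoint and axis, velocity at frame transition
#' \eqn{t \to t+1} is the difference quotient
#' \eqn{(p_{t+1} - p_t) / \Delta t} with \eqn{\Delta t = 1/\mathrm{fps}},
#' giving pixels per second. A sequence of \eqn{n} frames yields
#' \eqn{n - 1} transitions; no padding row is prepended.
#'
#' @param seq A [pose_sequence()] with at least 2 frames. The sequence
#'   should normally have been cleaned first ([clean_pose()]); this is not
#'   enforced.
#' @return A `motion_field` object with matrices `vx`, `vy` of shape
#'   `(n_frames - 1) x n_points` (pixels/second), plus `fps`, `model` and
#'   `quantity = "velocity"`.
#' @export
velocity <- function(seq) {
  stopifnot(inherits(seq, "pose_sequence"))
  if (n_frames(seq) < 2L)
    stop("velocity requires at least 2 frames", call. = FALSE)
  motion_field(diff(seq$x) * seq$fps, diff(seq$y) * seq$fps,
               fps = seq$fps, quantity = "velocity", model = seq$model)
}

#' Per-point acceleration by second differencing
#'
#' The first difference of the velocity field divided by the frame
#' interval: \eqn{a_t = (v_{t+1} - v_t) \cdot \mathrm{fps}}, in pixels per
#' second squared, with \eqn{n - 2} entries for an \eqn{n}-frame clip.
#'
#' @param seq A [pose_sequence()] with at least 3 frames.
#' @return A `motion_field` with `quantity = "acceleration"` and matrices
#'   `vx`, `vy` of shape `(n_frames - 2) x n_points` (pixels/second^2).
#' @export
acceleration <- function(seq) {
  stopifnot(inherits(seq, "pose_sequence"))
  if (n_frames(seq) < 3L)
    stop("acceleration requires at least 3 frames", call. = FALSE)
  motion_field(diff(seq$x, differences = 2) * seq$fps^2,
               diff(seq$y, differences = 2) * seq$fps^2,
               fps = seq$fps, quantity = "acceleration", model = seq$model)
}

motion_field <- function(vx, vy, fps, quantity, model = NULL) {
  vx <- as.matrix(vx); vy <- as.matrix(vy)
  if (!identical(dim(vx), dim(vy)))
    stop("axis arrays have mismatched shapes", call. = FALSE)
  structure(list(vx = vx, vy = vy, fps = fps, quantity = quantity,
                 model = model),
            class = "motion_field")
}

#' @export
print.motion_field <- function(x, ...) {
  cat(sprintf("<motion_field> %s: %d transitions x %d points, %g fps\n",
              x$quantity, nrow(x$vx), ncol(x$vx), x$fps))
  invisible(x)
}

#' Euclidean norm of the summed motion vectors
#'
#' Reduces a velocity or acceleration field to one scalar per frame
#' transition: the per-point vectors are first summed over all N model
#' points and the Euclidean norm of that resultant is then taken,
#' \deqn{MF_1(t) = \left\lVert \sum_{i=1}^{N} v_i(t) \right\rVert
#'              = \sqrt{\Big(\sum_i v_{x,i}\Big)^2 + \Big(\sum_i v_{y,i}\Big)^2}.}
#' The sum-then-norm order means equal-and-opposite motions cancel; see
#' [sum_of_norms()] for the non-cancelling variant.
#'
#' @param field A `motion_field` from [velocity()] or [acceleration()].
#' @return A `motion_series` object: non-negative `values`, one per frame
#'   transition, plus `quantity` and `fps`.
#' @export
en_of_sums <- function(field) {
  stopifnot(inherits(field, "motion_field"))
  if (!identical(dim(field$vx), dim(field$vy)))
    stop("axis arrays have mismatched shapes", call. = FALSE)
  motion_series(sqrt(rowSums(field$vx)^2 + rowSums(field$vy)^2),
                quantity = field$quantity, fps = field$fps)
}

#' Sum of per-point vector norms
#'
#' The non-cancelling companion of [en_of_sums()]:
#' \eqn{\sum_i \lVert v_i \rVert} per transition, i.e. total speed summed
#' over points. Never the default motion measure; provided because
#' opposing movements (e.g. two hands converging) cancel under
#' sum-then-norm.
#'
#' @inheritParams en_of_sums
#' @return A `motion_series`.
#' @export
sum_of_norms <- function(field) {
  stopifnot(inherits(field, "motion_field"))
  if (!identical(dim(field$vx), dim(field$vy)))
    stop("axis arrays have mismatched shapes", call. = FALSE)
  motion_series(rowSums(sqrt(field$vx^2 + field$vy^2)),
                quantity = field$quantity, fps = field$fps)
}

motion_series <- function(values, quantity, fps) {
  structure(list(values = as.numeric(values), quantity = quantity, fps = fps),
            class = "motion_series")
}

#' @export
print.motion_series <- function(x, ...) {
  cat(sprintf("<motion_series> %s: %d transitions at %g fps (peak %.4g)\n",
              x$quantity, length(x$values), x$fps,
              if (length(x$values)) max(x$values) else NA_real_))
  invisible(x)
}

#' Per-clip motion summary
#'
#' The headline statistics of a motion time series: the sum over all frame
#' transitions (the single per-clip scalar used for matching stimulus
#' conditions), the mean, the peak value, and the transition index of the
#' peak (1-based; transition t covers frames t-1 to t in 0-based frame
#' numbering).
#'
#' @param object A `motion_series`.
#' @param ... Unused.
#' @return A list with `sum`, `mean`, `peak`, `peak_transition`, plus
#'   `quantity` and `fps`.
#' @export
summary.motion_series <- function(object, ...) {
  if (length(object$values) == 0L)
    stop("cannot summarize an empty motion series", call. = FALSE)
  out <- list(sum = sum(object$values),
              mean = mean(object$values),
              peak = max(object$values),
              peak_transition = which.max(object$values),
              quantity = object$quantity,
              fps = object$fps,
              n = length(object$values))
  class(out) <- "summary.motion_series"
  out
}

#' @export
print.summary.motion_series <- function(x, ...) {
  cat(sprintf("Motion summary (%s, %d transitions at %g fps)\n",
              x$quantity, x$n, x$fps))
  cat(sprintf("  total %.6g   mean %.6g   peak %.6g at transition %d (t = %.3f s)\n",
              x$sum, x$mean, x$peak, x$peak_transition, x$peak_transition / x$fps))
  invisible(x)
}

#' @export
plot.motion_series <- function(x, ...) plot_timeseries(x, ...)

#' Detect movement bursts in a motion series
#'
#' Thresholds the series at a fraction of its own maximum and returns the
#' contiguous supra-threshold runs as candidate movement segments (e.g.
#' sign onset/offset bursts): runs separated by fewer than `min_len`
#' sub-threshold transitions are merged, and merged runs shorter than
#' `min_len` are dropped. A heuristic utility, not a published algorithm;
#' defaults are implementation conveniences.
#'
#' @param series A `motion_series`.
#' @param threshold_frac Fraction of `max(values)` in `(0, 1)`; default 0.1.
#' @param min_len Minimum segment length in transitions; default 3.
#' @return A data frame with columns `onset`, `offset` (1-based transition
#'   indices, inclusive), in temporal order; zero rows for an all-zero
#'   series.
#' @export
detect_motion_segments <- function(series, threshold_frac = 0.1, min_len = 3L) {
  stopifnot(inherits(series, "motion_series"))
  if (!is.numeric(threshold_frac) || length(threshold_frac) != 1L ||
      threshold_frac <= 0 || threshold_frac >= 1)
    stop("threshold_frac must lie strictly between 0 and 1", call. = FALSE)
  v <- series$values
  if (length(v) == 0L)
    stop("empty motion series", call. = FALSE)
  empty <- data.frame(onset = integer(0), offset = integer(0))
  if (max(v) <= 0) return(empty)
  above <- v > threshold_frac * max(v)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(onset = starts[r$values], offset = ends[r$values])
  if (nrow(seg) == 0L) return(empty)
  # merge runs separated by a short quiet gap
  merged <- seg[1, , drop = FALSE]
  if (nrow(seg) > 1) for (k in 2:nrow(seg)) {
    gap <- seg$onset[k] - merged$offset[nrow(merged)] - 1L
    if (gap < min_len) {
      merged$offset[nrow(merged)] <- seg$offset[k]
    } else {
      merged <- rbind(merged, seg[k, ])
    }
  }
  merged <- merged[(merged$offset - merged$onset + 1L) >= min_len, , drop = FALSE]
  rownames(merged) <- NULL
  merged
}

# ---- file-level wrappers (suffix-conventional batch interface) ----------

read_axis_csv <- function(path) {
  lines <- readLines(path)
  fps <- 25
  if (length(lines) > 0 && startsWith(lines[1], "#")) {
    m <- regmatches(lines[1], regexpr("fps=[^ ]+", lines[1]))
    if (length(m)) fps <- as.numeric(sub("fps=", "", m))
    lines <- lines[-1]
  }
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  body <- lines[-1]
  m <- do.call(rbind, lapply(body, function(l)
    as.numeric(strsplit(l, ",", fixed = TRUE)[[1]])))
  if (is.null(m)) m <- matrix(numeric(0), 0, length(header))
  list(values = m, fps = fps)
}

write_axis_csv <- function(m, path, fps, prefix) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("#fps=%s", format(fps, digits = 17)), con)
  writeLines(paste(sprintf("%s%d", prefix, seq_len(ncol(m)) - 1L),
                   collapse = ","), con)
  if (nrow(m) > 0)
    writeLines(apply(m, 1L, function(v)
      paste(sprintf("%.17g", v), collapse = ",")), con)
  invisible(path)
}

#' Compute velocity (or acceleration) for a clip CSV file
#'
#' File-level wrappers over [velocity()]/[acceleration()]: read a cleaned
#' clip table and write one CSV per axis with the conventional suffixes
#' `_velocity_x`/`_velocity_y` (resp. `_acceleration_x`/`_acceleration_y`),
#' one row per frame transition and one column per model point.
#'
#' @param path Path to a clip CSV (normally the `_cleaned` file).
#' @param fps Frame-rate override; default comes from the file.
#' @return Character vector of the two paths written, invisibly.
#' @export
velocity_file <- function(path, fps = NULL) {
  seq <- read_pose_csv(path, fps = fps)
  fld <- velocity(seq)
  stem <- file.path(dirname(path), tools::file_path_sans_ext(basename(path)))
  out <- c(paste0(stem, "_velocity_x.csv"), paste0(stem, "_velocity_y.csv"))
  write_axis_csv(fld$vx, out[1], fld$fps, "vx")
  write_axis_csv(fld$vy, out[2], fld$fps, "vy")
  invisible(out)
}

#' @rdname velocity_file
#' @export
acceleration_file <- function(path, fps = NULL) {
  seq <- read_pose_csv(path, fps = fps)
  fld <- acceleration(seq)
  stem <- file.path(dirname(path), tools::file_path_sans_ext(basename(path)))
  out <- c(paste0(stem, "_acceleration_x.csv"), paste0(stem, "_acceleration_y.csv"))
  write_axis_csv(fld$vx, out[1], fld$fps, "ax")
  write_axis_csv(fld$vy, out[2], fld$fps, "ay")
  invisible(out)
}

#' Euclidean norm of sums for axis CSV files
#'
#' File-level wrapper over [en_of_sums()]: reads the `_velocity_x`/`_y`
#' (or `_acceleration_x`/`_y`) pair and writes a single-column CSV with
#' the suffix `_en_velocity` (resp. `_en_acceleration`), one value per
#' frame transition.
#'
#' @param x_path,y_path Paths to the per-axis CSVs written by
#'   [velocity_file()] or [acceleration_file()].
#' @return The path written, invisibly.
#' @export
en_file <- function(x_path, y_path) {
  ax <- read_axis_csv(x_path)
  ay <- read_axis_csv(y_path)
  quantity <- if (grepl("_acceleration_x\\.csv$", x_path)) "acceleration" else "velocity"
  fld <- motion_field(ax$values, ay$values, fps = ax$fps, quantity = quantity)
  series <- en_of_sums(fld)
  stem <- sub(sprintf("_%s_x\\.csv$", quantity), "", x_path)
  out <- sprintf("%s_en_%s.csv", stem, quantity)
  con <- file(out, open = "wt")
  writeLines(c(sprintf("#fps=%s quantity=%s", format(series$fps, digits = 17),
                       quantity),
               "en",
               sprintf("%.17g", series$values)), con)
  close(con)
  invisible(out)
}

#' Read a motion series written by [en_file()]
#'
#' @param path Path to an `_en_velocity.csv` / `_en_acceleration.csv` file.
#' @return A `motion_series`.
#' @export
read_motion_series <- function(path) {
  lines <- readLines(path)
  fps <- 25; quantity <- "velocity"
  if (length(lines) > 0 && startsWith(lines[1], "#")) {
    m <- regmatches(lines[1], regexpr("fps=[^ ]+", lines[1]))
    if (length(m)) fps <- as.numeric(sub("fps=", "", m))
    q <- regmatches(lines[1], regexpr("quantity=[^ ]+", lines[1]))
    if (length(q)) quantity <- sub("quantity=", "", q)
    lines <- lines[-1]
  }
  motion_series(as.numeric(lines[-1]), quantity = quantity, fps = fps)
}
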