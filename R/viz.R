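#' Bin keypoint observations into a 2-D histogram
#'
#' Counts all valid `(x, y)` observations (across every frame and point)
#' into square pixel bins. The binning underlying [plot_frontal()],
#' exposed separately so the counts can be inspected or tested: the bin
#' counts always sum to the number of valid observations.
#'
#' @param seq A [pose_sequence()].
#' @param bin_size Bin edge length in pixels; default 10.
#' @param cutoff Confidence cutoff defining validity (see
#'   [find_invalid()]); default 0.3.
#' @return A data frame with one row per occupied bin: `xbin`, `ybin`
#'   (bin lower edges, pixels) and `count`.
#' @export
frontal_bins <- function(seq, bin_size = 10, cutoff = 0.3) {
  stopifnot(inherits(seq, "pose_sequence"))
  if (!is.numeric(bin_size) || bin_size <= 0)
    stop("bin_size must be positive", call. = FALSE)
  ok <- !find_invalid(seq, cutoff = cutoff)
  xs <- seq$x[ok]; ys <- seq$y[ok]
  if (length(xs) == 0L) {
    warning("no valid observations to bin; empty histogram")
    return(data.frame(xbin = numeric(0), ybin = numeric(0),
                      count = integer(0)))
  }
  xb <- floor(xs / bin_size) * bin_size
  yb <- floor(ys / bin_size) * bin_size
  agg <- stats::aggregate(list(count = rep(1L, length(xb))),
                          by = list(xbin = xb, ybin = yb), FUN = sum)
  agg <- agg[order(agg$xbin, agg$ybin), ]
  rownames(agg) <- NULL
  agg
}

#' Frontal keypoint heatmap
#'
#' A 2-D histogram of every valid keypoint observation in the clip,
#' rendered in image orientation: pose coordinates have their origin at
#' the top-left with y growing downward, so the y axis is inverted by
#' default to make the figure look like the actor. Deterministic for a
#' fixed input and spec (fixed style, no timestamps).
#'
#' @inheritParams frontal_bins
#' @param invert_y Flip the y axis into screen orientation; default `TRUE`.
#' @param file Optional output path (`.png`/`.svg`/`.pdf`); when given the
#'   figure is also written to disk via [ggplot2::ggsave()].
#' @return The ggplot object, invisibly when `file` is given.
#' @export
plot_frontal <- function(seq, bin_size = 10, cutoff = 0.3, invert_y = TRUE,
                         file = NULL) {
  bins <- frontal_bins(seq, bin_size = bin_size, cutoff = cutoff)
  p <- ggplot2::ggplot(bins, ggplot2::aes(
         x = .data$xbin + bin_size / 2,
         y = .data$ybin + bin_size / 2,
         fill = .data$count)) +
    ggplot2::geom_tile(width = bin_size, height = bin_size) +
    ggplot2::scale_fill_viridis_c(name = "observations") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = sprintf("Keypoint density: %s", seq$source_id)) +
    ggplot2::theme_minimal()
  if (invert_y) p <- p + ggplot2::scale_y_reverse()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 6, height = 6, dpi = 150)
    return(invisible(p))
  }
  p
}

#' Motion time-series plot
#'
#' A line plot of the motion series against time in seconds (transition t
#' is drawn at t/fps, so the velocity series of a 125-frame, 25 fps clip
#' spans 0.04–4.96 s). Detected movement segments, e.g. from
#' [detect_motion_segments()], are overlaid as shaded regions — the sign's
#' onset and offset bursts show up as peaks inside them.
#'
#' @param series A `motion_series`.
#' @param segments Optional data frame with `onset`/`offset` transition
#'   indices to shade.
#' @param file Optional output path; when given the figure is written via
#'   [ggplot2::ggsave()].
#' @return The ggplot object, invisibly when `file` is given.
#' @export
plot_timeseries <- function(series, segments = NULL, file = NULL) {
  stopifnot(inherits(series, "motion_series"))
  if (length(series$values) == 0L)
    stop("cannot plot an empty motion series", call. = FALSE)
  df <- data.frame(time = seq_along(series$values) / series$fps,
                   value = series$values)
  ylab <- if (identical(series$quantity, "acceleration"))
    "acceleration (px/s²)" else "velocity (px/s)"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value))
  if (!is.null(segments) && nrow(segments) > 0) {
    shade <- data.frame(xmin = (segments$onset - 1) / series$fps,
                        xmax = segments$offset / series$fps)
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax),
      ymin = -Inf, ymax = Inf, fill = "grey80", alpha = 0.6,
      inherit.aes = FALSE)
  }
  p <- p + ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "time (s)", y = ylab,
                  title = sprintf("Euclidean norm of summed %s vectors",
                                  series$quantity)) +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 7, height = 4, dpi = 150)
    return(invisible(p))
  }
  p
}
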