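#' Specify a synthetic clip trajectory
#'
#' Describes a fully synthetic motion-tracking clip: per-point motion
#' programs plus optional coordinate noise and keypoint dropout. Fixtures
#' generated from such a spec exercise the whole pipeline — frame JSON
#' parsing, aggregation, cleaning, kinematics, laterality — without video,
#' a GPU, or downloads, and come with analytically known ground truth.
#'
#' Motion programs (each applies to a set of 0-based point indices;
#' unprogrammed points stay static at their base position):
#' \describe{
#'   \item{`linear(dx, dy)`}{constant per-frame displacement in pixels.}
#'   \item{`quadratic(qx, qy)`}{position offset `0.5 * q * t^2` px, i.e.
#'     constant acceleration in frame units.}
#'   \item{`burst(start, len, amplitude)`}{a Gaussian-windowed positional
#'     excursion of the given peak amplitude (px) centred inside frames
#'     `[start, start + len)`; quiet elsewhere.}
#' }
#'
#' Dropout cells are written either as all-zero triplets (a failed model
#' fit) or with confidence drawn uniformly below 0.3; valid cells carry
#' confidence uniform in `[0.6, 1]`. Noise is Gaussian on x and y of
#' valid cells only, so ground truth remains exact when `noise_sd = 0`.
#'
#' @param n_frames Number of frames.
#' @param fps Frame rate (default 25).
#' @param programs List of programs, each a list with `points` (0-based
#'   indices), `type` (`"linear"`, `"quadratic"`, `"burst"`) and the
#'   type's parameters (`dx`/`dy`, `qx`/`qy`, or
#'   `start`/`len`/`amplitude` plus optional `axis = "x"|"y"`).
#' @param noise_sd Gaussian noise SD in pixels on valid cells; default 0.
#' @param dropout Optional data frame with columns `frame`, `point`
#'   (0-based) and `mode` (`"zero"` or `"lowconf"`).
#' @param seed RNG seed; fixed seed, fixed files.
#' @param base Length-2 numeric: top-left of the base-position grid.
#' @return An object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(n_frames, fps = 25, programs = list(),
                            noise_sd = 0, dropout = NULL, seed = 1L,
                            base = c(200, 100)) {
  stopifnot(is.numeric(n_frames), n_frames >= 1)
  if (!is.null(dropout)) {
    stopifnot(all(c("frame", "point") %in% names(dropout)))
    if (is.null(dropout$mode)) dropout$mode <- "zero"
    if (any(dropout$frame < 0 | dropout$frame >= n_frames))
      stop("dropout frame index out of range", call. = FALSE)
  }
  for (pr in programs) {
    if (!pr$type %in% c("linear", "quadratic", "burst"))
      stop(sprintf("unknown motion program type '%s'", pr$type), call. = FALSE)
    if (pr$type == "burst" &&
        (pr$start < 0 || pr$start + pr$len > n_frames))
      stop("burst window out of range", call. = FALSE)
  }
  structure(list(n_frames = as.integer(n_frames), fps = fps,
                 programs = programs, noise_sd = noise_sd,
                 dropout = dropout, seed = as.integer(seed), base = base),
            class = "trajectory_spec")
}

# Noise-free positions implied by the motion programs.
trajectory_positions <- function(spec, model) {
  model <- as_pose_model(model)
  n <- spec$n_frames; p <- model$n_points
  t <- 0:(n - 1)
  # base grid: points spaced out so they land in distinct heatmap bins
  gx <- spec$base[1] + 30 * ((seq_len(p) - 1) %% 5)
  gy <- spec$base[2] + 30 * ((seq_len(p) - 1) %/% 5)
  x <- matrix(gx, n, p, byrow = TRUE)
  y <- matrix(gy, n, p, byrow = TRUE)
  for (pr in spec$programs) {
    cols <- pr$points + 1L
    off <- switch(pr$type,
      linear = list(x = (pr$dx %||% 0) * t, y = (pr$dy %||% 0) * t),
      quadratic = list(x = 0.5 * (pr$qx %||% 0) * t^2,
                       y = 0.5 * (pr$qy %||% 0) * t^2),
      burst = {
        centre <- pr$start + pr$len / 2
        w <- pmax(pr$len / 4, 1)
        bump <- pr$amplitude * exp(-((t - centre) / w)^2)
        if (identical(pr$axis %||% "x", "y")) list(x = 0 * t, y = bump)
        else list(x = bump, y = 0 * t)
      })
    x[, cols] <- x[, cols] + off$x
    y[, cols] <- y[, cols] + off$y
  }
  list(x = x, y = y)
}

#' Generate a synthetic clip and its ground truth
#'
#' Writes `n_frames` per-frame JSON files in the pose estimator's output
#' schema (zero-padded frame suffixes) into `dir` and returns the
#' analytically derived ground truth for every pipeline stage. With a
#' fixed seed, regeneration is byte-identical.
#'
#' @param spec A [trajectory_spec()].
#' @param model A [pose_model()] or name; default `"body25"`.
#' @param dir Output directory for the frame files; `NULL` skips writing
#'   (ground truth only).
#' @param stem Filename stem for the frame files; default `"clip"`.
#' @return A list with `files` (the JSON paths, or `NULL`), `seq` (the
#'   noisy/dropped-out [pose_sequence()] as written), and `truth`: the
#'   noise-free positions `x`, `y`, velocity `vx`, `vy` and acceleration
#'   `ax`, `ay` (px/s, px/s^2), the motion series `mf1_velocity` and
#'   `mf1_acceleration` (Euclidean norm of summed vectors), and the
#'   `laterality` label implied by the programs.
#' @export
generate_fixture <- function(spec, model = "body25", dir = NULL,
                             stem = "clip") {
  stopifnot(inherits(spec, "trajectory_spec"))
  model <- as_pose_model(model)
  pos <- trajectory_positions(spec, model)
  n <- spec$n_frames; p <- model$n_points
  fps <- spec$fps

  # ground-truth kinematics from the noise-free trajectory
  truth <- list(x = pos$x, y = pos$y)
  if (n >= 2) {
    truth$vx <- diff(pos$x) * fps
    truth$vy <- diff(pos$y) * fps
    truth$mf1_velocity <- sqrt(rowSums(truth$vx)^2 + rowSums(truth$vy)^2)
  }
  if (n >= 3) {
    truth$ax <- diff(pos$x, differences = 2) * fps^2
    truth$ay <- diff(pos$y, differences = 2) * fps^2
    truth$mf1_acceleration <- sqrt(rowSums(truth$ax)^2 + rowSums(truth$ay)^2)
  }
  truth$laterality <- truth_laterality(truth, model)

  set.seed(spec$seed)
  x <- pos$x; y <- pos$y
  conf <- matrix(stats::runif(n * p, 0.6, 1), n, p)
  if (spec$noise_sd > 0) {
    x <- x + matrix(stats::rnorm(n * p, sd = spec$noise_sd), n, p)
    y <- y + matrix(stats::rnorm(n * p, sd = spec$noise_sd), n, p)
  }
  if (!is.null(spec$dropout)) {
    for (k in seq_len(nrow(spec$dropout))) {
      r <- spec$dropout$frame[k] + 1L
      j <- spec$dropout$point[k] + 1L
      if (identical(spec$dropout$mode[k], "lowconf")) {
        conf[r, j] <- stats::runif(1, 0, 0.3 - 1e-6)
      } else {
        x[r, j] <- 0; y[r, j] <- 0; conf[r, j] <- 0
      }
    }
  }
  seq <- pose_sequence(x, y, conf, model = model, fps = fps,
                       source_id = stem)
  files <- if (!is.null(dir)) write_openpose_json(seq, dir, stem = stem)
  list(files = files, seq = seq, truth = truth, spec = spec, model = model)
}

# Laterality implied by which arm-chain points the programs move.
truth_laterality <- function(truth, model) {
  if (model$name != "body25" || is.null(truth$vx)) return(NA_character_)
  speed <- sqrt(truth$vx^2 + truth$vy^2)
  right <- sum(speed[, BODY25_RIGHT_ARM + 1L])
  left  <- sum(speed[, BODY25_LEFT_ARM + 1L])
  hi <- max(left, right)
  if (hi < 1) "none"
  else if (min(left, right) / hi >= 0.5) "both"
  else if (left > right) "left" else "right"
}
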