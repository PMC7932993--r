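#' Parse a single OpenPose frame document
#'
#' OpenPose writes one JSON file per video frame, containing a `"people"`
#' array whose entries hold flat `[x0, y0, c0, x1, y1, c1, ...]` keypoint
#' arrays per model. This parses one such document and extracts the
#' `(x, y, confidence)` triplets of exactly one person.
#'
#' An empty `"people"` array yields an all-zero frame (the estimator's own
#' convention for a failed fit), which the cleaning step later imputes.
#'
#' @param json_text A length-1 character string holding the JSON document.
#' @param model A [pose_model()] or model name.
#' @param person_policy How to choose among multiple detected people:
#'   `"first"` takes the first array entry, `"highest_mean_confidence"`
#'   the person whose keypoint confidences have the largest mean,
#'   `"error_if_multiple"` refuses documents with two or more people.
#' @param file Optional source filename, used in error messages.
#' @return A list with numeric vectors `x`, `y`, `conf` of length
#'   `model$n_points`.
#' @export
parse_openpose_frame <- function(json_text, model = "body25",
                                 person_policy = c("first",
                                                   "highest_mean_confidence",
                                                   "error_if_multiple"),
                                 file = NULL) {
  model <- as_pose_model(model)
  person_policy <- match.arg(person_policy)
  where <- if (is.null(file)) "frame document" else sprintf("'%s'", file)
  doc <- tryCatch(
    jsonlite::fromJSON(json_text, simplifyVector = FALSE),
    error = function(e) stop(sprintf("malformed JSON in %s: %s",
                                     where, conditionMessage(e)), call. = FALSE)
  )
  people <- doc[["people"]]
  if (is.null(people))
    stop(sprintf("no \"people\" array in %s", where), call. = FALSE)
  if (length(people) == 0L) {
    z <- numeric(model$n_points)
    return(frame_pose(z, z, z, model))
  }
  triplets <- lapply(people, function(p) {
    kp <- as.numeric(unlist(p[[model$json_field]]))
    if (length(kp) != 3L * model$n_points)
      stop(sprintf(
        "keypoint array '%s' in %s has length %d, expected %d for model '%s'",
        model$json_field, where, length(kp), 3L * model$n_points, model$name),
        call. = FALSE)
    kp
  })
  idx <- switch(person_policy,
    first = 1L,
    highest_mean_confidence = {
      mc <- vapply(triplets, function(kp) mean(kp[seq(3, length(kp), by = 3)]),
                   numeric(1))
      which.max(mc)
    },
    error_if_multiple = {
      if (length(triplets) > 1L)
        stop(sprintf("%d people detected in %s but person_policy is 'error_if_multiple'",
                     length(triplets), where), call. = FALSE)
      1L
    }
  )
  kp <- triplets[[idx]]
  ix <- seq(1, length(kp), by = 3)
  frame_pose(kp[ix], kp[ix + 1], kp[ix + 2], model)
}

#' @rdname parse_openpose_frame
#' @param path Path to a per-frame JSON file.
#' @param ... Passed on to `parse_openpose_frame()`.
#' @export
read_openpose_frame <- function(path, model = "body25", ...) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  parse_openpose_frame(txt, model = model, ..., file = path)
}

# Frame index from the numeric suffix of an OpenPose output filename,
# e.g. "clip_000000000017_keypoints.json" -> 17. Frame order comes from
# this suffix, never from directory listing order.
frame_index_from_name <- function(files) {
  stems <- sub("_keypoints\\.json$", "", basename(files), ignore.case = TRUE)
  stems <- sub("\\.json$", "", stems, ignore.case = TRUE)
  mm <- regexpr("[0-9]+$", stems)
  if (any(mm == -1L))
    stop("cannot extract a numeric frame suffix from: ",
         paste(basename(files)[mm == -1L], collapse = ", "), call. = FALSE)
  as.integer(regmatches(stems, mm))
}

#' Aggregate per-frame keypoint files into a pose sequence
#'
#' Reads every OpenPose per-frame JSON file in a directory (or an explicit
#' file list), orders frames by the numeric suffix of their filenames, and
#' combines them into a single [pose_sequence()] — one row per frame.
#' A clip of duration 5 s at 25 fps therefore yields a 125-frame sequence
#' from 125 individual files.
#'
#' @param dir Directory containing the per-frame JSON files, or a character
#'   vector of file paths.
#' @param model A [pose_model()] or model name.
#' @param fps Frame rate of the source clip (default 25).
#' @param pattern Filename filter when `dir` is a directory.
#' @param missing How to treat gaps in the 0-based frame numbering:
#'   `"error"` (default) fails listing the absent indices; `"zero"` inserts
#'   all-zero frames, which cleaning can impute.
#' @param person_policy Passed to [parse_openpose_frame()].
#' @param source_id Clip identifier; defaults to the common filename stem.
#' @return A [pose_sequence()] with one frame per input file.
#' @export
read_openpose_dir <- function(dir, model = "body25", fps = 25,
                              pattern = "\\.json$",
                              missing = c("error", "zero"),
                              person_policy = "first",
                              source_id = NULL) {
  model <- as_pose_model(model)
  missing <- match.arg(missing)
  files <- if (length(dir) == 1L && dir.exists(dir)) {
    list.files(dir, pattern = pattern, full.names = TRUE)
  } else {
    as.character(dir)
  }
  if (length(files) == 0L)
    stop("no frame files found", call. = FALSE)
  idx <- frame_index_from_name(files)
  files <- files[order(idx)]
  idx <- sort(idx)
  if (anyDuplicated(idx))
    stop("duplicate frame indices: ",
         paste(unique(idx[duplicated(idx)]), collapse = ", "), call. = FALSE)
  full <- seq(0L, max(idx))
  absent <- setdiff(full, idx)
  if (length(absent) > 0L || idx[1] != 0L) {
    if (idx[1] != 0L) absent <- sort(union(absent, seq(0L, idx[1] - 1L)))
    if (missing == "error")
      stop("missing frame file(s) for index: ",
           paste(absent, collapse = ", "), call. = FALSE)
  }
  n <- max(idx) + 1L
  x <- matrix(0, n, model$n_points)
  y <- matrix(0, n, model$n_points)
  conf <- matrix(0, n, model$n_points)
  for (k in seq_along(files)) {
    fp <- read_openpose_frame(files[k], model = model,
                              person_policy = person_policy)
    r <- idx[k] + 1L
    x[r, ] <- fp$x; y[r, ] <- fp$y; conf[r, ] <- fp$conf
  }
  if (is.null(source_id)) {
    stems <- sub("_?[0-9]*(_keypoints)?\\.json$", "", basename(files),
                 ignore.case = TRUE)
    source_id <- if (length(unique(stems)) == 1L && nzchar(stems[1]))
      stems[1] else "clip"
  }
  pose_sequence(x, y, conf, model = model, fps = fps, source_id = source_id)
}

#' Write a pose sequence as per-frame OpenPose JSON files
#'
#' Serializes each frame to the standard OpenPose output schema
#' (`people[[1]]$<model>_keypoints_2d` flat triplet array), one file per
#' frame with a zero-padded numeric suffix. The inverse of
#' [read_openpose_dir()]; round-trips all values exactly.
#'
#' @param seq A [pose_sequence()].
#' @param dir Output directory (created if absent).
#' @param stem Filename stem; defaults to the sequence's `source_id`.
#' @return Invisibly, the vector of files written.
#' @export
write_openpose_json <- function(seq, dir, stem = NULL) {
  stopifnot(inherits(seq, "pose_sequence"))
  if (is.null(stem)) stem <- seq$source_id
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  field <- seq$model$json_field
  files <- character(n_frames(seq))
  for (t in seq_len(n_frames(seq))) {
    kp <- as.numeric(rbind(seq$x[t, ], seq$y[t, ], seq$conf[t, ]))
    # %.17g so every double round-trips exactly through the JSON text
    doc <- sprintf('{"version":1.3,"people":[{"%s":[%s]}]}',
                   field, paste(sprintf("%.17g", kp), collapse = ","))
    files[t] <- file.path(dir, sprintf("%s_%012d_keypoints.json", stem, t - 1L))
    writeLines(doc, files[t])
  }
  invisible(files)
}

csv_header_line <- function(seq) {
  sprintf("#model=%s fps=%s source=%s",
          seq$model$name, format(seq$fps, digits = 17), seq$source_id)
}

#' Write and read the per-clip tabular keypoint format
#'
#' The tabular dialect stores one row per frame with interleaved per-point
#' triplet columns `x0,y0,c0,x1,y1,c1,...` (matching the flat JSON array
#' order), i.e. `3 * n_points` data columns. A leading comment line
#' `#model=... fps=... source=...` carries the model name and frame rate so
#' that `read_pose_csv(write_pose_csv(seq))` reproduces the sequence — all
#' x/y/confidence values exactly (full-precision serialization), plus fps.
#'
#' @param seq A [pose_sequence()].
#' @param path Output CSV path.
#' @return `write_pose_csv()`: invisibly, `path`. `read_pose_csv()`: a
#'   [pose_sequence()].
#' @export
write_pose_csv <- function(seq, path) {
  stopifnot(inherits(seq, "pose_sequence"))
  p <- seq$model$n_points
  header <- paste(sprintf("%s%d", rep(c("x", "y", "c"), p),
                          rep(0:(p - 1), each = 3)), collapse = ",")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(csv_header_line(seq), header), con)
  if (n_frames(seq) > 0) {
    m <- matrix(NA_real_, n_frames(seq), 3L * p)
    m[, seq(1, 3 * p, by = 3)] <- seq$x
    m[, seq(2, 3 * p, by = 3)] <- seq$y
    m[, seq(3, 3 * p, by = 3)] <- seq$conf
    rows <- apply(m, 1L, function(v)
      paste(sprintf("%.17g", v), collapse = ","))
    writeLines(rows, con)
  }
  invisible(path)
}

#' @rdname write_pose_csv
#' @param model Optional [pose_model()] or name; when `NULL` it is taken
#'   from the file's comment line (or inferred from the column count).
#' @param fps Optional frame-rate override; default comes from the file.
#' @export
read_pose_csv <- function(path, model = NULL, fps = NULL) {
  lines <- readLines(path)
  meta <- list(model = NULL, fps = 25, source = tools::file_path_sans_ext(basename(path)))
  if (length(lines) > 0 && startsWith(lines[1], "#")) {
    kv <- regmatches(lines[1], gregexpr("[a-z]+=[^ ]+", lines[1]))[[1]]
    for (item in kv) {
      key <- sub("=.*", "", item); val <- sub("^[a-z]+=", "", item)
      if (key == "model") meta$model <- val
      if (key == "fps") meta$fps <- as.numeric(val)
      if (key == "source") meta$source <- val
    }
    lines <- lines[-1]
  }
  if (length(lines) == 0L)
    stop(sprintf("'%s' has no header row", path), call. = FALSE)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  body <- lines[-1]
  if (is.null(model)) {
    model <- if (!is.null(meta$model)) pose_model(meta$model) else {
      np <- length(header) / 3
      nm <- c(body25 = 25, face = 70)[match(np, c(25, 70))]
      if (is.na(nm))
        stop(sprintf("cannot infer model from %d columns in '%s'",
                     length(header), path), call. = FALSE)
      pose_model(names(nm))
    }
  }
  model <- as_pose_model(model)
  if (length(header) != 3L * model$n_points)
    stop(sprintf(
      "'%s' has %d data columns but model '%s' requires %d (3 x %d points)",
      path, length(header), model$name, 3L * model$n_points, model$n_points),
      call. = FALSE)
  if (is.null(fps)) fps <- meta$fps
  n <- length(body)
  m <- matrix(NA_real_, n, 3L * model$n_points)
  for (r in seq_len(n)) {
    cells <- strsplit(body[r], ",", fixed = TRUE)[[1]]
    if (length(cells) != 3L * model$n_points)
      stop(sprintf("'%s': row %d has %d columns, expected %d",
                   path, r, length(cells), 3L * model$n_points), call. = FALSE)
    vals <- suppressWarnings(as.numeric(cells))
    if (anyNA(vals))
      stop(sprintf("'%s': non-numeric cell at row %d, column %d ('%s')",
                   path, r, which(is.na(vals))[1], cells[which(is.na(vals))[1]]),
           call. = FALSE)
    m[r, ] <- vals
  }
  pose_sequence(m[, seq(1, ncol(m), 3), drop = FALSE],
                m[, seq(2, ncol(m), 3), drop = FALSE],
                m[, seq(3, ncol(m), 3), drop = FALSE],
                model = model, fps = fps, source_id = meta$source)
}

#' Convert a directory of per-frame JSON files to a per-clip CSV
#'
#' File-level wrapper around [read_openpose_dir()] and [write_pose_csv()]:
#' aggregates a clip's frame files and writes `<stem>_<model>.csv` into the
#' output directory (the model suffix convention, e.g. `clip_body25.csv`).
#'
#' @inheritParams read_openpose_dir
#' @param out_dir Output directory (default: `dir`).
#' @param stem Output filename stem; defaults to the clip's source id.
#' @return The path of the CSV written, invisibly.
#' @export
convert_clip <- function(dir, model = "body25", fps = 25, out_dir = dir,
                         stem = NULL, ...) {
  model <- as_pose_model(model)
  seq <- read_openpose_dir(dir, model = model, fps = fps, ...)
  if (!is.null(stem)) seq$source_id <- stem
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(out_dir, sprintf("%s_%s.csv", seq$source_id, model$name))
  write_pose_csv(seq, out)
  invisible(out)
}
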