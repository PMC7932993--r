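#' Probe technical metadata of a video file
#'
#' Extracts duration, frame rate, frame count, resolution and codec from a
#' video container. Probing is delegated to an external tool through a
#' pluggable prober function; the default prober runs `ffprobe` with a
#' pinned machine-readable contract:
#'
#' ```
#' ffprobe -v error -print_format json -show_format -show_streams FILE
#' ```
#'
#' and this function parses the resulting JSON. Frame rates reported as
#' rationals (`"25/1"`) are converted to decimal; variable-framerate files
#' report the average rate with `vfr = TRUE`. When `nb_frames` is absent
#' from the container, the frame count is reconstructed as
#' `round(duration * fps)` (containers may round by one frame either way).
#'
#' @param path Path to the video file.
#' @param prober A function `(path) -> character` returning the probe
#'   tool's JSON output; defaults to [ffprobe_prober()]. Supplying a
#'   custom prober lets tests and exotic setups bypass the binary.
#' @return An object of class `video_meta` (also a one-row data frame)
#'   with columns `filename`, `duration`, `fps`, `n_frames`, `width`,
#'   `height`, `codec`, `vfr`.
#' @export
probe_video <- function(path, prober = ffprobe_prober()) {
  if (!file.exists(path))
    stop(sprintf("video file '%s' does not exist", path), call. = FALSE)
  json <- prober(path)
  doc <- tryCatch(jsonlite::fromJSON(json, simplifyVector = FALSE),
                  error = function(e)
                    stop(sprintf("probe output for '%s' is not valid JSON: %s",
                                 path, conditionMessage(e)), call. = FALSE))
  streams <- doc$streams
  vid <- NULL
  for (s in streams) if (identical(s$codec_type, "video")) { vid <- s; break }
  if (is.null(vid))
    stop(sprintf("no video stream found in '%s'", path), call. = FALSE)
  avg <- parse_rational(vid$avg_frame_rate)
  rfr <- parse_rational(vid$r_frame_rate)
  fps <- if (is.finite(avg) && avg > 0) avg else rfr
  duration <- as.numeric(vid$duration %||% doc$format$duration)
  n_frames <- if (!is.null(vid$nb_frames)) as.integer(vid$nb_frames)
              else as.integer(round(duration * fps))
  out <- data.frame(
    filename = basename(path),
    duration = duration,
    fps = fps,
    n_frames = n_frames,
    width = as.integer(vid$width),
    height = as.integer(vid$height),
    codec = as.character(vid$codec_name %||% NA_character_),
    vfr = is.finite(avg) && is.finite(rfr) && abs(avg - rfr) > 1e-9,
    stringsAsFactors = FALSE
  )
  class(out) <- c("video_meta", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_rational <- function(x) {
  if (is.null(x)) return(NA_real_)
  if (is.numeric(x)) return(as.numeric(x))
  parts <- as.numeric(strsplit(as.character(x), "/", fixed = TRUE)[[1]])
  if (length(parts) == 1L) return(parts)
  if (parts[2] == 0) return(NA_real_)
  parts[1] / parts[2]
}

#' Default ffprobe-based prober
#'
#' Returns a prober function for [probe_video()] that shells out to
#' `ffprobe` (part of FFmpeg). Errors immediately — with an installation
#' hint — if the binary is not on the `PATH`, and propagates the tool's
#' diagnostic on unreadable or corrupt files.
#'
#' @param cmd Name or path of the ffprobe binary.
#' @return A function `(path) -> character` (the JSON probe output).
#' @export
ffprobe_prober <- function(cmd = getOption("posemotion.ffprobe", "ffprobe")) {
  force(cmd)
  function(path) {
    if (Sys.which(cmd) == "")
      stop(sprintf(paste0(
        "probe tool '%s' not found on PATH; install FFmpeg ",
        "(https://ffmpeg.org) or pass a custom `prober`"), cmd),
        call. = FALSE)
    res <- suppressWarnings(system2(
      cmd,
      c("-v", "error", "-print_format", "json", "-show_format",
        "-show_streams", shQuote(path)),
      stdout = TRUE, stderr = TRUE))
    status <- attr(res, "status")
    if (!is.null(status) && status != 0)
      stop(sprintf("probe of '%s' failed: %s", path,
                   paste(res, collapse = " ")), call. = FALSE)
    paste(res, collapse = "\n")
  }
}

#' Build a metadata index over a directory of video files
#'
#' Probes every file in `dir` whose name matches `pattern` and assembles a
#' per-file metadata table, sorted by filename; optionally written as CSV.
#' A directory with no matching files yields an empty (header-only) index
#' with a warning rather than an error.
#'
#' @param dir Directory to index.
#' @param pattern Filename regular expression; default matches common
#'   video containers.
#' @param out_csv Optional CSV output path.
#' @param prober Passed to [probe_video()].
#' @return A data frame with one [probe_video()] row per matching file.
#' @export
build_video_index <- function(dir, pattern = "\\.(mp4|mov|avi|mkv|webm)$",
                              out_csv = NULL, prober = ffprobe_prober()) {
  if (!dir.exists(dir))
    stop(sprintf("directory '%s' does not exist", dir), call. = FALSE)
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0L) {
    warning(sprintf("no files matching '%s' in '%s'", pattern, dir))
    idx <- data.frame(filename = character(0), duration = numeric(0),
                      fps = numeric(0), n_frames = integer(0),
                      width = integer(0), height = integer(0),
                      codec = character(0), vfr = logical(0),
                      stringsAsFactors = FALSE)
  } else {
    idx <- do.call(rbind, lapply(files, function(f) {
      m <- probe_video(f, prober = prober)
      class(m) <- "data.frame"
      m
    }))
  }
  rownames(idx) <- NULL
  if (!is.null(out_csv))
    utils::write.csv(idx, out_csv, row.names = FALSE)
  idx
}
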