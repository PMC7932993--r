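# In-code fixture builders shared across test files.

# A pose sequence with every point static at a distinct position.
static_seq <- function(n = 10, model = "body25", fps = 25, conf = 1) {
  model <- posemotion::pose_model(model)
  p <- model$n_points
  x <- matrix(rep(100 + 20 * seq_len(p), each = n), n, p)
  y <- matrix(rep(50 + 10 * seq_len(p), each = n), n, p)
  pose_sequence(x, y, matrix(conf, n, p), model = model, fps = fps,
                source_id = "static")
}

# A random-walk pose sequence (all confidences valid).
random_seq <- function(n, p_model = "body25", fps = 25, seed = 1) {
  model <- posemotion::pose_model(p_model)
  p <- model$n_points
  set.seed(seed)
  x <- matrix(cumsum(rnorm(n * p)), n, p) + 500
  y <- matrix(cumsum(rnorm(n * p)), n, p) + 300
  pose_sequence(x, y, matrix(runif(n * p, 0.6, 1), n, p),
                model = model, fps = fps, source_id = "rand")
}

# Minimal OpenPose frame document with the given flat keypoint arrays
# (one numeric vector per person).
openpose_doc <- function(..., field = "pose_keypoints_2d") {
  people <- lapply(list(...), function(kp)
    sprintf('{"%s":[%s]}', field, paste(sprintf("%.17g", kp), collapse = ",")))
  sprintf('{"version":1.3,"people":[%s]}', paste(people, collapse = ","))
}

# Flat [x,y,c] triplet array for a body25 person with constant values.
body25_kp <- function(x = 1, y = 2, conf = 0.9) {
  as.numeric(rbind(rep(x, 25), rep(y, 25), rep(conf, 25)))
}

# A prober emitting canned ffprobe-style JSON, honouring the pinned
# subprocess contract without the binary.
stub_prober <- function(duration = 5, fps = 25, width = 1280, height = 720,
                        codec = "h264", nb_frames = NULL, vfr = FALSE) {
  function(path) {
    nf <- if (is.null(nb_frames)) "" else
      sprintf('"nb_frames":"%d",', nb_frames)
    rfr <- if (vfr) sprintf("%d/1", round(fps * 2)) else sprintf("%g/1", fps)
    sprintf(paste0(
      '{"streams":[',
      '{"codec_type":"audio","codec_name":"aac"},',
      '{"codec_type":"video","codec_name":"%s","width":%d,"height":%d,',
      '%s"avg_frame_rate":"%g/1","r_frame_rate":"%s","duration":"%g"}],',
      '"format":{"duration":"%g"}}'),
      codec, width, height, nf, fps, rfr, duration, duration)
  }
}
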