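test_that("a single-person frame document unpacks into (x, y, c) triplets in array order", {
  kp <- as.numeric(rbind(101:125, 201:225, seq(0.5, 0.98, by = 0.02)))
  fp <- parse_openpose_frame(openpose_doc(kp), "body25")
  expect_equal(fp$x, 101:125)
  expect_equal(fp$y, 201:225)
  expect_equal(fp$conf, seq(0.5, 0.98, by = 0.02))
})

test_that("an empty people array yields an all-zero frame for cleaning to impute", {
  fp <- parse_openpose_frame('{"version":1.3,"people":[]}', "body25")
  expect_true(all(fp$x == 0) && all(fp$y == 0) && all(fp$conf == 0))
  expect_length(fp$x, 25)
})

test_that("person selection policies behave as contracted", {
  weak <- body25_kp(x = 10, y = 10, conf = 0.4)
  strong <- body25_kp(x = 99, y = 98, conf = 0.8)
  doc <- openpose_doc(weak, strong)
  expect_equal(parse_openpose_frame(doc, "body25", "first")$x[1], 10)
  # mean confidences 0.4 vs 0.8: the 0.8 person wins
  best <- parse_openpose_frame(doc, "body25", "highest_mean_confidence")
  expect_equal(best$x[1], 99)
  expect_equal(best$conf, rep(0.8, 25))
  expect_error(parse_openpose_frame(doc, "body25", "error_if_multiple"),
               "2 people")
})

test_that("malformed and model-mismatched documents raise informative errors", {
  expect_error(parse_openpose_frame("{not json", "body25", file = "f17.json"),
               "malformed JSON.*f17\\.json")
  short <- openpose_doc(c(1, 2, 0.5))  # 3 values, body25 needs 75
  expect_error(parse_openpose_frame(short, "body25"), "length 3, expected 75")
  expect_error(parse_openpose_frame('{"foo":1}', "body25"), "people")
})

test_that("aggregation orders frames by numeric suffix and counts them exactly", {
  d <- withr::local_tempdir()
  n <- 7
  for (t in seq_len(n) - 1)
    writeLines(openpose_doc(body25_kp(x = 100 + t)),
               file.path(d, sprintf("clip_%012d_keypoints.json", t)))
  seq <- read_openpose_dir(d, "body25", fps = 25)
  expect_equal(n_frames(seq), n)
  expect_equal(seq$x[, 1], 100 + 0:(n - 1))
  expect_equal(seq$source_id, "clip")

  # directory listing order must not matter: same files given reversed
  files <- rev(list.files(d, full.names = TRUE))
  seq2 <- read_openpose_dir(files, "body25", fps = 25)
  expect_identical(seq2$x, seq$x)
})

test_that("gaps in frame numbering error naming the missing index, or zero-fill on request", {
  d <- withr::local_tempdir()
  for (t in c(0, 1, 3))
    writeLines(openpose_doc(body25_kp(conf = 0.9)),
               file.path(d, sprintf("clip_%012d_keypoints.json", t)))
  expect_error(read_openpose_dir(d, "body25"), "missing frame.*2")
  seq <- read_openpose_dir(d, "body25", missing = "zero")
  expect_equal(n_frames(seq), 4)
  expect_true(all(seq$conf[3, ] == 0))  # inserted frame is all-zero
})

test_that("a one-frame clip aggregates, and velocity on it is an error", {
  d <- withr::local_tempdir()
  writeLines(openpose_doc(body25_kp()),
             file.path(d, "clip_000000000000_keypoints.json"))
  seq <- read_openpose_dir(d, "body25")
  expect_equal(n_frames(seq), 1)
  expect_error(velocity(seq), "at least 2 frames")
})

test_that("CSV round-trip is lossless for values, fps and model", {
  seq <- random_seq(12, seed = 3, fps = 30)
  p <- withr::local_tempfile(fileext = ".csv")
  write_pose_csv(seq, p)
  # body25: header plus 75 data columns per row
  header <- strsplit(readLines(p, n = 2)[2], ",")[[1]]
  expect_length(header, 75)
  expect_equal(header[1:3], c("x0", "y0", "c0"))
  back <- read_pose_csv(p)
  expect_identical(back$x, seq$x)
  expect_identical(back$y, seq$y)
  expect_identical(back$conf, seq$conf)
  expect_equal(back$fps, 30)
  expect_equal(back$model$name, "body25")
})

test_that("interleaved column order matches the per-point triplet layout", {
  seq <- random_seq(5, seed = 9)
  p <- withr::local_tempfile(fileext = ".csv")
  write_pose_csv(seq, p)
  row1 <- as.numeric(strsplit(readLines(p)[3], ",")[[1]])
  for (i in seq_len(25)) {
    expect_identical(row1[3 * i - 2], seq$x[1, i])
    expect_identical(row1[3 * i - 1], seq$y[1, i])
    expect_identical(row1[3 * i], seq$conf[1, i])
  }
})

test_that("an empty sequence writes a header-only table that reads back empty", {
  m <- matrix(numeric(0), 0, 25)
  seq <- pose_sequence(m, m, m, "body25", fps = 25, source_id = "empty")
  p <- withr::local_tempfile(fileext = ".csv")
  write_pose_csv(seq, p)
  back <- read_pose_csv(p)
  expect_equal(n_frames(back), 0)
})

test_that("dialect violations are reported with position", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("#model=body25 fps=25 source=x",
               paste(sprintf("%s%d", rep(c("x", "y", "c"), 25),
                             rep(0:24, each = 3)), collapse = ","),
               paste(rep("1", 75), collapse = ","),
               paste(c(rep("1", 40), "oops", rep("1", 34)), collapse = ",")),
             p)
  expect_error(read_pose_csv(p), "row 2, column 41")
  writeLines(c("#model=body25 fps=25 source=x",
               paste(rep("x", 10), collapse = ",")), p)
  expect_error(read_pose_csv(p), "10 data columns")
})

test_that("JSON serialization round-trips through parsing exactly", {
  fx <- generate_fixture(
    trajectory_spec(8, fps = 25, noise_sd = 3.1,
                    programs = list(list(points = 0:24, type = "linear",
                                         dx = 0.37, dy = -1.41)),
                    seed = 11),
    "body25", dir = withr::local_tempdir(), stem = "rt")
  back <- read_openpose_dir(dirname(fx$files[1]), "body25", fps = 25)
  expect_identical(back$x, fx$seq$x)
  expect_identical(back$y, fx$seq$y)
  expect_identical(back$conf, fx$seq$conf)
})

test_that("convert_clip writes the model-suffixed CSV with one row per frame file", {
  d <- withr::local_tempdir()
  fx <- generate_fixture(trajectory_spec(6, seed = 2), "body25", dir = d,
                         stem = "sign")
  out <- convert_clip(d, "body25", fps = 25)
  expect_equal(basename(out), "sign_body25.csv")
  expect_equal(n_frames(read_pose_csv(out)), 6)
})

test_that("face and hand models parse with their own point counts", {
  kp_face <- rep(c(5, 6, 0.9), 70)
  fp <- parse_openpose_frame(
    openpose_doc(kp_face, field = "face_keypoints_2d"), "face")
  expect_length(fp$x, 70)
  kp_hand <- rep(c(1, 2, 0.8), 21)
  fp2 <- parse_openpose_frame(
    openpose_doc(kp_hand, field = "hand_left_keypoints_2d"), "hand_left")
  expect_length(fp2$x, 21)
  expect_equal(pose_model("body25")$n_points, 25)
  expect_false(anyDuplicated(pose_model("face")$labels) > 0)
})
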