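test_that("a static sequence has identically zero velocity, acceleration and motion series", {
  seq <- static_seq(12)
  v <- velocity(seq)
  a <- acceleration(seq)
  expect_true(all(v$vx == 0) && all(v$vy == 0))
  expect_true(all(a$vx == 0) && all(a$vy == 0))
  expect_true(all(en_of_sums(v)$values == 0))
  expect_true(all(en_of_sums(a)$values == 0))
})

test_that("a 10 px inter-frame step at 25 fps is 250 px/s", {
  seq <- static_seq(2)
  seq$x[2, 1] <- seq$x[1, 1] + 10
  v <- velocity(seq)
  expect_equal(v$vx[1, 1], 250)
  expect_equal(v$vy[1, 1], 0)
})

test_that("x = t^2 at 1 fps gives acceleration exactly 2 px/s^2 at every interior transition", {
  n <- 10
  seq <- static_seq(n, fps = 1)
  seq$x[, 1] <- (0:(n - 1))^2
  a <- acceleration(seq)
  expect_equal(a$vx[, 1], rep(2, n - 2))
})

test_that("field shapes are n-1 and n-2 transitions", {
  seq <- random_seq(17, seed = 2)
  expect_equal(dim(velocity(seq)$vx), c(16, 25))
  expect_equal(dim(acceleration(seq)$vx), c(15, 25))
  expect_error(velocity(static_seq(1)), "at least 2")
  expect_error(acceleration(static_seq(2)), "at least 3")
})

test_that("sum-then-norm: orthogonal pair gives 5, opposing pair cancels to 0", {
  # two moving points among static ones: displacements (3,0) and (0,4)
  # per frame at 1 fps -> per-transition velocities (3,0), (0,4) px/s
  seq <- static_seq(3, fps = 1)
  seq$x[, 1] <- seq$x[1, 1] + 3 * (0:2)
  seq$y[, 2] <- seq$y[1, 2] + 4 * (0:2)
  s <- en_of_sums(velocity(seq))
  expect_equal(s$values, c(5, 5))

  seq2 <- static_seq(3, fps = 1)
  seq2$x[, 1] <- seq2$x[1, 1] + 2 * (0:2)
  seq2$x[, 2] <- seq2$x[1, 2] - 2 * (0:2)   # equal and opposite
  expect_equal(en_of_sums(velocity(seq2))$values, c(0, 0))
  # the non-cancelling variant sees the motion
  expect_equal(sum_of_norms(velocity(seq2))$values, c(4, 4))
})

test_that("rigid translation closed form: N * fps * ||d|| at every transition", {
  n <- 6
  seq <- static_seq(n, fps = 25)
  seq$x <- seq$x + outer(0:(n - 1), rep(1, 25))   # (1, 0) px per frame
  s <- en_of_sums(velocity(seq))
  expect_equal(s$values, rep(25 * 25 * 1, n - 1), tolerance = 1e-12)
})

test_that("vectorized kinematics match the naive loop oracle on random sequences", {
  for (seed in 1:20) {
    n <- sample(10:50, 1)
    seq <- random_seq(n, seed = seed, fps = sample(c(24, 25, 30, 50), 1))
    v <- velocity(seq); o <- oracle_velocity(seq)
    expect_equal(v$vx, o$vx, tolerance = 1e-12)
    expect_equal(v$vy, o$vy, tolerance = 1e-12)
    a <- acceleration(seq); oa <- oracle_acceleration(seq)
    expect_equal(a$vx, oa$ax, tolerance = 1e-12)
    expect_equal(a$vy, oa$ay, tolerance = 1e-12)
    expect_equal(en_of_sums(v)$values, oracle_en_of_sums(o$vx, o$vy),
                 tolerance = 1e-12)
  }
})

test_that("norm-of-sums never exceeds the sum of norms (triangle inequality)", {
  for (seed in 1:10) {
    seq <- random_seq(20, seed = 100 + seed)
    v <- velocity(seq)
    expect_true(all(en_of_sums(v)$values <= sum_of_norms(v)$values + 1e-9))
  }
})

test_that("doubling fps doubles every velocity and motion value exactly", {
  seq25 <- random_seq(15, seed = 31, fps = 25)
  seq50 <- seq25; seq50$fps <- 50
  expect_identical(velocity(seq50)$vx, 2 * velocity(seq25)$vx)
  expect_identical(en_of_sums(velocity(seq50))$values,
                   2 * en_of_sums(velocity(seq25))$values)
})

test_that("time reversal negates velocities and reverses the motion series", {
  seq <- random_seq(12, seed = 8)
  rev_seq <- seq
  rev_seq$x <- seq$x[nrow(seq$x):1, ]
  rev_seq$y <- seq$y[nrow(seq$y):1, ]
  v <- velocity(seq); vr <- velocity(rev_seq)
  expect_equal(vr$vx, -v$vx[nrow(v$vx):1, ], tolerance = 1e-12)
  expect_equal(en_of_sums(vr)$values, rev(en_of_sums(v)$values),
               tolerance = 1e-12)
})

test_that("clip summary reports sum, mean, peak and the peak transition", {
  seq <- static_seq(4, fps = 1)
  seq$x[, 1] <- c(0, 1, 3, 6)      # velocities 1, 2, 3 px/s
  s <- en_of_sums(velocity(seq))
  sm <- summary(s)
  expect_equal(sm$sum, 6)
  expect_equal(sm$mean, 2)
  expect_equal(sm$peak, 3)
  expect_equal(sm$peak_transition, 3)
  zero <- en_of_sums(velocity(static_seq(5)))
  smz <- summary(zero)
  expect_equal(c(smz$sum, smz$mean, smz$peak), c(0, 0, 0))
  expect_equal(smz$peak_transition, 1)
})

test_that("motion segments follow the threshold/merge/min-length rule", {
  ms <- function(v) posemotion:::motion_series(v, "velocity", 25)
  expect_equal(nrow(detect_motion_segments(ms(rep(0, 10)))), 0)
  seg <- detect_motion_segments(ms(c(0, 0, 5, 6, 5, 0, 0)),
                                threshold_frac = 0.5, min_len = 1)
  expect_equal(seg, data.frame(onset = 3L, offset = 5L))
  # two bursts separated by a long quiet span stay separate
  v <- c(rep(0, 5), rep(10, 4), rep(0, 20), rep(8, 5), rep(0, 5))
  seg2 <- detect_motion_segments(ms(v), threshold_frac = 0.1, min_len = 3)
  expect_equal(nrow(seg2), 2)
  expect_equal(seg2$onset, c(6L, 30L))
  expect_equal(seg2$offset, c(9L, 34L))
  # a short quiet gap merges the bursts
  v2 <- c(rep(10, 4), 0, rep(10, 4))
  seg3 <- detect_motion_segments(ms(v2), threshold_frac = 0.5, min_len = 3)
  expect_equal(seg3, data.frame(onset = 1L, offset = 9L))
  expect_error(detect_motion_segments(ms(c(1, 2)), threshold_frac = 1.2),
               "threshold_frac")
})

test_that("file-level wrappers write suffix-conventional axis and norm tables", {
  d <- withr::local_tempdir()
  fx <- generate_fixture(
    trajectory_spec(10, fps = 25, seed = 6,
                    programs = list(list(points = 0:24, type = "linear",
                                         dx = 1, dy = 0))),
    "body25", dir = d, stem = "clip")
  raw <- convert_clip(d, "body25", fps = 25)
  cleaned <- clean_file(raw)
  vpaths <- velocity_file(cleaned)
  expect_equal(basename(vpaths),
               c("clip_body25_cleaned_velocity_x.csv",
                 "clip_body25_cleaned_velocity_y.csv"))
  apaths <- acceleration_file(cleaned)
  expect_equal(basename(apaths)[1], "clip_body25_cleaned_acceleration_x.csv")
  en <- en_file(vpaths[1], vpaths[2])
  expect_equal(basename(en), "clip_body25_cleaned_en_velocity.csv")
  s <- read_motion_series(en)
  expect_equal(s$values, rep(625, 9), tolerance = 1e-9)
  expect_equal(s$fps, 25)
  ena <- en_file(apaths[1], apaths[2])
  expect_equal(basename(ena), "clip_body25_cleaned_en_acceleration.csv")
  expect_equal(read_motion_series(ena)$quantity, "acceleration")
})
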