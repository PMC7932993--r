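# Independent naive-loop kinematics oracles: plain per-point, per-frame
# loops over the difference quotients, kept deliberately separate from the
# package's vectorized implementations.

oracle_velocity <- function(seq) {
  n <- n_frames(seq); p <- seq$model$n_points; dt <- 1 / seq$fps
  vx <- matrix(NA_real_, n - 1, p); vy <- matrix(NA_real_, n - 1, p)
  for (t in seq_len(n - 1)) {
    for (i in seq_len(p)) {
      vx[t, i] <- (seq$x[t + 1, i] - seq$x[t, i]) / dt
      vy[t, i] <- (seq$y[t + 1, i] - seq$y[t, i]) / dt
    }
  }
  list(vx = vx, vy = vy)
}

oracle_acceleration <- function(seq) {
  v <- oracle_velocity(seq)
  n <- nrow(v$vx); p <- ncol(v$vx); dt <- 1 / seq$fps
  ax <- matrix(NA_real_, n - 1, p); ay <- matrix(NA_real_, n - 1, p)
  for (t in seq_len(n - 1)) {
    for (i in seq_len(p)) {
      ax[t, i] <- (v$vx[t + 1, i] - v$vx[t, i]) / dt
      ay[t, i] <- (v$vy[t + 1, i] - v$vy[t, i]) / dt
    }
  }
  list(ax = ax, ay = ay)
}

oracle_en_of_sums <- function(vx, vy) {
  out <- numeric(nrow(vx))
  for (t in seq_len(nrow(vx))) {
    sx <- 0; sy <- 0
    for (i in seq_len(ncol(vx))) {
      sx <- sx + vx[t, i]
      sy <- sy + vy[t, i]
    }
    out[t] <- sqrt(sx^2 + sy^2)
  }
  out
}
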