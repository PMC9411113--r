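# Brute-force oracles, kept deliberately naive and independent of the
# package's vectorized implementations.

oracle_displacement <- function(traj) {
  n <- traj$n_frames
  out <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    out[i] <- sqrt((traj$x[i + 1L] - traj$x[i])^2 +
                     (traj$y[i + 1L] - traj$y[i])^2)
  }
  out
}

# signed heading change via atan2 of unit-vector products
oracle_yaw <- function(traj) {
  n <- traj$n_frames
  out <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    a <- traj$orientation[i] * pi / 180
    b <- traj$orientation[i + 1L] * pi / 180
    ua <- c(cos(a), sin(a)); ub <- c(cos(b), sin(b))
    out[i] <- atan2(ua[1L] * ub[2L] - ua[2L] * ub[1L],
                    ua[1L] * ub[1L] + ua[2L] * ub[2L]) * 180 / pi
  }
  out
}

oracle_sliding_mean <- function(v, s) {
  n <- length(v)
  half <- (s - 1L) %/% 2L
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - half >= 1L && i + half <= n) {
      acc <- 0
      for (j in (i - half):(i + half)) acc <- acc + v[j]
      out[i] <- acc / s
    }
  }
  out
}

oracle_aim <- function(v, s, c, eps = 1e-9, signed = FALSE) {
  vs <- oracle_sliding_mean(v, s)
  h <- 0L
  qual <- integer(0)
  for (i in seq_along(v)) {
    if (is.na(vs[i]) || v[i] <= eps || vs[i] <= eps) next
    lr <- log10(v[i] / vs[i])
    stat <- if (signed) lr else abs(lr)
    if (stat > c) { h <- h + 1L; qual <- c(qual, i) }
  }
  list(raw_H = h, qualifying = qual)
}

oracle_peak_deviation <- function(v, s, eps = 1e-9) {
  vs <- oracle_sliding_mean(v, s)
  best <- -Inf
  for (i in seq_along(v)) {
    if (is.na(vs[i]) || vs[i] <= eps) next
    dev <- (v[i] - vs[i]) / vs[i] * 100
    if (dev > best) best <- dev
  }
  best
}

oracle_freeze_count <- function(d, eps) {
  k <- 0L
  for (i in seq_along(d)) if (d[i] <= eps) k <- k + 1L
  k / length(d)
}

# Random trajectory with arbitrary positions/headings (not a plausible fly,
# just exercise for the kinematics code paths).
random_trajectory <- function(n, seed, frame_rate = 30.06) {
  set.seed(seed)
  fly_trajectory(frame = 0:(n - 1L),
                 x = runif(n, -20, 20), y = runif(n, -20, 20),
                 orientation = runif(n, -180, 180),
                 calibration = arena_calibration(frame_rate = frame_rate))
}

# Trajectory whose per-step instantaneous speeds equal `v` exactly:
# motion along x with displacement v/frame_rate per step.
trajectory_from_speeds <- function(v, frame_rate = 30.06, orientation = 0) {
  n <- length(v) + 1L
  fly_trajectory(frame = 0:(n - 1L),
                 x = c(0, cumsum(v / frame_rate)), y = rep(0, n),
                 orientation = rep(orientation, length.out = n),
                 calibration = arena_calibration(frame_rate = frame_rate))
}

kin_from_speeds <- function(v, frame_rate = 30.06) {
  kinematic_series(trajectory_from_speeds(v, frame_rate))
}

# the worked-example speed series: unit baseline with single-frame bursts
worked_example_speeds <- function() {
  v <- rep(1, 200)
  v[c(30, 50, 70, 90, 110, 130, 150)] <- 10
  v
}
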