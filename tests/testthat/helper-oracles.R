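# Independent oracles used across the suite. These deliberately take a
# different route than the package implementation (naive loops, rotation
# matrices) so agreement is evidence, not tautology.

# naive windowed mean, same edge policy as the pipeline (shrinking
# centered window, extra sample on the earlier side for even windows)
bf_moving_average <- function(x, w) {
  n <- length(x)
  left <- w %/% 2L
  right <- w - left - 1L
  vapply(seq_len(n),
         function(i) mean(x[max(1L, i - left):min(n, i + right)]),
         numeric(1))
}

quat_to_rotmat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Rz(yaw) %*% Ry(pitch) %*% Rx(roll), angles in degrees
euler_to_rotmat <- function(yaw, pitch, roll) {
  a <- yaw * pi / 180; b <- pitch * pi / 180; g <- roll * pi / 180
  Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)),
               3, 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(g), -sin(g), 0, sin(g), cos(g)),
               3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

rand_unit_quat <- function(n) {
  m <- matrix(stats::rnorm(4 * n), n, 4)
  m / sqrt(rowSums(m^2))
}

# non-degenerate random Euler angles (well away from gimbal lock)
rand_euler <- function(n) {
  cbind(yaw = stats::runif(n, -175, 175),
        pitch = stats::runif(n, -85, 85),
        roll = stats::runif(n, -175, 175))
}

# one-cycle recording with a single rectified-noise activation burst;
# returns the pieces needed for peak-recovery checks
make_burst_recording <- function(peak_pct, cycle_s = 8, rate = 1000,
                                 baseline_mv = 0.2, amp_mv = 0.8,
                                 burst_sd_pct = 8) {
  n <- cycle_s * rate + 1L
  time <- (seq_len(n) - 1L) / rate
  pct <- time / cycle_s * 100
  sigma <- baseline_mv + amp_mv * exp(-(pct - peak_pct)^2 / (2 * burst_sd_pct^2))
  mv <- stats::rnorm(n) * sigma
  list(time = time, mv = mv, sigma = sigma, pct = pct)
}
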