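test_that("quaternion decomposition matches the rotation-matrix route", {
  expect_equal(unname(quat_to_euler(c(1, 0, 0, 0))[1, ]), c(0, 0, 0))
  e <- quat_to_euler(c(sqrt(2) / 2, 0, 0, sqrt(2) / 2))
  expect_equal(unname(e[1, ]), c(90, 0, 0), tolerance = 1e-9)
  set.seed(31)
  q <- rand_unit_quat(200)
  e <- quat_to_euler(q)
  for (i in 1:200) {
    # rebuilding the rotation from the extracted angles must reproduce
    # the quaternion's rotation matrix
    expect_equal(euler_to_rotmat(e[i, 1], e[i, 2], e[i, 3]),
                 quat_to_rotmat(q[i, ]), tolerance = 1e-9)
  }
  expect_error(quat_to_euler(c(2, 0, 0, 0)), "non-unit")
})

test_that("euler-quaternion round trips are exact away from gimbal lock", {
  set.seed(32)
  ang <- rand_euler(500)
  back <- quat_to_euler(euler_to_quat(ang))
  expect_lt(max(abs(back - ang)), 1e-6)
})

test_that("gimbal lock is resolved by assigning the residual rotation to yaw", {
  q <- euler_to_quat(cbind(yaw = 25, pitch = 90, roll = 10))
  e <- quat_to_euler(q)
  expect_true(attr(e, "gimbal")[1])
  expect_equal(unname(e[1, "roll"]), 0)
  expect_equal(unname(e[1, "pitch"]), 90, tolerance = 1e-6)
  # the flagged decomposition still reproduces the same rotation
  expect_equal(euler_to_rotmat(e[1, 1], e[1, 2], e[1, 3]),
               quat_to_rotmat(q[1, ]), tolerance = 1e-6)
})

test_that("anatomical sign conventions mirror the roll/pitch axes between limbs", {
  e <- cbind(yaw = 0, pitch = 0, roll = 5)
  expect_equal(unname(euler_to_anatomical(e, "dominant")[1, "abad"]), 5)  # ABD
  expect_equal(unname(euler_to_anatomical(e, "non_dominant")[1, "abad"]), -5) # ADD
  z <- euler_to_anatomical(cbind(yaw = 0, pitch = 0, roll = 0), "dominant")
  expect_equal(unname(z[1, ]), c(0, 0, 0))
  # extension is +yaw on both limbs
  map_d <- motion_axis_map("dominant")
  map_n <- motion_axis_map("non_dominant")
  for (m in list(map_d, map_n)) {
    expect_equal(m$sign[m$motion == "E"], 1)
    expect_equal(m$axis[m$motion %in% c("F", "E")], c("yaw", "yaw"))
  }
  expect_equal(map_d$sign[map_d$motion == "ABD"], 1)
  expect_equal(map_n$sign[map_n$motion == "ABD"], -1)
  expect_equal(map_d$sign[map_d$motion == "LR"], 1)
  expect_equal(map_n$sign[map_n$motion == "MR"], 1)
})

test_that("angle smoothing unwraps the branch cut first", {
  spec <- acq_spec(imu_window = 10)
  # steady rotation crossing +180: smoothing must not swing through 360
  yaw_true <- seq(170, 200, length.out = 100)
  wrapped <- ((yaw_true + 180) %% 360) - 180
  e <- cbind(yaw = wrapped, pitch = 0, roll = 0)
  sm <- smooth_angles(e, spec)
  expect_lt(max(abs(diff(sm[, "yaw"]))), 1)
  expect_equal(sm[, "pitch"], rep(0, 100))
  cst <- smooth_angles(cbind(yaw = rep(12, 50), pitch = rep(-4, 50),
                             roll = rep(3, 50)), spec)
  expect_equal(unname(cst[, "yaw"]), rep(12, 50))
  imp <- cbind(yaw = c(rep(0, 49), 1, rep(0, 50)), pitch = 0, roll = 0)
  expect_equal(max(smooth_angles(imp, spec)[, "yaw"]), 1 / 10)
})

test_that("angle cycles are zero-aligned and invariant to constant offsets", {
  spec <- acq_spec(n_resample = 500)
  rate <- 100
  time <- (0:1200) / rate
  ann <- phase_annotation("t", 1 + cumsum(c(0, rep(10 / 7, 7))))
  # constant orientation: all-zero cycles
  const <- cbind(yaw = rep(30, 1201), pitch = rep(5, 1201),
                 roll = rep(-12, 1201))
  cyc <- angle_cycles(time, const, list(ann), spec)
  expect_equal(unname(cyc[[1]]), matrix(0, 500, 3))
  # ramp 0 -> 30 degrees across the cycle
  ramp <- cbind(yaw = (time - 1) * 3, pitch = 0, roll = 0)
  rc <- angle_cycles(time, ramp, list(ann), spec)[[1]]
  expect_equal(unname(rc[1, "yaw"]), 0)
  expect_equal(unname(rc[500, "yaw"]), 30, tolerance = 1e-9)
  # adding a 12-degree pre-rotation offset changes nothing after alignment
  off <- angle_cycles(time, ramp + 12, list(ann), spec)[[1]]
  expect_equal(off, rc, tolerance = 1e-9)
})

test_that("motion peaks report signed extrema in each motion's direction", {
  sch <- adl_reference_schedule("drinking")
  axis <- cycle_axis(9000)
  lobe <- function(pk, width, amp) {
    v <- numeric(9000)
    inl <- abs(axis - pk) < width / 2
    v[inl] <- amp / 2 * (1 + cos(2 * pi * (axis[inl] - pk) / width))
    v
  }
  # dominant-arm drinking-like trajectory: ADD is a negative roll lobe
  cyc <- cbind(yaw = lobe(70.3, 50, 8.9), pitch = lobe(45.5, 50, 20.1),
               roll = -lobe(47.7, 50, 28.1))
  p <- angle_peak_summary(cyc, sch, "dominant")
  add <- p[p$motion == "ADD", ]
  expect_equal(add$peak_time, 47.7, tolerance = 0.05)
  expect_equal(add$peak_value, -28.1, tolerance = 1e-6)
  expect_identical(add$phase_at_peak, 4L)
  expect_equal(p[p$motion == "LR", "peak_value"], 20.1, tolerance = 1e-6)
  expect_equal(p[p$motion == "E", "peak_time"], 70.3, tolerance = 0.05)
  # the paired motion reports the largest opposite-sign value (here ~0)
  expect_lt(abs(p[p$motion == "ABD", "peak_value"]), 1e-9)
  # flat cycle: all peaks zero at the first sample by the tie rule
  pf <- angle_peak_summary(matrix(0, 9000, 3,
                                  dimnames = list(NULL, c("yaw", "pitch", "roll"))),
                           sch, "dominant")
  expect_equal(pf$peak_value, rep(0, 6))
  expect_equal(pf$peak_time, rep(0, 6))
})

test_that("raised-cosine lobes survive smoothing within the analytic attenuation", {
  spec <- acq_spec(n_resample = 2000)
  rate <- 100
  cycle_s <- 10
  time <- (0:(cycle_s * rate)) / rate
  pct <- time / cycle_s * 100
  width <- 50; amp <- 28.1; pk <- 47.7
  v <- numeric(length(pct))
  inl <- abs(pct - pk) < width / 2
  v[inl] <- amp / 2 * (1 + cos(2 * pi * (pct[inl] - pk) / width))
  e <- cbind(yaw = 0 * v, pitch = 0 * v, roll = -v)
  sm <- smooth_angles(e, spec)
  ann <- phase_annotation("t", cumsum(c(0, rep(cycle_s / 7, 7))))
  cyc <- angle_cycles(time, sm, list(ann), spec)[[1]]
  w_pct <- 100 * (spec$imu_window / rate) / cycle_s
  atten <- raised_cosine_boxcar_attenuation(width, w_pct)
  axis <- cycle_axis(spec$n_resample)
  expect_lt(abs(axis[which.min(cyc[, "roll"])] - pk), 1)
  expect_lt(abs(min(cyc[, "roll"]) - (-amp * atten)), 0.5)
})
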