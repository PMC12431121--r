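small_cfg <- function(...) {
  synth_config(n_subjects = 2, n_trials = 2, cycle_mean_s = 4,
               rest_s = 2, lead_s = 1, ...)
}

test_that("the generator is fully deterministic under a fixed seed", {
  a <- simulate_adl_dataset(small_cfg(), seed = 5)
  b <- simulate_adl_dataset(small_cfg(), seed = 5)
  expect_identical(a$subjects[[1]]$limbs$dominant$emg$counts,
                   b$subjects[[1]]$limbs$dominant$emg$counts)
  expect_identical(a$subjects[[2]]$limbs$non_dominant$imu$quat,
                   b$subjects[[2]]$limbs$non_dominant$imu$quat)
  expect_identical(a$subjects[[1]]$annotations[[1]]$boundaries,
                   b$subjects[[1]]$annotations[[1]]$boundaries)
  c <- simulate_adl_dataset(small_cfg(), seed = 6)
  expect_false(identical(a$subjects[[1]]$limbs$dominant$emg$counts,
                         c$subjects[[1]]$limbs$dominant$emg$counts))
})

test_that("zero jitter reproduces the template schedule in every trial", {
  cfg <- small_cfg(jitter_scale = 0, snap_to_frames = FALSE)
  truth <- sample_protocol(cfg, seed = 9)
  tmpl <- adl_reference_schedule("drinking")$mean_duration
  for (s in truth$subjects)
    for (tr in s$trials)
      expect_equal(unname(durations_from_annotation(tr$boundaries)), tmpl,
                   tolerance = 1e-9)
  # with frame snapping the durations move by at most one frame per boundary
  truth2 <- sample_protocol(small_cfg(jitter_scale = 0), seed = 9)
  d2 <- durations_from_annotation(truth2$subjects[[1]]$trials[[1]]$boundaries)
  expect_lt(max(abs(d2 - tmpl)), 2 * 100 / (30 * 4)) # 2 frames of a 4 s cycle
})

test_that("cohort moments are matched to the template", {
  cfg <- synth_config(n_subjects = 10, n_trials = 5, snap_to_frames = FALSE)
  truth <- sample_protocol(cfg, seed = 10)
  dur <- do.call(rbind, lapply(truth$subjects, function(s)
    t(vapply(s$trials, function(tr)
      unname(durations_from_annotation(tr$boundaries)), numeric(7)))))
  tmpl <- adl_reference_schedule("drinking")
  # moment-matched sampling: cohort means essentially exact, SDs close
  expect_lt(max(abs(colMeans(dur) - tmpl$mean_duration)), 0.05)
  sds <- apply(dur, 2, sd)
  expect_lt(max(abs(sds - tmpl$sd_duration) / tmpl$sd_duration), 0.35)
  expect_true(all(abs(rowSums(dur) - 100) < 1e-6))
})

test_that("synthetic EMG carries the analytic half-normal envelope", {
  # resting-level check: all burst amplitudes zero, baseline well above
  # one ADC code so quantization only adds lsb^2/12 of variance
  mt <- default_muscle_templates("drinking")
  mt$peak_mv <- 0
  cfg <- small_cfg(muscle_templates = mt, emg_baseline_mv = 0.8)
  truth <- sample_protocol(cfg, seed = 15)
  emg <- synth_emg(truth$subjects[[1]], cfg, "dominant", seed = 44)
  mv <- bits_to_mv(emg$counts, cfg$spec)
  lsb <- 1000 * cfg$spec$adc_range / (2^cfg$spec$adc_bits - 1)
  sigma_eff <- sqrt(0.8^2 + lsb^2 / 12)
  got <- colMeans(rectify_emg(mv))
  expect_true(all(abs(got - sigma_eff * sqrt(2 / pi)) <
                    0.03 * sigma_eff))
  expect_identical(synth_emg(truth$subjects[[1]], cfg, "dominant", seed = 44)$counts,
                   emg$counts)
})

test_that("synthetic IMU encodes the injected lobes exactly before smoothing", {
  # no lobes and no noise: identity quaternions throughout
  lt0 <- default_lobe_templates("drinking")[0, ]
  cfg0 <- small_cfg(lobe_templates = lt0, angle_noise_deg = 0)
  truth0 <- sample_protocol(cfg0, seed = 16)
  imu0 <- synth_imu(truth0$subjects[[1]], cfg0, "dominant", seed = 45)
  expect_lt(max(abs(sweep(imu0$quat, 2, c(1, 0, 0, 0)))), 1e-12)

  # one 30-degree yaw lobe round-trips through the quaternion encoding
  lt <- data.frame(limb = "dominant", motion = "E", peak_time_pct = 50,
                   peak_deg = 30, width_pct = 60, stringsAsFactors = FALSE)
  cfg <- small_cfg(lobe_templates = lt, angle_noise_deg = 0,
                   jitter_scale = 0, snap_to_frames = FALSE)
  truth <- sample_protocol(cfg, seed = 17)
  imu <- synth_imu(truth$subjects[[1]], cfg, "dominant", seed = 46)
  ang <- quat_to_euler(imu$quat)
  tr <- truth$subjects[[1]]$trials[[1]]
  idx <- which(imu$time >= tr$start & imu$time <= tr$start + tr$cycle_s)
  pct <- (imu$time[idx] - tr$start) / tr$cycle_s * 100
  inl <- abs(pct - 50) < 30
  expected <- numeric(length(pct))
  expected[inl] <- 30 / 2 * (1 + cos(2 * pi * (pct[inl] - 50) / 60))
  expect_lt(max(abs(ang[idx, "yaw"] - expected)), 1e-6)
  expect_equal(max(ang[idx, "yaw"]), 30, tolerance = 1e-6)
  # rotation lobes at or beyond 90 degrees are rejected up front
  bad <- data.frame(limb = "dominant", motion = "LR", peak_time_pct = 50,
                    peak_deg = 95, width_pct = 60)
  expect_error(small_cfg(lobe_templates = bad), "gimbal")
})

test_that("datasets round-trip through the on-disk dialect with a valid manifest", {
  ds <- simulate_adl_dataset(small_cfg(), seed = 19)
  dir <- file.path(tempfile(), "ds")
  write_adl_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_adl_dataset(dir)
  expect_identical(back$subjects[[1]]$limbs$dominant$emg$counts,
                   ds$subjects[[1]]$limbs$dominant$emg$counts)
  expect_equal(unname(back$subjects[[2]]$limbs$non_dominant$imu$quat),
               unname(ds$subjects[[2]]$limbs$non_dominant$imu$quat),
               tolerance = 5e-9)
  expect_equal(back$subjects[[1]]$annotations[[2]]$boundaries,
               ds$subjects[[1]]$annotations[[2]]$boundaries,
               tolerance = 1e-9)
  # truth sidecars travel with the data
  expect_equal(back$truth$subjects[[1]]$trials[[1]]$cycle_s,
               ds$truth$subjects[[1]]$trials[[1]]$cycle_s,
               tolerance = 1e-9)
  # refusal to clobber, unless asked
  expect_error(write_adl_dataset(ds, dir), "not empty")
  expect_silent(write_adl_dataset(ds, dir, overwrite = TRUE))
  # a tampered file breaks the checksum validation
  f <- file.path(dir, "S01", "annotations.csv")
  writeLines(c(readLines(f), ""), f)
  expect_error(read_adl_dataset(dir), "checksum")
})
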