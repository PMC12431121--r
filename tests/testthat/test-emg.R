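test_that("ADC counts convert to mV around the mid-scale zero", {
  expect_equal(bits_to_mv(2048), 0)
  expect_equal(bits_to_mv(4095, offset = 0), 1600)
  expect_equal(bits_to_mv(3072), 1024 * 1600 / 4095)
  # conversion is affine: differences are independent of the offset
  expect_equal(bits_to_mv(3000) - bits_to_mv(2000),
               bits_to_mv(3000, offset = 0) - bits_to_mv(2000, offset = 0))
})

test_that("rectification removes DC and halves Gaussian noise to sigma*sqrt(2/pi)", {
  t <- seq(0, 1, by = 1e-3)
  s <- 1.5 * sin(2 * pi * 5 * t)
  expect_equal(rectify_emg(s), abs(s), tolerance = 1e-12)
  expect_equal(rectify_emg(rep(4.2, 100)), rep(0, 100))
  set.seed(21)
  sigma <- 0.7
  x <- rnorm(2e5, mean = 3, sd = sigma)
  half_normal_mean <- sigma * sqrt(2 / pi)
  se <- sigma * sqrt(1 - 2 / pi) / sqrt(2e5)
  expect_lt(abs(mean(rectify_emg(x)) - half_normal_mean), 4 * se)
})

test_that("the envelope preserves burst timing and spreads an impulse to 1/window", {
  spec <- acq_spec()
  x <- numeric(5000); x[2500] <- 1
  expect_equal(max(emg_envelope(x, spec)), 1 / spec$emg_window)
  expect_equal(emg_envelope(rep(2, 3000), spec), rep(2, 3000))
  set.seed(22)
  rec <- make_burst_recording(peak_pct = 45)
  env <- emg_envelope(rectify_emg(rec$mv), spec)
  peak_pct <- rec$pct[which.max(env)]
  expect_lt(abs(peak_pct - 45), 0.6 + 0.02) # 0.6 % plus one grid step
  # envelope bounded by the rectified input
  r <- rectify_emg(rec$mv)
  expect_true(all(env >= 0) && max(env) <= max(r))
})

test_that("cycle extraction trims annotated spans and rejects bad annotations", {
  rate <- 1000
  time <- (0:60000) / rate
  x <- sin(time)
  anns <- lapply(0:4, function(k)
    phase_annotation(paste0("t", k), k * 12 + cumsum(c(0, rep(10 / 7, 7)))))
  segs <- extract_cycles(time, x, anns)
  expect_length(segs, 5)
  for (k in 1:5) {
    expect_equal(segs[[k]]$time[1], 0)
    n_expect <- round(10 * rate)
    expect_lte(abs(nrow(segs[[k]]$values) - n_expect), 1)
  }
  overlapping <- list(phase_annotation("a", seq(0, 14, 2)),
                      phase_annotation("b", seq(10, 24, 2)))
  expect_error(extract_cycles(time, x, overlapping), "overlap")
  outside <- phase_annotation("c", seq(55, 69, 2))
  expect_error(extract_cycles(time, x, list(outside)), "outside")
})

test_that("subject mean cycles equal the brute-force resample-then-average", {
  spec <- acq_spec(n_resample = 500)
  seg <- function(dur, f) {
    tm <- seq(0, dur, by = 1e-2)
    list(time = tm, values = cbind(a = f(tm), b = 2 * f(tm)))
  }
  s1 <- seg(3, function(t) sin(t))
  s2 <- seg(4.5, function(t) cos(t))
  got <- subject_mean_cycle(list(s1, s2), spec)
  # oracle: stats::approx onto each segment's own uniform grid, then average
  oracle <- function(s, col) {
    g <- seq(s$time[1], s$time[length(s$time)], length.out = 500)
    approx(s$time, s$values[, col], xout = g)$y
  }
  expect_equal(got[, "a"], (oracle(s1, "a") + oracle(s2, "a")) / 2,
               tolerance = 1e-9)
  expect_equal(got[, "b"], (oracle(s1, "b") + oracle(s2, "b")) / 2,
               tolerance = 1e-9)
  # identical segments average to themselves
  same <- subject_mean_cycle(list(s1, s1), spec)
  expect_equal(same, subject_mean_cycle(list(s1), spec))
  # two constant segments average pointwise
  c0 <- list(time = 0:10, values = cbind(v = rep(0, 11)))
  c2 <- list(time = 0:8, values = cbind(v = rep(2, 9)))
  expect_equal(unname(subject_mean_cycle(list(c0, c2), spec)[, 1]),
               rep(1, 500))
})

test_that("min-max normalization maps to [0,1] with flat cycles at zero", {
  expect_equal(minmax_normalize(c(1, 3, 5)), c(0, 0.5, 1))
  set.seed(23)
  x <- rnorm(1000)
  nx <- minmax_normalize(x)
  expect_equal(range(nx), c(0, 1))
  expect_equal(minmax_normalize(rep(7, 50)), rep(0, 50))
  m <- cbind(a = x, b = rep(1, 1000))
  nm <- minmax_normalize(m)
  expect_equal(range(nm[, "a"]), c(0, 1))
  expect_equal(unname(nm[, "b"]), rep(0, 1000))
})

test_that("group averaging is pointwise with bookkeeping of contributors", {
  v <- matrix(runif(200), 100, 2)
  expect_equal(group_mean_cycle(list(v)), v, ignore_attr = TRUE)
  g <- group_mean_cycle(list(v, -v + 2))
  expect_equal(unname(g), matrix(1, 100, 2), ignore_attr = TRUE)
  expect_identical(attr(g, "n_contributing"), 2L)
  expect_error(group_mean_cycle(list(v, v[1:50, ])), "shape")
})

test_that("peak summaries report the first maximum and its phase", {
  sch <- adl_reference_schedule("drinking")
  axis <- cycle_axis(9000)
  bump <- exp(-(axis - 40)^2 / 50)
  cyc <- cbind(AD = bump)
  p <- emg_peak_summary(cyc, sch)
  expect_equal(p$peak_time, 40, tolerance = 0.02)
  expect_identical(p$phase_at_peak, 4L)
  # exact ties resolve to the earlier time
  flat2 <- numeric(9000); flat2[c(1000, 5000)] <- 1
  p2 <- emg_peak_summary(cbind(x = flat2), sch)
  expect_equal(p2$peak_time, axis[1000])
})

test_that("the EMG branch is scale-equivariant up to normalization", {
  set.seed(24)
  spec <- acq_spec(n_resample = 1000)
  rec <- make_burst_recording(peak_pct = 40, cycle_s = 4)
  ann <- phase_annotation("t", cumsum(c(0, rep(4 / 7, 7))))
  run <- function(mv) {
    env <- emg_envelope(rectify_emg(mv), spec)
    segs <- extract_cycles(rec$time, env, list(ann))
    m <- subject_mean_cycle(segs, spec)
    list(mv = m, norm = minmax_normalize(m))
  }
  base <- run(rec$mv)
  scaled <- run(3.5 * rec$mv)
  expect_equal(scaled$mv, 3.5 * base$mv, tolerance = 1e-9)
  expect_equal(scaled$norm, base$norm, tolerance = 1e-9)
})

test_that("injected burst peaks are recovered across many noisy trials", {
  set.seed(25)
  spec <- acq_spec()
  n_trials <- 100
  injected <- runif(n_trials, 20, 60)
  baseline <- 0.2; amp <- 0.8; burst_sd <- 8 # SNR 4 at the peak
  t_err <- numeric(n_trials)
  peak_mv <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    rec <- make_burst_recording(injected[i], cycle_s = 8,
                                baseline_mv = baseline, amp_mv = amp,
                                burst_sd_pct = burst_sd)
    env <- emg_envelope(rectify_emg(rec$mv), spec)
    segs <- extract_cycles(rec$time, env,
                           list(phase_annotation("t", cumsum(c(0, rep(8 / 7, 7))))))
    cyc <- subject_mean_cycle(segs, spec)
    axis <- cycle_axis(spec$n_resample)
    t_err[i] <- axis[which.max(cyc)] - injected[i]
    peak_mv[i] <- max(cyc)
  }
  expect_lt(median(abs(t_err)), 1)
  # analytic expected envelope peak: half-normal mean of the modulated
  # sigma, attenuated by the smoothing window (1 s of an 8 s cycle)
  atten <- gaussian_boxcar_attenuation(burst_sd, 100 * 1 / 8)
  expected <- sqrt(2 / pi) * (baseline + amp * atten)
  expect_lt(abs(median(peak_mv) - expected) / expected, 0.15)
})
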