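# Synthetic wearable recordings with ground-truth sidecars.
#
# EMG model: amplitude-modulated Gaussian interference. The raw signal is
# zero-mean Gaussian noise whose standard deviation sigma(t) follows a
# baseline plus one Gaussian burst per muscle and cycle; the expected
# rectified value is sigma(t) * sqrt(2/pi) (half-normal mean), so every
# stage of the envelope pipeline has an analytic target.
#
# Kinematic model: each Euler axis is a sum of raised-cosine lobes (smooth,
# compactly supported), whose attenuation under moving-average smoothing
# has a closed form, plus small Gaussian jitter.
#
# Cohort sampling is moment-matched: per-trial parameters are drawn by
# Latin-hypercube quantile strata and recentred so the finite cohort's
# means equal the templates exactly (in the spirit of
# MASS::mvrnorm(empirical = TRUE)). Recovery tests therefore measure
# pipeline error, not Monte-Carlo drift of the cohort itself.

# ---- moment-matched samplers -------------------------------------------

.lhs_u <- function(n) (sample.int(n) - 0.5) / n

.lhs_normal <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  mean + sd * stats::qnorm(.lhs_u(n)) # symmetric strata: mean is exact
}

.lhs_gamma <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  shape <- (mean / sd)^2
  x <- stats::qgamma(.lhs_u(n), shape = shape, scale = sd^2 / mean)
  pmax(x + (mean - mean(x)), 0.02 * mean) # recentre; keep positive
}

#' Peak attenuation of a Gaussian bump under moving-average smoothing
#'
#' Closed-form factor by which a centered boxcar of width `window` scales
#' the peak of a Gaussian bump of standard deviation `sd` (both in the same
#' units, e.g. percent of cycle).
#'
#' @param sd Gaussian bump standard deviation.
#' @param window Smoothing window width.
#' @return Attenuation factor in (0, 1].
#' @export
gaussian_boxcar_attenuation <- function(sd, window) {
  if (window <= 0) return(1)
  sqrt(2 * pi) * sd / window * (2 * stats::pnorm(window / (2 * sd)) - 1)
}

#' Peak attenuation of a raised-cosine lobe under moving-average smoothing
#'
#' A lobe `A/2 * (1 + cos(2*pi*(t - t0)/W))` on `|t - t0| < W/2` smoothed by
#' a centered boxcar of width `w` keeps the fraction
#' `1/2 * (1 + W/(pi*w) * sin(pi*w/W))` of its peak while `w <= W`, and
#' `W/(2*w)` once the window covers the whole lobe.
#'
#' @param width Full lobe width `W`.
#' @param window Smoothing window width `w` (same units).
#' @return Attenuation factor in (0, 1].
#' @export
raised_cosine_boxcar_attenuation <- function(width, window) {
  if (window <= 0) return(1)
  if (window <= width)
    0.5 * (1 + width / (pi * window) * sin(pi * window / width))
  else
    width / (2 * window)
}

# ---- configuration ------------------------------------------------------

#' Default muscle activation-burst templates
#'
#' Per limb and muscle: the normalized-cycle time of the activation peak
#' and the expected rectified-envelope peak in mV. Values are seeded from
#' the normative drinking/eating reference magnitudes so that demonstration
#' output is visually comparable to typical healthy-adult recordings;
#' they are generator parameters, not reproductions of any measurement.
#'
#' @param task `"drinking"` or `"eating"`.
#' @return Data frame with columns `limb`, `muscle`, `peak_time_pct`,
#'   `peak_mv`.
#' @export
default_muscle_templates <- function(task = c("drinking", "eating")) {
  task <- match.arg(task)
  m <- muscles()
  if (task == "drinking") {
    dom_t <- c(PM = 38.3, AD = 42.0, MD = 43.1, PD = 42.6, UT = 36.1, LT = 40.7)
    dom_a <- c(PM = 0.3, AD = 0.9, MD = 0.4, PD = 0.2, UT = 0.6, LT = 0.4)
    nd_t <- c(PM = 44.8, AD = 39.1, MD = 40.2, PD = 28.0, UT = 54.8, LT = 53.3)
    nd_a <- c(PM = 0.4, AD = 0.2, MD = 0.1, PD = 0.1, UT = 0.4, LT = 0.4)
  } else {
    dom_t <- c(PM = 47.8, AD = 46.3, MD = 46.7, PD = 78.0, UT = 46.1, LT = 47.9)
    dom_a <- c(PM = 0.3, AD = 0.7, MD = 0.4, PD = 0.3, UT = 0.8, LT = 0.4)
    nd_t <- c(PM = 82.0, AD = 79.5, MD = 52.2, PD = 59.9, UT = 47.0, LT = 58.1)
    nd_a <- c(PM = 0.4, AD = 0.2, MD = 0.2, PD = 0.2, UT = 0.6, LT = 0.3)
  }
  rbind(
    data.frame(limb = "dominant", muscle = m, peak_time_pct = dom_t[m],
               peak_mv = dom_a[m], row.names = NULL),
    data.frame(limb = "non_dominant", muscle = m, peak_time_pct = nd_t[m],
               peak_mv = nd_a[m], row.names = NULL))
}

#' Default joint-excursion lobe templates
#'
#' Per limb: the primary excursion lobe on each Euler axis, given as the
#' motion label, the normalized-cycle time of its peak, its magnitude in
#' degrees (the Euler sign follows [motion_axis_map()]), and the full lobe
#' width in percent of cycle. Motions without a listed lobe correspond to
#' near-zero rows in the summary tables. Magnitudes are seeded from the
#' normative reference values (comparability only).
#'
#' @param task `"drinking"` or `"eating"`.
#' @return Data frame with columns `limb`, `motion`, `peak_time_pct`,
#'   `peak_deg`, `width_pct`.
#' @export
default_lobe_templates <- function(task = c("drinking", "eating")) {
  task <- match.arg(task)
  if (task == "drinking") {
    data.frame(
      limb = c("dominant", "dominant", "dominant",
               "non_dominant", "non_dominant", "non_dominant", "non_dominant"),
      motion = c("E", "LR", "ADD", "E", "MR", "ADD", "F"),
      peak_time_pct = c(70.3, 45.5, 47.7, 58.5, 36.2, 52.5, 84.7),
      peak_deg = c(8.9, 20.1, 28.1, 0.1, 0.5, 0.9, 0.2),
      width_pct = c(50, 50, 50, 40, 30, 40, 20),
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      limb = c(rep("dominant", 6), rep("non_dominant", 3)),
      motion = c("E", "F", "MR", "LR", "ABD", "ADD", "E", "MR", "ADD"),
      peak_time_pct = c(44.9, 80.5, 23.8, 49.2, 12.1, 51.7, 55.4, 31.4, 63.6),
      peak_deg = c(6.1, 3.6, 2.7, 6.1, 0.9, 6.0, 0.3, 1.0, 1.3),
      width_pct = c(30, 30, 24, 24, 24, 30, 30, 30, 30),
      stringsAsFactors = FALSE)
  }
}

#' Configuration of the synthetic-recording generator
#'
#' The defaults emulate the normative study protocol: 30 subjects, five
#' repetitions separated by 5 s rests, movement cycles of about 10 s at a
#' comfortable speed, phase durations following the task's reference
#' schedule, per-muscle activation bursts, and raised-cosine joint
#' excursions with limb-specific signs.
#'
#' @param task `"drinking"` or `"eating"`.
#' @param n_subjects Number of subjects.
#' @param n_trials Repetitions per subject.
#' @param rest_s Rest between repetitions, seconds.
#' @param lead_s Recording lead-in/out before the first and after the last
#'   cycle, seconds.
#' @param cycle_mean_s,cycle_sd_s Mean and between-trial SD of the cycle
#'   duration, seconds.
#' @param schedule Phase-duration template (a `phase_schedule`).
#' @param muscle_templates See [default_muscle_templates()].
#' @param lobe_templates See [default_lobe_templates()].
#' @param emg_baseline_mv Baseline (resting) rectified-envelope level, mV.
#' @param emg_burst_sd_pct Gaussian burst standard deviation, % of cycle.
#' @param emg_time_sd_pct Between-trial SD of burst peak times, % of cycle.
#' @param emg_amp_cv Between-trial coefficient of variation of burst
#'   amplitudes.
#' @param angle_time_sd_pct Between-trial SD of lobe peak times, % of cycle.
#' @param angle_amp_cv Between-trial coefficient of variation of lobe
#'   amplitudes.
#' @param angle_noise_deg Additive Gaussian angle jitter, degrees.
#' @param jitter_scale Global multiplier on every between-trial SD above
#'   (0 makes all trials exactly match the templates).
#' @param snap_to_frames Snap phase boundaries to the video frame grid, as
#'   a human annotator stepping through frames would (set `FALSE` for
#'   continuous-time boundaries).
#' @param spec An [acq_spec()].
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(task = c("drinking", "eating"),
                         n_subjects = 30, n_trials = 5,
                         rest_s = 5, lead_s = 2,
                         cycle_mean_s = 10, cycle_sd_s = 1,
                         schedule = adl_reference_schedule(task),
                         muscle_templates = default_muscle_templates(task),
                         lobe_templates = default_lobe_templates(task),
                         emg_baseline_mv = 0.05, emg_burst_sd_pct = 8,
                         emg_time_sd_pct = 2, emg_amp_cv = 0.1,
                         angle_time_sd_pct = 0.75, angle_amp_cv = 0.05,
                         angle_noise_deg = 0.2,
                         jitter_scale = 1,
                         snap_to_frames = TRUE,
                         spec = acq_spec()) {
  task <- match.arg(task)
  if (n_subjects < 1 || n_trials < 1)
    stop("synth_config: counts must be positive", call. = FALSE)
  if (any(schedule$sd_duration < 0))
    stop("synth_config: schedule SDs must be non-negative", call. = FALSE)
  bad_pitch <- lobe_templates$motion %in% c("MR", "LR") &
    lobe_templates$peak_deg >= 90
  if (any(bad_pitch))
    stop("synth_config: rotation lobes of 90 degrees or more reach gimbal lock",
         call. = FALSE)
  structure(list(task = task, n_subjects = n_subjects, n_trials = n_trials,
                 rest_s = rest_s, lead_s = lead_s,
                 cycle_mean_s = cycle_mean_s, cycle_sd_s = cycle_sd_s,
                 schedule = schedule,
                 muscle_templates = muscle_templates,
                 lobe_templates = lobe_templates,
                 emg_baseline_mv = emg_baseline_mv,
                 emg_burst_sd_pct = emg_burst_sd_pct,
                 emg_time_sd_pct = emg_time_sd_pct,
                 emg_amp_cv = emg_amp_cv,
                 angle_time_sd_pct = angle_time_sd_pct,
                 angle_amp_cv = angle_amp_cv,
                 angle_noise_deg = angle_noise_deg,
                 jitter_scale = jitter_scale,
                 snap_to_frames = snap_to_frames,
                 spec = spec),
            class = "synth_config")
}

# durations: n trials x 7 phases, percent, rows summing to 100, cohort
# column means matching the template exactly (see file header).
.sample_durations <- function(n, schedule, jitter_scale) {
  mu <- schedule$mean_duration
  sdv <- schedule$sd_duration * jitter_scale
  d <- matrix(0, n, 7L)
  for (k in 1:7) d[, k] <- .lhs_gamma(n, mu[k], sdv[k])
  d <- pmax(d, 0.5)
  d <- d / rowSums(d) * 100
  shift <- mu / sum(mu) * 100 - colMeans(d)
  d <- sweep(d, 2L, shift, "+") # shifts sum to 0: row sums stay 100
  if (any(d <= 0.3)) {
    d <- pmax(d, 0.3)
    d <- d / rowSums(d) * 100
  }
  d
}

#' Draw the ground-truth protocol for a synthetic cohort
#'
#' Samples, for every subject and trial: the cycle duration, the seven
#' phase durations (gamma marginals around the template schedule,
#' moment-matched across the cohort), the phase-boundary times snapped to
#' the video frame grid, and the per-trial burst and lobe parameters for
#' both limbs. Deterministic given `seed`.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @return Object of class `synth_truth`: a list with one element per
#'   subject, each holding per-trial `boundaries` (seconds, on the frame
#'   grid) and per-limb burst/lobe parameter tables.
#' @export
sample_protocol <- function(config, seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(as.integer(seed))
  ns <- config$n_subjects
  nt <- config$n_trials
  n <- ns * nt
  fps <- config$spec$video_fps
  js <- config$jitter_scale

  cyc <- .lhs_normal(n, config$cycle_mean_s, config$cycle_sd_s * js)
  cyc <- pmax(cyc, 0.3 * config$cycle_mean_s)
  dur <- .sample_durations(n, config$schedule, js)

  mt <- config$muscle_templates
  bursts <- vector("list", nrow(mt))
  for (r in seq_len(nrow(mt))) {
    bursts[[r]] <- list(
      limb = mt$limb[r], muscle = mt$muscle[r],
      peak_time = .lhs_normal(n, mt$peak_time_pct[r],
                              config$emg_time_sd_pct * js),
      sigma_amp = mt$peak_mv[r] / sqrt(2 / pi) *
        (1 + config$emg_amp_cv * js * stats::qnorm(.lhs_u(n))))
  }

  lt <- config$lobe_templates
  lobes <- vector("list", nrow(lt))
  for (r in seq_len(nrow(lt))) {
    lobes[[r]] <- list(
      limb = lt$limb[r], motion = lt$motion[r], width = lt$width_pct[r],
      peak_time = .lhs_normal(n, lt$peak_time_pct[r],
                              config$angle_time_sd_pct * js),
      amp = lt$peak_deg[r] *
        (1 + config$angle_amp_cv * js * stats::qnorm(.lhs_u(n))))
  }

  subjects <- vector("list", ns)
  for (i in seq_len(ns)) {
    rows <- (i - 1L) * nt + seq_len(nt)
    trials <- vector("list", nt)
    t0 <- config$lead_s
    for (j in seq_len(nt)) {
      r <- rows[j]
      b <- t0 + cumsum(c(0, dur[r, ] / 100 * cyc[r]))
      if (isTRUE(config$snap_to_frames)) {
        b <- round(b * fps) / fps # annotate on the video frame grid
        if (any(diff(b) <= 0)) # snapping collapsed a short phase
          b <- b[1L] + cumsum(c(0, pmax(diff(b), 1 / fps)))
      }
      trial_bursts <- lapply(bursts, function(bb)
        list(limb = bb$limb, muscle = bb$muscle,
             peak_time = bb$peak_time[r], sigma_amp = max(bb$sigma_amp[r], 0)))
      trial_lobes <- lapply(lobes, function(ll)
        list(limb = ll$limb, motion = ll$motion, width = ll$width,
             peak_time = ll$peak_time[r], amp = ll$amp[r]))
      trials[[j]] <- list(trial = j, start = b[1L], boundaries = b,
                          cycle_s = b[8L] - b[1L],
                          bursts = trial_bursts, lobes = trial_lobes)
      t0 <- b[8L] + config$rest_s
    }
    subjects[[i]] <- list(subject_id = sprintf("S%02d", i),
                          trials = trials,
                          total_s = t0 - config$rest_s + config$lead_s)
  }
  structure(list(task = config$task, seed = as.integer(seed),
                 subjects = subjects),
            class = "synth_truth")
}

# sigma(t) in mV for one limb of one subject, plus the same on an arbitrary
# percent grid (analytic expected envelope support).
.emg_sigma <- function(truth_subject, limb, config, time) {
  sigma <- matrix(config$emg_baseline_mv, length(time), 6L,
                  dimnames = list(NULL, muscles()))
  w <- config$emg_burst_sd_pct
  for (tr in truth_subject$trials) {
    idx <- which(time >= tr$start & time <= tr$start + tr$cycle_s)
    if (!length(idx)) next
    pct <- (time[idx] - tr$start) / tr$cycle_s * 100
    for (bb in tr$bursts) {
      if (bb$limb != limb) next
      sigma[idx, bb$muscle] <- sigma[idx, bb$muscle] +
        bb$sigma_amp * exp(-(pct - bb$peak_time)^2 / (2 * w^2))
    }
  }
  sigma
}

#' Synthesize the EMG recording for one subject and limb
#'
#' Generates amplitude-modulated Gaussian interference with the subject's
#' ground-truth burst parameters, quantizes to ADC counts around mid-scale,
#' and clips at the converter rails (the saturated fraction is stored in
#' the `saturated` attribute).
#'
#' @param truth_subject One subject element of a [sample_protocol()] result.
#' @param config The [synth_config()] used to draw the truth.
#' @param limb `"dominant"` or `"non_dominant"`.
#' @param seed Integer seed for the carrier noise.
#' @return A [raw_emg()] with attribute `saturated`.
#' @export
synth_emg <- function(truth_subject, config, limb = "dominant", seed = 1L) {
  set.seed(as.integer(seed))
  spec <- config$spec
  n <- round(truth_subject$total_s * spec$emg_rate) + 1L
  time <- (seq_len(n) - 1L) / spec$emg_rate
  sigma <- .emg_sigma(truth_subject, limb, config, time)
  mv <- matrix(stats::rnorm(n * 6L), n, 6L) * sigma
  lsb <- 1000 * spec$adc_range / (2^spec$adc_bits - 1)
  mid <- 2^(spec$adc_bits - 1)
  cnt <- round(mid + mv / lsb)
  sat <- mean(cnt < 0 | cnt > 2^spec$adc_bits - 1)
  cnt <- pmin(pmax(cnt, 0), 2^spec$adc_bits - 1)
  out <- raw_emg(limb, time, cnt, rate = spec$emg_rate)
  attr(out, "saturated") <- sat
  out
}

# raised-cosine lobe values at percent positions
.rc_lobe <- function(pct, peak_time, width, amp) {
  v <- numeric(length(pct))
  in_lobe <- abs(pct - peak_time) < width / 2
  v[in_lobe] <- amp / 2 * (1 + cos(2 * pi * (pct[in_lobe] - peak_time) / width))
  v
}

# Euler angle matrix (yaw, pitch, roll in degrees) for one subject/limb
.imu_angles <- function(truth_subject, limb, config, time) {
  ang <- matrix(0, length(time), 3L,
                dimnames = list(NULL, c("yaw", "pitch", "roll")))
  for (tr in truth_subject$trials) {
    idx <- which(time >= tr$start & time <= tr$start + tr$cycle_s)
    if (!length(idx)) next
    pct <- (time[idx] - tr$start) / tr$cycle_s * 100
    for (ll in tr$lobes) {
      if (ll$limb != limb) next
      map <- motion_axis_map(ll$limb)
      k <- match(ll$motion, map$motion)
      ax <- map$axis[k]
      ang[idx, ax] <- ang[idx, ax] +
        map$sign[k] * .rc_lobe(pct, ll$peak_time, ll$width, ll$amp)
    }
  }
  ang
}

#' Synthesize the IMU recording for one subject and limb
#'
#' Builds each Euler axis as the sum of the subject's ground-truth
#' raised-cosine lobes plus Gaussian jitter, then converts to unit
#' quaternions under the package's Z-Y-X convention.
#'
#' @inheritParams synth_emg
#' @return A [raw_imu()].
#' @export
synth_imu <- function(truth_subject, config, limb = "dominant", seed = 1L) {
  set.seed(as.integer(seed))
  spec <- config$spec
  n <- round(truth_subject$total_s * spec$imu_rate) + 1L
  time <- (seq_len(n) - 1L) / spec$imu_rate
  ang <- .imu_angles(truth_subject, limb, config, time)
  if (config$angle_noise_deg > 0)
    ang <- ang + matrix(stats::rnorm(n * 3L, sd = config$angle_noise_deg), n, 3L)
  if (any(abs(ang[, "pitch"]) >= 90))
    stop("synth_imu: pitch reached 90 degrees (gimbal lock); reduce lobe amplitudes",
         call. = FALSE)
  raw_imu(limb, time, euler_to_quat(ang), rate = spec$imu_rate)
}

#' Generate a full synthetic cohort dataset
#'
#' Draws the protocol ground truth and synthesizes EMG and IMU recordings
#' for both limbs of every subject, with per-trial phase annotations on the
#' video frame grid. Fully deterministic given `seed`.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed for all randomness.
#' @return Object of class `adl_dataset`: list with elements `task`,
#'   `spec`, `config`, `truth`, and `subjects` (each subject holding
#'   `annotations` and per-limb `emg`/`imu` recordings).
#' @examples
#' ds <- simulate_adl_dataset(synth_config(n_subjects = 2, n_trials = 2), seed = 7)
#' names(ds$subjects[[1]]$limbs)
#' @export
simulate_adl_dataset <- function(config = synth_config(), seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  truth <- sample_protocol(config, seed = seed)
  set.seed(as.integer(seed) + 1L)
  sub_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 config$n_subjects * 2L),
                      ncol = 2L)
  subjects <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    ts <- truth$subjects[[i]]
    ann <- lapply(ts$trials, function(tr) {
      fr <- if (isTRUE(config$snap_to_frames))
        as.integer(round(tr$boundaries * config$spec$video_fps)) else NULL
      phase_annotation(sprintf("%s_T%d", ts$subject_id, tr$trial),
                       tr$boundaries, frames = fr,
                       fps = if (is.null(fr)) NULL else config$spec$video_fps)
    })
    limbs <- list(
      dominant = list(
        emg = synth_emg(ts, config, "dominant", seed = sub_seeds[i, 1L]),
        imu = synth_imu(ts, config, "dominant", seed = sub_seeds[i, 1L] + 1L)),
      non_dominant = list(
        emg = synth_emg(ts, config, "non_dominant", seed = sub_seeds[i, 2L]),
        imu = synth_imu(ts, config, "non_dominant", seed = sub_seeds[i, 2L] + 1L)))
    subjects[[i]] <- list(subject_id = ts$subject_id,
                          annotations = ann, limbs = limbs)
  }
  structure(list(task = config$task, spec = config$spec, config = config,
                 seed = as.integer(seed), truth = truth,
                 subjects = subjects),
            class = "adl_dataset")
}

#' @export
print.adl_dataset <- function(x, ...) {
  cat(sprintf("Synthetic ADL dataset: %s task, %d subject(s), %d trial(s) each\n",
              x$task, length(x$subjects),
              length(x$subjects[[1L]]$annotations)))
  invisible(x)
}

# ---- dataset serialization ---------------------------------------------

.truth_to_json <- function(truth_subject) {
  jsonlite::toJSON(truth_subject, auto_unbox = TRUE, digits = NA)
}

#' Write a synthetic dataset to a device-dialect file tree
#'
#' Emits, per subject, EMG and IMU CSVs for both limbs, the annotation CSV,
#' and a ground-truth JSON sidecar; a `manifest.json` at the root lists all
#' files with MD5 checksums. Refuses to write into an existing non-empty
#' directory unless `overwrite = TRUE`.
#'
#' @param dataset An `adl_dataset`.
#' @param dir Output directory.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_adl_dataset <- function(dataset, dir, overwrite = FALSE) {
  stopifnot(inherits(dataset, "adl_dataset"))
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite)
    stop("write_adl_dataset: '", dir,
         "' exists and is not empty (use overwrite = TRUE)", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (i in seq_along(dataset$subjects)) {
    sub <- dataset$subjects[[i]]
    sdir <- file.path(dir, sub$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    for (limb in names(sub$limbs)) {
      fe <- file.path(sdir, paste0("emg_", limb, ".csv"))
      fi <- file.path(sdir, paste0("imu_", limb, ".csv"))
      write_emg_csv(sub$limbs[[limb]]$emg, fe)
      write_imu_csv(sub$limbs[[limb]]$imu, fi)
      files <- c(files, fe, fi)
    }
    fa <- file.path(sdir, "annotations.csv")
    write_annotations(sub$annotations, fa, fps = dataset$spec$video_fps)
    ft <- file.path(sdir, "truth.json")
    writeLines(.truth_to_json(dataset$truth$subjects[[i]]), ft)
    files <- c(files, fa, ft)
  }
  rel <- sub(paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", dir), "/?"),
             "", files)
  manifest <- list(task = dataset$task, seed = dataset$seed,
                   n_subjects = length(dataset$subjects),
                   video_fps = dataset$spec$video_fps,
                   files = data.frame(path = rel,
                                      md5 = unname(tools::md5sum(files)),
                                      stringsAsFactors = FALSE))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Read a dataset written by [write_adl_dataset()]
#'
#' Validates the manifest checksums and loads every subject's recordings,
#' annotations, and ground-truth sidecars.
#'
#' @param dir Dataset directory containing `manifest.json`.
#' @param check_manifest Verify MD5 checksums (default `TRUE`).
#' @return An `adl_dataset` (without the generator `config`).
#' @export
read_adl_dataset <- function(dir, check_manifest = TRUE) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf))
    stop("read_adl_dataset: no manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::fromJSON(mf)
  if (check_manifest) {
    paths <- file.path(dir, manifest$files$path)
    sums <- unname(tools::md5sum(paths))
    bad <- which(sums != manifest$files$md5)
    if (length(bad))
      stop("read_adl_dataset: checksum mismatch for ",
           manifest$files$path[bad[1L]], call. = FALSE)
  }
  sdirs <- sort(list.dirs(dir, recursive = FALSE))
  subjects <- vector("list", length(sdirs))
  truth_subjects <- vector("list", length(sdirs))
  for (i in seq_along(sdirs)) {
    sdir <- sdirs[i]
    ann <- read_annotations(file.path(sdir, "annotations.csv"))
    limbs <- list()
    for (limb in c("dominant", "non_dominant")) {
      limbs[[limb]] <- list(
        emg = read_emg_csv(file.path(sdir, paste0("emg_", limb, ".csv"))),
        imu = read_imu_csv(file.path(sdir, paste0("imu_", limb, ".csv"))))
    }
    tf <- file.path(sdir, "truth.json")
    truth_subjects[[i]] <- if (file.exists(tf))
      jsonlite::fromJSON(tf, simplifyDataFrame = FALSE) else NULL
    subjects[[i]] <- list(subject_id = basename(sdir),
                          annotations = ann, limbs = limbs)
  }
  structure(list(task = manifest$task, spec = acq_spec(),
                 seed = manifest$seed,
                 truth = structure(list(task = manifest$task,
                                        subjects = truth_subjects),
                                   class = "synth_truth"),
                 subjects = subjects),
            class = "adl_dataset")
}
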