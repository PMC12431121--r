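#' Acquisition specification for the wearable device
#'
#' Bundles the fixed acquisition and processing constants of the two-sensor
#' wearable: EMG sampled at 1000 Hz through a 12-bit ADC spanning 1.6 V,
#' orientation quaternions at 100 Hz, phase annotations from 30 fps video,
#' 1 s moving-average smoothing windows on both branches, and the common
#' 9000-sample normalized-cycle axis.
#'
#' @param emg_rate EMG sampling frequency in Hz.
#' @param imu_rate IMU sampling frequency in Hz.
#' @param video_fps Video frame rate used for phase annotation, frames/s.
#' @param adc_bits ADC resolution in bits.
#' @param adc_range ADC full-scale range in volts.
#' @param emg_window EMG smoothing window length in samples
#'   (1000 samples = 1 s at the default rate).
#' @param imu_window IMU smoothing window length in samples
#'   (100 samples = 1 s at the default rate).
#' @param n_resample Number of samples of the normalized 0--100 % cycle axis.
#'
#' @return An object of class `acq_spec`.
#' @examples
#' spec <- acq_spec()
#' spec$emg_window / spec$emg_rate # 1 second
#' @export
acq_spec <- function(emg_rate = 1000, imu_rate = 100, video_fps = 30,
                     adc_bits = 12, adc_range = 1.6,
                     emg_window = 1000, imu_window = 100,
                     n_resample = 9000) {
  vals <- list(emg_rate = emg_rate, imu_rate = imu_rate,
               video_fps = video_fps, adc_bits = adc_bits,
               adc_range = adc_range, emg_window = emg_window,
               imu_window = imu_window, n_resample = n_resample)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("acq_spec: '", nm, "' must be a single positive number", call. = FALSE)
  }
  vals$adc_bits <- as.integer(vals$adc_bits)
  structure(vals, class = "acq_spec")
}

#' @export
print.acq_spec <- function(x, ...) {
  cat("Acquisition spec:\n")
  cat(sprintf("  EMG  %g Hz, %d-bit ADC over %g V, smoothing window %d samples\n",
              x$emg_rate, x$adc_bits, x$adc_range, x$emg_window))
  cat(sprintf("  IMU  %g Hz, smoothing window %d samples\n",
              x$imu_rate, x$imu_window))
  cat(sprintf("  Video %g fps; normalized cycle %d samples\n",
              x$video_fps, x$n_resample))
  invisible(x)
}

#' Shoulder muscles and motions covered by the device
#'
#' `muscles()` returns the six shoulder muscles recorded by the EMG branch,
#' in channel order; `motions()` the six anatomical motion labels of the
#' kinematic branch. Flexion/Extension share the yaw axis,
#' Abduction/Adduction the roll axis and Medial/Lateral Rotation the pitch
#' axis, with limb-specific signs (see [motion_axis_map()]).
#'
#' @return A character vector of codes.
#' @export
muscles <- function() c("PM", "AD", "MD", "PD", "UT", "LT")

#' @rdname muscles
#' @export
motions <- function() c("F", "E", "MR", "LR", "ABD", "ADD")

#' Labels of the seven task phases
#'
#' The drinking and eating cycles are divided into seven contiguous phases:
#' reach, grasp, transport to the mouth, in-mouth, return to the table,
#' return to the start position, and rest.
#'
#' @return Character vector of length 7, ordered phase 1 to 7.
#' @export
phase_labels <- function() {
  c("start-to-reach", "grasp", "transport-to-mouth", "in-mouth",
    "return-to-table", "return-to-start", "rest")
}

#' Normalized cycle axis
#'
#' @param n Number of samples.
#' @return `n` uniformly spaced positions from 0 to 100 (% of cycle).
#' @export
cycle_axis <- function(n) seq(0, 100, length.out = n)
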