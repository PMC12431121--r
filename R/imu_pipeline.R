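# Orientation convention: intrinsic Z-Y-X (aerospace yaw-pitch-roll),
# R = Rz(yaw) %*% Ry(pitch) %*% Rx(roll), quaternions as (w, x, y, z).

#' Convert unit quaternions to yaw/pitch/roll Euler angles
#'
#' Decomposes each orientation under the intrinsic Z-Y-X convention and
#' returns degrees. Near gimbal lock (`|pitch| -> 90` degrees, where yaw and
#' roll are not separable) the residual rotation is assigned to yaw, roll is
#' set to 0, and the sample is flagged in the `gimbal` attribute.
#'
#' @param q Numeric matrix with columns `(w, x, y, z)` (or a length-4
#'   vector). Norms must be within `1e-6` of 1; rows are renormalized.
#' @return Matrix with columns `yaw`, `pitch`, `roll` in degrees; attribute
#'   `gimbal` is a logical vector flagging locked samples.
#' @examples
#' quat_to_euler(c(sqrt(2)/2, 0, 0, sqrt(2)/2)) # yaw 90, pitch 0, roll 0
#' @export
quat_to_euler <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1L)
  q <- as.matrix(q)
  if (ncol(q) != 4L) stop("quat_to_euler: expected 4 columns (w, x, y, z)",
                          call. = FALSE)
  nrm <- sqrt(rowSums(q^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("quat_to_euler: non-unit quaternion (|q| off by more than 1e-6)",
         call. = FALSE)
  q <- q / nrm
  w <- q[, 1L]; x <- q[, 2L]; y <- q[, 3L]; z <- q[, 4L]
  sinp <- 2 * (w * y - z * x)
  lock <- abs(sinp) >= 1 - 1e-9
  yaw <- atan2(2 * (x * y + w * z), 1 - 2 * (y^2 + z^2))
  pitch <- asin(pmin(pmax(sinp, -1), 1))
  roll <- atan2(2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
  if (any(lock)) {
    # at the poles only yaw -/+ roll is defined; put it all in yaw
    yaw[lock] <- atan2(2 * (w[lock] * z[lock] - x[lock] * y[lock]),
                       1 - 2 * (x[lock]^2 + z[lock]^2))
    pitch[lock] <- sign(sinp[lock]) * pi / 2
    roll[lock] <- 0
  }
  out <- cbind(yaw = yaw, pitch = pitch, roll = roll) * 180 / pi
  attr(out, "gimbal") <- lock
  out
}

#' Convert yaw/pitch/roll Euler angles to unit quaternions
#'
#' Inverse of [quat_to_euler()] under the same intrinsic Z-Y-X convention.
#'
#' @param euler Matrix with columns `yaw`, `pitch`, `roll` in degrees (or a
#'   length-3 vector).
#' @return Matrix with columns `(w, x, y, z)`.
#' @export
euler_to_quat <- function(euler) {
  if (is.null(dim(euler))) euler <- matrix(euler, nrow = 1L)
  e <- as.matrix(euler) * pi / 360 # half angles in radians
  cy <- cos(e[, 1L]); sy <- sin(e[, 1L])
  cp <- cos(e[, 2L]); sp <- sin(e[, 2L])
  cr <- cos(e[, 3L]); sr <- sin(e[, 3L])
  cbind(w = cr * cp * cy + sr * sp * sy,
        x = sr * cp * cy - cr * sp * sy,
        y = cr * sp * cy + sr * cp * sy,
        z = cr * cp * sy - sr * sp * cy)
}

#' Motion-to-Euler-axis sign map for a limb
#'
#' Each anatomical motion corresponds to a fixed direction on one Euler
#' axis, mirrored between limbs for the mediolateral axes: Extension is
#' +yaw and Flexion -yaw on both limbs; on the dominant limb Abduction is
#' +roll and Lateral Rotation +pitch, while on the non-dominant limb the
#' roll and pitch signs are reversed (Adduction +roll, Medial Rotation
#' +pitch).
#'
#' @param limb `"dominant"` or `"non_dominant"`.
#' @return Data frame with columns `motion`, `axis`, `sign`.
#' @export
motion_axis_map <- function(limb = c("dominant", "non_dominant")) {
  limb <- match.arg(limb)
  mirror <- if (limb == "dominant") 1 else -1
  data.frame(motion = c("F", "E", "MR", "LR", "ABD", "ADD"),
             axis = c("yaw", "yaw", "pitch", "pitch", "roll", "roll"),
             sign = c(-1, 1, -mirror, mirror, mirror, -mirror),
             stringsAsFactors = FALSE)
}

#' Map Euler angles to anatomically signed axes
#'
#' Re-signs the Euler axes so that, for either limb, positive values mean
#' Extension (`fe` axis), Abduction (`abad` axis) and Lateral Rotation
#' (`rot` axis); the paired motions (F, ADD, MR) are negative on the same
#' axes.
#'
#' @param euler Matrix with columns `yaw`, `pitch`, `roll` in degrees.
#' @param limb `"dominant"` or `"non_dominant"`.
#' @return Matrix with columns `fe`, `abad`, `rot`, degrees.
#' @examples
#' euler_to_anatomical(cbind(yaw = 0, pitch = 0, roll = 5), "dominant")
#' # abad +5: abduction. On the non-dominant limb the same roll is adduction.
#' @export
euler_to_anatomical <- function(euler, limb = c("dominant", "non_dominant")) {
  limb <- match.arg(limb)
  if (is.null(dim(euler))) euler <- matrix(euler, nrow = 1L,
                                           dimnames = list(NULL, c("yaw", "pitch", "roll")))
  mirror <- if (limb == "dominant") 1 else -1
  cbind(fe = euler[, "yaw"],
        abad = mirror * euler[, "roll"],
        rot = mirror * euler[, "pitch"])
}

#' Smooth Euler angle series
#'
#' Unwraps the yaw and roll series (which live on a +/-180 degree circle)
#' and applies the spec's IMU moving-average window (100 samples = 1 s at
#' 100 Hz). Pitch is confined to [-90, 90] and needs no unwrapping.
#'
#' @param euler Matrix with columns `yaw`, `pitch`, `roll`, degrees.
#' @param spec An [acq_spec()].
#' @return Smoothed matrix, same shape.
#' @export
smooth_angles <- function(euler, spec = acq_spec()) {
  e <- as.matrix(euler)
  e[, "yaw"] <- unwrap_degrees(e[, "yaw"])
  e[, "roll"] <- unwrap_degrees(e[, "roll"])
  moving_average(e, spec$imu_window)
}

#' Per-cycle zero-aligned angle trajectories
#'
#' Segments an angle series by the phase annotations, subtracts each
#' cycle's first sample from every channel (zero-alignment, so all cycles
#' start at 0 degrees), and resamples to the normalized-cycle length.
#'
#' @param time Sample times of the recording, seconds.
#' @param angles Matrix of (smoothed) angles, one row per sample.
#' @param annotations List of [phase_annotation()] objects.
#' @param spec An [acq_spec()].
#' @return List of `n_resample`-row matrices, one per cycle.
#' @export
angle_cycles <- function(time, angles, annotations, spec = acq_spec()) {
  segs <- extract_cycles(time, angles, annotations)
  lapply(segs, function(seg) {
    v <- sweep(seg$values, 2L, seg$values[1L, ])
    r <- vapply(seq_len(ncol(v)),
                function(j) resample_cycle(v[, j], spec$n_resample, seg$time),
                numeric(spec$n_resample))
    colnames(r) <- colnames(seg$values)
    r
  })
}

#' Per-motion joint-excursion peak summary
#'
#' For each of the six anatomical motions, finds the extremum of the
#' zero-aligned group trajectory in that motion's direction on its Euler
#' axis and reports the axis value at that point (so the sign follows the
#' limb's Euler convention, as in the device's reports), its
#' normalized-cycle time (first occurrence on ties), and the phase
#' containing it.
#'
#' @param cycle Matrix with columns `yaw`, `pitch`, `roll`: the zero-aligned
#'   group mean trajectory, degrees.
#' @param schedule A `phase_schedule`.
#' @param limb `"dominant"` or `"non_dominant"` (selects the sign map).
#' @return Data frame with columns `motion`, `peak_time`, `peak_value`,
#'   `phase_at_peak`.
#' @export
angle_peak_summary <- function(cycle, schedule,
                               limb = c("dominant", "non_dominant")) {
  limb <- match.arg(limb)
  cycle <- as.matrix(cycle)
  axis <- cycle_axis(nrow(cycle))
  map <- motion_axis_map(limb)
  rows <- lapply(seq_len(nrow(map)), function(k) {
    v <- cycle[, map$axis[k]]
    i <- which.max(map$sign[k] * v)
    data.frame(motion = map$motion[k], peak_time = axis[i],
               peak_value = v[i],
               phase_at_peak = locate_phase(axis[i], schedule))
  })
  do.call(rbind, rows)
}
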