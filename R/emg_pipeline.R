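#' Convert ADC counts to millivolts
#'
#' `mV = (count - offset) * (1000 * adc_range) / (2^adc_bits - 1)`. The
#' default offset is mid-scale (2048 for 12 bits), the zero-volt code of a
#' bipolar analog front end.
#'
#' @param counts Numeric vector or matrix of ADC counts.
#' @param spec An [acq_spec()].
#' @param offset ADC count representing 0 V.
#' @return Signal in mV, same shape as `counts`.
#' @examples
#' bits_to_mv(2048) # 0
#' bits_to_mv(4095, offset = 0) # 1600 (full scale = 1.6 V)
#' @export
bits_to_mv <- function(counts, spec = acq_spec(),
                       offset = 2^(spec$adc_bits - 1)) {
  (counts - offset) * (1000 * spec$adc_range) / (2^spec$adc_bits - 1)
}

#' Full-wave rectification with DC removal
#'
#' Subtracts the per-channel mean (removes the front-end DC offset) and
#' takes the absolute value, yielding a non-negative signal whose local mean
#' tracks muscle-activation intensity. For zero-mean Gaussian interference
#' of standard deviation sigma the expected rectified value is
#' `sigma * sqrt(2/pi)` (half-normal mean).
#'
#' @param x Signal in mV; vector or matrix (channels in columns).
#' @return Rectified signal, same shape.
#' @export
rectify_emg <- function(x) {
  if (is.matrix(x)) {
    return(abs(sweep(x, 2L, colMeans(x))))
  }
  abs(x - mean(x))
}

#' EMG activation envelope
#'
#' Moving-average smoothing of the rectified signal with the spec's EMG
#' window (1000 samples = 1 s at 1000 Hz).
#'
#' @param x Rectified signal in mV; vector or matrix.
#' @param spec An [acq_spec()].
#' @return Envelope, same shape as `x`.
#' @export
emg_envelope <- function(x, spec = acq_spec()) {
  moving_average(x, spec$emg_window)
}

#' Cut a recording into per-cycle segments
#'
#' Extracts one segment per annotation, spanning the start of phase 1 to the
#' end of phase 7; samples between annotations (the inter-trial rests) are
#' discarded and each segment's clock restarts at zero.
#'
#' @param time Sample times of the recording, seconds.
#' @param x Signal values; vector or matrix with one row per sample.
#' @param annotations List of [phase_annotation()] objects, non-overlapping
#'   and inside the recording span.
#' @return List of segments, each a list with elements `time` (starting at
#'   0), `values` (matrix), and `boundaries` (phase boundaries re-zeroed).
#' @export
extract_cycles <- function(time, x, annotations) {
  if (inherits(annotations, "phase_annotation"))
    annotations <- list(annotations)
  if (!length(annotations))
    stop("extract_cycles: no annotations", call. = FALSE)
  x <- as.matrix(x)
  starts <- vapply(annotations, function(a) a$boundaries[1L], 0)
  ends <- vapply(annotations, function(a) a$boundaries[8L], 0)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]; annotations <- annotations[o]
  if (any(starts[-1L] < ends[-length(ends)]))
    stop("extract_cycles: annotations overlap", call. = FALSE)
  if (starts[1L] < time[1L] - 1e-9 || ends[length(ends)] > time[length(time)] + 1e-9)
    stop("extract_cycles: annotation outside recording span", call. = FALSE)
  lapply(annotations, function(a) {
    b <- a$boundaries
    idx <- which(time >= b[1L] - 1e-9 & time <= b[8L] + 1e-9)
    if (length(idx) < 2L)
      stop("extract_cycles: annotation spans fewer than 2 samples",
           call. = FALSE)
    list(time = time[idx] - time[idx[1L]],
         values = x[idx, , drop = FALSE],
         boundaries = b - b[1L])
  })
}

#' Subject-mean normalized cycle
#'
#' Resamples each segment to the normalized-cycle length by linear
#' interpolation and averages the segments pointwise, giving one mean cycle
#' per channel for the subject.
#'
#' @param segments List of segments from [extract_cycles()].
#' @param spec An [acq_spec()] (`n_resample` sets the output length).
#' @return Numeric matrix, `n_resample` rows by one column per channel.
#' @export
subject_mean_cycle <- function(segments, spec = acq_spec()) {
  if (!length(segments)) stop("subject_mean_cycle: no segments", call. = FALSE)
  n <- spec$n_resample
  acc <- NULL
  for (seg in segments) {
    v <- as.matrix(seg$values)
    r <- vapply(seq_len(ncol(v)),
                function(j) resample_cycle(v[, j], n, seg$time),
                numeric(n))
    acc <- if (is.null(acc)) r else acc + r
  }
  out <- acc / length(segments)
  colnames(out) <- colnames(as.matrix(segments[[1L]]$values))
  out
}

#' Min-max normalization to the unit interval
#'
#' `(x - min) / (max - min)` per channel; a flat channel (max == min) maps
#' to all zeros by convention.
#'
#' @param x Numeric vector or matrix (channels in columns).
#' @return Normalized values in `[0, 1]`, same shape.
#' @examples
#' minmax_normalize(c(1, 3, 5)) # 0, 0.5, 1
#' @export
minmax_normalize <- function(x) {
  if (is.matrix(x)) {
    out <- x
    for (j in seq_len(ncol(x))) out[, j] <- minmax_normalize(x[, j])
    return(out)
  }
  rng <- range(x)
  if (rng[2L] - rng[1L] <= 0) return(rep(0, length(x)))
  (x - rng[1L]) / (rng[2L] - rng[1L])
}

#' Pointwise mean cycle across subjects
#'
#' @param cycles List of equally sized numeric matrices (one per subject).
#' @return Matrix of pointwise means with attribute `n_contributing`.
#' @export
group_mean_cycle <- function(cycles) {
  if (!length(cycles)) stop("group_mean_cycle: no cycles", call. = FALSE)
  dims <- vapply(cycles, function(m) paste(dim(as.matrix(m)), collapse = "x"), "")
  if (length(unique(dims)) != 1L)
    stop("group_mean_cycle: cycles differ in shape", call. = FALSE)
  out <- Reduce(`+`, lapply(cycles, as.matrix)) / length(cycles)
  attr(out, "n_contributing") <- length(cycles)
  out
}

#' Per-muscle activation-peak summary
#'
#' For each muscle channel of a group mean envelope, reports the envelope
#' maximum (mV), the normalized-cycle time at which it occurs (first
#' occurrence on ties), and the task phase containing that time.
#'
#' @param cycle Matrix of group mean envelopes in mV (`n` rows, one column
#'   per muscle).
#' @param schedule A `phase_schedule` used to attribute the peak to a phase.
#' @return Data frame with columns `muscle`, `peak_time`, `peak_value`,
#'   `phase_at_peak`.
#' @export
emg_peak_summary <- function(cycle, schedule) {
  cycle <- as.matrix(cycle)
  axis <- cycle_axis(nrow(cycle))
  nm <- colnames(cycle)
  if (is.null(nm)) nm <- paste0("ch", seq_len(ncol(cycle)))
  rows <- lapply(seq_len(ncol(cycle)), function(j) {
    i <- which.max(cycle[, j]) # earliest index on exact ties
    data.frame(muscle = nm[j], peak_time = axis[i],
               peak_value = cycle[i, j],
               phase_at_peak = locate_phase(axis[i], schedule))
  })
  do.call(rbind, rows)
}
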