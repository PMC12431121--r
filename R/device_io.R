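# Device file dialect: comma-separated, dot decimal, UTF-8, one "#"-prefixed
# metadata line followed by one header line. EMG files carry integer ADC
# counts; IMU files carry unit quaternions written with 9 decimals.

.parse_meta <- function(line) {
  line <- sub("^#\\s*", "", line)
  parts <- strsplit(trimws(line), "\\s+")[[1L]]
  kv <- strsplit(parts, "=")
  vals <- vapply(kv, `[`, "", 2L)
  names(vals) <- vapply(kv, `[`, "", 1L)
  vals
}

#' Raw EMG recording for one limb
#'
#' @param limb `"dominant"` or `"non_dominant"`.
#' @param time Sample times, seconds, non-decreasing.
#' @param counts Integer matrix of ADC counts, one column per muscle in
#'   [muscles()] order, values in `[0, 2^adc_bits - 1]`.
#' @param rate Nominal sampling rate, Hz.
#' @return Object of class `raw_emg`.
#' @export
raw_emg <- function(limb, time, counts, rate = 1000) {
  limb <- match.arg(limb, c("dominant", "non_dominant"))
  counts <- as.matrix(counts)
  if (ncol(counts) != 6L) stop("raw_emg: expected 6 muscle channels",
                               call. = FALSE)
  if (nrow(counts) != length(time))
    stop("raw_emg: time and channels have different lengths", call. = FALSE)
  if (any(diff(time) < 0))
    stop("raw_emg: time must be non-decreasing", call. = FALSE)
  storage.mode(counts) <- "integer"
  colnames(counts) <- muscles()
  structure(list(limb = limb, time = as.numeric(time),
                 counts = counts, rate = rate),
            class = "raw_emg")
}

#' Raw IMU recording for one limb
#'
#' Quaternions are renormalized to unit length at construction; rows with
#' (near-)zero norm are rejected.
#'
#' @param limb `"dominant"` or `"non_dominant"`.
#' @param time Sample times, seconds, non-decreasing.
#' @param quat Numeric matrix with columns `w, x, y, z`.
#' @param rate Nominal sampling rate, Hz.
#' @return Object of class `raw_imu`.
#' @export
raw_imu <- function(limb, time, quat, rate = 100) {
  limb <- match.arg(limb, c("dominant", "non_dominant"))
  quat <- as.matrix(quat)
  if (ncol(quat) != 4L) stop("raw_imu: expected 4 quaternion columns",
                             call. = FALSE)
  if (nrow(quat) != length(time))
    stop("raw_imu: time and quaternions have different lengths", call. = FALSE)
  if (any(diff(time) < 0))
    stop("raw_imu: time must be non-decreasing", call. = FALSE)
  nrm <- sqrt(rowSums(quat^2))
  bad <- which(nrm < 1e-8)
  if (length(bad))
    stop("raw_imu: zero-norm quaternion at row ", bad[1L], call. = FALSE)
  quat <- quat / nrm
  colnames(quat) <- c("w", "x", "y", "z")
  structure(list(limb = limb, time = as.numeric(time),
                 quat = quat, rate = rate),
            class = "raw_imu")
}

#' Read and write device EMG CSV files
#'
#' The file starts with a metadata line `# limb=<limb> rate_hz=<rate>`,
#' followed by a header `time_s,PM,AD,MD,PD,UT,LT`. Counts outside the ADC
#' range are clipped on read (ADCs saturate rather than fail) and the number
#' of clipped cells is reported as a warning and stored in the `clipped`
#' attribute.
#'
#' @param path File path.
#' @param spec An [acq_spec()] (sets the ADC range used for clipping).
#' @return `read_emg_csv` returns a [raw_emg()]; `write_emg_csv` returns
#'   `path` invisibly.
#' @export
read_emg_csv <- function(path, spec = acq_spec()) {
  if (!file.exists(path)) stop("read_emg_csv: no such file: ", path,
                               call. = FALSE)
  meta <- .parse_meta(readLines(path, n = 1L))
  if (!all(c("limb", "rate_hz") %in% names(meta)))
    stop("read_emg_csv: missing limb/rate_hz metadata line", call. = FALSE)
  dt <- data.table::fread(path, skip = 1L, header = TRUE)
  need <- c("time_s", muscles())
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("read_emg_csv: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cols <- dt[, muscles(), with = FALSE]
  for (m in muscles()) {
    col <- cols[[m]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      if (anyNA(num))
        stop("read_emg_csv: non-numeric count in column ", m,
             " at data row ", which(is.na(num))[1L], call. = FALSE)
      cols[[m]] <- num
    } else if (anyNA(col)) {
      stop("read_emg_csv: missing count in column ", m,
           " at data row ", which(is.na(col))[1L], call. = FALSE)
    }
  }
  cnt <- as.matrix(cols)
  hi <- 2^spec$adc_bits - 1
  nclip <- sum(cnt < 0 | cnt > hi)
  if (nclip > 0) {
    warning("read_emg_csv: clipped ", nclip, " out-of-range count(s)",
            call. = FALSE)
    cnt[cnt < 0] <- 0
    cnt[cnt > hi] <- hi
  }
  out <- raw_emg(meta[["limb"]], dt$time_s, cnt,
                 rate = as.numeric(meta[["rate_hz"]]))
  attr(out, "clipped") <- nclip
  out
}

#' @rdname read_emg_csv
#' @param emg A [raw_emg()] object.
#' @export
write_emg_csv <- function(emg, path) {
  stopifnot(inherits(emg, "raw_emg"))
  writeLines(sprintf("# limb=%s rate_hz=%g", emg$limb, emg$rate), path)
  dt <- data.table::data.table(time_s = round(emg$time, 6))
  for (m in muscles()) dt[[m]] <- as.integer(emg$counts[, m])
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read and write device IMU CSV files
#'
#' The file starts with `# limb=<limb> rate_hz=<rate>` followed by a header
#' `time_s,qw,qx,qy,qz`. Quaternions are written with 9 decimals and
#' renormalized to unit length on read; a zero-norm row is an error naming
#' the row.
#'
#' @param path File path.
#' @return `read_imu_csv` returns a [raw_imu()]; `write_imu_csv` returns
#'   `path` invisibly.
#' @export
read_imu_csv <- function(path) {
  if (!file.exists(path)) stop("read_imu_csv: no such file: ", path,
                               call. = FALSE)
  meta <- .parse_meta(readLines(path, n = 1L))
  dt <- data.table::fread(path, skip = 1L, header = TRUE)
  need <- c("time_s", "qw", "qx", "qy", "qz")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("read_imu_csv: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  q <- as.matrix(dt[, c("qw", "qx", "qy", "qz"), with = FALSE])
  raw_imu(meta[["limb"]], dt$time_s, q, rate = as.numeric(meta[["rate_hz"]]))
}

#' @rdname read_imu_csv
#' @param imu A [raw_imu()] object.
#' @export
write_imu_csv <- function(imu, path) {
  stopifnot(inherits(imu, "raw_imu"))
  writeLines(sprintf("# limb=%s rate_hz=%g", imu$limb, imu$rate), path)
  dt <- data.table::data.table(time_s = round(imu$time, 6),
                               qw = round(imu$quat[, 1L], 9),
                               qx = round(imu$quat[, 2L], 9),
                               qy = round(imu$quat[, 3L], 9),
                               qz = round(imu$quat[, 4L], 9))
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read and write phase-annotation CSV files
#'
#' One row per trial and phase with columns `trial_id`, `phase_index`, and
#' either `start_frame`/`end_frame` (converted to seconds via the fps stored
#' in the `# fps=<fps>` metadata line) or `start_s`/`end_s`. Phases must be
#' complete (1--7) and contiguous: the end of each phase must equal the
#' start of the next.
#'
#' @param path File path.
#' @return `read_annotations` returns a list of [phase_annotation()]
#'   objects, one per trial.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("read_annotations: no such file: ", path,
                               call. = FALSE)
  meta <- .parse_meta(readLines(path, n = 1L))
  fps <- as.numeric(meta[["fps"]])
  dt <- data.table::fread(path, skip = 1L, header = TRUE)
  frame_dialect <- all(c("start_frame", "end_frame") %in% names(dt))
  if (!frame_dialect && !all(c("start_s", "end_s") %in% names(dt)))
    stop("read_annotations: need start_frame/end_frame or start_s/end_s",
         call. = FALSE)
  out <- list()
  for (id in unique(dt$trial_id)) {
    rows <- dt[dt$trial_id == id, ]
    rows <- rows[order(rows$phase_index), ]
    if (!identical(as.integer(rows$phase_index), 1:7))
      stop("read_annotations: trial ", id, " does not have phases 1..7",
           call. = FALSE)
    if (frame_dialect) {
      s <- rows$start_frame / fps
      e <- rows$end_frame / fps
      fr <- c(rows$start_frame, rows$end_frame[7L])
    } else {
      s <- rows$start_s
      e <- rows$end_s
      fr <- NULL
    }
    gaps <- abs(s[-1L] - e[-7L])
    if (any(gaps > 1e-9))
      stop("read_annotations: trial ", id, ": phase ",
           which(gaps > 1e-9)[1L], " does not end where phase ",
           which(gaps > 1e-9)[1L] + 1L, " starts", call. = FALSE)
    out[[length(out) + 1L]] <- phase_annotation(
      id, c(s, e[7L]), frames = fr, fps = if (frame_dialect) fps else NULL)
  }
  out
}

#' @rdname read_annotations
#' @param annotations List of [phase_annotation()] objects.
#' @param fps Frame rate written to the metadata line. Annotations carrying
#'   frame indices are written in the frame dialect; otherwise in seconds.
#' @export
write_annotations <- function(annotations, path, fps = 30) {
  if (inherits(annotations, "phase_annotation"))
    annotations <- list(annotations)
  rows <- lapply(annotations, function(a) {
    b <- a$boundaries
    if (!is.null(a$frames)) {
      data.table::data.table(trial_id = a$trial_id, phase_index = 1:7,
                             start_frame = a$frames[1:7],
                             end_frame = a$frames[2:8])
    } else {
      data.table::data.table(trial_id = a$trial_id, phase_index = 1:7,
                             start_s = round(b[1:7], 6),
                             end_s = round(b[2:8], 6))
    }
  })
  writeLines(sprintf("# fps=%g", fps), path)
  data.table::fwrite(data.table::rbindlist(rows), path, append = TRUE,
                     col.names = TRUE)
  invisible(path)
}
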