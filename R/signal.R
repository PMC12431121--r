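#' Centered moving average with shrinking edge windows
#'
#' Smooths a signal with a centered moving-average window of `window`
#' samples. Near the edges the window shrinks to the available samples, so
#' no padding values are invented and the output has the same length as the
#' input. For an even window the extra sample is taken on the earlier side
#' (the window at index i spans `[i - floor(window/2), i + ceiling(window/2) - 1]`,
#' clipped to the signal).
#'
#' @param x Numeric vector (or matrix; columns smoothed independently).
#' @param window Window length in samples, >= 1.
#' @return Smoothed signal, same shape as `x`.
#' @examples
#' moving_average(rep(2, 10), 4)          # constants are invariant
#' max(moving_average(c(rep(0, 2499), 1, rep(0, 2500)), 1000)) # 1/1000
#' @export
moving_average <- function(x, window) {
  if (!is.numeric(window) || length(window) != 1L || !is.finite(window) ||
      window < 1)
    stop("moving_average: 'window' must be a single number >= 1", call. = FALSE)
  window <- as.integer(window)
  if (is.matrix(x)) {
    out <- x
    for (j in seq_len(ncol(x))) out[, j] <- moving_average(x[, j], window)
    return(out)
  }
  n <- length(x)
  if (n == 0L) stop("moving_average: empty signal", call. = FALSE)
  left <- window %/% 2L
  right <- window - left - 1L
  idx <- seq_len(n)
  lo <- pmax(idx - left, 1L)
  hi <- pmin(idx + right, n)
  cs <- c(0, cumsum(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Resample a cycle onto a uniform grid by linear interpolation
#'
#' Linearly interpolates a signal onto `n` uniformly spaced points spanning
#' the full time range of the input, preserving the endpoints exactly. This
#' is the time-normalization step that puts every movement cycle on the
#' common 9000-sample 0--100 % axis.
#'
#' @param x Numeric values of the signal.
#' @param n Target length.
#' @param time Optional strictly increasing time grid of `x`; defaults to a
#'   uniform grid, in which case the operation only changes the sample count.
#' @return Numeric vector of length `n`.
#' @examples
#' resample_cycle(c(0, 10), 5) # 0, 2.5, 5, 7.5, 10
#' @export
resample_cycle <- function(x, n, time = NULL) {
  m <- length(x)
  if (m < 2L) stop("resample_cycle: need at least 2 samples", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n < 2L)
    stop("resample_cycle: 'n' must be a single number >= 2", call. = FALSE)
  n <- as.integer(n)
  if (is.null(time)) time <- seq_len(m)
  if (length(time) != m)
    stop("resample_cycle: 'time' and 'x' lengths differ", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("resample_cycle: time grid must be strictly increasing", call. = FALSE)
  if (m == n && isTRUE(all.equal(diff(time), rep(diff(time)[1], m - 1L))))
    return(x)
  grid <- seq(time[1L], time[m], length.out = n)
  y <- stats::approx(time, x, xout = grid, method = "linear", ties = "ordered")$y
  y[1L] <- x[1L]
  y[n] <- x[m]
  y
}

#' Remove +/-180 degree wrap discontinuities from an angle series
#'
#' Successive differences larger than 180 degrees in magnitude are shifted
#' by multiples of 360 degrees so the series varies continuously; needed
#' before smoothing or averaging yaw/roll angles near the branch cut.
#'
#' @param x Angle series in degrees.
#' @return Unwrapped series, same length; first sample unchanged.
#' @export
unwrap_degrees <- function(x) {
  n <- length(x)
  if (n < 2L) return(x)
  d <- diff(x)
  d <- d - 360 * round(d / 360)
  c(x[1L], x[1L] + cumsum(d))
}
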