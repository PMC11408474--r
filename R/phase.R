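#' Centered moving average with shrinking edges
#'
#' Smooths a series with a centered window of odd length. At the boundaries
#' the window shrinks to the available samples rather than padding, so no
#' values are fabricated outside the record.
#'
#' @param x Numeric vector.
#' @param window Odd positive integer window length.
#' @return Numeric vector, same length as `x`.
#' @export
moving_average <- function(x, window) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort("moving_average: input must be finite numeric")
  }
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    abort("moving_average: window must be a positive odd integer")
  }
  n <- length(x)
  k <- (window - 1L) %/% 2L
  # cumulative-sum sliding mean; edges use the truncated window
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - k, 1L)
  hi <- pmin(seq_len(n) + k, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Strict local maxima of a series filtered by topographic prominence and a
# minimum peak-to-peak distance (higher peaks suppress lower ones greedily).
find_peaks <- function(x, min_distance = 1L, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  idx <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] > x[3:n]) + 1L
  if (!length(idx)) return(integer(0))
  # prominence: height above the higher of the two bounding saddle minima,
  # where each side extends to the nearest strictly higher sample (or the end)
  prom <- vapply(idx, function(i) {
    h <- x[i]
    j <- i - 1L
    left_min <- h
    while (j >= 1L && x[j] <= h) {
      if (x[j] < left_min) left_min <- x[j]
      j <- j - 1L
    }
    j <- i + 1L
    right_min <- h
    while (j <= n && x[j] <= h) {
      if (x[j] < right_min) right_min <- x[j]
      j <- j + 1L
    }
    h - max(left_min, right_min)
  }, numeric(1))
  idx <- idx[prom >= min_prominence]
  if (!length(idx)) return(integer(0))
  # enforce min distance, keeping taller peaks first
  ord <- idx[order(x[idx], decreasing = TRUE)]
  keep <- logical(0)
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_distance)) {
      kept <- c(kept, i)
    }
  }
  sort(kept)
}

#' Derive continuous gait-phase labels from a foot-pressure signal
#'
#' The plantar-pressure pulse train is smoothed with a centered moving
#' average; its local maxima mark successive stride boundaries (the initial
#' contact events). Between consecutive marked peaks the phase ramps linearly
#' from 0 at the peak up to (but not including) 100 just before the next peak.
#' Samples before the first peak and after the last peak carry no stride
#' context and are flagged invalid rather than extrapolated.
#'
#' @param pressure Numeric vector of foot-pressure samples (finite).
#' @param smooth_window Odd moving-average length in samples (default 15).
#' @param min_peak_distance Minimum distance between marked peaks in samples
#'   (default 50, i.e. half a second at 100 Hz — shorter than any plausible
#'   stride at walking speeds).
#' @param min_prominence Minimum topographic prominence of a marked peak, in
#'   pressure units. Default `NULL` uses 10% of the smoothed signal's range.
#' @return A tibble with columns `phase` (percent of gait cycle, `NA` where
#'   invalid) and `valid` (logical).
#' @examples
#' p <- rep(0, 30); p[c(5, 15, 25)] <- 1
#' derive_phase_labels(p, smooth_window = 3, min_peak_distance = 5,
#'                     min_prominence = 0.1)
#' @export
derive_phase_labels <- function(pressure, smooth_window = 15L,
                                min_peak_distance = 50L,
                                min_prominence = NULL) {
  if (!is.numeric(pressure) || anyNA(pressure) || any(!is.finite(pressure))) {
    abort("derive_phase_labels: pressure must be finite numeric")
  }
  if (length(pressure) <= smooth_window) {
    abort("derive_phase_labels: series shorter than the smoothing window")
  }
  if (min_peak_distance < 1L) {
    abort("derive_phase_labels: min_peak_distance must be >= 1")
  }
  sm <- moving_average(pressure, smooth_window)
  if (is.null(min_prominence)) {
    min_prominence <- 0.1 * diff(range(sm))
  }
  peaks <- find_peaks(sm, min_distance = min_peak_distance,
                      min_prominence = min_prominence)
  if (length(peaks) < 2L) {
    abort("insufficient strides: fewer than two pressure peaks found")
  }
  n <- length(pressure)
  phase <- rep(NA_real_, n)
  for (k in seq_len(length(peaks) - 1L)) {
    a <- peaks[k]
    b <- peaks[k + 1L]
    t <- a:(b - 1L)
    phase[t] <- 100 * (t - a) / (b - a)
  }
  phase[peaks[length(peaks)]] <- 0 # final marked initial contact
  tibble::tibble(phase = phase, valid = !is.na(phase))
}

#' Circular phase encoding and decoding
#'
#' A gait phase `p` in percent is mapped onto the unit circle,
#' `(sin, cos)(2*pi*p/100)`, so that 0% and 100% — kinematically almost the
#' same posture — are adjacent in label space and a squared-error loss does
#' not penalise wrap-around. `cartesian_to_phase()` inverts the map via
#' `atan2`, wrapping negative angles into `[0, 100)`.
#'
#' @param phase Numeric vector of phases in percent. Values outside
#'   `[0, 100]` are reduced modulo 100.
#' @return `phase_to_cartesian()`: a tibble with columns `y_sin`, `y_cos`.
#' @examples
#' phase_to_cartesian(c(0, 25, 75))
#' cartesian_to_phase(phase_to_cartesian(42))
#' @export
phase_to_cartesian <- function(phase) {
  if (!is.numeric(phase) || anyNA(phase) || any(!is.finite(phase))) {
    abort("phase_to_cartesian: phase must be finite numeric")
  }
  ang <- 2 * pi * (phase %% 100) / 100
  tibble::tibble(y_sin = sin(ang), y_cos = cos(ang))
}

#' @rdname phase_to_cartesian
#' @param y_sin,y_cos Numeric vectors: the sine and cosine label components.
#'   Alternatively `y_sin` may be a two-column object (matrix or data frame)
#'   holding both components, in which case `y_cos` is ignored. Predictions
#'   need not lie on the unit circle; only the direction matters.
#' @return `cartesian_to_phase()`: numeric vector of phases in `[0, 100)`.
#' @export
cartesian_to_phase <- function(y_sin, y_cos = NULL) {
  if (is.null(y_cos)) {
    if (is.data.frame(y_sin)) {
      stopifnot(ncol(y_sin) == 2L)
      y_cos <- as.numeric(y_sin[[2]])
      y_sin <- as.numeric(y_sin[[1]])
    } else if (is.matrix(y_sin)) {
      stopifnot(ncol(y_sin) == 2L)
      y_cos <- as.numeric(y_sin[, 2])
      y_sin <- as.numeric(y_sin[, 1])
    } else {
      abort("cartesian_to_phase: supply y_sin and y_cos")
    }
  }
  if (anyNA(y_sin) || anyNA(y_cos) ||
      any(!is.finite(y_sin)) || any(!is.finite(y_cos))) {
    abort("cartesian_to_phase: components must be finite")
  }
  if (any(y_sin == 0 & y_cos == 0)) {
    abort("undefined phase: zero vector has no direction")
  }
  theta <- atan2(y_sin, y_cos)
  theta <- ifelse(theta < 0, theta + 2 * pi, theta)
  theta * 100 / (2 * pi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Circular distance between phases
#'
#' Shortest distance around the 0-100 cycle, in phase units (at most 50).
#'
#' @param a,b Numeric phase vectors in percent.
#' @return Numeric vector of circular distances.
#' @export
circular_phase_distance <- function(a, b) {
  d <- abs((a - b) %% 100)
  pmin(d, 100 - d)
}

#' The four reporting bins of the gait cycle
#'
#' Evaluation is stratified over four named spans of the cycle: pre-stance
#' (0-30%), post-stance (31-60%), pre-swing (61-80%) and post-swing
#' (81-100%). For continuous phases the integer printed bounds become
#' half-open intervals: `[0,30]`, `(30,60]`, `(60,80]`, `(80,100]`.
#'
#' @return A tibble with columns `bin`, `lo`, `hi`.
#' @export
gait_phase_bins <- function() {
  tibble::tibble(
    bin = phase_bin_levels(),
    lo = c(0, 30, 60, 80),
    hi = c(30, 60, 80, 100)
  )
}

phase_bin_levels <- function() {
  c("pre-stance", "post-stance", "pre-swing", "post-swing")
}

#' @rdname gait_phase_bins
#' @param phase Numeric vector of phases in `[0, 100]`.
#' @return `assign_phase_bin()`: a factor with the four bin levels.
#' @examples
#' assign_phase_bin(c(15, 45, 70, 100))
#' @export
assign_phase_bin <- function(phase) {
  if (!is.numeric(phase) || anyNA(phase) || any(!is.finite(phase))) {
    abort("assign_phase_bin: phase must be finite numeric")
  }
  if (any(phase < 0 | phase > 100)) {
    abort("assign_phase_bin: phase must lie in [0, 100]")
  }
  cut(phase, breaks = c(0, 30, 60, 80, 100), labels = phase_bin_levels(),
      include.lowest = TRUE, right = TRUE)
}

#' Anti-aliased integer-factor downsampling
#'
#' Decimates a channel from `in_rate` to `out_rate` (the ratio must be an
#' integer). A zero-phase 4th-order Butterworth low-pass at 90% of the output
#' Nyquist removes energy that would alias, then every factor-th sample is
#' kept. Used to bring natively fast channels (e.g. 2000 Hz surface EMG) onto
#' the common 100 Hz clock.
#'
#' @param series Finite numeric vector.
#' @param in_rate,out_rate Input and output sampling rates in Hz.
#' @return Numeric vector of length `floor(length(series) / factor)`.
#' @export
downsample_channel <- function(series, in_rate, out_rate) {
  if (!is.numeric(series) || anyNA(series) || any(!is.finite(series))) {
    abort("downsample_channel: series must be finite numeric")
  }
  stopifnot(in_rate > 0, out_rate > 0)
  factor <- in_rate / out_rate
  if (abs(factor - round(factor)) > 1e-9) {
    abort("downsample_channel: in_rate must be an integer multiple of out_rate")
  }
  factor <- as.integer(round(factor))
  n_out <- floor(length(series) / factor)
  if (n_out < 1L) abort("downsample_channel: series shorter than one output sample")
  if (factor == 1L) return(series[seq_len(n_out)])
  if (length(series) < 24L) {
    abort("downsample_channel: series too short to filter")
  }
  bf <- signal::butter(4, 0.9 / factor, type = "low")
  m <- mean(series) # filter the zero-mean part: keeps DC exact at the edges
  filtered <- signal::filtfilt(bf, series - m) + m
  filtered[seq(1L, by = factor, length.out = n_out)]
}
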