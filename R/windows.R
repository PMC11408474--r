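#' Sliding-window dataset for phase prediction
#'
#' Cuts a recording into overlapping windows of `window_len` time steps
#' advanced by `stride`, pairing each window with the gait phase at its final
#' (most recent) time step — the causal convention a real-time controller
#' needs. Windows whose final step has no valid phase label are dropped.
#'
#' @param recording A [gait_recording()].
#' @param phase Either the tibble returned by [derive_phase_labels()] (columns
#'   `phase`, `valid`) or a numeric phase vector (`NA` marks invalid samples).
#'   Must match the recording length.
#' @param window_len Window length L in time steps (default 100, one second
#'   at 100 Hz).
#' @param stride Step between successive window end points (default 1).
#' @return A `window_dataset`: list with `windows` (array `M x L x K`),
#'   `channel_names`, `modality`, `phase` (length-K true phases), `labels`
#'   (`K x 2` matrix of sin/cos targets), `end_index`, `window_len`, `stride`.
#' @examples
#' rec <- gait_recording(data.frame(a = sin(1:120 / 5)), 100, c(a = "IMU"))
#' ds <- make_windows(rec, rep(seq(0, 99.9, length.out = 120)), 100, 1)
#' n_windows(ds)
#' @export
make_windows <- function(recording, phase, window_len = 100L, stride = 1L) {
  stopifnot(inherits(recording, "gait_recording"))
  window_len <- as.integer(window_len)
  stride <- as.integer(stride)
  if (stride < 1L) abort("make_windows: stride must be >= 1")
  if (is.data.frame(phase)) {
    stopifnot(all(c("phase", "valid") %in% names(phase)))
    valid <- phase$valid & !is.na(phase$phase)
    phase <- phase$phase
  } else {
    valid <- !is.na(phase) & is.finite(phase)
  }
  T_len <- n_samples(recording)
  if (length(phase) != T_len) {
    abort("make_windows: phase length must equal the recording length")
  }
  if (T_len < window_len) abort("series too short: fewer samples than window_len")
  X <- signal_matrix(recording)
  ends <- seq.int(window_len, T_len, by = stride)
  ends <- ends[valid[ends]]
  K <- length(ends)
  M <- nrow(X)
  win <- array(0, dim = c(M, window_len, K))
  for (k in seq_len(K)) {
    win[, , k] <- X[, (ends[k] - window_len + 1L):ends[k], drop = FALSE]
  }
  ph <- phase[ends]
  lab <- phase_to_cartesian(ph)
  structure(
    list(windows = win,
         channel_names = channel_names(recording),
         modality = recording$modality,
         phase = ph,
         labels = cbind(y_sin = lab$y_sin, y_cos = lab$y_cos),
         end_index = ends,
         window_len = window_len,
         stride = stride),
    class = "window_dataset"
  )
}

#' @rdname make_windows
#' @param x A `window_dataset`.
#' @export
n_windows <- function(x) {
  stopifnot(inherits(x, "window_dataset"))
  length(x$phase)
}

#' @rdname make_windows
#' @param i Integer index vector of windows to keep.
#' @param ... Ignored.
#' @export
`[.window_dataset` <- function(x, i, ...) {
  out <- x
  out$windows <- x$windows[, , i, drop = FALSE]
  out$phase <- x$phase[i]
  out$labels <- x$labels[i, , drop = FALSE]
  out$end_index <- x$end_index[i]
  out
}

#' @export
print.window_dataset <- function(x, ...) {
  cat(sprintf("<window_dataset> %d windows of %d channels x %d steps (stride %d)\n",
              n_windows(x), dim(x$windows)[1], x$window_len, x$stride))
  invisible(x)
}

#' Window dataset as a tidy tibble
#'
#' @param x A `window_dataset`.
#' @param ... Ignored.
#' @return A tibble with one row per window: `window` (index), `end_index`,
#'   `phase`, `y_sin`, `y_cos`, `bin`.
#' @exportS3Method generics::tidy
tidy.window_dataset <- function(x, ...) {
  tibble::tibble(
    window = seq_len(n_windows(x)),
    end_index = x$end_index,
    phase = x$phase,
    y_sin = x$labels[, 1],
    y_cos = x$labels[, 2],
    bin = assign_phase_bin(x$phase)
  )
}
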