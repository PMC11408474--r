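#' Build a multichannel sensor recording
#'
#' A `gait_recording` bundles synchronized, equal-length sensor channels
#' sampled at a common rate, an optional foot-pressure series used only for
#' phase labelling, and a modality tag (`"IMU"`, `"STRETCH"` or `"EMG"`) per
#' channel. All downstream steps — phase labelling, windowing, model training
#' and channel selection — consume this container.
#'
#' @param signals A data frame with one numeric column per sensor channel.
#'   Column names are the channel names and must be unique.
#' @param rate_hz Common sampling rate in Hz (positive scalar).
#' @param modality Named character vector mapping every channel name to one of
#'   `"IMU"`, `"STRETCH"`, `"EMG"`.
#' @param foot_pressure Optional numeric vector, same length as the channels,
#'   holding the (channel-averaged) plantar pressure signal. It is a labelling
#'   aid, not a model input channel.
#'
#' @return An object of class `gait_recording`: a list with elements
#'   `signals` (tibble), `rate_hz`, `modality`, `foot_pressure`.
#' @examples
#' rec <- gait_recording(
#'   data.frame(knee = sin(1:200 / 10), shank = cos(1:200 / 10)),
#'   rate_hz = 100,
#'   modality = c(knee = "STRETCH", shank = "IMU")
#' )
#' n_samples(rec)
#' @export
gait_recording <- function(signals, rate_hz, modality,
                           foot_pressure = NULL) {
  signals <- tibble::as_tibble(signals)
  if (ncol(signals) < 1L) abort("recording needs at least one channel")
  nm <- names(signals)
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate channel name: ", nm[duplicated(nm)][1]))
  }
  if (!all(vapply(signals, is.numeric, logical(1)))) {
    abort("all channels must be numeric")
  }
  if (nrow(signals) < 1L) abort("channels must have length >= 1")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || !is.finite(rate_hz) ||
      rate_hz <= 0) {
    abort("rate_hz must be a positive finite scalar")
  }
  modality <- validate_modality(modality, nm)
  if (!is.null(foot_pressure)) {
    if (!is.numeric(foot_pressure) || length(foot_pressure) != nrow(signals)) {
      abort("foot_pressure must be numeric with the same length as the channels")
    }
  }
  structure(
    list(signals = signals, rate_hz = as.numeric(rate_hz),
         modality = modality, foot_pressure = foot_pressure),
    class = "gait_recording"
  )
}

validate_modality <- function(modality, channel_names) {
  if (is.null(names(modality)) || !all(channel_names %in% names(modality))) {
    missing <- setdiff(channel_names, names(modality))
    abort(paste0("modality missing for channel(s): ",
                 paste(missing, collapse = ", ")))
  }
  modality <- modality[channel_names]
  bad <- setdiff(unique(modality), c("IMU", "STRETCH", "EMG"))
  if (length(bad)) {
    abort(paste0("unknown modality: ", paste(bad, collapse = ", ")))
  }
  modality
}

#' @rdname gait_recording
#' @param x,object A `gait_recording`.
#' @export
n_samples <- function(x) nrow(x$signals)

#' @rdname gait_recording
#' @export
channel_names <- function(x) names(x$signals)

#' @rdname gait_recording
#' @param ... Ignored.
#' @export
print.gait_recording <- function(x, ...) {
  cat(sprintf("<gait_recording> %d channels x %d samples @ %g Hz\n",
              ncol(x$signals), nrow(x$signals), x$rate_hz))
  tab <- table(x$modality)
  cat("  modalities:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  cat("  foot pressure:", if (is.null(x$foot_pressure)) "absent" else "present",
      "\n")
  invisible(x)
}

#' Keep a subset of channels
#'
#' @param recording A [gait_recording()].
#' @param channels Character vector of channel names to retain, in the
#'   requested order.
#' @return A `gait_recording` with only those channels (foot pressure kept).
#' @export
select_channels <- function(recording, channels) {
  stopifnot(inherits(recording, "gait_recording"))
  missing <- setdiff(channels, channel_names(recording))
  if (length(missing)) {
    abort(paste0("unknown channel(s): ", paste(missing, collapse = ", ")))
  }
  gait_recording(recording$signals[channels], recording$rate_hz,
                 recording$modality[channels], recording$foot_pressure)
}

#' Signal matrix of a recording
#'
#' @param recording A [gait_recording()].
#' @return A channels-by-samples numeric matrix (rows in channel order).
#' @export
signal_matrix <- function(recording) {
  stopifnot(inherits(recording, "gait_recording"))
  t(as.matrix(recording$signals))
}
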