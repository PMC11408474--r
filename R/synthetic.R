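#' Specify a synthetic multimodal gait recording
#'
#' The generator emulates the structure of treadmill walking data: a
#' stride-periodic ground-truth phase (0-100% per stride), kinematic
#' channels that are smooth harmonics of that phase, EMG-like channels whose
#' rectified-noise bursts are gated by a phase-locked envelope, a knee-like
#' piecewise-smooth stretch ramp, optional pure-noise channels carrying no
#' phase information, and a foot-pressure pulse train peaking exactly at
#' each stride boundary. Because the true phase is known sample-by-sample,
#' every downstream stage (labelling, windowing, training, attribution) can
#' be validated against ground truth.
#'
#' @param n_strides Number of strides (>= 2).
#' @param stride_len_mean Mean stride length in samples (>= 10; default 100,
#'   i.e. one second at 100 Hz).
#' @param stride_len_jitter Fraction in `[0, 1)`: each stride's length is
#'   drawn uniformly in `mean * (1 +/- jitter)`.
#' @param channels Tibble with columns `name`, `modality`
#'   (IMU/STRETCH/EMG), `kind` (`"kinematic-sinusoid"`, `"emg-burst"`,
#'   `"stretch-ramp"`, `"noise"`), `phase_offset` (percent) and `snr`.
#'   `snr` is the signal-to-noise amplitude ratio `sd(signal)/sd(noise)`;
#'   `snr = 0` is the noise-free limit (no noise added).
#' @param rate_hz Nominal sampling rate attached to the recording.
#' @param seed Integer seed; identical specs give identical recordings.
#' @return A `synthetic_spec` list.
#' @examples
#' spec <- synthetic_spec(n_strides = 5, seed = 2)
#' rec <- generate_recording(spec)
#' @export
synthetic_spec <- function(n_strides, stride_len_mean = 100L,
                           stride_len_jitter = 0,
                           channels = default_channel_spec(),
                           rate_hz = 100, seed = 1L) {
  channels <- tibble::as_tibble(channels)
  spec <- structure(
    list(n_strides = as.integer(n_strides),
         stride_len_mean = as.integer(stride_len_mean),
         stride_len_jitter = stride_len_jitter,
         channels = channels, rate_hz = rate_hz, seed = as.integer(seed)),
    class = "synthetic_spec")
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  if (spec$n_strides < 2L) abort("invalid spec field n_strides: must be >= 2")
  if (spec$stride_len_mean < 10L) {
    abort("invalid spec field stride_len_mean: must be >= 10")
  }
  if (spec$stride_len_jitter < 0 || spec$stride_len_jitter >= 1) {
    abort("invalid spec field stride_len_jitter: must be in [0, 1)")
  }
  ch <- spec$channels
  need <- c("name", "modality", "kind", "phase_offset", "snr")
  if (nrow(ch) < 1L) abort("invalid spec field channels: empty channel list")
  if (!all(need %in% names(ch))) {
    abort(paste0("invalid spec field channels: missing column(s) ",
                 paste(setdiff(need, names(ch)), collapse = ", ")))
  }
  if (anyDuplicated(ch$name)) abort("invalid spec field channels: duplicate names")
  bad_kind <- setdiff(ch$kind, c("kinematic-sinusoid", "emg-burst",
                                 "stretch-ramp", "noise"))
  if (length(bad_kind)) {
    abort(paste0("invalid spec field channels: unknown kind ",
                 paste(bad_kind, collapse = ", ")))
  }
  if (any(ch$snr < 0)) abort("invalid spec field channels: snr must be >= 0")
  invisible(spec)
}

#' @rdname synthetic_spec
#' @export
default_channel_spec <- function() {
  tibble::tibble(
    name = c("shank_angle", "thigh_gyro", "knee_stretch",
             "emg_gastroc", "emg_tibialis"),
    modality = c("IMU", "IMU", "STRETCH", "EMG", "EMG"),
    kind = c("kinematic-sinusoid", "kinematic-sinusoid", "stretch-ramp",
             "emg-burst", "emg-burst"),
    # EMG bursts near push-off (~40%) and swing (~90%)
    phase_offset = c(0, 25, 0, 40, 90),
    snr = c(20, 20, 20, 10, 10)
  )
}

synth_channel <- function(kind, phase, offset, snr) {
  p <- (phase - offset) %% 100
  ang <- 2 * pi * p / 100
  sig <- switch(
    kind,
    "kinematic-sinusoid" = sin(ang) + 0.5 * sin(2 * ang + 0.6),
    "emg-burst" = exp(6 * (cos(ang) - 1)) * abs(rnorm(length(p))),
    "stretch-ramp" = {
      ramp <- ifelse(p <= 70, p / 70, (100 - p) / 30)
      moving_average(ramp, 9L)
    },
    "noise" = rnorm(length(p))
  )
  if (kind != "noise" && snr > 0) {
    sig <- sig + rnorm(length(sig), sd = sd(sig) / snr)
  }
  sig
}

#' Generate a synthetic recording with known ground-truth phase
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `recording` (a [gait_recording()] including the
#'   foot-pressure channel) and `phase` (tibble of the exact generator phase
#'   with `valid = TRUE` everywhere).
#' @export
generate_recording <- function(spec) {
  validate_synthetic_spec(spec)
  local_seed(spec$seed)
  jit <- spec$stride_len_jitter
  lens <- if (jit == 0) {
    rep(spec$stride_len_mean, spec$n_strides)
  } else {
    pmax(10L, as.integer(round(
      spec$stride_len_mean * (1 + runif(spec$n_strides, -jit, jit)))))
  }
  phase <- unlist(lapply(lens, function(l) 100 * (seq_len(l) - 1) / l))
  pressure <- exp(8 * (cos(2 * pi * phase / 100) - 1))
  ch <- spec$channels
  sig <- purrr::pmap(list(ch$kind, ch$phase_offset, ch$snr),
                     function(kind, off, snr) synth_channel(kind, phase, off, snr))
  names(sig) <- ch$name
  rec <- gait_recording(tibble::as_tibble(sig), spec$rate_hz,
                        setNames(ch$modality, ch$name),
                        foot_pressure = pressure)
  list(recording = rec,
       phase = tibble::tibble(phase = phase, valid = TRUE))
}

#' Generate a windowed dataset straight from a synthetic spec
#'
#' Composes [generate_recording()], phase labelling and [make_windows()].
#' Labels can come from the exact generator phase (default) or from the full
#' foot-pressure pipeline ([derive_phase_labels()]), which exercises the
#' label-construction path end to end.
#'
#' @param spec A [synthetic_spec()].
#' @param window_len,stride Windowing parameters (see [make_windows()]).
#' @param labels `"ground_truth"` or `"pressure"`.
#' @param ... Passed to [derive_phase_labels()] when `labels = "pressure"`.
#' @return A `window_dataset` with attribute `label_source`.
#' @export
generate_dataset <- function(spec, window_len = 100L, stride = 1L,
                             labels = c("ground_truth", "pressure"), ...) {
  labels <- match.arg(labels)
  gen <- generate_recording(spec)
  ph <- if (labels == "ground_truth") {
    gen$phase
  } else {
    derive_phase_labels(gen$recording$foot_pressure, ...)
  }
  ds <- make_windows(gen$recording, ph, window_len, stride)
  attr(ds, "label_source") <- labels
  ds
}
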