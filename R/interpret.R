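#' Cross-attention channel-importance report
#'
#' For every window the global token's cross-attention distributes one unit
#' of softmax mass over the M channels (per head). Averaging those rows over
#' heads and then over windows yields a per-channel importance weight; the
#' dispersion across windows is reported alongside. Weights sum to 1 within
#' numerical tolerance both per window and after averaging.
#'
#' @param model A trained [ptt_model()].
#' @param dataset A `window_dataset` matching the model (typically the
#'   held-out split: attention on training windows can reflect optimisation
#'   artifacts).
#' @param head_reduction `"mean"` (default) averages heads before the window
#'   average; `"per_head"` keeps one row per channel and head.
#' @param batch_size Windows per forward batch.
#' @return A `channel_weight_report` tibble with columns `channel`,
#'   `modality`, `mean_weight`, `sd_weight` (plus `head` for per-head
#'   reports) and attributes `n_windows`, `head_reduction`.
#' @export
channel_weights <- function(model, dataset,
                            head_reduction = c("mean", "per_head"),
                            batch_size = 128L) {
  stopifnot(inherits(model, "ptt_model"))
  head_reduction <- match.arg(head_reduction)
  check_model_dataset(model, dataset)
  K <- n_windows(dataset)
  if (K < 1L) abort("channel_weights: empty dataset")
  pr <- ptt_predict_internal(model, dataset, batch_size, keep_weights = TRUE)
  W <- pr$weights # M x K x h
  M <- dim(W)[1]
  nm <- dataset$channel_names
  mod <- unname(dataset$modality[nm])
  if (head_reduction == "mean") {
    Wm <- apply(W, c(1L, 2L), mean) # M x K
    out <- tibble::tibble(
      channel = nm, modality = mod,
      mean_weight = rowMeans(Wm),
      sd_weight = apply(Wm, 1L, sd)
    )
  } else {
    out <- tidyr::expand_grid(head = seq_len(dim(W)[3]),
                              channel = nm) |>
      dplyr::mutate(
        modality = rep(mod, times = dim(W)[3]),
        mean_weight = as.vector(apply(W, c(1L, 3L), mean)),
        sd_weight = as.vector(apply(W, c(1L, 3L), sd))
      )
  }
  attr(out, "n_windows") <- K
  attr(out, "head_reduction") <- head_reduction
  class(out) <- c("channel_weight_report", class(out))
  out
}

#' Within-channel attention-scope heatmaps
#'
#' Averages a model's encoder self-attention matrices over a chosen set of
#' layers and heads, per channel, showing which time segments of the window
#' the encoding of each channel token attends to. The default averages the
#' last three layers and last six heads (capped at what the configuration
#' has). Rows of the averaged map remain stochastic (a convex combination of
#' softmax rows).
#'
#' @param x A trained [ptt_model()], or a `ptt_trace` from
#'   [ptt_forward()] with `capture = TRUE`.
#' @param window `M x L` matrix (required when `x` is a model). Channel
#'   normalisation stored in the model is applied automatically.
#' @param layers,heads Integer index sets; defaults are the last
#'   `min(3, n_layers)` layers and last `min(6, n_heads)` heads.
#' @return An `attention_scope_map`: list with `maps` (per-channel `S x S`
#'   matrices), `layers_used`, `heads_used`.
#' @export
attention_scope <- function(x, window = NULL, layers = NULL, heads = NULL) {
  if (inherits(x, "ptt_model")) {
    cfg <- x$config
    if (cfg$n_layers == 0L) abort("no trace: model has no encoder layers")
    if (is.null(window)) abort("attention_scope: supply a window")
    if (!is.null(x$norm)) {
      window <- (window - x$norm$mu) / x$norm$sd
    }
    trace <- ptt_forward(window, x, capture = TRUE)
  } else if (inherits(x, "ptt_trace")) {
    trace <- x
    if (is.null(trace$encoder_attention)) {
      abort("no trace: forward pass was run without capture = TRUE")
    }
    cfg <- list(n_layers = length(trace$encoder_attention[[1]]),
                n_heads = dim(trace$encoder_attention[[1]][[1]])[1])
  } else {
    abort("attention_scope: x must be a ptt_model or ptt_trace")
  }
  N <- cfg$n_layers
  h <- cfg$n_heads
  if (N < 1L) abort("no trace: model has no encoder layers")
  if (is.null(layers)) layers <- (N - min(3L, N) + 1L):N
  if (is.null(heads)) heads <- (h - min(6L, h) + 1L):h
  if (any(layers < 1L | layers > N)) abort("attention_scope: layer index out of range")
  if (any(heads < 1L | heads > h)) abort("attention_scope: head index out of range")
  maps <- lapply(trace$encoder_attention, function(per_layer) {
    acc <- 0
    for (l in layers) for (j in heads) acc <- acc + per_layer[[l]][j, , ]
    acc / (length(layers) * length(heads))
  })
  names(maps) <- names(trace$encoder_attention)
  structure(list(maps = maps, layers_used = sort(layers),
                 heads_used = sort(heads)),
            class = "attention_scope_map")
}

#' @export
print.attention_scope_map <- function(x, ...) {
  cat(sprintf("<attention_scope_map> %d channels, layers {%s} x heads {%s}\n",
              length(x$maps), paste(x$layers_used, collapse = ","),
              paste(x$heads_used, collapse = ",")))
  invisible(x)
}

#' Attention-guided channel selection
#'
#' Ranks channels by mean cross-attention weight within each modality and
#' keeps the top k per modality. Ties are broken by lexicographic channel
#' name, making the selection deterministic and invariant to the report's
#' row order.
#'
#' @param report A [channel_weights()] report (head-averaged).
#' @param k_per_modality Named integer vector, e.g.
#'   `c(IMU = 8, EMG = 8)`.
#' @param modality_of Optional named modality map overriding the report's
#'   `modality` column.
#' @param source_spec Label describing the fused data source.
#' @return A `channel_selection`: list with `source_spec`, `selected`
#'   (ordered channel names) and `k_per_modality`.
#' @export
select_top_channels <- function(report, k_per_modality, modality_of = NULL,
                                source_spec = NULL) {
  stopifnot(is.data.frame(report), all(c("channel", "mean_weight") %in% names(report)))
  if (!is.null(modality_of)) {
    report$modality <- unname(modality_of[report$channel])
  }
  if (!"modality" %in% names(report)) {
    abort("select_top_channels: no modality information")
  }
  sel <- character(0)
  for (m in names(k_per_modality)) {
    k <- k_per_modality[[m]]
    rows <- report[report$modality == m, ]
    if (nrow(rows) == 0L) {
      abort(paste0("select_top_channels: modality not present: ", m))
    }
    if (k > nrow(rows)) {
      abort(sprintf(
        "select_top_channels: requested %d channels but modality %s has only %d",
        k, m, nrow(rows)))
    }
    ord <- order(-rows$mean_weight, rows$channel)
    sel <- c(sel, rows$channel[ord][seq_len(k)])
  }
  structure(
    list(source_spec = source_spec %||% paste(names(k_per_modality), collapse = "+"),
         selected = sel,
         k_per_modality = k_per_modality),
    class = "channel_selection")
}

#' @export
print.channel_selection <- function(x, ...) {
  cat(sprintf("<channel_selection> %s: %d channels\n", x$source_spec,
              length(x$selected)))
  cat(" ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' The four fused sensor configurations
#'
#' From a full channel-weight report over the 34-channel base registry
#' (16 IMU + 16 EMG + 2 stretch), builds the four 16-channel fused data
#' sources: IMU+EMG takes the top 8 of each; Stretch+EMG and IMU+Stretch
#' take both stretch channels plus the top 14 of the other modality; and
#' IMU+Stretch+EMG takes both stretch channels plus the top 7 from IMU and
#' EMG each.
#'
#' @param report A head-averaged [channel_weights()] report covering IMU,
#'   EMG and STRETCH channels.
#' @return Named list of four `channel_selection` objects
#'   (`"IMU+EMG"`, `"Stretch+EMG"`, `"IMU+Stretch"`, `"IMU+Stretch+EMG"`),
#'   each selecting 16 channels.
#' @export
build_fused_source_specs <- function(report) {
  stopifnot(is.data.frame(report))
  for (m in c("IMU", "EMG", "STRETCH")) {
    if (!any(report$modality == m)) {
      abort(paste0("build_fused_source_specs: missing modality ", m))
    }
  }
  n_stretch <- sum(report$modality == "STRETCH")
  list(
    "IMU+EMG" = select_top_channels(
      report, c(IMU = 8L, EMG = 8L), source_spec = "IMU+EMG"),
    "Stretch+EMG" = select_top_channels(
      report, c(STRETCH = n_stretch, EMG = 14L), source_spec = "Stretch+EMG"),
    "IMU+Stretch" = select_top_channels(
      report, c(STRETCH = n_stretch, IMU = 14L), source_spec = "IMU+Stretch"),
    "IMU+Stretch+EMG" = select_top_channels(
      report, c(STRETCH = n_stretch, IMU = 7L, EMG = 7L),
      source_spec = "IMU+Stretch+EMG")
  )
}

#' The study's 34-channel base sensor registry
#'
#' The selected channel set of the human experiments: 16 IMU channels
#' (x-axis angles, angular velocities and accelerations of thighs, shanks
#' and trunk, plus shank z-axis accelerations), 2 knee stretch channels and
#' 16 EMG channels (every fourth electrode of the 64-channel array over
#' tibialis anterior and gastrocnemius).
#'
#' @return Tibble with columns `channel`, `modality`.
#' @export
standard_channel_registry <- function() {
  imu <- c("L_T_agl_x", "L_T_gyro_x", "L_T_acc_x",
           "R_T_agl_x", "R_T_gyro_x", "R_T_acc_x",
           "L_S_agl_x", "L_S_gyro_x", "L_S_acc_x", "L_S_acc_z",
           "R_S_gyro_x", "R_S_acc_x", "R_S_acc_z",
           "Tk_agl_x", "Tk_gyro_x", "Tk_acc_x")
  stretch <- c("L_leg_str", "R_leg_str")
  emg <- paste0("EMG_", seq(1L, 61L, by = 4L))
  tibble::tibble(
    channel = c(imu, stretch, emg),
    modality = c(rep("IMU", length(imu)), rep("STRETCH", length(stretch)),
                 rep("EMG", length(emg)))
  )
}
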