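#' Tidiers and plots for fitted models and reports
#'
#' `tidy()` on a trained model returns the per-epoch training-loss history;
#' `glance()` returns a one-row model summary. `autoplot()` methods cover
#' the three result types: phase-stratified metrics, channel-weight reports
#' and attention-scope heatmaps.
#'
#' @param x A trained `gait_model`.
#' @param ... Ignored.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.gait_model <- function(x, ...) {
  if (is.null(x$history)) abort("model has not been trained")
  x$history
}

#' @rdname tidy.gait_model
#' @exportS3Method generics::glance
glance.gait_model <- function(x, ...) {
  tibble::tibble(
    model = if (inherits(x, "ptt_model")) "patch-transformer" else x$family,
    n_params = length(params_flatten(x$params)),
    n_channels = x$config$n_channels,
    window_len = x$config$window_len,
    epochs = if (is.null(x$history)) 0L else nrow(x$history),
    final_train_loss = if (is.null(x$history)) NA_real_ else
      x$history$train_loss[nrow(x$history)]
  )
}

#' @rdname tidy.gait_model
#' @param object A result object (dispatch for `autoplot`).
#' @exportS3Method ggplot2::autoplot
autoplot.phase_metrics <- function(object, ...) {
  df <- dplyr::filter(object, .data$bin != "overall")
  df$bin <- factor(df$bin, levels = phase_bin_levels())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$rmse)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "RMSE (phase units)",
                  title = "Prediction error by gait-phase bin") +
    ggplot2::theme_minimal()
}

#' @rdname tidy.gait_model
#' @exportS3Method ggplot2::autoplot
autoplot.channel_weight_report <- function(object, ...) {
  df <- dplyr::arrange(object, dplyr::desc(.data$mean_weight))
  df$channel <- factor(df$channel, levels = rev(df$channel))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_weight, y = .data$channel,
                                   fill = .data$modality)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = pmax(.data$mean_weight - .data$sd_weight, 0),
                   xmax = .data$mean_weight + .data$sd_weight),
      height = 0.3, linewidth = 0.3) +
    ggplot2::labs(x = "mean cross-attention weight", y = NULL,
                  title = "Channel importance") +
    ggplot2::theme_minimal()
}

#' @rdname tidy.gait_model
#' @exportS3Method ggplot2::autoplot
autoplot.attention_scope_map <- function(object, ...) {
  nm <- names(object$maps) %||% paste0("channel ", seq_along(object$maps))
  df <- purrr::map2_dfr(object$maps, nm, function(m, n) {
    tibble::tibble(
      channel = n,
      query = rep(seq_len(nrow(m)), times = ncol(m)),
      key = rep(seq_len(ncol(m)), each = nrow(m)),
      weight = as.vector(m)
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$key, y = .data$query,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "attended position (token + patches)",
                  y = "query position",
                  title = "Attention scope") +
    ggplot2::theme_minimal()
}

#' Plot predicted against true phase
#'
#' @param predictions Output of [predict_phase()].
#' @return A ggplot object.
#' @export
plot_phase_predictions <- function(predictions) {
  ggplot2::ggplot(predictions,
                  ggplot2::aes(x = .data$phase_true, y = .data$phase_pred)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "orange",
                         linetype = "dashed") +
    ggplot2::labs(x = "true phase (%)", y = "predicted phase (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
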