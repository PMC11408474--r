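#' Loss and regression metrics
#'
#' `mse_loss()` is the training criterion: the mean of squared differences
#' between predicted and target label components, averaged over both the
#' batch and the two (sin, cos) components. `rmse()` and `r2()` are the
#' reporting metrics, computed on decoded phase values with plain (linear)
#' differences — deliberately not circular, which is why errors near the
#' 0/100 wrap can be large and per-bin R-squared can go negative at the
#' cycle boundaries.
#'
#' @param y_pred,y_label Numeric matrices (rows = samples, 2 columns) or
#'   vectors of equal shape.
#' @return `mse_loss()`: a non-negative scalar.
#' @examples
#' mse_loss(c(0, 0), c(0, 1))   # 0.5
#' rmse(c(0, 0), c(3, 4))       # sqrt(12.5)
#' @export
mse_loss <- function(y_pred, y_label) {
  if (length(y_pred) != length(y_label)) {
    abort("mse_loss: shape mismatch between prediction and label")
  }
  if (any(!is.finite(y_pred)) || any(!is.finite(y_label))) {
    abort("mse_loss: inputs must be finite")
  }
  mean((as.numeric(y_pred) - as.numeric(y_label))^2)
}

#' @rdname mse_loss
#' @param y True values; `y_hat` predictions (equal nonzero length).
#' @param y_hat Predicted values.
#' @return `rmse()`: root-mean-squared error (same units as `y`).
#' @export
rmse <- function(y, y_hat) {
  if (length(y) == 0L || length(y) != length(y_hat)) {
    abort("rmse: inputs must have equal nonzero length")
  }
  sqrt(mean((y - y_hat)^2))
}

#' @rdname mse_loss
#' @return `r2()`: coefficient of determination (at most 1; negative when
#'   predictions fit worse than the mean).
#' @export
r2 <- function(y, y_hat) {
  if (length(y) < 2L || length(y) != length(y_hat)) {
    abort("r2: inputs must have equal length >= 2")
  }
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) abort("undefined R-squared: constant true values")
  1 - sum((y - y_hat)^2) / ss_tot
}

#' Phase-stratified evaluation
#'
#' Decodes predictions to phase percentages, stratifies windows by the
#' *true* phase into the four gait bins, and reports RMSE and R-squared per
#' bin plus overall. Differences are plain (non-circular), so bins touching
#' the 0/100 wrap (pre-stance, post-swing) naturally show inflated errors —
#' a property of the reporting convention, not a model defect. Bins holding
#' fewer than two windows get `NA` metrics rather than fabricated values.
#'
#' @param model A trained `gait_model`.
#' @param dataset The full `window_dataset` the model was trained on, or any
#'   compatible dataset.
#' @param windows Which windows to evaluate: `"test"` (default; the model's
#'   held-out split), `"train"`, or `"all"`. Ignored when `indices` is given
#'   or the model carries no split.
#' @param indices Optional explicit window indices.
#' @return A `phase_metrics` tibble: rows pre-stance, post-stance, pre-swing,
#'   post-swing, overall; columns `bin`, `n`, `rmse`, `r2`.
#' @export
evaluate_per_phase <- function(model, dataset,
                               windows = c("test", "train", "all"),
                               indices = NULL) {
  windows <- match.arg(windows)
  if (is.null(indices)) {
    indices <- if (!is.null(model$split) && windows != "all") {
      model$split[[if (windows == "test") "test" else "train"]]
    } else {
      seq_len(n_windows(dataset))
    }
  }
  if (length(indices) < 1L) abort("empty evaluation set")
  preds <- predict_phase(model, dataset[indices])
  phase_metrics_table(preds$phase_true, preds$phase_pred)
}

#' @rdname evaluate_per_phase
#' @param phase_true,phase_pred Numeric vectors of true and predicted phases
#'   in percent (for computing the table directly from predictions).
#' @export
phase_metrics_table <- function(phase_true, phase_pred) {
  stopifnot(length(phase_true) == length(phase_pred))
  bins <- assign_phase_bin(phase_true)
  per_bin <- lapply(phase_bin_levels(), function(b) {
    sel <- bins == b
    n <- sum(sel)
    tibble::tibble(
      bin = b, n = n,
      rmse = if (n >= 2L) rmse(phase_true[sel], phase_pred[sel]) else NA_real_,
      r2 = if (n >= 2L && var(phase_true[sel]) > 0) {
        r2(phase_true[sel], phase_pred[sel])
      } else {
        NA_real_
      }
    )
  })
  overall <- tibble::tibble(
    bin = "overall", n = length(phase_true),
    rmse = rmse(phase_true, phase_pred),
    r2 = if (var(phase_true) > 0) r2(phase_true, phase_pred) else NA_real_
  )
  out <- dplyr::bind_rows(c(per_bin, list(overall)))
  class(out) <- c("phase_metrics", class(out))
  out
}
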