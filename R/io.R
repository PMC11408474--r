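#' Read and write sensor recordings
#'
#' Two on-disk forms are supported. The delimited-text form is a CSV with
#' one header row of unique channel names and one column per channel; the
#' sampling rate, the channel-to-modality map and (optionally) the name of
#' the foot-pressure column live in a YAML sidecar (`<path>.yaml` by
#' default). The bundle form is a single self-describing binary file
#' (arrays plus metadata) for compact storage of long recordings.
#'
#' @param path File path. For `format = "csv"`, the sidecar is
#'   `paste0(path, ".yaml")` unless `sidecar` is given.
#' @param format `"csv"` or `"bundle"`.
#' @param sidecar Optional explicit sidecar path (CSV format only).
#' @return A [gait_recording()].
#' @export
read_recording <- function(path, format = c("csv", "bundle"), sidecar = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "bundle") {
    obj <- readRDS(path)
    if (!all(c("signals", "rate_hz", "modality") %in% names(obj))) {
      abort("bundle is missing recording fields")
    }
    return(gait_recording(obj$signals, obj$rate_hz, obj$modality,
                          obj$foot_pressure))
  }
  sidecar <- sidecar %||% paste0(path, ".yaml")
  if (!file.exists(sidecar)) {
    abort(paste0("missing sidecar config: ", sidecar))
  }
  meta <- yaml::read_yaml(sidecar)
  if (is.null(meta$rate_hz)) abort("sidecar missing required field rate_hz")
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (anyDuplicated(header)) {
    abort(paste0("duplicate column name in header: ",
                 header[duplicated(header)][1]))
  }
  tab <- utils::read.csv(path, check.names = FALSE)
  n_fields <- utils::count.fields(path, sep = ",")
  if (any(n_fields != length(header))) {
    abort(sprintf("ragged row at line %d: expected %d fields, found %d",
                  which(n_fields != length(header))[1], length(header),
                  n_fields[n_fields != length(header)][1]))
  }
  pressure_col <- meta$pressure_col
  pressure <- NULL
  if (!is.null(pressure_col)) {
    if (!pressure_col %in% names(tab)) {
      abort(paste0("pressure column not found: ", pressure_col))
    }
    pressure <- tab[[pressure_col]]
    tab[[pressure_col]] <- NULL
  }
  modality <- unlist(meta$modality)
  gait_recording(tab, meta$rate_hz, modality, pressure)
}

#' @rdname read_recording
#' @param recording A [gait_recording()].
#' @export
write_recording <- function(recording, path, format = c("csv", "bundle"),
                            sidecar = NULL) {
  stopifnot(inherits(recording, "gait_recording"))
  format <- match.arg(format)
  if (format == "bundle") {
    saveRDS(list(signals = recording$signals, rate_hz = recording$rate_hz,
                 modality = recording$modality,
                 foot_pressure = recording$foot_pressure),
            path)
    return(invisible(path))
  }
  tab <- recording$signals
  meta <- list(rate_hz = recording$rate_hz,
               modality = as.list(recording$modality))
  if (!is.null(recording$foot_pressure)) {
    tab <- dplyr::mutate(tab, foot_pressure = recording$foot_pressure)
    meta$pressure_col <- "foot_pressure"
  }
  utils::write.csv(tab, path, row.names = FALSE)
  yaml::write_yaml(meta, sidecar %||% paste0(path, ".yaml"))
  invisible(path)
}

#' Write and re-read result tables
#'
#' Delimited-text serialisation for [phase_metrics_table()] tables and
#' [channel_weights()] reports with a fixed column order; re-reading
#' reproduces values at full precision.
#'
#' @param table A `phase_metrics` or `channel_weight_report` tibble (or any
#'   data frame).
#' @param path Output CSV path.
#' @export
write_report <- function(table, path) {
  stopifnot(is.data.frame(table))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}

#' Model checkpoints
#'
#' A checkpoint is a single file holding the model class, configuration,
#' parameters, normalisation statistics and training history. Loading
#' validates every parameter shape against the embedded configuration.
#'
#' @param model A `gait_model`.
#' @param path Checkpoint path.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "gait_model"))
  saveRDS(list(class = class(model), model = unclass(model)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  obj <- readRDS(path)
  model <- structure(obj$model, class = obj$class)
  if (inherits(model, "ptt_model")) {
    ref <- with_preserved_seed(ptt_init_params(model$config))
    check_same_shapes(ref, model$params)
  }
  model
}

with_preserved_seed <- function(expr) {
  local_seed(0L)
  expr
}

check_same_shapes <- function(ref, got, path = "params") {
  if (is.list(ref)) {
    if (!is.list(got) || length(ref) != length(got)) {
      abort(paste0("checkpoint shape mismatch at ", path))
    }
    for (nm in seq_along(ref)) {
      check_same_shapes(ref[[nm]], got[[nm]],
                        paste0(path, "$", names(ref)[nm] %||% nm))
    }
  } else {
    dr <- dim(ref) %||% length(ref)
    dg <- dim(got) %||% length(got)
    if (!identical(as.integer(dr), as.integer(dg))) {
      abort(paste0("checkpoint shape mismatch at ", path))
    }
    if (any(!is.finite(got))) abort(paste0("non-finite parameters at ", path))
  }
  invisible(TRUE)
}

#' Run the full synthetic pipeline end to end
#'
#' simulate -> label -> window -> train -> evaluate -> explain ->
#' select-channels, writing every artifact under `out_dir` and returning a
#' manifest. One global seed fans out to stage-specific derived seeds so
#' stages stay individually reproducible.
#'
#' @param out_dir Output directory (created if needed).
#' @param spec A [synthetic_spec()]; its seed is re-derived from `seed`.
#' @param model_config A [ptt_config()] (channel count must match `spec`).
#' @param train_cfg A [train_config()].
#' @param window_len,stride Windowing parameters.
#' @param labels Label source passed to [generate_dataset()].
#' @param select Named integer vector of per-modality selection counts for
#'   the channel-selection stage, or `NULL` to select half the channels of
#'   each available modality.
#' @param seed Global pipeline seed.
#' @param verbose Log each stage.
#' @return List with `manifest` (tibble of stage, path) and `results`
#'   (metrics table, weight report, selection).
#' @export
run_pipeline <- function(out_dir, spec, model_config, train_cfg,
                         window_len = 100L, stride = 1L,
                         labels = "pressure", select = NULL,
                         seed = 1L, verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) if (verbose) message(sprintf(...))
  paths <- character(0)
  stage <- character(0)
  emit <- function(st, p) {
    stage <<- c(stage, st)
    paths <<- c(paths, p)
  }
  # stage seeds derived from the one global seed
  seeds <- seed + seq_len(3L) * 1000L
  spec$seed <- seeds[1]

  log_stage("simulate: %d strides, %d channels, seed %d",
            spec$n_strides, nrow(spec$channels), spec$seed)
  gen <- generate_recording(spec)
  rec_path <- file.path(out_dir, "recording.csv")
  write_recording(gen$recording, rec_path)
  emit("simulate", rec_path)

  log_stage("label + window: L=%d stride=%d (%s labels)", window_len, stride,
            labels)
  ds <- generate_dataset(spec, window_len, stride, labels = labels)

  log_stage("train: %d epochs, lr %g, seed %d", train_cfg$epochs,
            train_cfg$learning_rate, seeds[2])
  train_cfg$seed <- seeds[2]
  model <- ptt_model(model_config, seed = seeds[3])
  fit <- train_model(model, ds, train_cfg)
  ckpt_path <- file.path(out_dir, "checkpoint.rds")
  save_checkpoint(fit, ckpt_path)
  emit("train", ckpt_path)

  metrics <- evaluate_per_phase(fit, ds, windows = "test")
  metrics_path <- file.path(out_dir, "metrics.csv")
  write_report(metrics, metrics_path)
  emit("evaluate", metrics_path)

  report <- channel_weights(fit, ds[fit$split$test])
  report_path <- file.path(out_dir, "channel_weights.csv")
  write_report(report, report_path)
  emit("explain", report_path)

  if (is.null(select)) {
    mods <- unique(report$modality)
    select <- setNames(
      vapply(mods, function(m) max(1L, sum(report$modality == m) %/% 2L),
             integer(1)),
      mods)
  }
  sel <- select_top_channels(report, select)
  sel_path <- file.path(out_dir, "selection.yaml")
  yaml::write_yaml(list(source_spec = sel$source_spec,
                        selected = as.list(sel$selected),
                        k_per_modality = as.list(sel$k_per_modality),
                        seed = seed),
                   sel_path)
  emit("select-channels", sel_path)

  list(manifest = tibble::tibble(stage = stage, path = paths),
       results = list(metrics = metrics, weights = report, selection = sel))
}
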