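# End-to-end orchestration: simulate -> normalize/rescale -> segment/label/
# balance -> split -> rasterize -> resize -> train -> predict -> evaluate.
# All randomness flows from one master seed through derive_seed(), so every
# stage is independently re-runnable and the whole run is reproducible.

#' Pipeline configuration
#'
#' One nested configuration covering every stage. The defaults are the
#' full-scale study conditions (ten 200-s recordings at 20 kHz, 3.3 Hz firing
#' per class, 56-sample windows, raster resolution 0.0005 with 20 dummy
#' columns, the full 320 x 320 network trained 20 epochs); see
#' [desk_scale_config()] for the reduced configuration used in examples and
#' acceptance runs.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param simulation list of [simulation_config()] arguments (any subset).
#' @param window_len window length in samples.
#' @param cap_ratio noise-class cap passed to [balance_noise()].
#' @param train_fraction,shuffle split parameters (see [split_windows()]).
#' @param raster list of [raster_config()] arguments.
#' @param model list of [cnn_config()] arguments; `input_size` is also the
#'   [resize_for_model()] target.
#' @param write_images write every rasterized window as PNG when an output
#'   directory is given (off by default; image sets are large).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            simulation = list(),
                            window_len = 56L,
                            cap_ratio = 1.2,
                            train_fraction = 0.30,
                            shuffle = TRUE,
                            raster = list(),
                            model = list(),
                            write_images = FALSE) {
  structure(list(seed = as.integer(seed), simulation = simulation,
                 window_len = as.integer(window_len), cap_ratio = cap_ratio,
                 train_fraction = train_fraction, shuffle = shuffle,
                 raster = raster, model = model,
                 write_images = isTRUE(write_images)),
            class = "pipeline_config")
}

#' Desk-scale pipeline configuration
#'
#' The reduced problem size used for the end-to-end evaluation on one CPU:
#' two 200-s recordings at one SNR (about 1,300 windows per spike class),
#' raster resolution 0.005 with 4 dummy columns, 64 x 64 model input with 16
#' feature maps per convolution stage, 10 training epochs. Data-generating
#' conditions (sampling rate, firing rate, window length, split fraction)
#' are unchanged from the full-scale defaults.
#'
#' @param snr signal-to-noise ratio of the simulated recordings.
#' @param seed master seed.
#' @return a [pipeline_config()].
#' @export
desk_scale_config <- function(snr = 2.0, seed = 1L) {
  pipeline_config(
    seed = seed,
    simulation = list(snr = snr, n_recordings = 2L),
    raster = list(resolution = 0.005, dummy = 4L),
    model = list(input_size = c(64L, 64L),
                 conv_maps = c(16L, 16L, 16L, 16L, 16L),
                 epochs = 10L))
}

#' Write / read a pipeline configuration as YAML
#'
#' Round-trips losslessly, including custom spike-template parameter sets.
#'
#' @param cfg a [pipeline_config()].
#' @param path YAML file path.
#' @return `path` invisibly; the reader returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  x <- unclass(cfg)
  if (!is.null(x$simulation$templates))
    x$simulation$templates <- lapply(x$simulation$templates, unclass)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$simulation$templates))
    x$simulation$templates <- lapply(x$simulation$templates, function(p)
      spike_params(p$amplitude, p$tau1, p$tau2, p$tau_ph, p$class_id))
  do.call(pipeline_config, x)
}

log_stage <- function(verbose, stage, fmt, ...) {
  if (verbose)
    message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ",
            sprintf(fmt, ...))
}

#' Run the full pipeline
#'
#' Executes simulate, normalize/rescale, segment/label, balance, split,
#' rasterize/resize, train, predict and evaluate, returning the evaluation
#' of the held-out test partition. Fully reproducible from
#' (configuration, seed). With `out_dir` set, intermediate artifacts
#' (recordings, window-set CSVs, split manifest, training history, model
#' checkpoint, report) are written to disk and indexed in
#' `manifest.json`.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir optional artifact directory (created if missing).
#' @param verbose log stage-tagged progress lines.
#' @return list with `report` ([metrics_report()]), `confusion`, `model`,
#'   `history`, `class_counts`, `split_sizes`, `config`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  seed <- cfg$seed
  artifacts <- character(0)
  save_artifact <- function(p) artifacts <<- c(artifacts, p)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  # --- simulate ------------------------------------------------------------
  sim_args <- cfg$simulation
  sim_args$seed <- derive_seed(seed, "simulate")
  sim <- do.call(simulation_config, sim_args)
  log_stage(verbose, "simulate", "%d recording(s), %g s @ %g Hz, snr = %g",
            sim$n_recordings, sim$duration, sim$fs, sim$snr)
  sets <- vector("list", sim$n_recordings)
  for (i in seq_len(sim$n_recordings)) {
    rec <- simulate_recording(sim, recording_id = i)
    if (!is.null(out_dir)) {
      p <- file.path(out_dir, sprintf("recording-%02d", i))
      write_recording(rec, p)
      save_artifact(paste0(p, ".samples.bin"))
    }
    rec <- normalize_recording(rec)
    sets[[i]] <- segment_windows(rec, cfg$window_len, recording_id = i)
  }
  ws <- bind_window_sets(sets)
  log_stage(verbose, "segment", "%d windows of length %d",
            nrow(ws$values), ws$n)

  # --- balance + split -----------------------------------------------------
  ws <- balance_noise(ws, cfg$cap_ratio, seed = derive_seed(seed, "balance"))
  cnt <- class_counts(ws)
  log_stage(verbose, "balance", "%s",
            paste(names(cnt), as.integer(cnt), sep = "=", collapse = " "))
  sp <- split_windows(ws, cfg$train_fraction, seed = derive_seed(seed, "split"),
                      shuffle = cfg$shuffle)
  log_stage(verbose, "split", "train %d / test %d",
            nrow(sp$train$values), nrow(sp$test$values))
  if (!is.null(out_dir)) {
    write_window_set(sp$train, file.path(out_dir, "train-windows.csv"))
    write_window_set(sp$test, file.path(out_dir, "test-windows.csv"))
    jsonlite::write_json(
      list(seed = seed, train_fraction = cfg$train_fraction,
           counts = as.list(as.integer(cnt)),
           train = nrow(sp$train$values), test = nrow(sp$test$values)),
      file.path(out_dir, "split-manifest.json"), auto_unbox = TRUE,
      digits = NA)
    save_artifact(file.path(out_dir, c("train-windows.csv",
                                       "test-windows.csv",
                                       "split-manifest.json")))
  }

  # --- rasterize + resize --------------------------------------------------
  rcfg <- do.call(raster_config, cfg$raster)
  model_args <- cfg$model
  input_size <- model_args$input_size %||% c(320L, 320L)
  log_stage(verbose, "rasterize", "r = %g, d = %d, resize to %d x %d",
            rcfg$resolution, rcfg$dummy, input_size[1], input_size[2])
  x_train <- rasterize_windows(sp$train, rcfg, target = input_size)
  x_test <- rasterize_windows(sp$test, rcfg, target = input_size)
  if (!is.null(out_dir) && cfg$write_images) {
    img_dir <- file.path(out_dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    imgs <- rasterize_windows(sp$test, rcfg)
    for (i in seq_along(imgs))
      write_raster_image(imgs[[i]],
                         file.path(img_dir, sprintf("test-%05d.png", i)))
    save_artifact(img_dir)
  }

  # --- train ---------------------------------------------------------------
  model_args$n_classes <- model_args$n_classes %||% length(unique(ws$label))
  model_args$seed <- derive_seed(seed, "model")
  mcfg <- do.call(cnn_config, model_args)
  model <- build_model(mcfg, classes = sort(unique(ws$label)))
  log_stage(verbose, "train", "%d parameters, %d epochs, batch %d, lr %g",
            count_parameters(model), mcfg$epochs, mcfg$batch_size,
            mcfg$learning_rate)
  model <- train_cnn(model, x_train, attr(x_train, "labels"),
                     verbose = verbose)
  if (!is.null(out_dir)) {
    utils::write.csv(model$history, file.path(out_dir, "history.csv"),
                     row.names = FALSE)
    write_model(model, file.path(out_dir, "model.rds"))
    save_artifact(file.path(out_dir, c("history.csv", "model.rds")))
  }

  # --- evaluate ------------------------------------------------------------
  pred <- predict(model, x_test)
  cm <- confusion_matrix(attr(x_test, "labels"), pred$label,
                         classes = model$classes)
  report <- metrics_report(cm)
  log_stage(verbose, "evaluate", "test accuracy %.2f%%",
            round_half_up(report$accuracy, 2))
  if (!is.null(out_dir)) {
    write_metrics_report(report, file.path(out_dir, "report"))
    save_artifact(file.path(out_dir, c("report.csv", "report.json")))
    jsonlite::write_json(list(seed = seed, artifacts = artifacts),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(report = report, confusion = cm, model = model,
       history = model$history, class_counts = cnt,
       split_sizes = c(train = nrow(sp$train$values),
                       test = nrow(sp$test$values)),
       config = cfg)
}
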