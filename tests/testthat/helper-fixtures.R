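# Small fixtures built in code.

# A hand-built normalized recording: values already in [0, 1], with optional
# annotations, for exercising segmentation without running the simulator.
toy_recording <- function(samples, annotations = NULL, fs = 20000,
                          support_len = 56L) {
  structure(list(samples = samples, fs = fs, snr = Inf, seed = 0L,
                 annotations = annotations %||%
                   data.frame(time_index = integer(0), class_id = integer(0)),
                 noise_sd = 0, support_len = support_len),
            class = "spike_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Straight-line rasterization oracle: for each major-axis coordinate the
# minor-axis pixel of the ideal real line, rounded to nearest (ties noted).
ideal_line_deviation <- function(pts, x0, y0, x1, y1) {
  dx <- x1 - x0; dy <- y1 - y0
  if (abs(dx) >= abs(dy)) {
    ideal <- y0 + (pts[, "x"] - x0) * dy / ifelse(dx == 0, 1, dx)
    abs(pts[, "y"] - ideal)
  } else {
    ideal <- x0 + (pts[, "y"] - y0) * dx / dy
    abs(pts[, "x"] - ideal)
  }
}

# Tiny pipeline configuration used by smoke/determinism tests.
tiny_pipeline_config <- function(seed = 11) {
  pipeline_config(
    seed = seed,
    simulation = list(duration = 5, n_recordings = 1, snr = 4),
    raster = list(resolution = 0.01, dummy = 2),
    model = list(input_size = c(32L, 32L), conv_maps = c(4L, 4L, 4L, 4L, 8L),
                 epochs = 2L))
}
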