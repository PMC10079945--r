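# Rasterization: quantize a [0,1]-valued window onto a binary pixel grid and
# join consecutive sample pixels with Bresenham's integer line algorithm.

#' Rasterization configuration
#'
#' @param resolution amplitude units per pixel row `r` (0 < r <= 1 and 1/r an
#'   integer; default 0.0005 gives 2,001 rows for amplitudes in \[0, 1\]).
#' @param dummy count `d` of empty "dummy" pixel columns inserted between
#'   consecutive real samples (default 20), so the polyline renders as a
#'   smooth curve; sample `i` (0-based) sits at column `i * (d + 1)`.
#' @param polarity pixel value used for signal pixels (background is 0).
#' @return an object of class `raster_config`. Row 0 is the image top and
#'   represents amplitude 1 (top-left origin).
#' @export
raster_config <- function(resolution = 0.0005, dummy = 20L, polarity = 1L) {
  if (!is_scalar_num(resolution) || resolution <= 0 || resolution > 1)
    stop("`resolution` must be in (0, 1]")
  if (abs(1 / resolution - round(1 / resolution)) > 1e-9)
    stop("1/resolution must be an integer")
  if (!is_scalar_num(dummy) || dummy < 0) stop("`dummy` must be >= 0")
  structure(list(resolution = resolution, dummy = as.integer(dummy),
                 polarity = as.integer(polarity)),
            class = "raster_config")
}

#' Bresenham's line algorithm
#'
#' Integer-only rasterization of the straight line between two pixel
#' positions, valid in all octants. The decision variable starts at
#' `2*db - da` (da, db the absolute major/minor-axis spans) and is updated
#' by integer adds only: `+2*db - 2*da` after a diagonal step (taken when the
#' decision is >= 0, i.e. ties break toward the diagonal), `+2*db` after an
#' axis step. For steep lines the roles of the axes are swapped; steps use
#' the sign of each axis span.
#'
#' @param x0,y0,x1,y1 integer endpoint coordinates (any sign, any octant).
#' @return integer matrix with columns `x`, `y`: first row `(x0, y0)`, last
#'   row `(x1, y1)`, exactly `max(|dx|, |dy|) + 1` rows, consecutive pixels
#'   8-connected, one pixel per major-axis coordinate.
#' @export
bresenham_line <- function(x0, y0, x1, y1) {
  x0 <- as.integer(x0); y0 <- as.integer(y0)
  x1 <- as.integer(x1); y1 <- as.integer(y1)
  dx <- x1 - x0; dy <- y1 - y0
  sx <- if (dx >= 0L) 1L else -1L
  sy <- if (dy >= 0L) 1L else -1L
  adx <- abs(dx); ady <- abs(dy)
  steep <- ady > adx
  da <- if (steep) ady else adx   # major-axis span
  db <- if (steep) adx else ady   # minor-axis span
  npt <- da + 1L
  px <- integer(npt); py <- integer(npt)
  x <- x0; y <- y0
  nabla <- 2L * db - da
  for (i in seq_len(npt)) {
    px[i] <- x; py[i] <- y
    if (i == npt) break
    if (nabla >= 0L) {            # diagonal move (ties included)
      if (steep) x <- x + sx else y <- y + sy
      nabla <- nabla + 2L * db - 2L * da
    } else {
      nabla <- nabla + 2L * db
    }
    if (steep) y <- y + sy else x <- x + sx
  }
  cbind(x = px, y = py)
}

#' Rasterize one window into a binary image
#'
#' Sample `i` (0-based) of a \[0, 1\]-valued window is quantized to pixel
#' `(col, row) = (i * (d + 1), round_half_up((1 - value_i) / r))` — row 0 is
#' the top of the image and represents amplitude 1 — and every consecutive
#' pair of sample pixels is joined with [bresenham_line()]. The grid has
#' `1/r + 1` rows and `(n - 1) * (d + 1) + 1` columns.
#'
#' @param w numeric vector in \[0, 1\] (a window's values), or a one-row slice
#'   of a `window_set`.
#' @param cfg a [raster_config()].
#' @param label optional class label carried in the result.
#' @param source_id optional window identifier.
#' @return an object of class `raster_image`: integer `grid` (H x W of
#'   0/polarity), `config`, `label`, `source_id`.
#' @export
window_to_image <- function(w, cfg = raster_config(), label = NA_character_,
                            source_id = NA) {
  stopifnot(inherits(cfg, "raster_config"))
  if (!is.numeric(w) || length(w) < 1) stop("`w` must be a numeric vector")
  if (any(!is.finite(w)) || min(w) < 0 || max(w) > 1)
    stop("window values must lie in [0, 1]")
  r <- cfg$resolution; d <- cfg$dummy
  H <- as.integer(round(1 / r)) + 1L
  n <- length(w)
  W <- (n - 1L) * (d + 1L) + 1L
  rows0 <- as.integer(round_half_up((1 - w) / r))  # 0-based, 0 = top
  cols0 <- (seq_len(n) - 1L) * (d + 1L)
  grid <- matrix(0L, H, W)
  if (n == 1L) {
    grid[rows0[1] + 1L, 1L] <- cfg$polarity
  } else {
    for (i in seq_len(n - 1L)) {
      pts <- bresenham_line(cols0[i], rows0[i], cols0[i + 1L], rows0[i + 1L])
      grid[pts[, "y"] + 1L + H * pts[, "x"]] <- cfg$polarity
    }
  }
  structure(list(grid = grid, config = cfg, label = label,
                 source_id = source_id),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image> %d x %d, %d signal pixels, label = %s\n",
              nrow(x$grid), ncol(x$grid), sum(x$grid != 0),
              as.character(x$label)))
  invisible(x)
}

#' Write / read a rasterized window as a bilevel PNG
#'
#' Lossless round trip: signal pixels are written white (1) on black (0).
#' Label, source id and the raster configuration travel in a JSON sidecar
#' `<path>.json`.
#'
#' @param img a `raster_image`.
#' @param path PNG path.
#' @return `path` invisibly; the reader returns a `raster_image`.
#' @export
write_raster_image <- function(img, path) {
  stopifnot(inherits(img, "raster_image"))
  png::writePNG((img$grid != 0) * 1, path)
  jsonlite::write_json(
    list(label = img$label, source_id = img$source_id,
         resolution = img$config$resolution, dummy = img$config$dummy,
         polarity = img$config$polarity,
         height = nrow(img$grid), width = ncol(img$grid)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_raster_image
#' @export
read_raster_image <- function(path) {
  g <- tryCatch(png::readPNG(path),
                error = function(e) stop("not a readable PNG raster: ", path))
  if (length(dim(g)) == 3) g <- g[, , 1]
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  else list(label = NA_character_, source_id = NA, resolution = NULL,
            dummy = NULL, polarity = 1L)
  cfg <- raster_config(
    resolution = meta$resolution %||% (1 / (nrow(g) - 1)),
    dummy = meta$dummy %||% 0L,
    polarity = meta$polarity %||% 1L)
  grid <- matrix(as.integer(g > 0.5) * cfg$polarity, nrow(g), ncol(g))
  structure(list(grid = grid, config = cfg, label = meta$label,
                 source_id = meta$source_id),
            class = "raster_image")
}

#' Downscale a binary raster by block max-pooling
#'
#' Input row `i` (0-based) maps to output row `floor(i * target_h / H)` and
#' likewise for columns; an output pixel is lit when *any* covered input
#' pixel is lit. Max-pooling (not interpolation) preserves the one-pixel-wide
#' signal trace that bilinear resampling would wash out.
#'
#' @param img a `raster_image` or a binary matrix.
#' @param target integer `c(height, width)`, each <= the input size and
#'   >= 32 when used as model input.
#' @return numeric matrix of 0/1 with dimensions `target`.
#' @export
resize_for_model <- function(img, target) {
  g <- if (inherits(img, "raster_image")) img$grid else img
  stopifnot(is.matrix(g), length(target) == 2)
  H <- nrow(g); W <- ncol(g)
  th <- as.integer(target[1]); tw <- as.integer(target[2])
  if (th > H || tw > W)
    stop("resize_for_model() only downscales: target exceeds image size")
  rg <- floor((seq_len(H) - 1) * th / H)
  cg <- floor((seq_len(W) - 1) * tw / W)
  m <- rowsum(g, rg, reorder = TRUE)            # th x W
  m <- t(rowsum(t(m), cg, reorder = TRUE))      # th x tw
  dimnames(m) <- NULL
  (m > 0) * 1
}

#' Rasterize a whole window set into a model-ready image array
#'
#' @param ws a `window_set` with values in \[0, 1\].
#' @param cfg a [raster_config()].
#' @param target optional `c(height, width)`; when given, each image is
#'   downscaled with [resize_for_model()] and the result is a single
#'   `H x W x 1 x n` array (the network's input layout), else a list of
#'   `raster_image` objects.
#' @return array or list (see `target`), with a `labels` attribute.
#' @export
rasterize_windows <- function(ws, cfg = raster_config(), target = NULL) {
  stopifnot(inherits(ws, "window_set"))
  nb <- nrow(ws$values)
  if (is.null(target)) {
    out <- vector("list", nb)
    for (i in seq_len(nb))
      out[[i]] <- window_to_image(ws$values[i, ], cfg, label = ws$label[i],
                                  source_id = i)
    attr(out, "labels") <- ws$label
    return(out)
  }
  th <- as.integer(target[1]); tw <- as.integer(target[2])
  arr <- array(0, c(th, tw, 1L, nb))
  for (i in seq_len(nb)) {
    img <- window_to_image(ws$values[i, ], cfg)
    arr[, , 1L, i] <- resize_for_model(img$grid, c(th, tw))
  }
  attr(arr, "labels") <- ws$label
  arr
}
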