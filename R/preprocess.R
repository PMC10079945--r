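# Normalization, windowing, labeling and train/test splitting.
# Pipeline order is fixed: l2_normalize -> rescale_unit_interval -> segment,
# so every emitted window lies in [0, 1] and is ready for rasterization.

#' Scale a sample vector to unit L2 norm
#'
#' @param x finite, nonzero numeric vector.
#' @return `x / sqrt(sum(x^2))`, Euclidean norm 1.
#' @export
l2_normalize <- function(x) {
  if (!is.numeric(x) || length(x) == 0) stop("`x` must be a numeric vector")
  if (!all(is.finite(x))) stop("`x` must be finite")
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) stop("cannot L2-normalize the all-zero vector")
  x / nrm
}

#' Affine rescale to the unit interval
#'
#' Maps the whole vector so that its minimum hits 0 and its maximum hits 1.
#' Applied over a *whole recording* (not per window) so that relative
#' amplitudes between windows are preserved.
#'
#' @param y finite, non-constant numeric vector.
#' @return vector in \[0, 1\] attaining both bounds.
#' @export
rescale_unit_interval <- function(y) {
  if (!is.numeric(y) || length(y) == 0) stop("`y` must be a numeric vector")
  if (!all(is.finite(y))) stop("`y` must be finite")
  r <- range(y)
  if (r[1] == r[2]) stop("constant input: unit-interval rescale is undefined")
  (y - r[1]) / (r[2] - r[1])
}

#' Normalize a recording in place
#'
#' Convenience wrapper applying [l2_normalize()] then
#' [rescale_unit_interval()] to `rec$samples`.
#'
#' @param rec a `spike_recording`.
#' @return the recording with `samples` in \[0, 1\] and a `normalized` flag.
#' @export
normalize_recording <- function(rec) {
  stopifnot(inherits(rec, "spike_recording"))
  rec$samples <- rescale_unit_interval(l2_normalize(rec$samples))
  rec$normalized <- TRUE
  rec
}

#' Construct a window set
#'
#' @param values numeric matrix, one row per window.
#' @param label per-window class labels (length `nrow(values)`).
#' @param source optional provenance data.frame (`recording`, `start`,
#'   `center`); a placeholder is generated when omitted.
#' @return an object of class `window_set`.
#' @export
window_set <- function(values, label, source = NULL) {
  if (is.null(source))
    source <- data.frame(recording = NA_integer_,
                         start = rep(NA_integer_, nrow(values)),
                         center = NA_integer_)
  new_window_set(values, label, source)
}

new_window_set <- function(values, label, source) {
  stopifnot(is.matrix(values), nrow(values) == length(label),
            nrow(values) == nrow(source))
  structure(list(values = values, label = as.character(label),
                 source = source, n = ncol(values)),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of length %d\n", nrow(x$values), x$n))
  print(class_counts(x))
  invisible(x)
}

#' Per-class window tally
#' @param ws a `window_set`.
#' @return named integer vector of counts per label.
#' @export
class_counts <- function(ws) {
  stopifnot(inherits(ws, "window_set"))
  table(factor(ws$label))
}

#' Segment a normalized recording into labeled fixed-length windows
#'
#' Spike windows are centered on each ground-truth annotation (annotations
#' whose window would overrun a recording edge are dropped; windows overlapped
#' by a second annotation of a *different* class are discarded so each image
#' carries one shape). Noise windows are consecutive non-overlapping
#' `window_len` stretches that contain no part of any spike's support.
#'
#' @param rec a `spike_recording` whose samples are already normalized and
#'   rescaled to \[0, 1\] (see [normalize_recording()]).
#' @param window_len window length in samples (>= 2; 56 gives 2.8 ms at
#'   20 kHz).
#' @param recording_id identifier stored in each window's provenance.
#' @return a `window_set` with labels `"spike-<k>"` and `"noise"`, and a
#'   `source` data.frame (`recording`, `start`, `center`) of 1-based sample
#'   indices into the recording.
#' @export
segment_windows <- function(rec, window_len = 56L, recording_id = 1L) {
  stopifnot(inherits(rec, "spike_recording"))
  if (!is_scalar_num(window_len) || window_len < 2)
    stop("`window_len` must be >= 2")
  window_len <- as.integer(window_len)
  x <- rec$samples
  n <- length(x)
  if (window_len > n) stop("`window_len` exceeds the recording length")
  if (min(x) < 0 || max(x) > 1)
    stop("recording must be normalized and rescaled to [0, 1] first")

  ann <- rec$annotations
  half_sup <- (rec$support_len %||% window_len) %/% 2L
  co <- window_len %/% 2L  # 0-based center offset within a window

  starts <- integer(0); centers <- integer(0); labels <- character(0)
  if (nrow(ann) > 0) {
    sup_lo <- ann$time_index - half_sup
    sup_hi <- ann$time_index + half_sup
    for (i in seq_len(nrow(ann))) {
      s <- ann$time_index[i] - co
      e <- s + window_len - 1L
      if (s < 1L || e > n) next
      clash <- which(sup_hi >= s & sup_lo <= e & ann$class_id != ann$class_id[i])
      if (length(clash) > 0) next
      starts <- c(starts, s); centers <- c(centers, ann$time_index[i])
      labels <- c(labels, paste0("spike-", ann$class_id[i]))
    }
  }

  # noise stretches: tile the recording, keep annotation-free tiles
  tile_starts <- seq.int(1L, n - window_len + 1L, by = window_len)
  if (nrow(ann) > 0) {
    keep <- vapply(tile_starts, function(s) {
      e <- s + window_len - 1L
      !any(ann$time_index + half_sup >= s & ann$time_index - half_sup <= e)
    }, logical(1))
    tile_starts <- tile_starts[keep]
  }
  starts <- c(starts, tile_starts)
  centers <- c(centers, tile_starts + co)
  labels <- c(labels, rep("noise", length(tile_starts)))

  vals <- matrix(0, length(starts), window_len)
  for (i in seq_along(starts))
    vals[i, ] <- x[starts[i]:(starts[i] + window_len - 1L)]
  new_window_set(vals, labels,
                 data.frame(recording = recording_id, start = starts,
                            center = centers))
}

#' Concatenate window sets
#' @param ... `window_set` objects with equal window length.
#' @return one combined `window_set`.
#' @export
bind_window_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !inherits(sets[[1]], "window_set"))
    sets <- sets[[1]]
  stopifnot(length(sets) >= 1,
            all(vapply(sets, inherits, logical(1), "window_set")))
  lens <- vapply(sets, function(s) s$n, numeric(1))
  if (length(unique(lens)) != 1) stop("window lengths differ")
  new_window_set(do.call(rbind, lapply(sets, `[[`, "values")),
                 unlist(lapply(sets, `[[`, "label")),
                 do.call(rbind, lapply(sets, `[[`, "source")))
}

subset_window_set <- function(ws, idx) {
  new_window_set(ws$values[idx, , drop = FALSE], ws$label[idx],
                 ws$source[idx, , drop = FALSE])
}

#' Cap the noise class so classes stay nearly balanced
#'
#' Randomly subsamples (seeded) the `"noise"` windows so their count does not
#' exceed `cap_ratio` times the mean spike-class count; all other classes are
#' untouched. A no-op when the noise class is already under the cap.
#'
#' @param ws a `window_set` containing a `"noise"` class.
#' @param cap_ratio maximum noise/mean-spike-count ratio (default 1.2).
#' @param seed RNG seed for the subsample.
#' @return the capped `window_set`.
#' @export
balance_noise <- function(ws, cap_ratio = 1.2, seed = 1L) {
  stopifnot(inherits(ws, "window_set"))
  cnt <- class_counts(ws)
  if (!"noise" %in% names(cnt)) return(ws)
  spike_cnt <- cnt[names(cnt) != "noise"]
  if (length(spike_cnt) == 0) return(ws)
  cap <- floor(cap_ratio * mean(spike_cnt))
  noise_idx <- which(ws$label == "noise")
  if (length(noise_idx) <= cap) return(ws)
  set.seed(as.integer(seed))
  keep_noise <- sort(sample(noise_idx, cap))
  subset_window_set(ws, sort(c(which(ws$label != "noise"), keep_noise)))
}

#' Shuffled train/test split
#'
#' Seeded permutation of all windows followed by a disjoint, exhaustive
#' partition with `floor(train_fraction * total)` training windows.
#'
#' @param ws a non-empty `window_set`.
#' @param train_fraction fraction in (0, 1), default 0.30.
#' @param seed RNG seed for the shuffle.
#' @param shuffle permute before splitting (default TRUE).
#' @return list with `window_set` elements `train` and `test`.
#' @export
split_windows <- function(ws, train_fraction = 0.30, seed = 1L,
                          shuffle = TRUE) {
  stopifnot(inherits(ws, "window_set"))
  total <- nrow(ws$values)
  if (total == 0) stop("cannot split an empty window set")
  if (!is_scalar_num(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1)
    stop("`train_fraction` must be in (0, 1)")
  idx <- seq_len(total)
  if (shuffle) {
    set.seed(as.integer(seed))
    idx <- sample(idx)
  }
  n_train <- floor(train_fraction * total)
  list(train = subset_window_set(ws, idx[seq_len(n_train)]),
       test = subset_window_set(ws, idx[setdiff(seq_len(total), seq_len(n_train))]))
}

#' Write / read a window set as CSV
#'
#' One row per window: `n` value columns `X1..Xn`, a `label` column and
#' provenance columns (`recording`, `start`, `center`) — the same dialect as
#' the public epoch CSVs plus provenance.
#'
#' @param ws a `window_set`.
#' @param path CSV path.
#' @return `path` invisibly; the reader returns a `window_set`.
#' @export
write_window_set <- function(ws, path) {
  stopifnot(inherits(ws, "window_set"))
  df <- as.data.frame(ws$values)
  names(df) <- paste0("X", seq_len(ws$n))
  df$label <- ws$label
  df <- cbind(df, ws$source)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_window_set
#' @export
read_window_set <- function(path) {
  df <- utils::read.csv(path, check.names = TRUE)
  val_cols <- grep("^X[0-9]+$", names(df))
  src_cols <- intersect(c("recording", "start", "center"), names(df))
  new_window_set(as.matrix(df[, val_cols, drop = FALSE]), df$label,
                 df[, src_cols, drop = FALSE])
}

#' Turn an epoch table into a window set
#'
#' Epoch tables (synthetic or public EEG CSVs) are already windowed, so
#' segmentation is skipped; each row is L2-normalized and min-max rescaled
#' *per row* (rows come from different subjects/recordings, so no common
#' amplitude scale exists).
#'
#' @param df data.frame from [simulate_binary_epochs()] or
#'   [read_uci_epochs()]: feature columns plus integer label column `y`.
#' @return a `window_set` with labels `"seizure"` / `"non-seizure"`.
#' @export
epochs_to_window_set <- function(df) {
  stopifnot(is.data.frame(df), "y" %in% names(df))
  y <- df$y
  vals <- as.matrix(df[, setdiff(names(df), "y"), drop = FALSE])
  vals <- t(apply(vals, 1, function(r) rescale_unit_interval(l2_normalize(r))))
  new_window_set(vals,
                 ifelse(y == 1L, "seizure", "non-seizure"),
                 data.frame(recording = seq_len(nrow(vals)), start = 1L,
                            center = ncol(vals) %/% 2L))
}
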