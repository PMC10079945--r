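# Normalization, segmentation, balancing, splitting and window-set I/O.

test_that("l2_normalize scales to unit Euclidean norm", {
  expect_equal(l2_normalize(c(3, 4)), c(0.6, 0.8))
  expect_equal(l2_normalize(c(0, 1, 0)), c(0, 1, 0))
  set.seed(17)
  x <- rnorm(100)
  y <- l2_normalize(x)
  expect_equal(sqrt(sum(y^2)), 1, tolerance = 1e-12)
  expect_equal(y * sqrt(sum(x^2)), x)  # output proportional to input
  expect_error(l2_normalize(numeric(5)), "zero")
  expect_error(l2_normalize(c(1, NA)), "finite")
})

test_that("rescale_unit_interval maps the range onto [0, 1]", {
  expect_equal(rescale_unit_interval(c(-1, 0, 1)), c(0, 0.5, 1))
  v <- c(0, 0.25, 1)
  expect_equal(rescale_unit_interval(v), v)
  set.seed(2)
  x <- rnorm(50)
  y <- rescale_unit_interval(x)
  expect_equal(range(y), c(0, 1))
  expect_identical(order(y), order(x))
  expect_error(rescale_unit_interval(rep(2, 4)), "constant")
})

test_that("segmentation tiles annotation-free recordings into noise windows", {
  rec <- toy_recording(rescale_unit_interval(sin(1:560)))
  ws <- segment_windows(rec, 56)
  expect_equal(nrow(ws$values), 10L)
  expect_true(all(ws$label == "noise"))
  # window duration at 20 kHz
  expect_equal(ws$n / rec$fs, 0.0028)
})

test_that("spike windows are centered on their annotation", {
  x <- rescale_unit_interval(rnorm(560))
  rec <- toy_recording(x, data.frame(time_index = 280L, class_id = 2L))
  ws <- segment_windows(rec, 56)
  spike <- which(ws$label == "spike-2")
  expect_length(spike, 1L)
  expect_equal(ws$source$center[spike], 280L)
  expect_equal(ws$source$start[spike], 280L - 28L)
  # round trip: stored values equal the recording slice at the source indices
  for (i in seq_len(nrow(ws$values)))
    expect_equal(ws$values[i, ],
                 x[ws$source$start[i]:(ws$source$start[i] + 55L)])
  # no noise window overlaps the spike support
  noise <- ws$source$start[ws$label == "noise"]
  expect_true(all(noise + 55L < 280L - 28L | noise > 280L + 28L))
})

test_that("windows overlapping two different spike classes are discarded", {
  x <- rescale_unit_interval(rnorm(600))
  rec <- toy_recording(x, data.frame(time_index = c(280L, 300L),
                                     class_id = c(1L, 2L)),
                       support_len = 56L)
  ws <- segment_windows(rec, 56)
  expect_false(any(grepl("spike", ws$label)))
  # same-class neighbors are kept
  rec2 <- toy_recording(x, data.frame(time_index = c(280L, 300L),
                                      class_id = c(1L, 1L)),
                        support_len = 56L)
  ws2 <- segment_windows(rec2, 56)
  expect_equal(sum(ws2$label == "spike-1"), 2L)
})

test_that("edge annotations and bad window lengths are handled", {
  x <- rescale_unit_interval(rnorm(200))
  rec <- toy_recording(x, data.frame(time_index = c(5L, 100L),
                                     class_id = c(1L, 2L)))
  ws <- segment_windows(rec, 56)
  expect_equal(sum(grepl("spike", ws$label)), 1L)  # edge spike dropped
  expect_error(segment_windows(rec, 1), "window_len")
  expect_error(segment_windows(toy_recording(rnorm(100) + 5), 56), "\\[0, 1\\]")
})

test_that("balance_noise caps the noise class at the configured ratio", {
  vals <- matrix(runif(800 * 8), 800)
  ws <- window_set(vals, rep(c("spike-1", "spike-2", "spike-3", "noise"),
                             times = c(100, 100, 100, 500)))
  out <- balance_noise(ws, cap_ratio = 1.2, seed = 1)
  expect_equal(as.integer(class_counts(out)[["noise"]]), 120L)
  expect_equal(as.integer(class_counts(out)[["spike-1"]]), 100L)
  # already under the cap: untouched
  expect_identical(balance_noise(out, cap_ratio = 1.2, seed = 1), out)
})

test_that("split sizes follow floor(fraction x total) and partition cleanly", {
  ws <- window_set(matrix(runif(10 * 4), 10), rep("a", 10))
  sp <- split_windows(ws, 0.5, seed = 1)
  expect_equal(nrow(sp$train$values), 5L)
  expect_equal(nrow(sp$test$values), 5L)
  # disjoint and exhaustive on a labeled set
  ws2 <- window_set(matrix(seq_len(40), 20, 2), sprintf("w%02d", 1:20))
  sp2 <- split_windows(ws2, 0.3, seed = 7)
  expect_equal(sort(c(sp2$train$label, sp2$test$label)), sort(ws2$label))
  expect_length(intersect(sp2$train$label, sp2$test$label), 0L)
  # determinism
  sp3 <- split_windows(ws2, 0.3, seed = 7)
  expect_identical(sp2$train$label, sp3$train$label)
  expect_error(split_windows(ws, 1.5), "train_fraction")
})

test_that("window sets round-trip through CSV", {
  ws <- window_set(matrix(runif(12), 3, 4), c("noise", "spike-1", "noise"),
                   data.frame(recording = 1L, start = c(1L, 5L, 9L),
                              center = c(3L, 7L, 11L)))
  path <- file.path(withr::local_tempdir(), "ws.csv")
  write_window_set(ws, path)
  back <- read_window_set(path)
  expect_equal(back$values, ws$values, ignore_attr = TRUE)
  expect_equal(back$label, ws$label)
  expect_equal(back$source$start, ws$source$start)
})

test_that("epoch tables become per-row normalized window sets", {
  df <- simulate_binary_epochs(6, window_len = 50, seed = 3)
  ws <- epochs_to_window_set(df)
  expect_equal(nrow(ws$values), 12L)
  expect_setequal(unique(ws$label), c("seizure", "non-seizure"))
  expect_true(all(ws$values >= 0 & ws$values <= 1))
  expect_equal(apply(ws$values, 1, min), rep(0, 12))
  expect_equal(apply(ws$values, 1, max), rep(1, 12))
})
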