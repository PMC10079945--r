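# Layer-size arithmetic, network construction, training and prediction.

test_that("convolution and pooling size formulas match the standard arithmetic", {
  expect_equal(conv_output_size(320, 1, 3, 1), 320L)  # same-padding identity
  expect_equal(conv_output_size(10, 0, 1, 1), 10L)    # 1x1 kernel identity
  expect_equal(conv_output_size(5, 0, 3, 1), 3L)      # valid convolution
  expect_error(conv_output_size(2, 0, 5, 1), "too small")
  expect_equal(pool_output_size(320, 2, 2), 160L)
  expect_equal(pool_output_size(10, 2, 2), 5L)
  expect_error(pool_output_size(1, 2, 2), "smaller")
})

test_that("the default geometry flattens to 1600 units", {
  geom <- model_geometry(cnn_config())
  # five same-padded conv + 2x2 pool stages: 320 -> 160 -> 80 -> 40 -> 20 -> 10
  expect_equal(geom$height[geom$type == "pool"], c(160L, 80L, 40L, 20L, 10L))
  expect_equal(attr(geom, "flatten_size"), 1600L)
  m <- build_model(cnn_config())
  expect_equal(m$flatten_size, 1600L)
  # dataset-2 variant: two output classes
  m2 <- build_model(cnn_config(n_classes = 2L))
  out <- m2$layers[[length(m2$layers)]]
  expect_equal(nrow(out$W), 2L)
})

test_that("the default parameter count is a pure function of the config", {
  m <- build_model(cnn_config())
  # independent arithmetic: conv W+b per stage, batch-norm scale/shift,
  # FC and output layers
  expected <- (128 * 9 * 1 + 128) + (64 * 9 * 128 + 64) +
    (32 * 9 * 64 + 32) + (32 * 9 * 32 + 32) + 2 * 32 +
    (16 * 9 * 32 + 16) + (512 * 1600 + 512) + (4 * 512 + 4)
  expect_equal(count_parameters(m), expected)
  expect_equal(count_parameters(build_model(cnn_config())), expected)
})

test_that("forward tensor shapes equal the chained formula predictions", {
  cfg <- cnn_config(input_size = c(32L, 32L), conv_maps = c(4L, 4L, 4L, 4L, 8L),
                    fc_size = 16L, n_classes = 3L, seed = 2)
  m <- build_model(cfg, classes = c("a", "b", "c"))
  geom <- model_geometry(cfg)
  fwd <- rasterspike:::cnn_forward(m, array(runif(32 * 32 * 2), c(32, 32, 1, 2)),
                                   trace = TRUE)
  shp <- fwd$shapes
  conv_shapes <- shp[grep("^conv", names(shp))]
  pool_shapes <- shp[grep("^pool", names(shp))]
  for (l in 1:5) {
    g <- geom[geom$layer == paste0("conv", l), ]
    expect_equal(unname(conv_shapes[[l]]), c(g$height, g$width, g$channels))
    g <- geom[geom$layer == paste0("pool", l), ]
    expect_equal(unname(pool_shapes[[l]]), c(g$height, g$width, g$channels))
  }
  expect_equal(prod(shp[[grep("flatten", names(shp))]]),
               attr(geom, "flatten_size"))
  # softmax output: columns sum to one
  expect_equal(colSums(fwd$probs), rep(1, 2), tolerance = 1e-6)
})

test_that("inputs too small for five poolings are rejected", {
  expect_error(build_model(cnn_config(input_size = c(16L, 16L),
                                      conv_maps = c(2L, 2L, 2L, 2L, 2L))),
               "smaller|too small")
})

test_that("the network memorizes a separable two-image task", {
  set.seed(42)
  imgA <- matrix(0, 32, 32); imgA[8, 4:28] <- 1            # horizontal bar
  imgB <- matrix(0, 32, 32); imgB[4:28, 24] <- 1           # vertical bar
  x <- array(0, c(32, 32, 1, 100))
  for (i in 1:50) x[, , 1, i] <- imgA
  for (i in 51:100) x[, , 1, i] <- imgB
  labels <- rep(c("bar-h", "bar-v"), each = 50)
  cfg <- cnn_config(input_size = c(32L, 32L), conv_maps = c(4L, 4L, 4L, 4L, 8L),
                    fc_size = 32L, n_classes = 2L, epochs = 5L,
                    dropout_rate = 0.2, seed = 7)
  m <- train_cnn(build_model(cfg), x, labels)
  h <- m$history
  expect_equal(h$accuracy[nrow(h)], 1.0)                   # perfect overfit
  expect_lt(h$loss[nrow(h)], h$loss[1])                    # loss decreased
  # prediction is deterministic (dropout off) and correct on both images
  p1 <- predict(m, x[, , , c(1, 100), drop = FALSE])
  p2 <- predict(m, x[, , , c(1, 100), drop = FALSE])
  expect_identical(p1$prob, p2$prob)
  expect_equal(p1$label, c("bar-h", "bar-v"))
  expect_equal(rowSums(p1$prob), c(1, 1), tolerance = 1e-6)
  # duplicate inputs give identical outputs
  p3 <- predict(m, x[, , , c(1, 1), drop = FALSE])
  expect_identical(p3$prob[1, ], p3$prob[2, ])
})

test_that("training validates labels and shapes", {
  cfg <- cnn_config(input_size = c(32L, 32L), conv_maps = c(2L, 2L, 2L, 2L, 2L),
                    fc_size = 8L, n_classes = 3L, epochs = 1L, seed = 1)
  m <- build_model(cfg, classes = c("a", "b", "c"))
  x <- array(runif(32 * 32 * 4), c(32, 32, 1, 4))
  expect_warning(train_cnn(m, x, rep(c("a", "b"), 2)), "absent")
  expect_error(train_cnn(m, x, rep("a", 3)), "labels")
  expect_error(train_cnn(m, array(0, c(16, 16, 1, 2)), c("a", "b")),
               "input size")
  expect_error(predict(build_model(cfg), x), "train")
})

test_that("trained models survive a save/load round trip", {
  cfg <- cnn_config(input_size = c(32L, 32L), conv_maps = c(2L, 2L, 2L, 2L, 4L),
                    fc_size = 8L, n_classes = 2L, epochs = 1L, seed = 3)
  x <- array(runif(32 * 32 * 8), c(32, 32, 1, 8))
  m <- train_cnn(build_model(cfg), x, rep(c("a", "b"), 4))
  path <- file.path(withr::local_tempdir(), "model.rds")
  write_model(m, path)
  back <- read_model(path)
  expect_identical(predict(back, x)$prob, predict(m, x)$prob)
})
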