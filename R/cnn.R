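# Modified LeNet-5-style 2D CNN: five 3x3 convolution + max-pooling stages
# (128 feature maps in the first stage narrowing to 16 in the last, batch
# normalization between the fourth convolution and its pooling), a 512-unit
# fully connected layer with dropout, and a softmax output; trained with
# RMSprop on categorical cross-entropy.

#' Convolution output size
#'
#' The standard valid/padded convolution arithmetic
#' `floor((N + 2P - K)/S) + 1` for one spatial dimension.
#'
#' @param n_c input size (width or height).
#' @param p_c padding, `k_c` kernel size, `s_c` stride.
#' @param k_c,s_c see above.
#' @return integer output size (>= 1, else an error).
#' @export
conv_output_size <- function(n_c, p_c, k_c, s_c) {
  stopifnot(n_c >= 0, p_c >= 0, k_c >= 1, s_c >= 1)
  out <- floor((n_c + 2 * p_c - k_c) / s_c) + 1
  if (out < 1) stop("convolution output size < 1: layer too small")
  as.integer(out)
}

#' Pooling output size
#'
#' `floor((N - K)/S) + 1` for one spatial dimension.
#'
#' @param n_p input size; must be >= `k_p`.
#' @param k_p pool kernel size, `s_p` pool stride.
#' @param s_p see above.
#' @return integer output size.
#' @export
pool_output_size <- function(n_p, k_p, s_p) {
  stopifnot(k_p >= 1, s_p >= 1)
  if (n_p < k_p) stop("pooling input smaller than the pool kernel")
  as.integer(floor((n_p - k_p) / s_p) + 1)
}

#' Network configuration
#'
#' Defaults reproduce the reference architecture: 320 x 320 single-channel
#' input, five same-padded 3x3 convolutions with feature maps
#' 128-64-32-32-16, 2x2/stride-2 max pooling after each, batch normalization
#' between convolution 4 and pooling 4, a 1,600-unit flatten
#' (16 maps x 10 x 10), a 512-unit fully connected layer, dropout 0.5 and a
#' softmax output; RMSprop with learning rate 0.001, 20 epochs, batch size
#' 32. Every field is overridable, e.g. smaller inputs and feature-map counts
#' for desk-scale runs.
#'
#' @param input_size `c(height, width)` of the (single-channel) input.
#' @param conv_maps integer vector of length 5: feature maps per convolution.
#' @param kernel,pad,stride convolution kernel size / padding / stride.
#' @param pool_kernel,pool_stride pooling kernel size / stride.
#' @param batch_norm_after_conv index of the convolution followed by batch
#'   normalization (default 4).
#' @param fc_size fully connected layer width.
#' @param dropout_rate dropout probability on the fully connected layer.
#' @param n_classes output classes (4 for the spike task, 2 for the EEG task).
#' @param learning_rate,epochs,batch_size,rho RMSprop training parameters
#'   (`rho` is the squared-gradient decay).
#' @param seed RNG seed for weight initialization, shuffling and dropout.
#' @return an object of class `cnn_config`.
#' @export
cnn_config <- function(input_size = c(320L, 320L),
                       conv_maps = c(128L, 64L, 32L, 32L, 16L),
                       kernel = 3L, pad = 1L, stride = 1L,
                       pool_kernel = 2L, pool_stride = 2L,
                       batch_norm_after_conv = 4L,
                       fc_size = 512L, dropout_rate = 0.5,
                       n_classes = 4L, learning_rate = 0.001,
                       epochs = 20L, batch_size = 32L, rho = 0.9,
                       seed = 1L) {
  if (length(conv_maps) != 5) stop("`conv_maps` must have length 5")
  stopifnot(all(conv_maps >= 1), kernel >= 1, stride >= 1, pad >= 0,
            pool_kernel >= 1, pool_stride >= 1, fc_size >= 1, n_classes >= 2,
            dropout_rate >= 0, dropout_rate < 1, learning_rate > 0,
            epochs >= 1, batch_size >= 1)
  structure(list(input_size = as.integer(input_size),
                 conv_maps = as.integer(conv_maps),
                 kernel = as.integer(kernel), pad = as.integer(pad),
                 stride = as.integer(stride),
                 pool_kernel = as.integer(pool_kernel),
                 pool_stride = as.integer(pool_stride),
                 batch_norm_after_conv = as.integer(batch_norm_after_conv),
                 fc_size = as.integer(fc_size), dropout_rate = dropout_rate,
                 n_classes = as.integer(n_classes),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), rho = rho,
                 seed = as.integer(seed)),
            class = "cnn_config")
}

#' Layer-by-layer geometry predicted by the size formulas
#'
#' Chains [conv_output_size()] and [pool_output_size()] through the five
#' convolution + pooling stages, giving the tensor sizes the built network
#' must report (cross-checked in the forward pass).
#'
#' @param cfg a [cnn_config()].
#' @return data.frame (`layer`, `type`, `height`, `width`, `channels`) with a
#'   `flatten_size` attribute.
#' @export
model_geometry <- function(cfg) {
  stopifnot(inherits(cfg, "cnn_config"))
  h <- cfg$input_size[1]; w <- cfg$input_size[2]
  rows <- list(data.frame(layer = "input", type = "input",
                          height = h, width = w, channels = 1L))
  for (l in 1:5) {
    h <- conv_output_size(h, cfg$pad, cfg$kernel, cfg$stride)
    w <- conv_output_size(w, cfg$pad, cfg$kernel, cfg$stride)
    rows <- c(rows, list(data.frame(layer = paste0("conv", l), type = "conv",
                                    height = h, width = w,
                                    channels = cfg$conv_maps[l])))
    h <- pool_output_size(h, cfg$pool_kernel, cfg$pool_stride)
    w <- pool_output_size(w, cfg$pool_kernel, cfg$pool_stride)
    rows <- c(rows, list(data.frame(layer = paste0("pool", l), type = "pool",
                                    height = h, width = w,
                                    channels = cfg$conv_maps[l])))
  }
  geom <- do.call(rbind, rows)
  attr(geom, "flatten_size") <- h * w * cfg$conv_maps[5]
  geom
}

#' Build the (untrained) network
#'
#' Allocates seeded He-initialized weights for the layer sequence
#' conv1-pool1 ... conv4-batchnorm-pool4, conv5-pool5, flatten,
#' FC(`fc_size`, ReLU), dropout, softmax output. The reported flatten size is
#' the chained [conv_output_size()] / [pool_output_size()] computation.
#'
#' @param cfg a [cnn_config()].
#' @param classes optional character vector of class names (length
#'   `n_classes`); otherwise fixed at first training call.
#' @return an object of class `spike_cnn` with fields `config`, `layers`,
#'   `flatten_size`, `classes`, `history`.
#' @export
build_model <- function(cfg, classes = NULL) {
  stopifnot(inherits(cfg, "cnn_config"))
  geom <- model_geometry(cfg)  # errors if input too small for 5 poolings
  flat <- attr(geom, "flatten_size")
  if (!is.null(classes) && length(classes) != cfg$n_classes)
    stop("`classes` must have length n_classes")
  set.seed(cfg$seed)
  layers <- list()
  cin <- 1L
  for (l in 1:5) {
    cout <- cfg$conv_maps[l]
    layers[[length(layers) + 1L]] <-
      list(type = "conv", W = he_init(cout, cfg$kernel^2 * cin),
           b = numeric(cout), K = cfg$kernel, P = cfg$pad)
    if (l == cfg$batch_norm_after_conv)
      layers[[length(layers) + 1L]] <-
        list(type = "batchnorm", gamma = rep(1, cout), beta = numeric(cout),
             run_mean = numeric(cout), run_var = rep(1, cout),
             momentum = 0.9, eps = 1e-5)
    layers[[length(layers) + 1L]] <-
      list(type = "pool", K = cfg$pool_kernel, S = cfg$pool_stride)
    cin <- cout
  }
  layers[[length(layers) + 1L]] <- list(type = "flatten")
  layers[[length(layers) + 1L]] <-
    list(type = "fc", W = he_init(cfg$fc_size, flat), b = numeric(cfg$fc_size))
  layers[[length(layers) + 1L]] <- list(type = "dropout",
                                        rate = cfg$dropout_rate)
  layers[[length(layers) + 1L]] <-
    list(type = "output", W = he_init(cfg$n_classes, cfg$fc_size),
         b = numeric(cfg$n_classes))
  structure(list(config = cfg, layers = layers, flatten_size = flat,
                 classes = classes, history = NULL, trained = FALSE),
            class = "spike_cnn")
}

#' @export
print.spike_cnn <- function(x, ...) {
  cat(sprintf(
    "<spike_cnn> %dx%d input, conv maps [%s], flatten %d, fc %d, %d classes (%s)\n",
    x$config$input_size[1], x$config$input_size[2],
    paste(x$config$conv_maps, collapse = ", "), x$flatten_size,
    x$config$fc_size, x$config$n_classes,
    if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Total learnable parameter count
#' @param model a `spike_cnn`.
#' @return integer count of weights, biases and batch-norm scale/shift terms.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "spike_cnn"))
  tot <- 0
  for (ly in model$layers)
    tot <- tot + switch(ly$type,
      conv = , output = , fc = length(ly$W) + length(ly$b),
      batchnorm = length(ly$gamma) + length(ly$beta),
      0)
  as.integer(tot)
}

# Full forward pass. `x` is (H, W, C, B); internally feature maps run
# channels-first as (C, H, W, B). Returns softmax probabilities
# (n_classes x B), per-layer caches (when keep_cache), recorded activation
# shapes (when trace) and the model (running batch-norm stats update during
# training).
cnn_forward <- function(model, x, training = FALSE, keep_cache = FALSE,
                        trace = FALSE) {
  d <- dim(x)
  B <- d[4]
  if (d[3] == 1L) {     # single channel: same memory layout either way
    A <- x
    dim(A) <- c(1L, d[1], d[2], B)
  } else A <- aperm(x, c(3, 1, 2, 4))
  caches <- vector("list", length(model$layers))
  shapes <- if (trace) list(input = d[1:3])
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (ly$type == "conv") {
      r <- conv_forward(A, ly$W, ly$b, ly$K, ly$P, relu = TRUE,
                        keep_cache = keep_cache)
      A <- r$out; caches[[i]] <- r$cache
    } else if (ly$type == "pool") {
      r <- maxpool_forward(A, ly$K, ly$S, keep_cache = keep_cache)
      A <- r$out; caches[[i]] <- r$cache
    } else if (ly$type == "batchnorm") {
      r <- batchnorm_forward(A, ly, training, keep_cache = keep_cache)
      A <- r$out; caches[[i]] <- r$cache
      model$layers[[i]] <- r$layer
    } else if (ly$type == "flatten") {
      caches[[i]] <- dim(A)
      A <- matrix(A, ncol = B)
    } else if (ly$type == "fc") {
      Z <- ly$W %*% A + ly$b
      caches[[i]] <- list(X = if (keep_cache) A, Z = if (keep_cache) Z)
      A <- pmax(Z, 0)
    } else if (ly$type == "dropout") {
      if (training && ly$rate > 0) {
        mask <- (stats::runif(length(A)) >= ly$rate) / (1 - ly$rate)
        dim(mask) <- dim(A)
        A <- A * mask
        caches[[i]] <- mask
      }
    } else if (ly$type == "output") {
      caches[[i]] <- list(X = if (keep_cache) A)
      A <- softmax_cols(ly$W %*% A + ly$b)
    }
    if (trace) {
      dm <- dim(A) %||% c(length(A) / B, 1)
      # report (height, width, channels) for feature maps
      shapes[[paste0(ly$type, "_", i)]] <-
        if (length(dm) == 4) dm[c(2, 3, 1)] else dm[seq_len(max(1, length(dm) - 1))]
    }
  }
  list(probs = A, caches = caches, shapes = shapes, model = model)
}

# Backward pass from softmax + cross-entropy; returns gradients indexed like
# model$layers.
cnn_backward <- function(model, fwd, Y) {
  B <- ncol(Y)
  grads <- vector("list", length(model$layers))
  dA <- (fwd$probs - Y) / B
  for (i in rev(seq_along(model$layers))) {
    ly <- model$layers[[i]]
    ch <- fwd$caches[[i]]
    if (ly$type == "output") {
      grads[[i]] <- list(dW = tcrossprod(dA, ch$X), db = rowSums(dA))
      dA <- crossprod(ly$W, dA)
    } else if (ly$type == "dropout") {
      if (!is.null(ch)) dA <- dA * ch
    } else if (ly$type == "fc") {
      dZ <- dA * (ch$Z > 0)
      grads[[i]] <- list(dW = tcrossprod(dZ, ch$X), db = rowSums(dZ))
      dA <- crossprod(ly$W, dZ)
    } else if (ly$type == "flatten") {
      dA <- array(dA, ch)
    } else if (ly$type == "batchnorm") {
      r <- batchnorm_backward(dA, ly, ch)
      grads[[i]] <- list(dgamma = r$dgamma, dbeta = r$dbeta)
      dA <- r$dA
    } else if (ly$type == "pool") {
      dA <- maxpool_backward(dA, ch)
    } else if (ly$type == "conv") {
      r <- conv_backward(dA, ly$W, ch, need_dA = i > 1L)
      grads[[i]] <- list(dW = r$dW, db = r$db)
      dA <- r$dA
    }
  }
  grads
}

one_hot <- function(labels, classes) {
  Y <- matrix(0, length(classes), length(labels))
  Y[cbind(match(labels, classes), seq_along(labels))] <- 1
  Y
}

#' Train the network
#'
#' Minimizes categorical cross-entropy by backpropagation with the RMSprop
#' optimizer (squared-gradient decay `rho`, the configured learning rate),
#' iterating seeded shuffled mini-batches for the configured number of
#' epochs. Per-epoch mean loss and training accuracy are appended to the
#' model's `history`.
#'
#' @param model a `spike_cnn` from [build_model()].
#' @param x input array `H x W x 1 x n` (values in \[0, 1\]), matching the
#'   configured input size.
#' @param labels length-`n` class labels; every configured class should be
#'   present (a warning is raised otherwise).
#' @param verbose print one line per epoch.
#' @return the trained `spike_cnn` (with `history` data.frame: `epoch`,
#'   `loss`, `accuracy`).
#' @export
train_cnn <- function(model, x, labels, verbose = FALSE) {
  stopifnot(inherits(model, "spike_cnn"))
  cfg <- model$config
  if (length(dim(x)) != 4) stop("`x` must be an H x W x C x n array")
  d <- dim(x)
  if (d[1] != cfg$input_size[1] || d[2] != cfg$input_size[2])
    stop("image size does not match the configured input size")
  n <- d[4]
  if (n == 0) stop("empty training set")
  if (length(labels) != n) stop("labels must match the number of images")
  if (is.null(model$classes)) model$classes <- sort(unique(as.character(labels)))
  if (length(model$classes) != cfg$n_classes)
    stop("number of distinct classes does not match n_classes")
  missing_cls <- setdiff(model$classes, unique(as.character(labels)))
  if (length(missing_cls) > 0)
    warning("classes absent from training labels: ",
            paste(missing_cls, collapse = ", "))

  opt <- lapply(model$layers, function(ly) switch(ly$type,
    conv = , fc = , output = list(W = array(0, dim(ly$W)), b = numeric(length(ly$b))),
    batchnorm = list(gamma = numeric(length(ly$gamma)),
                     beta = numeric(length(ly$beta))),
    NULL))

  set.seed(derive_seed(cfg$seed, "train"))
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     accuracy = numeric(0))
  for (ep in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0
    for (b0 in seq.int(1L, n, by = cfg$batch_size)) {
      bi <- perm[b0:min(b0 + cfg$batch_size - 1L, n)]
      xb <- x[, , , bi, drop = FALSE]
      Y <- one_hot(labels[bi], model$classes)
      fwd <- cnn_forward(model, xb, training = TRUE, keep_cache = TRUE)
      model <- fwd$model
      p_true <- fwd$probs[cbind(match(labels[bi], model$classes),
                                seq_along(bi))]
      ep_loss <- ep_loss - sum(log(pmax(p_true, 1e-12)))
      ep_correct <- ep_correct +
        sum(apply(fwd$probs, 2, which.max) == match(labels[bi], model$classes))
      grads <- cnn_backward(model, fwd, Y)
      for (i in seq_along(model$layers)) {
        g <- grads[[i]]
        if (is.null(g)) next
        ly <- model$layers[[i]]
        if (ly$type == "batchnorm") {
          u <- rmsprop_update(ly$gamma, g$dgamma, opt[[i]]$gamma,
                              cfg$learning_rate, cfg$rho)
          model$layers[[i]]$gamma <- u$param; opt[[i]]$gamma <- u$cache
          u <- rmsprop_update(ly$beta, g$dbeta, opt[[i]]$beta,
                              cfg$learning_rate, cfg$rho)
          model$layers[[i]]$beta <- u$param; opt[[i]]$beta <- u$cache
        } else {
          u <- rmsprop_update(ly$W, g$dW, opt[[i]]$W,
                              cfg$learning_rate, cfg$rho)
          model$layers[[i]]$W <- u$param; opt[[i]]$W <- u$cache
          u <- rmsprop_update(ly$b, g$db, opt[[i]]$b,
                              cfg$learning_rate, cfg$rho)
          model$layers[[i]]$b <- u$param; opt[[i]]$b <- u$cache
        }
      }
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / n,
                                   accuracy = ep_correct / n))
    if (verbose)
      message(sprintf("epoch %d/%d  loss %.4f  acc %.4f", ep, cfg$epochs,
                      ep_loss / n, ep_correct / n))
  }
  model$history <- rbind(model$history, hist)
  model$trained <- TRUE
  model
}

#' Predict class probabilities and labels
#'
#' Deterministic forward pass (dropout disabled, batch normalization using
#' running statistics). Ties in the argmax resolve to the lowest class index.
#'
#' @param object a trained `spike_cnn`.
#' @param x image array `H x W x 1 x n`.
#' @param batch_size forward-pass chunk size.
#' @param ... unused.
#' @return list with `prob` (n x n_classes matrix, rows summing to 1,
#'   columns named by class) and `label` (character vector of argmax labels).
#' @export
predict.spike_cnn <- function(object, x, batch_size = 64L, ...) {
  stopifnot(inherits(object, "spike_cnn"))
  if (is.null(object$classes)) stop("model has no classes; train it first")
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (d[1] != object$config$input_size[1] ||
      d[2] != object$config$input_size[2])
    stop("image size does not match the configured input size")
  n <- d[4]
  probs <- matrix(0, n, length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (b0 in seq.int(1L, n, by = batch_size)) {
    bi <- b0:min(b0 + batch_size - 1L, n)
    fwd <- cnn_forward(object, x[, , , bi, drop = FALSE], training = FALSE)
    probs[bi, ] <- t(fwd$probs)
  }
  list(prob = probs, label = object$classes[max.col(probs, ties.method = "first")])
}

#' Save / load a trained model
#'
#' Weights are serialized to an RDS file with a JSON configuration sidecar
#' for quick inspection.
#'
#' @param model a `spike_cnn`.
#' @param path RDS path.
#' @return `path` invisibly; the reader returns the `spike_cnn`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "spike_cnn"))
  saveRDS(model, path)
  jsonlite::write_json(model$config[setdiff(names(model$config), "templates")],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "spike_cnn"))
  m
}
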