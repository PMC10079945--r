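# Native layer machinery for the modified LeNet-5-style network.
# Feature maps are carried channels-first as (C, H, W, B) arrays: the im2col
# patch matrix (compiled, see src/conv_ops.cpp) turns each convolution into
# one BLAS matrix product whose output reshapes into place without
# transposition. Pooling likewise runs compiled with argmax bookkeeping.

conv_forward <- function(A, Wm, b, K, P, relu = TRUE, keep_cache = TRUE) {
  d <- dim(A)  # (C, H, W, B)
  Pm <- cpp_im2col(A, d[1], d[2], d[3], d[4], K, P)
  Ho <- d[2] + 2L * P - K + 1L
  Wo <- d[3] + 2L * P - K + 1L
  Z <- Wm %*% Pm + b
  Aout <- if (relu) pmax(Z, 0) else Z
  dim(Aout) <- c(nrow(Wm), Ho, Wo, d[4])
  cache <- if (keep_cache)
    list(Pm = Pm, Z = Z, dims_in = d, K = K, P = P, relu = relu)
  list(out = Aout, cache = cache)
}

conv_backward <- function(dAout, Wm, cache, need_dA = TRUE) {
  dZ <- dAout
  dim(dZ) <- c(dim(dAout)[1], length(dAout) / dim(dAout)[1])
  if (cache$relu) dZ <- dZ * (cache$Z > 0)
  dW <- tcrossprod(dZ, cache$Pm)
  db <- rowSums(dZ)
  if (!need_dA) return(list(dA = NULL, dW = dW, db = db))
  d <- cache$dims_in
  dPm <- crossprod(Wm, dZ)
  dA <- cpp_col2im(dPm, d[1], d[2], d[3], d[4], cache$K, cache$P)
  list(dA = dA, dW = dW, db = db)
}

maxpool_forward <- function(A, K = 2L, S = 2L, keep_cache = TRUE) {
  d <- dim(A)
  if (d[2] < K || d[3] < K) stop("pooling input smaller than the pool kernel")
  r <- cpp_maxpool_fwd(A, d[1], d[2], d[3], d[4], K, S)
  cache <- if (keep_cache) list(arg = r$arg, dims_in = d)
  list(out = r$out, cache = cache)
}

maxpool_backward <- function(dOut, cache) {
  d <- cache$dims_in
  cpp_maxpool_bwd(dOut, cache$arg, d[1], d[2], d[3], d[4])
}

# Batch normalization per channel over (H, W, B). Channels-first layout makes
# the per-channel moments plain row operations on a (C, N) matrix view, and
# length-C vectors broadcast down columns without any reshaping.
batchnorm_forward <- function(A, layer, training, keep_cache = TRUE) {
  d <- dim(A); C <- d[1]; N <- length(A) / C
  M <- A
  dim(M) <- c(C, N)
  if (training) {
    mu <- rowMeans(M)
    v <- rowMeans(M^2) - mu^2
    v[v < 0] <- 0
    layer$run_mean <- layer$momentum * layer$run_mean + (1 - layer$momentum) * mu
    layer$run_var <- layer$momentum * layer$run_var + (1 - layer$momentum) * v
  } else {
    mu <- layer$run_mean; v <- layer$run_var
  }
  invstd <- 1 / sqrt(v + layer$eps)
  Xhat <- (M - mu) * invstd
  Y <- Xhat * layer$gamma + layer$beta
  dim(Y) <- d
  cache <- if (keep_cache) list(Xhat = Xhat, invstd = invstd, dims = d)
  list(out = Y, cache = cache, layer = layer)
}

batchnorm_backward <- function(dOut, layer, cache) {
  d <- cache$dims; C <- d[1]; N <- length(dOut) / C
  dY <- dOut
  dim(dY) <- c(C, N)
  dgamma <- rowSums(dY * cache$Xhat)
  dbeta <- rowSums(dY)
  dXhat <- dY * layer$gamma
  s1 <- rowSums(dXhat)
  s2 <- rowSums(dXhat * cache$Xhat)
  dM <- (dXhat - s1 / N - cache$Xhat * (s2 / N)) * cache$invstd
  dim(dM) <- d
  list(dA = dM, dgamma = dgamma, dbeta = dbeta)
}

softmax_cols <- function(Z) {
  Z <- Z - rep(apply(Z, 2, max), each = nrow(Z))
  E <- exp(Z)
  E / rep(colSums(E), each = nrow(Z))
}

he_init <- function(nout, nin) {
  matrix(stats::rnorm(nout * nin, sd = sqrt(2 / nin)), nout, nin)
}

rmsprop_update <- function(param, grad, cache, lr, rho, eps = 1e-8) {
  cache <- rho * cache + (1 - rho) * grad^2
  list(param = param - lr * grad / (sqrt(cache) + eps), cache = cache)
}
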