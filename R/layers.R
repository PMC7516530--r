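# Low-level layer primitives.  All activations are stored "maps x positions":
# each row is one feature map, columns run over (spatial position, batch
# element).  Every forward returns a cache with exactly what its backward
# needs; backwards return gradients in the same shapes as their inputs.

## ---- batch normalization (per row / feature map) ----

bn_forward <- function(z, gamma, beta, train, run, momentum, eps = 1e-5) {
  m <- nrow(z); n <- ncol(z)
  if (train) {
    mu <- .rowMeans(z, m, n)
    v <- .rowMeans(z * z, m, n) - mu * mu
    run$mean <- (1 - momentum) * run$mean + momentum * mu
    run$var <- (1 - momentum) * run$var + momentum * v
  } else {
    mu <- run$mean
    v <- run$var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (z - mu) * invstd
  list(y = gamma * xhat + beta, run = run,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma))
}

bn_backward <- function(dy, cache) {
  xhat <- cache$xhat
  m <- nrow(dy); n <- ncol(dy)
  dgamma <- .rowSums(dy * xhat, m, n)
  dbeta <- .rowSums(dy, m, n)
  # dz = invstd * gamma * (dy - mean(dy) - xhat * mean(dy * xhat)), with the
  # row means expressed through the sums already computed
  dz <- (cache$invstd * cache$gamma) *
    (dy - dbeta / n - xhat * (dgamma / n))
  list(dz = dz, dgamma = dgamma, dbeta = dbeta)
}

## ---- activations ----

elu_forward <- function(z) {
  y <- z
  neg <- z < 0
  y[neg] <- exp(z[neg]) - 1
  y
}

elu_backward <- function(dy, z, y) {
  d <- dy
  neg <- z < 0
  d[neg] <- dy[neg] * (y[neg] + 1)
  d
}

relu_forward <- function(z) pmax(z, 0)

relu_backward <- function(dy, z) dy * (z > 0)

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax_cols <- function(logits) {
  m <- apply(logits, 2L, max)
  e <- exp(sweep(logits, 2L, m))
  sweep(e, 2L, colSums(e), "/")
}

## ---- dropout (inverted scaling; mask drawn from the current RNG) ----

dropout_forward <- function(a, rate, train) {
  if (!train || rate <= 0) return(list(y = a, mask = NULL))
  mask <- array((stats::runif(length(a)) >= rate) / (1 - rate), dim(a))
  list(y = a * mask, mask = mask)
}

dropout_backward <- function(dy, mask) {
  if (is.null(mask)) dy else dy * mask
}

## ---- max pooling over the columns (time axis) of a (rows, T) matrix ----
# rows carry (map, sample); pooling windows are contiguous column blocks

maxpool_forward <- function(a, p) {
  R <- nrow(a); T <- ncol(a)
  Tp <- T %/% p
  b <- a[, seq_len(p * Tp), drop = FALSE]
  dim(b) <- c(R, p, Tp)
  y <- matrix(b[, 1L, ], R, Tp)
  arg <- matrix(1L, R, Tp)
  if (p > 1L) for (j in 2:p) {
    bj <- matrix(b[, j, ], R, Tp)
    w <- bj > y
    y[w] <- bj[w]
    arg[w] <- j
  }
  list(y = y, cache = list(arg = arg, p = p, T = T))
}

maxpool_backward <- function(dy, cache) {
  R <- nrow(dy); Tp <- ncol(dy)
  p <- cache$p
  da <- matrix(0, R, cache$T)
  cols <- rep((0:(Tp - 1L)) * p, each = R) + as.vector(cache$arg)
  da[cbind(rep.int(seq_len(R), Tp), cols)] <- dy
  da
}

## ---- im2col helpers for valid 1-d convolution over time ----
# inputs are matrices (rows, T) with time as the column index, so every
# shifted window is a contiguous column range

# single-map temporal conv: (R, t) -> (R*T1, k), column j = window shift j-1
im2col_shift <- function(m, k, T1) {
  out <- matrix(0, nrow(m) * T1, k)
  for (j in seq_len(k))
    out[, j] <- m[, j:(j + T1 - 1L)]
  out
}

# multi-map temporal conv: input (M, n, T) given as matrix (M*n, T) with
# map-count M -> (M*k, n*T3), row block j = all maps at shift j-1
im2col_block <- function(m, M, k, T3) {
  n <- nrow(m) / M
  out <- matrix(0, M * k, n * T3)
  for (j in seq_len(k)) {
    blk <- m[, j:(j + T3 - 1L), drop = FALSE]
    dim(blk) <- c(M, n * T3)
    out[((j - 1L) * M + 1L):(j * M), ] <- blk
  }
  out
}

## ---- parameter initialisation (He-scaled normal, current RNG) ----

init_weight <- function(nout, nin, fan_in = nin) {
  matrix(stats::rnorm(nout * nin, 0, sqrt(2 / fan_in)), nout, nin)
}

init_linear <- function(nout, nin, fan_in = nin) {
  list(W = init_weight(nout, nin, fan_in), b = numeric(nout))
}

init_bn <- function(m) list(gamma = rep(1, m), beta = numeric(m))

init_bn_run <- function(m) list(mean = numeric(m), var = rep(1, m))

zeros_like_params <- function(p) {
  rapply(p, function(x) x * 0, how = "replace")
}
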