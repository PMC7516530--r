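#' Architecture configuration for the Dense ConvNet decoder
#'
#' The feature extractor is a Spatio-Temporal block followed by a Dense-Conv
#' block.  The Spatio-Temporal block projects the `c` physical channels to
#' `n_proj` virtual channels with a 1x1 convolution, applies a temporal
#' convolution (kernel `k_temporal` along time, per virtual channel), then a
#' spatial convolution collapsing all virtual channels, an ELU, and a max
#' pool.  The Dense-Conv block applies a 1x1 convolution and a temporal
#' convolution (kernel `k_dense`), stacks the block's input and output
#' feature maps (the densely connected shortcut), max-pools, flattens, and
#' maps to `d_f` feature units with a fully connected layer.  Batch
#' normalization and dropout follow every convolution; all convolutions are
#' valid (no padding), stride 1; pools have stride equal to their size.
#'
#' @param n_channels,n_samples,n_classes input geometry `(c, t)` and class
#'   count `C`.
#' @param n_proj virtual channels produced by the channel projection.
#' @param n_temp,n_spat,n_dense feature maps of the temporal, spatial and
#'   dense convolutions.
#' @param k_temporal,k_dense temporal kernel lengths.
#' @param pool1,pool2 max-pool sizes (stride = size).
#' @param d_f extractor output dimension (the feature vector length).
#' @param clf_hidden hidden units of the two-layer classifier.
#' @param disc_hidden integer vector of discriminator hidden-layer sizes.
#' @param dropout dropout rate after each convolution (0 disables).
#' @param batchnorm logical; include batch normalization layers.
#' @param bn_momentum running-statistics momentum for batch normalization.
#' @param elu_dense logical; apply ELU after the Dense-Conv block
#'   convolutions as well (the Deep ConvNet convention this architecture
#'   descends from; the spatial-convolution ELU is always present).
#' @return an object of class `arch_config`.
#' @export
arch_config <- function(n_channels, n_samples, n_classes = 4L,
                        n_proj = 35L, n_temp = 25L, n_spat = 25L,
                        n_dense = 50L, k_temporal = 25L, k_dense = 11L,
                        pool1 = 3L, pool2 = 3L, d_f = 512L,
                        clf_hidden = 256L, disc_hidden = 64L,
                        dropout = 0.5, batchnorm = TRUE,
                        bn_momentum = 0.1, elu_dense = TRUE) {
  arch <- structure(
    list(n_channels = as.integer(n_channels),
         n_samples = as.integer(n_samples),
         n_classes = as.integer(n_classes), n_proj = as.integer(n_proj),
         n_temp = as.integer(n_temp), n_spat = as.integer(n_spat),
         n_dense = as.integer(n_dense), k_temporal = as.integer(k_temporal),
         k_dense = as.integer(k_dense), pool1 = as.integer(pool1),
         pool2 = as.integer(pool2), d_f = as.integer(d_f),
         clf_hidden = as.integer(clf_hidden),
         disc_hidden = as.integer(disc_hidden), dropout = dropout,
         batchnorm = isTRUE(batchnorm), bn_momentum = bn_momentum,
         elu_dense = isTRUE(elu_dense)),
    class = "arch_config")
  shape_infer(arch)                     # validates the geometry
  arch
}

#' Valid-convolution shape arithmetic for an architecture
#'
#' Computes the time-axis length after every stage and the flattened input
#' size of the final fully connected layer, erroring if any stage would be
#' empty.  The observed forward-pass shapes must (and, in the tests, do)
#' match these numbers.
#'
#' @param arch an [arch_config()].
#' @return list with elements `T1` (after temporal conv), `T2` (after first
#'   pool), `T3` (after the dense conv), `T4` (after the second pool),
#'   `crop` (samples trimmed from each side of the shortcut), `n_cat`
#'   (stacked feature maps) and `flat` (flattened length).
#' @export
shape_infer <- function(arch) {
  T1 <- arch$n_samples - arch$k_temporal + 1L
  if (T1 < 1L) stop("n_samples too short for k_temporal")
  T2 <- T1 %/% arch$pool1
  if (T2 < arch$k_dense)
    stop("pooled length ", T2, " is shorter than k_dense = ", arch$k_dense)
  T3 <- T2 - arch$k_dense + 1L
  T4 <- T3 %/% arch$pool2
  if (T4 < 1L) stop("no samples left after the second pool")
  n_cat <- arch$n_spat + arch$n_dense
  list(T1 = T1, T2 = T2, T3 = T3, T4 = T4,
       crop = (arch$k_dense - 1L) %/% 2L,
       n_cat = n_cat, flat = n_cat * T4)
}

## ---- parameter initialisation ----

init_extractor <- function(arch) {
  sh <- shape_infer(arch)
  p <- list(
    proj = init_linear(arch$n_proj, arch$n_channels),
    temp = init_linear(arch$n_temp, arch$k_temporal),
    spat = init_linear(arch$n_spat, arch$n_proj * arch$n_temp),
    d1   = init_linear(arch$n_dense, arch$n_spat),
    d2   = init_linear(arch$n_dense, arch$n_dense * arch$k_dense),
    fc   = init_linear(arch$d_f, sh$flat))
  if (arch$batchnorm) {
    p$bn0 <- init_bn(arch$n_proj);  p$bn1 <- init_bn(arch$n_temp)
    p$bn2 <- init_bn(arch$n_spat);  p$bn3 <- init_bn(arch$n_dense)
    p$bn4 <- init_bn(arch$n_dense)
  }
  p
}

init_bn_stats <- function(arch) {
  if (!arch$batchnorm) return(NULL)
  list(bn0 = init_bn_run(arch$n_proj), bn1 = init_bn_run(arch$n_temp),
       bn2 = init_bn_run(arch$n_spat), bn3 = init_bn_run(arch$n_dense),
       bn4 = init_bn_run(arch$n_dense))
}

init_classifier <- function(arch) {
  list(fc1 = init_linear(arch$clf_hidden, arch$d_f),
       fc2 = init_linear(arch$n_classes, arch$clf_hidden))
}

disc_input_dim <- function(arch, variant) {
  if (variant == "dan") arch$d_f else arch$d_f * arch$n_classes
}

init_discriminator <- function(arch, variant) {
  din <- disc_input_dim(arch, variant)
  sizes <- c(din, arch$disc_hidden, 1L)
  layers <- vector("list", length(sizes) - 1L)
  for (i in seq_along(layers))
    layers[[i]] <- init_linear(sizes[i + 1L], sizes[i])
  layers
}

## ---- extractor forward / backward ----

# x: (c, n, t) standardized input batch (time last, so that every
# convolution window is a contiguous column range); returns f (d_f x n)
# plus cache.  BN running statistics are updated in the returned `bn`
# element when train = TRUE.
ext_forward <- function(params, arch, x, bn, train = TRUE) {
  sh <- shape_infer(arch)
  t <- arch$n_samples; n <- dim(x)[2L]
  P <- arch$n_proj
  use_bn <- arch$batchnorm
  cache <- list(n = n, sh = sh)

  bnf <- function(z, name) {
    if (!use_bn) return(z)
    r <- bn_forward(z, params[[name]]$gamma, params[[name]]$beta,
                    train, bn[[name]], arch$bn_momentum)
    bn[[name]] <<- r$run
    cache[[paste0(name, "_c")]] <<- r$cache
    r$y
  }
  drop_f <- function(a, name) {
    r <- dropout_forward(a, arch$dropout, train)
    cache[[paste0(name, "_mask")]] <<- r$mask
    r$y
  }

  # channel projection (1x1 conv over physical channels)
  x0 <- x; dim(x0) <- c(arch$n_channels, n * t)
  cache$x0 <- x0
  z0 <- params$proj$W %*% x0 + params$proj$b
  a0 <- drop_f(bnf(z0, "bn0"), "d0")     # (P, n*t)
  dim(a0) <- c(P * n, t)                 # rows (virtual channel, sample)

  # temporal conv: 1 -> n_temp maps, per virtual channel
  xc1 <- im2col_shift(a0, arch$k_temporal, sh$T1)
  cache$xc1 <- xc1
  z1 <- tcrossprod(params$temp$W, xc1) + params$temp$b # (n_temp, P*n*T1)
  a1 <- drop_f(bnf(z1, "bn1"), "d1")
  dim(a1) <- c(arch$n_temp, P, n, sh$T1)
  a1 <- aperm(a1, c(2L, 1L, 3L, 4L))                   # (P, n_temp, n, T1)
  dim(a1) <- c(P * arch$n_temp, n * sh$T1)
  cache$a1m <- a1

  # spatial conv collapsing all virtual channels, then ELU + pool
  z2 <- params$spat$W %*% a1 + params$spat$b           # (n_spat, n*T1)
  z2n <- bnf(z2, "bn2")
  cache$z2n <- z2n
  e2 <- elu_forward(z2n)
  cache$e2 <- e2
  a2 <- drop_f(e2, "d2")
  dim(a2) <- c(arch$n_spat * n, sh$T1)
  mp1 <- maxpool_forward(a2, arch$pool1)
  cache$mp1 <- mp1$cache
  a2p <- mp1$y                                         # (n_spat*n, T2)
  cache$a2p <- a2p

  # dense block: 1x1 conv
  x3 <- a2p; dim(x3) <- c(arch$n_spat, n * sh$T2)
  z3 <- params$d1$W %*% x3 + params$d1$b
  z3n <- bnf(z3, "bn3")
  if (arch$elu_dense) {
    cache$z3n <- z3n
    z3n <- elu_forward(z3n)
    cache$e3 <- z3n
  }
  a3 <- drop_f(z3n, "d3")
  dim(a3) <- c(arch$n_dense * n, sh$T2)

  # dense block: temporal conv over all maps
  xc4 <- im2col_block(a3, arch$n_dense, arch$k_dense, sh$T3)
  cache$xc4 <- xc4
  z4 <- params$d2$W %*% xc4 + params$d2$b              # (n_dense, n*T3)
  z4n <- bnf(z4, "bn4")
  if (arch$elu_dense) {
    cache$z4n <- z4n
    z4n <- elu_forward(z4n)
    cache$e4 <- z4n
  }
  a4 <- drop_f(z4n, "d4")

  # densely connected shortcut: stack block input (time-cropped) and output
  crop <- a2p[, (sh$crop + 1L):(sh$crop + sh$T3), drop = FALSE]
  dim(crop) <- c(arch$n_spat, n * sh$T3)
  cat_a <- rbind(crop, a4)                             # (n_cat, n*T3)
  dim(cat_a) <- c(sh$n_cat * n, sh$T3)
  mp2 <- maxpool_forward(cat_a, arch$pool2)
  cache$mp2 <- mp2$cache
  flat <- mp2$y                                        # (n_cat*n, T4)
  dim(flat) <- c(sh$n_cat, n, sh$T4)
  flat <- aperm(flat, c(1L, 3L, 2L))
  dim(flat) <- c(sh$flat, n)
  cache$flat <- flat

  f <- params$fc$W %*% flat + params$fc$b              # (d_f, n)
  list(f = f, cache = cache, bn = bn)
}

# df: (d_f x n) gradient w.r.t. the feature output; returns gradients for
# every extractor parameter (same structure as the parameter list).
ext_backward <- function(params, arch, cache, df) {
  sh <- cache$sh; n <- cache$n
  P <- arch$n_proj
  use_bn <- arch$batchnorm
  g <- list()

  bnb <- function(dy, name) {
    if (!use_bn) return(dy)
    r <- bn_backward(dy, cache[[paste0(name, "_c")]])
    g[[name]] <<- list(gamma = r$dgamma, beta = r$dbeta)
    r$dz
  }
  dropb <- function(dy, name) dropout_backward(dy, cache[[paste0(name, "_mask")]])

  g$fc <- list(W = tcrossprod(df, cache$flat), b = .rowSums(df, nrow(df), ncol(df)))
  dflat <- crossprod(params$fc$W, df)
  dim(dflat) <- c(sh$n_cat, sh$T4, n)
  dflat <- aperm(dflat, c(1L, 3L, 2L))               # (n_cat, n, T4)
  dim(dflat) <- c(sh$n_cat * n, sh$T4)
  dcat <- maxpool_backward(dflat, cache$mp2)         # (n_cat*n, T3)
  dim(dcat) <- c(sh$n_cat, n * sh$T3)

  dcrop <- dcat[seq_len(arch$n_spat), , drop = FALSE]
  da4 <- dcat[arch$n_spat + seq_len(arch$n_dense), , drop = FALSE]

  # dense temporal conv
  de4 <- dropb(da4, "d4")
  if (arch$elu_dense) de4 <- elu_backward(de4, cache$z4n, cache$e4)
  dz4 <- bnb(de4, "bn4")
  g$d2 <- list(W = tcrossprod(dz4, cache$xc4), b = .rowSums(dz4, nrow(dz4), ncol(dz4)))
  dxc4 <- crossprod(params$d2$W, dz4)                # (n_dense*k, n*T3)
  da3 <- matrix(0, arch$n_dense * n, sh$T2)
  for (j in seq_len(arch$k_dense)) {
    blk <- dxc4[((j - 1L) * arch$n_dense + 1L):(j * arch$n_dense), ,
                drop = FALSE]
    dim(blk) <- c(arch$n_dense * n, sh$T3)
    da3[, j:(j + sh$T3 - 1L)] <- da3[, j:(j + sh$T3 - 1L)] + blk
  }

  # dense 1x1 conv
  dim(da3) <- c(arch$n_dense, n * sh$T2)
  de3 <- dropb(da3, "d3")
  if (arch$elu_dense) de3 <- elu_backward(de3, cache$z3n, cache$e3)
  dz3 <- bnb(de3, "bn3")
  x3 <- cache$a2p; dim(x3) <- c(arch$n_spat, n * sh$T2)
  g$d1 <- list(W = tcrossprod(dz3, x3), b = .rowSums(dz3, nrow(dz3), ncol(dz3)))
  dx3 <- crossprod(params$d1$W, dz3)                 # (n_spat, n*T2)

  # shortcut + 1x1 paths join at the pooled activations
  da2p <- matrix(0, arch$n_spat * n, sh$T2)
  da2p[, (sh$crop + 1L):(sh$crop + sh$T3)] <-
    matrix(dcrop, arch$n_spat * n, sh$T3)
  dim(dx3) <- c(arch$n_spat * n, sh$T2)
  da2p <- da2p + dx3

  # first pool, dropout, ELU, BN, spatial conv
  da2 <- maxpool_backward(da2p, cache$mp1)           # (n_spat*n, T1)
  dim(da2) <- c(arch$n_spat, n * sh$T1)
  de2 <- dropb(da2, "d2")
  dz2n <- elu_backward(de2, cache$z2n, cache$e2)
  dz2 <- bnb(dz2n, "bn2")
  g$spat <- list(W = tcrossprod(dz2, cache$a1m), b = .rowSums(dz2, nrow(dz2), ncol(dz2)))
  da1m <- crossprod(params$spat$W, dz2)
  dim(da1m) <- c(P, arch$n_temp, n, sh$T1)
  da1 <- aperm(da1m, c(2L, 1L, 3L, 4L))
  dim(da1) <- c(arch$n_temp, P * n * sh$T1)

  # temporal conv
  dz1 <- bnb(dropb(da1, "d1"), "bn1")
  g$temp <- list(W = dz1 %*% cache$xc1, b = .rowSums(dz1, nrow(dz1), ncol(dz1)))
  dxc1 <- crossprod(dz1, params$temp$W)              # (P*n*T1, k_t)
  da0 <- matrix(0, P * n, arch$n_samples)
  for (j in seq_len(arch$k_temporal)) {
    col <- dxc1[, j]
    dim(col) <- c(P * n, sh$T1)
    da0[, j:(j + sh$T1 - 1L)] <- da0[, j:(j + sh$T1 - 1L)] + col
  }

  # projection
  dim(da0) <- c(P, n * arch$n_samples)
  dz0 <- bnb(dropb(da0, "d0"), "bn0")
  g$proj <- list(W = tcrossprod(dz0, cache$x0), b = .rowSums(dz0, nrow(dz0), ncol(dz0)))
  g
}

## ---- classifier ----

clf_forward <- function(params, f) {
  z1 <- params$fc1$W %*% f + params$fc1$b
  h <- elu_forward(z1)
  logits <- params$fc2$W %*% h + params$fc2$b
  p <- softmax_cols(logits)
  list(logits = logits, p = p, cache = list(f = f, z1 = z1, h = h))
}

# dlogits: (C x n); returns parameter grads and the gradient into f
clf_backward <- function(params, cache, dlogits) {
  g <- list(fc2 = list(W = tcrossprod(dlogits, cache$h), b = rowSums(dlogits)))
  dh <- crossprod(params$fc2$W, dlogits)
  dz1 <- elu_backward(dh, cache$z1, cache$h)
  g$fc1 <- list(W = tcrossprod(dz1, cache$f), b = .rowSums(dz1, nrow(dz1), ncol(dz1)))
  list(grads = g, df = crossprod(params$fc1$W, dz1))
}

## ---- discriminator ----

disc_forward <- function(layers, h) {
  k <- length(layers)
  acts <- vector("list", k)  # post-activation inputs of each layer
  zs <- vector("list", k)
  a <- h
  for (i in seq_len(k)) {
    acts[[i]] <- a
    z <- layers[[i]]$W %*% a + layers[[i]]$b
    zs[[i]] <- z
    a <- if (i < k) relu_forward(z) else z
  }
  list(logit = a, score = sigmoid(a), cache = list(acts = acts, zs = zs))
}

# dlogit: (1 x n); returns parameter grads and the gradient into the input h
disc_backward <- function(layers, cache, dlogit) {
  k <- length(layers)
  g <- vector("list", k)
  dz <- dlogit
  for (i in rev(seq_len(k))) {
    g[[i]] <- list(W = tcrossprod(dz, cache$acts[[i]]), b = rowSums(dz))
    da <- crossprod(layers[[i]]$W, dz)
    dz <- if (i > 1L) relu_backward(da, cache$zs[[i - 1L]]) else da
  }
  list(grads = g, dh = dz)
}

## ---- multilinear map and gradient reversal ----

#' Multilinear (outer-product) conditioning map
#'
#' Joins a feature vector `f` (length `d_f`) and a class-probability vector
#' `p` (length `C`) into the flattened outer product `h` of length
#' `d_f * C`, laid out row-major in `f`: `h[(i-1)*C + j] = f[i] * p[j]`.
#' Matrix inputs are treated as one column per example.
#'
#' @param f numeric vector of length `d_f`, or a `d_f x n` matrix.
#' @param p numeric vector of length `C`, or a `C x n` matrix.
#' @return numeric vector of length `d_f * C`, or a `(d_f*C) x n` matrix.
#' @export
multilinear_map <- function(f, p) {
  if (is.matrix(f) || is.matrix(p)) {
    f <- as.matrix(f); p <- as.matrix(p)
    if (ncol(f) != ncol(p)) stop("f and p must have the same batch size")
    d_f <- nrow(f); d_p <- nrow(p)
    f[rep(seq_len(d_f), each = d_p), , drop = FALSE] *
      p[rep(seq_len(d_p), d_f), , drop = FALSE]
  } else {
    as.vector(vapply(seq_along(f), function(i) f[i] * p, numeric(length(p))))
  }
}

# gradient of a scalar loss w.r.t. f, given its gradient w.r.t. h = f (x) p
# with p treated as a constant
multilinear_backward <- function(dh, p) {
  d_p <- nrow(p); n <- ncol(p)
  d_f <- nrow(dh) / d_p
  df <- matrix(0, d_f, n)
  dha <- dh; dim(dha) <- c(d_p, d_f, n)
  for (j in seq_len(d_p)) {
    slice <- dha[j, , ]
    dim(slice) <- c(d_f, n)
    df <- df + slice * rep(p[j, ], each = d_f)
  }
  df
}

#' Gradient reversal layer (forward view)
#'
#' The identity map in the forward direction.  During backpropagation the
#' training loop multiplies the gradient flowing from the domain
#' discriminator back into the feature extractor by `-lambda`, which turns
#' the discriminator's minimisation into the extractor's maximisation — a
#' single backward pass realises the adversarial update.  This function
#' records `lambda` as an attribute so the contract is visible at the API
#' surface; the reversal itself is exercised (and finite-difference checked)
#' inside [train_da()].
#'
#' @param x numeric input (passed through unchanged).
#' @param lambda non-negative adversarial trade-off scalar.
#' @return `x`, with attribute `grl_lambda = lambda`.
#' @export
grl <- function(x, lambda) {
  if (lambda < 0) stop("lambda must be >= 0")
  attr(x, "grl_lambda") <- lambda
  x
}
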