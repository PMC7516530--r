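# The forward/backward stack is hand-written, so these tests lean on
# independent oracles: manual index arithmetic for the multilinear map,
# central finite differences for every gradient path, and the shape
# calculator against observed tensor sizes.

test_that("multilinear map equals the brute-force double loop", {
  f <- c(1, 2); p <- c(0.5, 0.5)
  expect_equal(multilinear_map(f, p), c(0.5, 0.5, 1, 1))
  expect_equal(multilinear_map(numeric(3), c(0.2, 0.8)), numeric(6))
  set.seed(3)
  for (rep in 1:50) {
    f <- rnorm(7); p <- rexp(4); p <- p / sum(p)
    h <- multilinear_map(f, p)
    oracle <- numeric(28)
    for (i in 1:7) for (j in 1:4) oracle[(i - 1) * 4 + j] <- f[i] * p[j]
    expect_identical(h, oracle)
  }
  # batched form agrees with per-column application
  F <- matrix(rnorm(7 * 5), 7); P <- matrix(rexp(4 * 5), 4)
  P <- sweep(P, 2, colSums(P), "/")
  H <- multilinear_map(F, P)
  for (s in 1:5) expect_equal(H[, s], multilinear_map(F[, s], P[, s]))
})

test_that("classifier head is a valid softmax with closed-form cases", {
  arch <- tiny_arch(C = 4)
  set.seed(4)
  par_clf <- cdaneeg:::init_classifier(arch)
  f <- matrix(rnorm(arch$d_f * 6), arch$d_f)
  out <- cdaneeg:::clf_forward(par_clf, f)
  expect_true(all(out$p >= 0))
  expect_equal(colSums(out$p), rep(1, 6), tolerance = 1e-12)
  # equal logits -> uniform; log-probability logits -> the probabilities
  expect_equal(cdaneeg:::softmax_cols(matrix(3, 4, 1))[, 1], rep(0.25, 4))
  expect_equal(cdaneeg:::softmax_cols(matrix(log(1:4), 4, 1))[, 1],
               (1:4) / 10, tolerance = 1e-12)
})

test_that("discriminator scores are sigmoid outputs in (0,1)", {
  arch <- tiny_arch(C = 3)
  set.seed(5)
  layers <- cdaneeg:::init_discriminator(arch, "cdan")
  h <- matrix(rnorm(arch$d_f * 3 * 8), arch$d_f * 3)
  s <- cdaneeg:::disc_forward(layers, h)$score
  expect_true(all(s > 0 & s < 1))
  # zeroed final layer -> sigmoid(0) = 0.5
  layers[[length(layers)]]$W[] <- 0
  layers[[length(layers)]]$b[] <- 0
  expect_equal(as.vector(cdaneeg:::disc_forward(layers, h)$score),
               rep(0.5, 8))
  # hand-set single-layer discriminator: sigmoid(w . h + b)
  one <- list(list(W = matrix(c(0.3, -0.2, 0.5, 0.1), 1), b = 0.2))
  h1 <- c(1, 0, 0, 0)
  expect_equal(cdaneeg:::disc_forward(one, matrix(h1))$score[1, 1],
               1 / (1 + exp(-(0.3 + 0.2))))
})

test_that("gradient reversal is the identity in the forward pass", {
  set.seed(6)
  x <- rnorm(10)
  y <- grl(x, 0.6)
  expect_equal(as.vector(y), x)
  expect_equal(attr(y, "grl_lambda"), 0.6)
  expect_error(grl(x, -0.1), ">= 0")
})

test_that("extractor output is deterministic in eval mode and shape-correct", {
  arch <- tiny_arch()
  set.seed(7)
  pe <- cdaneeg:::init_extractor(arch)
  bn <- cdaneeg:::init_bn_stats(arch)
  x <- array(rnorm(3 * 40 * 2), c(3, 2, 40))
  f1 <- cdaneeg:::ext_forward(pe, arch, x, bn, train = FALSE)$f
  f2 <- cdaneeg:::ext_forward(pe, arch, x, bn, train = FALSE)$f
  expect_identical(f1, f2)
  expect_equal(dim(f1), c(arch$d_f, 2L))
  expect_true(all(is.finite(f1)))
  # dropout makes training-mode forwards stochastic
  archd <- tiny_arch(dropout = 0.5)
  set.seed(8)
  g1 <- with_seed_local(1, cdaneeg:::ext_forward(pe, archd, x, bn, TRUE)$f)
  g2 <- with_seed_local(2, cdaneeg:::ext_forward(pe, archd, x, bn, TRUE)$f)
  expect_false(identical(g1, g2))
})

test_that("shape inference matches observed shapes on random configs", {
  set.seed(9)
  for (rep in 1:10) {
    c <- sample(2:6, 1); C <- sample(2:4, 1)
    k_t <- sample(3:8, 1); k_d <- sample(2:4, 1)
    p1 <- sample(2:3, 1); p2 <- sample(2:3, 1)
    t <- k_t + p1 * (k_d + p2 + sample(0:6, 1)) + sample(0:3, 1)
    arch <- try(arch_config(c, t, C, n_proj = sample(2:5, 1),
                            n_temp = sample(2:4, 1), n_spat = sample(2:4, 1),
                            n_dense = sample(2:5, 1), k_temporal = k_t,
                            k_dense = k_d, pool1 = p1, pool2 = p2,
                            d_f = sample(3:8, 1), clf_hidden = 4,
                            disc_hidden = 4, dropout = 0), silent = TRUE)
    if (inherits(arch, "try-error")) next   # geometry too short: rejected
    sh <- shape_infer(arch)
    pe <- cdaneeg:::init_extractor(arch)
    bn <- cdaneeg:::init_bn_stats(arch)
    x <- array(rnorm(c * t * 3), c(c, 3, t))
    fwd <- cdaneeg:::ext_forward(pe, arch, x, bn, train = TRUE)
    expect_equal(dim(fwd$f), c(arch$d_f, 3L))
    expect_equal(dim(fwd$cache$flat), c(sh$flat, 3L))
    expect_equal(dim(fwd$cache$a2p), c(arch$n_spat * 3L, sh$T2))
  }
  expect_error(arch_config(3, 10, 4, k_temporal = 25), "too short")
})

test_that("every backward pass matches central finite differences", {
  arch <- tiny_arch()
  set.seed(10)
  pe <- cdaneeg:::init_extractor(arch)
  pc <- cdaneeg:::init_classifier(arch)
  bn <- cdaneeg:::init_bn_stats(arch)
  n <- 5
  x <- array(rnorm(3 * 40 * n), c(3, n, 40))
  y <- sample(1:3, n, replace = TRUE)

  loss_of <- function(pe_, pc_) {
    fwd <- cdaneeg:::ext_forward(pe_, arch, x, bn, train = TRUE)
    classifier_loss(cdaneeg:::clf_forward(pc_, fwd$f)$p, y)
  }
  fwd <- cdaneeg:::ext_forward(pe, arch, x, bn, train = TRUE)
  cs <- cdaneeg:::clf_forward(pc, fwd$f)
  onehot <- matrix(0, 3, n); onehot[cbind(y, seq_len(n))] <- 1
  cb <- cdaneeg:::clf_backward(pc, cs$cache, (cs$p - onehot) / n)
  ge <- cdaneeg:::ext_backward(pe, arch, fwd$cache, cb$df)

  eps <- 1e-5
  fd_check <- function(get, set, ana, label) {
    v <- get()
    # probe a handful of coordinates to keep the test fast
    ii <- if (length(v) > 6) round(seq(1, length(v), length.out = 6)) else
      seq_along(v)
    for (i in ii) {
      vp <- v; vp[i] <- v[i] + eps; set(vp); lp <- loss_of(pe2, pc2)
      vm <- v; vm[i] <- v[i] - eps; set(vm); lm <- loss_of(pe2, pc2)
      set(v)
      fd <- (lp - lm) / (2 * eps)
      if (abs(fd) < 1e-8 && abs(ana[i]) < 1e-8) next  # BN-cancelled param
      expect_lt(abs(ana[i] - fd) / max(abs(fd), 1e-6), 1e-4,
                label = paste(label, "coordinate", i))
    }
  }
  pe2 <- pe; pc2 <- pc
  for (nm in c("proj", "temp", "spat", "d1", "d2", "fc")) {
    fd_check(function() pe2[[nm]]$W,
             function(v) pe2[[nm]]$W <<- v, ge[[nm]]$W, paste("ext", nm))
  }
  fd_check(function() pe2$bn2$gamma,
           function(v) pe2$bn2$gamma <<- v, ge$bn2$gamma, "bn2 gamma")
  for (nm in c("fc1", "fc2")) {
    fd_check(function() pc2[[nm]]$W,
             function(v) pc2[[nm]]$W <<- v, cb$grads[[nm]]$W,
             paste("clf", nm))
  }
})
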