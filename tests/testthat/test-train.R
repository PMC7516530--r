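# Training-loop contracts: seed discipline, the lambda = 0 decoupling, label
# hygiene, the adversarial gradient direction, and divergence handling.
# Heavy end-to-end adaptation runs live in test-acceptance.R.

small_cfg <- function(...) {
  args <- list(batch_size = 8L, max_iter = 10L, seed = 3L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(train_config, args)
}

test_that("training is deterministic given the seed", {
  pair <- fast_pair(n_trials = 6)
  arch <- tiny_arch(c = 8, t = 250, C = 4)
  m1 <- train_da(pair, arch, small_cfg(variant = "cdan"))
  m2 <- train_da(pair, arch, small_cfg(variant = "cdan"))
  expect_identical(m1$traces, m2$traces)
  expect_identical(m1$params, m2$params)
  m3 <- train_da(pair, arch, small_cfg(variant = "cdan", seed = 4L))
  expect_false(identical(m1$traces$L_c, m3$traces$L_c))
})

test_that("cdan with lambda = 0 follows the source-only trajectory exactly", {
  pair <- fast_pair(n_trials = 6)
  arch <- tiny_arch(c = 8, t = 250, C = 4, dropout = 0.3)
  m_src <- train_da(pair, arch, small_cfg(variant = "source_only"),
                    record_params = TRUE)
  m_cdan <- train_da(pair, arch, small_cfg(variant = "cdan", lambda = 0),
                     record_params = TRUE)
  expect_identical(m_src$traces$L_c, m_cdan$traces$L_c)
  for (it in seq_along(m_src$param_trace)) {
    expect_identical(m_src$param_trace[[it]]$clf,
                     m_cdan$param_trace[[it]]$clf)
    expect_identical(m_src$param_trace[[it]]$ext,
                     m_cdan$param_trace[[it]]$ext)
  }
  # the discriminator still trains on its own loss
  expect_true(all(is.finite(m_cdan$traces$L_d)))
})

test_that("target training labels are never read by any variant", {
  pair <- fast_pair(n_trials = 6)
  # the withheld-labels sentinel errors on any read access, so completing
  # training proves the labels were untouched
  expect_s3_class(pair$target_train$labels, "withheld_labels")
  arch <- tiny_arch(c = 8, t = 250, C = 4)
  for (v in c("source_only", "dan", "cdan1", "cdan")) {
    m <- train_da(pair, arch, small_cfg(variant = v, max_iter = 3L))
    expect_s3_class(m, "cdan_model")
  }
})

test_that("one adversarial step raises frozen-discriminator loss versus the
           unreversed step", {
  # construct a tiny model state, then compare the extractor moved along the
  # reversed gradient (+lambda ascent on L_d) with the extractor moved along
  # the unreversed direction, under a frozen discriminator
  arch <- tiny_arch(c = 4, t = 30, C = 3)
  set.seed(11)
  pe <- cdaneeg:::init_extractor(arch)
  pc <- cdaneeg:::init_classifier(arch)
  pd <- cdaneeg:::init_discriminator(arch, "cdan")
  bn <- cdaneeg:::init_bn_stats(arch)
  xs <- array(rnorm(4 * 30 * 6), c(4, 6, 30))
  xt <- array(rnorm(4 * 30 * 6) * 1.5 + 0.3, c(4, 6, 30))

  ld_of <- function(pe_) {
    fs <- cdaneeg:::ext_forward(pe_, arch, xs, bn, train = TRUE)$f
    ft <- cdaneeg:::ext_forward(pe_, arch, xt, bn, train = TRUE)$f
    ps <- cdaneeg:::clf_forward(pc, fs)$p
    pt <- cdaneeg:::clf_forward(pc, ft)$p
    s <- cdaneeg:::disc_forward(pd, cbind(multilinear_map(fs, ps),
                                          multilinear_map(ft, pt)))$score
    discriminator_loss(s[1, 1:6], s[1, 7:12])
  }

  # gradient of L_d w.r.t. extractor parameters (p detached)
  fs <- cdaneeg:::ext_forward(pe, arch, xs, bn, train = TRUE)
  ft <- cdaneeg:::ext_forward(pe, arch, xt, bn, train = TRUE)
  ps <- cdaneeg:::clf_forward(pc, fs$f)$p
  pt <- cdaneeg:::clf_forward(pc, ft$f)$p
  dfw <- cdaneeg:::disc_forward(pd, cbind(multilinear_map(fs$f, ps),
                                          multilinear_map(ft$f, pt)))
  sc <- dfw$score[1, ]
  dlogit <- matrix(c(-(1 - sc[1:6]) / 6, sc[7:12] / 6), 1)
  dh <- cdaneeg:::disc_backward(pd, dfw$cache, dlogit)$dh
  g <- cdaneeg:::add_params(
    cdaneeg:::ext_backward(pe, arch, fs$cache,
                           cdaneeg:::multilinear_backward(dh[, 1:6], ps)),
    cdaneeg:::ext_backward(pe, arch, ft$cache,
                           cdaneeg:::multilinear_backward(dh[, 7:12], pt)))

  alpha <- 1e-3; lambda <- 1
  pe_grl <- cdaneeg:::rmap2(pe, g, function(p, gg) p + alpha * lambda * gg)
  pe_rev <- cdaneeg:::rmap2(pe, g, function(p, gg) p - alpha * lambda * gg)
  l0 <- ld_of(pe)
  expect_gt(ld_of(pe_grl), l0)     # extractor moves adversarially
  expect_lt(ld_of(pe_rev), l0)     # unreversed step helps the discriminator
})

test_that("entropy weights act as constants in the gradient", {
  # the discriminator-logit gradient computed from live entropy weights must
  # equal the one computed from a frozen numeric copy of the same weights
  set.seed(12)
  p <- matrix(rexp(4 * 6), 4); p <- sweep(p, 2, colSums(p), "/")
  s <- runif(6, 0.1, 0.9)
  w_live <- entropy_weight(prediction_entropy(p))
  w_const <- as.numeric(format(w_live, digits = 22))
  g_live <- -w_live * (1 - s) / 6
  g_const <- -w_const * (1 - s) / 6
  expect_identical(g_live, g_const)
})

test_that("the simultaneous GRL update matches alternating updates to first
           order in the learning rate", {
  # quadratic toy in (theta_f, theta_d): L_c = (theta_f - 1)^2 / 2,
  # L_d = (theta_f - theta_d)^2 / 2.  Algorithm: minimise L_c - lambda L_d
  # over theta_f, minimise L_d over theta_d.
  lambda <- 0.6
  gLc <- function(f) f - 1
  gLd_f <- function(f, d) f - d
  gLd_d <- function(f, d) d - f
  grl_step <- function(f, d, a) {
    c(f - a * (gLc(f) - lambda * gLd_f(f, d)), d - a * gLd_d(f, d))
  }
  alt_step <- function(f, d, a) {
    f1 <- f - a * gLc(f)                       # classifier/extractor step
    d1 <- d - a * gLd_d(f1, d)                 # discriminator step
    f2 <- f1 + a * lambda * gLd_f(f1, d1)      # reversed extractor step
    c(f2, d1)
  }
  f0 <- 0.3; d0 <- -0.2
  err <- function(a) max(abs(grl_step(f0, d0, a) - alt_step(f0, d0, a)))
  # halving alpha quarters the discrepancy -> O(alpha^2) agreement
  expect_lt(err(1e-3) / err(2e-3), 0.3)
  expect_lt(err(1e-3), 1e-5)
})

test_that("divergent training aborts with a diagnostic", {
  pair <- fast_pair(n_trials = 4)
  arch <- tiny_arch(c = 8, t = 250, C = 4)
  cfg <- small_cfg(variant = "source_only", max_iter = 40L)
  cfg$alpha0 <- 50
  expect_error(train_da(pair, arch, cfg), "diverged")
})

test_that("config validation rejects bad settings", {
  expect_error(train_config(lambda = 1.5), "lambda")
  expect_error(train_config(alpha0 = 0), "alpha0")
  expect_error(train_config(variant = "gan"), "'arg'")
})
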