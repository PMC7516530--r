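#' Training configuration
#'
#' Hyperparameters of the adversarial training loop.  Defaults follow the
#' method's standard settings: trade-off `lambda = 0.6`, inverse-decay
#' learning rate with `alpha0 = 0.01`, `u = 10`, `beta = 0.75`, SGD momentum
#' 0.9.
#'
#' @param variant one of `"source_only"` (no adaptation), `"dan"`
#'   (discriminator on the raw feature vector), `"cdan1"` (multilinear
#'   conditioning, unweighted), `"cdan"` (multilinear conditioning with
#'   entropy weights).
#' @param lambda adversarial trade-off in `[0, 1]`.
#' @param alpha0,u,beta learning-rate schedule parameters (see
#'   [lr_schedule()]).
#' @param momentum SGD momentum.
#' @param batch_size examples per domain per iteration.
#' @param max_iter iteration budget (the stopping condition).
#' @param seed integer seed controlling initialisation, batch shuffling and
#'   dropout.  Source-side and target-side draws use two independent streams
#'   derived from it, so a `lambda = 0` adversarial run follows exactly the
#'   source-only trajectory.
#' @param standardize apply per-channel standardization fitted on the source
#'   set (frozen and reused for target data).
#' @return an object of class `train_config`.
#' @export
train_config <- function(variant = c("cdan", "cdan1", "dan", "source_only"),
                         lambda = 0.6, alpha0 = 0.01, u = 10, beta = 0.75,
                         momentum = 0.9, batch_size = 32L, max_iter = 300L,
                         seed = 1L, standardize = TRUE) {
  variant <- match.arg(variant)
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  if (alpha0 <= 0) stop("alpha0 must be positive")
  structure(list(variant = variant, lambda = lambda, alpha0 = alpha0,
                 u = u, beta = beta, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 max_iter = as.integer(max_iter), seed = as.integer(seed),
                 standardize = isTRUE(standardize)),
            class = "train_config")
}

## ---- independent RNG streams ----

make_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  with_seed(seed, e$state <- get(".Random.seed", envir = globalenv()))
  e
}

with_stream <- function(stream, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

## ---- recursive parameter-structure arithmetic ----

rmap2 <- function(a, b, f) {
  if (is.list(a)) {
    keys <- if (!is.null(names(a)) && all(nzchar(names(a)))) names(a)
            else seq_along(a)
    for (k in keys) a[[k]] <- rmap2(a[[k]], b[[k]], f)
    a
  } else f(a, b)
}

add_params <- function(a, b) rmap2(a, b, `+`)

# momentum SGD: v <- m v + g ; p <- p - alpha v.  Returns both.
sgd_step <- function(params, vel, grads, alpha, momentum) {
  vel <- rmap2(vel, grads, function(v, g) momentum * v + g)
  params <- rmap2(params, vel, function(p, v) p - alpha * v)
  list(params = params, vel = vel)
}

## ---- training ----

#' Train a decoder with (conditional) domain-adversarial adaptation
#'
#' Runs the minimax training loop: per iteration one labelled source batch
#' and one unlabelled target batch are drawn; both pass through the feature
#' extractor and classifier; the classifier loss `L_c` is computed on the
#' source batch only; the domain discriminator scores both batches (taking
#' the multilinear join of features and detached class probabilities for the
#' conditional variants, the raw features for `"dan"`), weighted by the
#' entropy criterion for `"cdan"`; and a single backward pass updates all
#' three subnetworks by momentum SGD, with the gradient flowing from the
#' discriminator into the extractor multiplied by `-lambda` (the gradient
#' reversal layer).  The learning rate follows the inverse-decay schedule.
#' Target training labels are withheld by construction and are never read.
#'
#' @param pair a [domain_pair()].
#' @param arch an [arch_config()]; its `n_channels`/`n_samples`/`n_classes`
#'   must match the data.
#' @param cfg a [train_config()].
#' @param record_params if `TRUE`, store a snapshot of the extractor and
#'   classifier parameters after every iteration (for trajectory
#'   comparisons; memory-heavy, test use only).
#' @return an object of class `cdan_model`: parameters, batch-norm running
#'   statistics, frozen channel statistics, the configs, and per-iteration
#'   loss traces (`$traces`: `iter`, `L_c`, `L_d`, `alpha`).
#' @export
train_da <- function(pair, arch, cfg, record_params = FALSE) {
  stopifnot(inherits(pair, "domain_pair"), inherits(arch, "arch_config"),
            inherits(cfg, "train_config"))
  src <- pair$source
  tgt <- pair$target_train
  if (n_channels(src) != arch$n_channels || n_samples(src) != arch$n_samples ||
      src$n_classes != arch$n_classes)
    stop("architecture does not match the data: expected (",
         arch$n_channels, ", ", arch$n_samples, ") x ", arch$n_classes,
         " classes, got (", n_channels(src), ", ", n_samples(src), ") x ",
         src$n_classes)
  adversarial <- cfg$variant != "source_only"
  C <- arch$n_classes

  ch_stats <- if (cfg$standardize) fit_channel_stats(src) else NULL
  if (!is.null(ch_stats)) {
    src <- apply_channel_stats(src, ch_stats)
    if (adversarial) tgt <- apply_channel_stats(tgt, ch_stats)
  }
  # (c, n, t) layout: batch slicing on dim 2, time-contiguous convolutions
  xs <- aperm(src$data, c(2L, 1L, 3L))
  ys <- src$labels
  n_s <- n_trials(src)
  if (adversarial) {
    xt <- aperm(tgt$data, c(2L, 1L, 3L))
    n_t <- dim(xt)[2L]
  }

  rs <- make_stream(cfg$seed)
  rt <- make_stream((cfg$seed %% 1000003L) + 499979L)

  par_ext <- with_stream(rs, init_extractor(arch))
  par_clf <- with_stream(rs, init_classifier(arch))
  par_dsc <- if (adversarial)
    with_stream(rt, init_discriminator(arch, cfg$variant)) else NULL
  # domain-specific batch-norm running statistics: each domain is evaluated
  # under its own normalization (the source stats never see target batches
  # and vice versa)
  bn_src <- init_bn_stats(arch)
  bn_tgt <- if (adversarial) init_bn_stats(arch) else NULL
  vel_ext <- zeros_like_params(par_ext)
  vel_clf <- zeros_like_params(par_clf)
  vel_dsc <- if (adversarial) zeros_like_params(par_dsc) else NULL

  bs <- cfg$batch_size
  traces <- data.frame(iter = seq_len(cfg$max_iter), L_c = NA_real_,
                       L_d = NA_real_, alpha = NA_real_)
  snaps <- if (record_params) vector("list", cfg$max_iter) else NULL

  for (it in seq_len(cfg$max_iter)) {
    tau <- (it - 1) / cfg$max_iter
    alpha <- lr_schedule(tau, cfg$alpha0, cfg$u, cfg$beta)

    # ---- source batch: forward through extractor + classifier ----
    src_pass <- with_stream(rs, {
      idx <- sample.int(n_s, bs, replace = bs > n_s)
      fwd <- ext_forward(par_ext, arch, xs[, idx, , drop = FALSE], bn_src,
                         train = TRUE)
      list(idx = idx, fwd = fwd)
    })
    bn_src <- src_pass$fwd$bn
    yb <- ys[src_pass$idx]
    clf_s <- clf_forward(par_clf, src_pass$fwd$f)
    L_c <- classifier_loss(clf_s$p, yb)

    onehot <- matrix(0, C, bs)
    onehot[cbind(yb, seq_len(bs))] <- 1
    dlogits <- (clf_s$p - onehot) / bs
    cb <- clf_backward(par_clf, clf_s$cache, dlogits)
    g_clf <- cb$grads
    df_s <- cb$df

    L_d <- NA_real_
    g_dsc <- NULL
    if (adversarial) {
      tgt_pass <- with_stream(rt, {
        idx <- sample.int(n_t, bs, replace = bs > n_t)
        fwd <- ext_forward(par_ext, arch, xt[, idx, , drop = FALSE], bn_tgt,
                           train = TRUE)
        list(idx = idx, fwd = fwd)
      })
      bn_tgt <- tgt_pass$fwd$bn
      f_s <- src_pass$fwd$f
      f_t <- tgt_pass$fwd$f
      p_t <- clf_forward(par_clf, f_t)$p     # probabilities only; detached

      if (cfg$variant == "dan") {
        h_s <- f_s; h_t <- f_t
      } else {
        h_s <- multilinear_map(f_s, clf_s$p)  # p detached from L_d
        h_t <- multilinear_map(f_t, p_t)
      }
      w_s <- w_t <- rep(1, bs)
      if (cfg$variant == "cdan") {
        w_s <- entropy_weight(prediction_entropy(clf_s$p))
        w_t <- entropy_weight(prediction_entropy(p_t))
      }
      dfw <- disc_forward(par_dsc, cbind(h_s, h_t))
      sc <- pmin(pmax(dfw$score[1L, ], 1e-12), 1 - 1e-12)
      i_s <- seq_len(bs); i_t <- bs + seq_len(bs)
      L_d <- discriminator_loss(sc[i_s], sc[i_t], w_s, w_t)
      # d L_d / d logit (weights are constants)
      dlogit <- matrix(0, 1L, 2L * bs)
      dlogit[1L, i_s] <- -w_s * (1 - sc[i_s]) / bs
      dlogit[1L, i_t] <- w_t * sc[i_t] / bs
      db <- disc_backward(par_dsc, dfw$cache, dlogit)
      g_dsc <- db$grads
      # gradient reversal into the extractor
      dh <- -cfg$lambda * db$dh
      if (cfg$variant == "dan") {
        df_adv_s <- dh[, i_s, drop = FALSE]
        df_adv_t <- dh[, i_t, drop = FALSE]
      } else {
        df_adv_s <- multilinear_backward(dh[, i_s, drop = FALSE], clf_s$p)
        df_adv_t <- multilinear_backward(dh[, i_t, drop = FALSE], p_t)
      }
      g_ext <- add_params(
        ext_backward(par_ext, arch, src_pass$fwd$cache, df_s + df_adv_s),
        ext_backward(par_ext, arch, tgt_pass$fwd$cache, df_adv_t))
    } else {
      g_ext <- ext_backward(par_ext, arch, src_pass$fwd$cache, df_s)
    }

    if (!is.finite(L_c) || (adversarial && !is.finite(L_d)))
      stop(sprintf("training diverged at iteration %d (L_c = %g, L_d = %g); last alpha = %g",
                   it, L_c, L_d, alpha))

    st <- sgd_step(par_ext, vel_ext, g_ext, alpha, cfg$momentum)
    par_ext <- st$params; vel_ext <- st$vel
    st <- sgd_step(par_clf, vel_clf, g_clf, alpha, cfg$momentum)
    par_clf <- st$params; vel_clf <- st$vel
    if (adversarial) {
      st <- sgd_step(par_dsc, vel_dsc, g_dsc, alpha, cfg$momentum)
      par_dsc <- st$params; vel_dsc <- st$vel
    }

    traces$L_c[it] <- L_c
    traces$L_d[it] <- L_d
    traces$alpha[it] <- alpha
    if (record_params) snaps[[it]] <- list(ext = par_ext, clf = par_clf)
  }

  structure(list(arch = arch, cfg = cfg, variant = cfg$variant,
                 params = list(ext = par_ext, clf = par_clf, disc = par_dsc),
                 bn = list(source = bn_src, target = bn_tgt),
                 target_subject = pair$target_train$subject_id,
                 channel_stats = ch_stats, traces = traces,
                 param_trace = snaps),
            class = "cdan_model")
}

#' @export
print.cdan_model <- function(x, ...) {
  cat(sprintf("<cdan_model> variant %s: (%d ch x %d samples) -> d_f = %d, %d classes; %d iterations\n",
              x$variant, x$arch$n_channels, x$arch$n_samples, x$arch$d_f,
              x$arch$n_classes, nrow(x$traces)))
  invisible(x)
}

## ---- inference ----

#' Extract features / class probabilities from a trained model
#'
#' Evaluation-mode forward passes: dropout off, batch-norm running
#' statistics, frozen channel standardization.  Batch normalization keeps
#' separate running statistics per domain during adversarial training;
#' `domain = "auto"` (the default) normalizes with the target statistics
#' when the model has them — the trained decoder serves the target subject —
#' and with the source statistics otherwise (or for source-domain
#' diagnostics via `domain = "source"`).
#'
#' @param model a `cdan_model` from [train_da()].
#' @param trials an [eeg_trial_set()] (labels, if any, are ignored).
#' @param batch internal mini-batch size for the forward pass.
#' @param domain which domain's batch-norm statistics to use: `"auto"`,
#'   `"target"` or `"source"`.
#' @return `extract_features()`: an `n x d_f` matrix.
#'   `predict_proba()`: an `n x C` matrix of class probabilities (rows sum
#'   to 1).  `predict_classes()`: integer vector of argmax classes.
#' @export
extract_features <- function(model, trials, batch = 256L,
                             domain = c("auto", "target", "source")) {
  stopifnot(inherits(model, "cdan_model"), inherits(trials, "eeg_trial_set"))
  domain <- match.arg(domain)
  bn <- switch(domain,
               auto = model$bn$target %||% model$bn$source,
               target = model$bn$target %||%
                 stop("model has no target-domain statistics"),
               source = model$bn$source)
  if (!is.null(model$channel_stats))
    trials <- apply_channel_stats(trials, model$channel_stats)
  x <- aperm(trials$data, c(2L, 1L, 3L))
  n <- dim(x)[2L]
  out <- matrix(0, n, model$arch$d_f)
  for (at in seq(1L, n, by = batch)) {
    idx <- at:min(at + batch - 1L, n)
    fwd <- ext_forward(model$params$ext, model$arch,
                       x[, idx, , drop = FALSE], bn, train = FALSE)
    out[idx, ] <- t(fwd$f)
  }
  out
}

#' @rdname extract_features
#' @export
predict_proba <- function(model, trials, batch = 256L,
                          domain = c("auto", "target", "source")) {
  f <- extract_features(model, trials, batch, domain = domain)
  t(clf_forward(model$params$clf, t(f))$p)
}

#' @rdname extract_features
#' @export
predict_classes <- function(model, trials, batch = 256L,
                            domain = c("auto", "target", "source")) {
  p <- predict_proba(model, trials, batch, domain = domain)
  max.col(p, ties.method = "first")
}

#' Classifier and discriminator heads as standalone maps
#'
#' `classify()` maps extracted feature vectors to logits and softmax
#' probabilities with a trained model's classifier head; `discriminate()`
#' scores conditional features with its domain discriminator (source ~ 1,
#' target ~ 0).  Both accept one column per example.
#'
#' @param model a `cdan_model`.
#' @param f feature matrix `(d_f x n)` or a single feature vector.
#' @param h conditional-feature matrix (`(d_f*C) x n` for conditional
#'   variants, `d_f x n` for `"dan"`) or a single vector.
#' @return `classify()`: list with `logits` (`C x n`) and `p` (`C x n`);
#'   `discriminate()`: numeric vector of domain scores in `(0, 1)`.
#' @export
classify <- function(model, f) {
  if (!is.matrix(f)) f <- matrix(f, ncol = 1L)
  r <- clf_forward(model$params$clf, f)
  list(logits = r$logits, p = r$p)
}

#' @rdname classify
#' @export
discriminate <- function(model, h) {
  if (is.null(model$params$disc))
    stop("model variant '", model$variant, "' has no discriminator")
  if (!is.matrix(h)) h <- matrix(h, ncol = 1L)
  as.vector(disc_forward(model$params$disc, h)$score)
}
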