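#' The calibrated cross-subject adaptation study
#'
#' Runs the package's end-to-end experiment at its standard desk-scale
#' conditions: a synthetic pool of `n_subjects` subjects under the default
#' generator settings (100 trials/class/subject, 8 channels, 4-s trials at
#' 125 Hz, 4 classes, the calibrated inter-subject domain shift), trials
#' cropped to their first 2 s for the network, the last subject held out as
#' the unlabelled target, and every requested variant trained for `n_seeds`
#' seeds with the reduced architecture described in the methods vignette.
#'
#' The adversarial trade-off is `lambda = 0.6` for the conditional variants
#' (`cdan`, `cdan1`).  The unconditional `dan` uses `lambda = 0.15`: with
#' the full trade-off its discriminator drives the scaled-down extractor
#' into the degenerate domain-invariant solution (features collapse and the
#' classifier returns to chance) — the failure mode that multilinear
#' conditioning is designed to prevent — while at 0.15 it adapts stably.
#'
#' @param seed master seed; drives the generator and the per-run training
#'   seeds (`seed + 0:(n_seeds-1)`).
#' @param variants variants to train.
#' @param n_seeds training seeds per variant.
#' @param n_subjects pool size (last subject is the target).
#' @param max_iter iteration budget per run.
#' @param trials_per_class generator trials per class per subject.
#' @return list with `results` (per-run data.frame from
#'   [compare_variants()]), `summary` (per-variant mean/sd target accuracy)
#'   and the `arch`/`cfg` used.
#' @export
adaptation_study <- function(seed = 1L,
                             variants = c("source_only", "dan", "cdan1",
                                          "cdan"),
                             n_seeds = 5L, n_subjects = 3L,
                             max_iter = 200L, trials_per_class = 100L) {
  spec <- synthetic_spec(n_trials = trials_per_class, seed = seed)
  pool <- lapply(generate_pool(spec, n_subjects),
                 function(s) crop_window(s, 0, 2))
  pair <- leave_one_out(pool, n_subjects)
  arch <- study_arch(n_samples(pair$source))
  lambda_for <- c(source_only = 0.6, dan = 0.15, cdan1 = 0.6, cdan = 0.6)
  rows <- list()
  for (v in variants) {
    cfg <- train_config(variant = v, lambda = lambda_for[[v]],
                        max_iter = max_iter, batch_size = 32L, seed = seed)
    rows[[v]] <- compare_variants(pair, v, n_seeds, arch, cfg,
                                  base_seed = seed)
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  list(results = results, summary = summarize_comparison(results),
       arch = arch, spec = spec)
}

# the reduced architecture used for the package's own experiments
study_arch <- function(t, c = 8L, C = 4L) {
  arch_config(c, t, C, n_proj = 8L, n_temp = 8L, n_spat = 8L,
              n_dense = 16L, k_temporal = 25L, k_dense = 11L,
              pool1 = 3L, pool2 = 3L, d_f = 32L, clf_hidden = 32L,
              disc_hidden = 32L, dropout = 0)
}

#' Sign-recovery study for the correlation maps
#'
#' Generates two-class data in which class 1 carries *elevated* 10 Hz power
#' on a known channel group (channels 1-2), trains a conditional
#' adversarial decoder, and reports the mean alpha-band correlation of
#' class 1 on that group.  A model that has learned the task must show a
#' positive value: more alpha power on the driving channels pushes
#' predictions toward class 1.
#'
#' Measurement choices: the map is taken on the source-domain trials (where
#' the trained decoder is accurate, so its responses carry signal) on the
#' logit scale (softmax probabilities saturate for confident models, which
#' suppresses the perturbation response; see [correlation_map()]).  The
#' two-class adversary runs at `lambda = 0.3`: with only two classes the
#' conditional features lose most of their class structure and the full
#' trade-off destabilises training, mirroring the unconditional case.
#'
#' @param seed master seed.
#' @param n_seeds how many independent trainings to run.
#' @param max_iter iteration budget per training.
#' @return data.frame with one row per seed: the mean correlation on the
#'   driving group (`r_group`), the mean absolute correlation elsewhere
#'   (`r_other`), and the training seed.
#' @export
sign_recovery_study <- function(seed = 1L, n_seeds = 3L, max_iter = 200L) {
  spec <- synthetic_spec(
    n_trials = 60L, n_channels = 8L, n_classes = 2L, n_samples = 250L,
    sources = list(
      list(channels = 1:2, freq = 10, bw = 2, amp = 12,
           class_mult = c(3, 1)),
      list(channels = 5:6, freq = 20, bw = 4, amp = 6,
           class_mult = c(1, 1))),
    domain_shift = list(gain_sd = 0.2, tilt_sd = 0.15, noise_mean = 3,
                        noise_sd = 0.3),
    seed = seed)
  pool <- generate_pool(spec, 3L)
  pair <- leave_one_out(pool, 3L)
  arch <- study_arch(250L, c = 8L, C = 2L)
  rows <- lapply(seq_len(n_seeds), function(i) {
    cfg <- train_config(variant = "cdan", lambda = 0.3,
                        max_iter = max_iter, batch_size = 32L,
                        seed = seed + i - 1L)
    model <- train_da(pair, arch, cfg)
    map <- correlation_map(model, pair$source,
                           bands = list(alpha = c(7, 13)),
                           n_repeats = 10L, noise_sd = 30,
                           seed = seed + i - 1L,
                           output = "logit", domain = "source")
    vals <- map$values[1L, , 1L]          # alpha band, class 1
    data.frame(seed = cfg$seed, r_group = mean(vals[1:2]),
               r_other = mean(abs(vals[3:8])))
  })
  do.call(rbind, rows)
}
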