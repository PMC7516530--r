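# Shared fixtures: tiny trial sets, a small architecture, and a fast
# synthetic spec.  Everything is generated in code at test time.

toy_trials <- function(n = 5, c = 3, t = 40, fs = 100, seed = 7,
                       labels = NULL, n_classes = 4L) {
  set.seed(seed)
  eeg_trial_set(array(rnorm(n * c * t), c(n, c, t)), labels, fs,
                n_classes = n_classes)
}

tiny_arch <- function(c = 3, t = 40, C = 3, dropout = 0, ...) {
  arch_config(n_channels = c, n_samples = t, n_classes = C,
              n_proj = 4, n_temp = 3, n_spat = 3, n_dense = 4,
              k_temporal = 5, k_dense = 3, pool1 = 2, pool2 = 2,
              d_f = 6, clf_hidden = 5, disc_hidden = 4,
              dropout = dropout, ...)
}

fast_spec <- function(n_trials = 12, seed = 1, ...) {
  synthetic_spec(n_trials = n_trials, n_samples = 250, seed = seed, ...)
}

# a small domain pair with real class structure, cheap enough for training
# smoke tests
fast_pair <- function(n_trials = 12, n_subjects = 3, target = n_subjects,
                      seed = 1) {
  leave_one_out(generate_pool(fast_spec(n_trials, seed), n_subjects), target)
}

expect_rel_equal <- function(actual, expected, tol = 1e-9) {
  expect_lt(max(abs(actual - expected)) / max(abs(expected), 1e-12), tol)
}

with_seed_local <- function(seed, expr) {
  set.seed(seed)
  expr
}
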