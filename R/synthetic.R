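#' Specification for the synthetic multi-subject EEG generator
#'
#' The generator emulates the statistics that make cross-subject motor-imagery
#' decoding hard: every channel carries 1/f background noise; narrowband
#' oscillatory sources (mu/alpha and beta rhythms) ride on top as band-pass
#' filtered Gaussian noise, whose Rayleigh-distributed envelope gives the
#' burst-like amplitude modulation of real sensorimotor rhythms; and each
#' class modulates the power of specific sources on specific channel groups
#' (event-related desynchronization appears as a power multiplier < 1 on the
#' contralateral group).  Each subject then receives a private domain shift —
#' per-channel gains, a spectral tilt, and extra sensor noise — drawn from the
#' subject's seed, which is what makes a source-only classifier degrade on a
#' held-out subject.
#'
#' Each element of `sources` is a list with fields `channels` (integer
#' indices), `freq` and `bw` (centre frequency and bandwidth in Hz), `amp`
#' (RMS amplitude in microvolts at multiplier 1) and `class_mult` (length-`C`
#' vector of per-class power multipliers; amplitude scales with its square
#' root).
#'
#' @param n_trials trials per class per subject.
#' @param n_channels,n_samples,fs,n_classes trial geometry.
#' @param background list with `exponent` (power-spectrum slope of the 1/f
#'   noise) and `scale` (RMS microvolts).
#' @param sources list of oscillatory source descriptions (see Details);
#'   `NULL` gives the default motor-imagery layout for 8 channels / 4 classes.
#' @param domain_shift list with `gain_sd` (sd of per-channel log-gains),
#'   `tilt_sd` (sd of the per-subject spectral-tilt exponent), `noise_mean`
#'   and `noise_sd` (log-normal extra white-noise RMS, microvolts).
#' @param seed integer master seed; together with the subject index it fully
#'   determines every generated sample.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_trials = 100L, n_channels = 8L,
                           n_samples = 500L, fs = 125, n_classes = 4L,
                           background = list(exponent = 1, scale = 6),
                           sources = NULL,
                           domain_shift = list(gain_sd = 0.4, tilt_sd = 0.3,
                                               noise_mean = 4, noise_sd = 0.5),
                           seed = 1L) {
  if (is.null(sources))
    sources <- default_mi_sources(n_channels, n_classes)
  for (s in sources) {
    if (s$freq - s$bw / 2 <= 0 || s$freq + s$bw / 2 >= fs / 2)
      stop("source band ", s$freq, " +/- ", s$bw / 2,
           " Hz lies outside (0, fs/2)")
    if (any(s$channels < 1L) || any(s$channels > n_channels))
      stop("source channel index out of range")
    if (length(s$class_mult) != n_classes)
      stop("class_mult must have one multiplier per class")
    if (any(s$class_mult <= 0)) stop("power multipliers must be positive")
  }
  structure(list(n_trials = as.integer(n_trials),
                 n_channels = as.integer(n_channels),
                 n_samples = as.integer(n_samples), fs = fs,
                 n_classes = as.integer(n_classes), background = background,
                 sources = sources, domain_shift = domain_shift,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Default lateralized rhythm layout on 8 channels: left {1,2}, right {3,4},
# central {5,6}, posterior {7,8}.  Class 1 = left hand (alpha/beta ERD on the
# right, i.e. contralateral, group), class 2 = right hand, class 3 = feet
# (central ERD), class 4 = rest (mild alpha increase).
default_mi_sources <- function(n_channels, n_classes) {
  if (n_channels < 8L || n_classes != 4L)
    stop("the default source layout needs >= 8 channels and 4 classes; ",
         "pass `sources` explicitly for other geometries")
  grp <- list(left = 1:2, right = 3:4, central = 5:6, posterior = 7:8)
  list(
    list(channels = grp$left,      freq = 10, bw = 2, amp = 10,
         class_mult = c(1, 0.25, 1, 1.3)),
    list(channels = grp$right,     freq = 10, bw = 2, amp = 10,
         class_mult = c(0.25, 1, 1, 1.3)),
    list(channels = grp$central,   freq = 10, bw = 2, amp = 8,
         class_mult = c(1, 1, 0.25, 1.3)),
    list(channels = grp$left,      freq = 20, bw = 4, amp = 6,
         class_mult = c(1, 0.4, 1, 1)),
    list(channels = grp$right,     freq = 20, bw = 4, amp = 6,
         class_mult = c(0.4, 1, 1, 1)),
    list(channels = grp$central,   freq = 20, bw = 4, amp = 6,
         class_mult = c(1, 1, 0.4, 1)),
    list(channels = grp$posterior, freq = 10, bw = 2, amp = 10,
         class_mult = c(1, 1, 1, 1.3)))
}

# evaluate an expression under a temporary RNG seed, restoring global state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# spectral amplitude shapes on the two-sided FFT frequency grid
fft_freqs <- function(t, fs) {
  f <- fs * (0:(t - 1)) / t
  pmin(f, fs - f)
}

# shaped Gaussian noise: one column per signal, unit expected RMS
shaped_noise <- function(t, m, shape) {
  w <- matrix(stats::rnorm(t * m), t, m)
  wf <- stats::mvfft(w) * shape
  y <- Re(stats::mvfft(wf, inverse = TRUE)) / t
  norm <- sqrt(mean(shape^2))
  if (norm < 1e-300) stop("spectral shape selects no frequency content")
  y / norm
}

#' Generate one synthetic subject
#'
#' Trials are synthesised class by class: 1/f background plus the
#' class-scaled narrowband sources, then the subject's domain shift is
#' applied in the order gain, spectral tilt, additive sensor noise.  The
#' subject index (not the id string) enters the seed, so a subject's data is
#' reproducible in isolation.
#'
#' @param spec a [synthetic_spec()].
#' @param subject_index positive integer; selects the subject's private
#'   domain shift and noise realisation.
#' @param subject_id id string; default `"sub<index>"`.
#' @return a labelled [eeg_trial_set()].
#' @export
generate_subject <- function(spec, subject_index, subject_id = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  subject_index <- as.integer(subject_index)
  if (subject_index < 1L) stop("subject_index must be >= 1")
  if (is.null(subject_id)) subject_id <- sprintf("sub%02d", subject_index)
  t <- spec$n_samples; c <- spec$n_channels; C <- spec$n_classes
  n <- spec$n_trials * C
  fs <- spec$fs
  with_seed(spec$seed + 7919L * subject_index, {
    ds <- spec$domain_shift
    gains <- exp(stats::rnorm(c, 0, ds$gain_sd))
    tilt <- stats::rnorm(1, 0, ds$tilt_sd)
    noise_rms <- ds$noise_mean * exp(stats::rnorm(1, 0, ds$noise_sd))
    labels <- sample(rep(seq_len(C), spec$n_trials))

    f <- fft_freqs(t, fs)
    bg_shape <- (pmax(f, 1))^(-spec$background$exponent / 2)
    bg_shape[1L] <- 0                     # no DC offset
    # signal matrix: columns ordered (channel fastest, then trial)
    x <- spec$background$scale * shaped_noise(t, n * c, bg_shape)
    dim(x) <- c(t, c, n)
    for (s in spec$sources) {
      shp <- exp(-(f - s$freq)^2 / (2 * (s$bw / 2)^2))
      nb <- shaped_noise(t, n * length(s$channels), shp)
      dim(nb) <- c(t, length(s$channels), n)
      ampl <- s$amp * sqrt(s$class_mult[labels])   # per trial
      for (k in seq_along(s$channels))
        x[, s$channels[k], ] <- x[, s$channels[k], ] +
          nb[, k, ] * rep(ampl, each = t)
    }
    # domain shift: gain -> tilt -> additive noise
    x <- x * rep(gains, each = t)
    if (abs(tilt) > 0) {
      tilt_shape <- (pmax(f, 1) / 10)^(-tilt / 2)   # unity at 10 Hz
      dim(x) <- c(t, c * n)
      x <- Re(stats::mvfft(stats::mvfft(x) * tilt_shape, inverse = TRUE)) / t
    }
    dim(x) <- c(t, c * n)
    x <- x + noise_rms * matrix(stats::rnorm(t * c * n), t, c * n)
    dim(x) <- c(t, c, n)
    eeg_trial_set(aperm(x, c(3, 2, 1)), labels, fs,
                  subject_id = subject_id, n_classes = C)
  })
}

#' Generate a pool of subjects
#'
#' @param spec a [synthetic_spec()].
#' @param n_subjects number of subjects.
#' @return list of labelled [eeg_trial_set()] objects.
#' @export
generate_pool <- function(spec, n_subjects) {
  lapply(seq_len(n_subjects), function(j) generate_subject(spec, j))
}

#' Leave-one-subject-out domain pair
#'
#' Pools every subject except `j` as the labelled source domain; subject
#' `j`'s trials become the target domain, split (stratified by class, last
#' fraction per class) into an unlabelled adaptation set and a labelled test
#' set.
#'
#' @param pool list of labelled [eeg_trial_set()] (one per subject).
#' @param j index of the target subject.
#' @param test_frac fraction of target trials held out for testing.
#' @return a [domain_pair()].
#' @export
leave_one_out <- function(pool, j, test_frac = 0.2) {
  j <- as.integer(j)
  if (j < 1L || j > length(pool))
    stop("target subject index ", j, " out of range 1..", length(pool))
  source <- concat_trials(pool[-j], subject_id = "source_pool")
  tgt <- pool[[j]]
  if (is.null(tgt$labels)) stop("pool subjects must be labelled")
  test_idx <- integer(0)
  for (k in sort(unique(tgt$labels))) {
    idx <- which(tgt$labels == k)
    n_test <- max(1L, ceiling(length(idx) * test_frac))
    test_idx <- c(test_idx, utils::tail(idx, n_test))
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(n_trials(tgt)), test_idx)
  domain_pair(source,
              subset_trials(tgt, train_idx),
              subset_trials(tgt, test_idx))
}

#' Welch band power
#'
#' Average power in `[lo, hi]` Hz via Welch's method (Hann windows, 50%
#' overlap).  Used by the generator's oracle checks and by the interpretation
#' module's tests.
#'
#' @param x numeric vector (one signal).
#' @param fs sampling rate in Hz.
#' @param lo,hi band edges in Hz.
#' @param nperseg segment length (default 128 or the signal length).
#' @return mean power spectral density within the band.
#' @export
band_power <- function(x, fs, lo, hi, nperseg = min(128L, length(x))) {
  x <- as.numeric(x)
  step <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, length(x) - nperseg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  scale <- sum(win^2)
  f <- fs * (0:(nperseg - 1)) / nperseg
  keep <- f >= lo & f <= hi & f <= fs / 2
  if (!any(keep)) stop("band [", lo, ", ", hi, "] Hz contains no FFT bins")
  pxx <- 0
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)] * win
    pxx <- pxx + Mod(stats::fft(seg))^2 / scale
  }
  mean(pxx[keep]) / length(starts)
}

#' Mean band power per trial over a channel group
#'
#' @param trials an [eeg_trial_set()].
#' @param lo,hi band edges in Hz.
#' @param channels integer channel indices (default all).
#' @return numeric vector, one value per trial.
#' @export
trial_band_power <- function(trials, lo, hi,
                             channels = seq_len(n_channels(trials))) {
  vapply(seq_len(n_trials(trials)), function(i) {
    mean(vapply(channels, function(j)
      band_power(trials$data[i, j, ], trials$fs, lo, hi), numeric(1L)))
  }, numeric(1L))
}

# log-log spectral slope over [lo, hi] Hz, for the 1/f invariant check
spectral_slope <- function(x, fs, lo = 2, hi = 40) {
  nper <- min(256L, length(x))
  f <- fs * (0:(nper - 1)) / nper
  keep <- f >= lo & f <= hi
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))
  step <- nper %/% 2L
  starts <- seq(1L, length(x) - nper + 1L, by = max(1L, step))
  pxx <- 0
  for (s in starts) pxx <- pxx + Mod(stats::fft(x[s:(s + nper - 1L)] * win))^2
  stats::coef(stats::lm(log(pxx[keep]) ~ log(f[keep])))[[2L]]
}
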