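#' Select (and reorder) channels by name
#'
#' Motor-imagery pipelines typically keep only the sensors over sensorimotor
#' cortex (44 of the 128 recorded channels for the High Gamma Dataset).  The
#' returned set has channels in the order of `keep`; data values are copied
#' unchanged and labels pass through untouched.
#'
#' @param trials an [eeg_trial_set()].
#' @param keep character vector of channel names to retain, in output order.
#' @return an `eeg_trial_set` with `length(keep)` channels.
#' @export
select_channels <- function(trials, keep) {
  stopifnot(inherits(trials, "eeg_trial_set"))
  keep <- as.character(keep)
  idx <- match(keep, trials$channel_names)
  if (anyNA(idx))
    stop("unknown channel name(s): ",
         paste(keep[is.na(idx)], collapse = ", "))
  eeg_trial_set(trials$data[, idx, , drop = FALSE], trials$labels, trials$fs,
                keep, trials$subject_id, trials$n_classes)
}

#' Crop a cue-relative time window from every trial
#'
#' Extracts `[t0, t1)` seconds relative to the cue sample of each trial.  For
#' pre-epoched data where every stored trial already starts at the beginning
#' of the window of interest (the usual cue-locked layout), leave `cue_index`
#' as `NULL`: the window then starts at the first stored sample and `t0`/`t1`
#' only determine its length.  The output has
#' `round((t1 - t0) * fs)` samples; with `fs = 250`, `t0 = -0.5`, `t1 = 4`
#' that is the conventional 1125-sample motor-imagery epoch.
#'
#' @param trials an [eeg_trial_set()].
#' @param t0,t1 window start / end in seconds relative to the cue.
#' @param cue_index 1-based cue sample, either a scalar (same for all trials)
#'   or one value per trial; `NULL` means the window begins at sample 1.
#' @return an `eeg_trial_set` with the cropped samples.
#' @export
crop_window <- function(trials, t0, t1, cue_index = NULL) {
  stopifnot(inherits(trials, "eeg_trial_set"))
  len <- round((t1 - t0) * trials$fs)
  if (len < 1L)
    stop("empty window: t1 must exceed t0 by at least one sample period")
  n <- n_trials(trials); t <- n_samples(trials)
  start <- if (is.null(cue_index)) rep(1L, n)
           else as.integer(cue_index) + as.integer(round(t0 * trials$fs))
  if (length(start) == 1L) start <- rep(start, n)
  if (length(start) != n) stop("`cue_index` must be scalar or one per trial")
  bad <- which(start < 1L | start + len - 1L > t)
  if (length(bad))
    stop(sprintf("window [%g, %g] s exceeds trial bounds for trial %d (samples %d..%d of %d)",
                 t0, t1, bad[1L], start[bad[1L]], start[bad[1L]] + len - 1L, t))
  out <- array(0, c(n, n_channels(trials), len))
  if (length(unique(start)) == 1L) {
    out <- trials$data[, , start[1L]:(start[1L] + len - 1L), drop = FALSE]
  } else {
    for (i in seq_len(n))
      out[i, , ] <- trials$data[i, , start[i]:(start[i] + len - 1L)]
  }
  eeg_trial_set(out, trials$labels, trials$fs, trials$channel_names,
                trials$subject_id, trials$n_classes)
}

#' Resample all trials to a new rate
#'
#' Polyphase resampling with built-in anti-aliasing (via
#' [signal::resample()]), applied channel by channel.  The rational
#' resampling factor is `fs_new / fs` reduced to lowest terms; the output
#' length is `round(t * fs_new / fs)`.
#'
#' @param trials an [eeg_trial_set()].
#' @param fs_new target sampling rate in Hz.
#' @return an `eeg_trial_set` at `fs_new`.
#' @export
resample_trials <- function(trials, fs_new) {
  stopifnot(inherits(trials, "eeg_trial_set"))
  if (!is.numeric(fs_new) || fs_new <= 0) stop("`fs_new` must be positive")
  if (fs_new == trials$fs) return(trials)
  # rational factor p/q in lowest terms (rates are kHz-scale integers/halves)
  scale <- 1e6
  p <- round(fs_new * scale); q <- round(trials$fs * scale)
  g <- gcd_int(p, q); p <- p / g; q <- q / g
  n <- n_trials(trials); c <- n_channels(trials); t <- n_samples(trials)
  t_new <- round(t * fs_new / trials$fs)
  out <- array(0, c(n, c, t_new))
  for (i in seq_len(n)) for (j in seq_len(c)) {
    y <- signal::resample(trials$data[i, j, ], p, q)
    out[i, j, ] <- y[seq_len(t_new)]
  }
  eeg_trial_set(out, trials$labels, fs_new, trials$channel_names,
                trials$subject_id, trials$n_classes)
}

gcd_int <- function(a, b) {
  while (b != 0) { r <- a %% b; a <- b; b <- r }
  a
}

#' Per-channel standardization statistics
#'
#' Computes, per channel, the mean and standard deviation over all trials and
#' time points of a (source training) set.  The statistics are frozen and
#' reapplied to any later data — including target-domain trials — so the
#' network always sees inputs on the scale of its training distribution.
#'
#' @param trials an [eeg_trial_set()] (typically the labelled source set).
#' @return list with numeric vectors `mean` and `sd` (one entry per channel).
#' @export
fit_channel_stats <- function(trials) {
  stopifnot(inherits(trials, "eeg_trial_set"))
  c <- n_channels(trials)
  m <- numeric(c); s <- numeric(c)
  for (j in seq_len(c)) {
    v <- trials$data[, j, ]
    m[j] <- mean(v)
    s[j] <- stats::sd(as.vector(v))
    if (!is.finite(s[j]) || s[j] < 1e-12) s[j] <- 1
  }
  list(mean = m, sd = s, channel_names = trials$channel_names)
}

#' Apply frozen channel statistics
#'
#' @param trials an [eeg_trial_set()].
#' @param stats result of [fit_channel_stats()].
#' @return standardized `eeg_trial_set`.
#' @export
apply_channel_stats <- function(trials, stats) {
  stopifnot(inherits(trials, "eeg_trial_set"))
  if (length(stats$mean) != n_channels(trials))
    stop("channel statistics do not match the number of channels")
  out <- trials$data
  for (j in seq_len(n_channels(trials)))
    out[, j, ] <- (out[, j, ] - stats$mean[j]) / stats$sd[j]
  eeg_trial_set(out, trials$labels, trials$fs, trials$channel_names,
                trials$subject_id, trials$n_classes)
}
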