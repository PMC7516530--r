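#' Perturb band amplitudes of all trials
#'
#' Transforms every channel of every trial to the frequency domain, adds
#' i.i.d. Gaussian noise (mean 0, standard deviation `noise_sd`) to the
#' amplitude of every FFT bin inside `band`, clips amplitudes at zero,
#' preserves phases (conjugate symmetry is maintained so the inverse
#' transform is real), and returns the time-domain signals together with the
#' net amplitude change per trial and channel.
#'
#' @param trials an [eeg_trial_set()].
#' @param band numeric `c(lo, hi)` in Hz, inside `(0, fs/2)`.
#' @param noise_sd standard deviation of the amplitude noise (the standard
#'   perturbation uses 1).
#' @param seed integer seed for the noise draw.
#' @return list with `trials` (perturbed `eeg_trial_set`) and `deltas`
#'   (`n_trials x n_channels` matrix of summed amplitude changes).
#' @export
perturb_amplitudes <- function(trials, band, noise_sd = 1, seed = 1L) {
  stopifnot(inherits(trials, "eeg_trial_set"), length(band) == 2L)
  fs <- trials$fs
  t <- n_samples(trials); c <- n_channels(trials); n <- n_trials(trials)
  f <- fs * (0:(t - 1)) / t
  idx <- which(f >= band[1L] & f <= band[2L] & f <= fs / 2 & f > 0)
  if (!length(idx))
    stop("band [", band[1L], ", ", band[2L],
         "] Hz contains no FFT bins at fs = ", fs)
  mirror <- t - idx + 2L                  # conjugate bins (t+2-k), 1-based
  self_conj <- mirror == idx | mirror > t # Nyquist bin / none
  x <- aperm(trials$data, c(3L, 2L, 1L))  # (t, c, n)
  dim(x) <- c(t, c * n)
  xf <- stats::mvfft(x)
  mag <- Mod(xf[idx, , drop = FALSE])
  ph <- Arg(xf[idx, , drop = FALSE])
  noise <- with_seed(seed,
    matrix(stats::rnorm(length(idx) * c * n, 0, noise_sd), length(idx)))
  new_mag <- pmax(mag + noise, 0)
  xf[idx, ] <- new_mag * exp(1i * ph)
  keep <- !self_conj
  if (any(keep))
    xf[mirror[keep], ] <- Conj(xf[idx[keep], , drop = FALSE])
  y <- Re(stats::mvfft(xf, inverse = TRUE)) / t
  dim(y) <- c(t, c, n)
  dmag <- new_mag - mag
  dim(dmag) <- c(length(idx), c, n)
  deltas <- t(colSums(dmag))              # (n, c): summed change per channel
  out <- trials
  out$data <- aperm(y, c(3L, 2L, 1L))
  list(trials = out, deltas = deltas)
}

#' Perturbation-based feature correlation map
#'
#' For each frequency band, repeatedly perturbs the band amplitudes of all
#' trials ([perturb_amplitudes()]), runs the model on the original and the
#' perturbed trials, and correlates (Pearson) the per-channel amplitude
#' change with the per-class change in predicted probability across all
#' (trial, repeat) pairs.  Positive values mean that more band power on that
#' electrode pushes the model toward that class.  Channels or classes with
#' zero variance yield a correlation of 0 and are flagged.
#'
#' @param model a `cdan_model` from [train_da()], or any function mapping an
#'   `eeg_trial_set` to an `n x C` matrix of class scores (useful for
#'   surrogate models in validation).
#' @param trials an [eeg_trial_set()] (labels not needed).
#' @param bands named list of `c(lo, hi)` Hz pairs; the default covers the
#'   alpha (7-13), beta (13-31) and gamma (71-91) bands.
#' @param n_repeats perturbation repeats per band.
#' @param noise_sd amplitude-noise standard deviation.
#' @param seed integer seed; the map is bitwise reproducible given it.
#' @param output correlate against softmax probabilities (default) or
#'   pre-softmax logits.  Probabilities saturate for a confident model
#'   (near-zero sensitivity to input perturbations); the logit scale keeps
#'   the response linear and is the better choice for validation studies.
#' @param domain which batch-norm statistics a `cdan_model` should use (see
#'   [predict_proba()]); ignored for function models.
#' @return an object of class `correlation_map`: `values` is an array
#'   `(n_bands, n_channels, n_classes)` of correlations in `[-1, 1]`,
#'   `zero_var` a parallel logical array flagging degenerate entries.
#' @export
correlation_map <- function(model, trials,
                            bands = list(alpha = c(7, 13), beta = c(13, 31),
                                         gamma = c(71, 91)),
                            n_repeats = 10L, noise_sd = 1, seed = 1L,
                            output = c("probability", "logit"),
                            domain = c("auto", "target", "source")) {
  stopifnot(inherits(model, "cdan_model") || is.function(model),
            inherits(trials, "eeg_trial_set"))
  output <- match.arg(output)
  domain <- match.arg(domain)
  predict_fn <- if (is.function(model)) {
    model
  } else if (output == "probability") {
    function(ts) predict_proba(model, ts, domain = domain)
  } else {
    function(ts) {
      f <- extract_features(model, ts, domain = domain)
      t(clf_forward(model$params$clf, t(f))$logits)
    }
  }
  c <- n_channels(trials)
  if (is.null(names(bands)))
    names(bands) <- vapply(bands, function(b)
      sprintf("%g-%gHz", b[1L], b[2L]), character(1L))
  p0 <- predict_fn(trials)
  C <- ncol(p0)
  values <- array(0, c(length(bands), c, C),
                  dimnames = list(band = names(bands),
                                  channel = trials$channel_names,
                                  class = seq_len(C)))
  zero_var <- array(FALSE, dim(values), dimnames = dimnames(values))
  for (bi in seq_along(bands)) {
    dA <- NULL; dP <- NULL
    for (r in seq_len(n_repeats)) {
      pert <- perturb_amplitudes(trials, bands[[bi]], noise_sd,
                                 seed = seed + 1000L * bi + r)
      p1 <- predict_fn(pert$trials)
      dA <- rbind(dA, pert$deltas)
      dP <- rbind(dP, p1 - p0)
    }
    for (ch in seq_len(c)) for (k in seq_len(C)) {
      sa <- stats::sd(dA[, ch]); sp <- stats::sd(dP[, k])
      if (sa < 1e-12 || sp < 1e-12 || !is.finite(sa) || !is.finite(sp)) {
        zero_var[bi, ch, k] <- TRUE
      } else {
        values[bi, ch, k] <- stats::cor(dA[, ch], dP[, k])
      }
    }
  }
  structure(list(values = values, zero_var = zero_var, bands = bands,
                 channel_names = trials$channel_names,
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf("<correlation_map> %d bands x %d channels x %d classes (|r| max %.2f)\n",
              dim(x$values)[1L], dim(x$values)[2L], dim(x$values)[3L],
              max(abs(x$values))))
  invisible(x)
}

#' Export a correlation map as per-band CSV matrices
#'
#' Writes one CSV per band (`<prefix>_<band>.csv`), channels in rows and
#' classes in columns.
#'
#' @param map a [correlation_map()].
#' @param prefix output path prefix.
#' @return character vector of written paths, invisibly.
#' @export
write_correlation_csv <- function(map, prefix) {
  paths <- character(0)
  for (bi in seq_along(map$bands)) {
    m <- map$values[bi, , ]
    df <- data.frame(channel = map$channel_names, m, check.names = FALSE)
    names(df)[-1L] <- paste0("class", seq_len(ncol(m)))
    path <- paste0(prefix, "_", names(map$bands)[bi], ".csv")
    utils::write.csv(df, path, row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
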