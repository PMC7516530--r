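#' Labelled EEG trial set
#'
#' The basic container of the package: a set of epoched EEG trials from one
#' subject (or a concatenation of subjects), stored as a numeric array of
#' dimension `(n_trials, n_channels, n_samples)` in microvolts, together with
#' optional integer class labels, the sampling rate, and channel names.
#'
#' Classes are numbered `1..n_classes`.  Labels may be absent (`NULL`), which
#' is how unlabelled target-domain data are represented, or *withheld* (see
#' [withhold_labels()]), which additionally guards against any accidental
#' read during training.
#'
#' @param data numeric array `(n_trials, n_channels, n_samples)`.
#' @param labels integer vector of per-trial class labels in `1..n_classes`,
#'   or `NULL` for unlabelled data.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector of channel names; defaults to
#'   `"ch01"`, `"ch02"`, ...
#' @param subject_id identifier string carried through preprocessing.
#' @param n_classes number of classes `C`; defaults to `max(labels)` (4 when
#'   no labels are present, the motor-imagery convention).
#' @return an object of class `eeg_trial_set`.
#' @export
eeg_trial_set <- function(data, labels = NULL, fs, channel_names = NULL,
                          subject_id = "S01", n_classes = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (n_trials, n_channels, n_samples)")
  storage.mode(data) <- "double"
  n <- dim(data)[1L]; c <- dim(data)[2L]; t <- dim(data)[3L]
  if (n < 1L) stop("need at least one trial")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)")
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(c))
  if (length(channel_names) != c)
    stop("`channel_names` must have one entry per channel (", c, ")")
  if (anyDuplicated(channel_names))
    stop("channel names must be unique")
  if (!is.null(labels) && !inherits(labels, "withheld_labels")) {
    labels <- as.integer(labels)
    if (length(labels) != n)
      stop("`labels` must have one entry per trial (", n, "), got ",
           length(labels))
    if (anyNA(labels) || any(labels < 1L))
      stop("labels must be integers >= 1")
    if (is.null(n_classes)) n_classes <- max(labels)
    if (any(labels > n_classes))
      stop("labels exceed n_classes = ", n_classes)
  }
  if (is.null(n_classes)) n_classes <- 4L
  structure(
    list(data = data, labels = labels, fs = as.numeric(fs),
         channel_names = as.character(channel_names),
         subject_id = as.character(subject_id),
         n_classes = as.integer(n_classes)),
    class = "eeg_trial_set")
}

#' @export
print.eeg_trial_set <- function(x, ...) {
  d <- dim(x$data)
  lab <- if (is.null(x$labels)) "unlabelled"
         else if (inherits(x$labels, "withheld_labels")) "labels withheld"
         else sprintf("%d classes", x$n_classes)
  cat(sprintf("<eeg_trial_set> subject %s: %d trials x %d channels x %d samples @ %g Hz (%s)\n",
              x$subject_id, d[1L], d[2L], d[3L], x$fs, lab))
  invisible(x)
}

#' @rdname eeg_trial_set
#' @param x an `eeg_trial_set`.
#' @export
n_trials <- function(x) dim(x$data)[1L]

#' @rdname eeg_trial_set
#' @export
n_channels <- function(x) dim(x$data)[2L]

#' @rdname eeg_trial_set
#' @export
n_samples <- function(x) dim(x$data)[3L]

#' Subset trials by index
#'
#' @param x an `eeg_trial_set`.
#' @param idx integer vector of trial indices.
#' @return an `eeg_trial_set` with the selected trials (labels subset too).
#' @export
subset_trials <- function(x, idx) {
  idx <- as.integer(idx)
  if (any(idx < 1L) || any(idx > n_trials(x)))
    stop("trial index out of range")
  labels <- if (is.null(x$labels) || inherits(x$labels, "withheld_labels"))
    x$labels else x$labels[idx]
  eeg_trial_set(x$data[idx, , , drop = FALSE], labels, x$fs,
                x$channel_names, x$subject_id, x$n_classes)
}

#' Concatenate trial sets along the trial axis
#'
#' All sets must agree on channels, samples, sampling rate and class count.
#' Used to pool the source subjects in leave-one-subject-out evaluation.
#'
#' @param sets a list of `eeg_trial_set` objects.
#' @param subject_id identifier for the pooled set.
#' @return an `eeg_trial_set`.
#' @export
concat_trials <- function(sets, subject_id = "pooled") {
  stopifnot(length(sets) >= 1L)
  ref <- sets[[1L]]
  for (s in sets) {
    if (n_channels(s) != n_channels(ref) || n_samples(s) != n_samples(ref) ||
        s$fs != ref$fs || s$n_classes != ref$n_classes ||
        !identical(s$channel_names, ref$channel_names))
      stop("trial sets are not compatible (channels/samples/fs/classes differ)")
  }
  data <- do.call(abind_trials, lapply(sets, function(s) s$data))
  labels <- if (any(vapply(sets, function(s) is.null(s$labels), logical(1L))))
    NULL else unlist(lapply(sets, function(s) s$labels), use.names = FALSE)
  eeg_trial_set(data, labels, ref$fs, ref$channel_names, subject_id,
                ref$n_classes)
}

# bind 3-d arrays along dim 1 without pulling in an extra dependency
abind_trials <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1L]])
  n_tot <- sum(vapply(arrs, function(a) dim(a)[1L], integer(1L)))
  out <- array(0, c(n_tot, d[2L], d[3L]))
  at <- 0L
  for (a in arrs) {
    n <- dim(a)[1L]
    out[at + seq_len(n), , ] <- a
    at <- at + n
  }
  out
}

#' Withheld label sentinel
#'
#' Wraps (or replaces) a label vector so that *any* attempt to read it —
#' subsetting, coercion, `length()`, printing — raises an error.  Target
#' training labels inside a [domain_pair()] are stored this way, turning the
#' "labels are never read during training" contract into an executable check:
#' if a training code path ever touches them, it fails loudly.
#'
#' @param labels ignored; present so that a real label vector can be swapped
#'   for a sentinel in instrumentation tests.
#' @return an object of class `withheld_labels`.
#' @export
withhold_labels <- function(labels = NULL) {
  structure(list(), class = "withheld_labels")
}

withheld_stop <- function()
  stop("target training labels are withheld and must never be read",
       call. = FALSE)

#' @export
`[.withheld_labels` <- function(x, ...) withheld_stop()
#' @export
`[[.withheld_labels` <- function(x, ...) withheld_stop()
#' @export
length.withheld_labels <- function(x) withheld_stop()
#' @export
print.withheld_labels <- function(x, ...) withheld_stop()
#' @export
format.withheld_labels <- function(x, ...) withheld_stop()
#' @export
as.integer.withheld_labels <- function(x, ...) withheld_stop()
#' @export
as.double.withheld_labels <- function(x, ...) withheld_stop()
#' @export
as.character.withheld_labels <- function(x, ...) withheld_stop()
#' @export
as.vector.withheld_labels <- function(x, mode = "any") withheld_stop()

#' Source/target domain pair
#'
#' Bundles a labelled source trial set with an unlabelled target training set
#' (labels withheld) and a labelled target test set used only for evaluation.
#' Source and target must agree on channels, samples, sampling rate and class
#' count.
#'
#' @param source labelled `eeg_trial_set` (the pooled other subjects).
#' @param target_train `eeg_trial_set` from the target subject; any labels it
#'   carries are discarded and replaced by a [withhold_labels()] sentinel.
#' @param target_test labelled `eeg_trial_set` from the target subject,
#'   evaluation only.
#' @return an object of class `domain_pair`.
#' @export
domain_pair <- function(source, target_train, target_test) {
  stopifnot(inherits(source, "eeg_trial_set"),
            inherits(target_train, "eeg_trial_set"),
            inherits(target_test, "eeg_trial_set"))
  if (is.null(source$labels)) stop("source trials must be labelled")
  if (is.null(target_test$labels)) stop("target test trials must be labelled")
  for (s in list(target_train, target_test)) {
    if (n_channels(s) != n_channels(source) ||
        n_samples(s) != n_samples(source) || s$fs != source$fs ||
        s$n_classes != source$n_classes)
      stop("source and target are not compatible (channels/samples/fs/classes)")
  }
  if (!inherits(target_train$labels, "withheld_labels"))
    target_train$labels <- withhold_labels()
  structure(list(source = source, target_train = target_train,
                 target_test = target_test),
            class = "domain_pair")
}

#' @export
print.domain_pair <- function(x, ...) {
  cat("<domain_pair>\n  source:       "); print(x$source)
  cat("  target_train: "); print(x$target_train)
  cat("  target_test:  "); print(x$target_test)
  invisible(x)
}
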