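#' Write / read a trial set as a single container file
#'
#' One hierarchical container file per subject, holding the data tensor,
#' labels, sampling rate, channel names and subject id.  Two formats are
#' supported, chosen by file extension:
#'
#' * `.rds` — R's native serialization; bitwise-exact round trip (default).
#' * `.json` — plain-text container with doubles printed to 17 significant
#'   digits; portable and diff-able, round trips doubles exactly in practice.
#'
#' @param trials an [eeg_trial_set()].
#' @param path output file; extension selects the format.
#' @return `write_trials()` returns `path` invisibly; `read_trials()` returns
#'   an `eeg_trial_set`.
#' @export
write_trials <- function(trials, path) {
  stopifnot(inherits(trials, "eeg_trial_set"))
  labels <- if (inherits(trials$labels, "withheld_labels")) NULL
            else trials$labels
  obj <- list(format = "cdaneeg-trials", version = 1L,
              dim = dim(trials$data), labels = labels, fs = trials$fs,
              channel_names = trials$channel_names,
              subject_id = trials$subject_id, n_classes = trials$n_classes)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj$data <- sprintf("%.17g", as.vector(trials$data))
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), path)
  } else {
    obj$data <- trials$data
    saveRDS(obj, path)
  }
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  obj <- if (ext == "json") {
    tryCatch(jsonlite::fromJSON(path),
             error = function(e) stop("malformed trial container ", path,
                                      ": ", conditionMessage(e)))
  } else {
    tryCatch(readRDS(path),
             error = function(e) stop("malformed trial container ", path,
                                      ": ", conditionMessage(e)))
  }
  if (!identical(as.character(obj$format), "cdaneeg-trials"))
    stop("malformed trial container ", path, ": missing format marker")
  dm <- as.integer(obj$dim)
  if (length(dm) != 3L)
    stop("malformed trial container ", path, ": bad dim record")
  data <- if (ext == "json") {
    v <- as.numeric(obj$data)
    if (length(v) != prod(dm))
      stop("malformed trial container ", path, ": data record has ",
           length(v), " values, expected ", prod(dm))
    array(v, dm)
  } else obj$data
  labels <- obj$labels
  if (!is.null(labels) && length(labels) == 0L) labels <- NULL
  if (!is.null(labels) && length(labels) != dm[1L])
    stop("malformed trial container ", path, ": ", length(labels),
         " labels for ", dm[1L], " trials")
  eeg_trial_set(data, labels, obj$fs, obj$channel_names, obj$subject_id,
                as.integer(obj$n_classes))
}

#' Export labels or predictions as CSV
#'
#' @param trials a labelled [eeg_trial_set()].
#' @param path output CSV path.
#' @param predictions optional integer vector of predicted classes to include
#'   alongside the true labels.
#' @return `path`, invisibly.
#' @export
export_labels_csv <- function(trials, path, predictions = NULL) {
  stopifnot(inherits(trials, "eeg_trial_set"))
  if (is.null(trials$labels) || inherits(trials$labels, "withheld_labels"))
    stop("trial set carries no readable labels")
  df <- data.frame(trial = seq_len(n_trials(trials)),
                   subject = trials$subject_id, label = trials$labels)
  if (!is.null(predictions)) df$prediction <- as.integer(predictions)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
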