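#' Construct an EEG recording object
#'
#' A lightweight container for one subject/condition signal block:
#' a channels-by-samples matrix in microvolts together with the sampling
#' rate, montage labels and subject metadata. Event-related recordings
#' additionally carry an event log of stimulus onsets.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one label per row of `data`.
#' @param subject_id subject identifier.
#' @param group one of `"R"`, `"NR"`, `"control"`.
#' @param sex `"F"` or `"M"`.
#' @param condition recording condition: `"EC"`, `"EO"` or `"ERP"`.
#' @param events optional data frame with columns `sample` (1-based onset
#'   sample index) and `stimulus` (`"Target"`, `"Standard"`, `"Distractor"`),
#'   required only for ERP recordings.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels = montage_1020(),
                          subject_id = "S01", group = c("R", "NR", "control"),
                          sex = c("F", "M"),
                          condition = c("EC", "EO", "ERP"),
                          events = NULL) {
  group <- match.arg(group)
  sex <- match.arg(sex)
  condition <- match.arg(condition)
  data <- as.matrix(data)
  if (nrow(data) != length(channel_labels))
    stop("rows of `data` must match `channel_labels` (",
         nrow(data), " vs ", length(channel_labels), ")")
  if (anyNA(data)) stop("recording data must not contain NA")
  if (fs <= 0) stop("`fs` must be positive")
  if (!is.null(events)) {
    stopifnot(all(c("sample", "stimulus") %in% names(events)))
    if (is.unsorted(events$sample, strictly = TRUE))
      stop("event sample indices must be strictly increasing")
    if (any(events$sample < 1) || any(events$sample > ncol(data)))
      stop("event sample indices out of range")
  }
  structure(
    list(subject_id = subject_id, group = group, sex = sex,
         condition = condition, channel_labels = channel_labels,
         fs = fs, data = data, events = events),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s [%s, %s, %s] %d ch x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$group, x$sex, x$condition,
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (!is.null(x$events))
    cat(sprintf("  events: %d (%s)\n", nrow(x$events),
                paste(names(table(x$events$stimulus)), table(x$events$stimulus),
                      sep = "=", collapse = ", ")))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `eeg_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$fs

#' Construct a feature matrix
#'
#' Instances-by-features container with per-column metadata (channel, band,
#' extraction method, within-block index) and per-row instance metadata
#' (subject, condition, class label). This is the object passed between
#' feature extraction, standardization, selection and classification.
#'
#' @param values numeric matrix, instances x features.
#' @param feature_meta data frame with one row per column of `values`;
#'   expected columns `feature`, `channel`, `band`, `method`, `index`.
#' @param instance_meta data frame with one row per row of `values`;
#'   expected columns `subject_id`, `condition`, `group`, and optionally
#'   `sex`.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, feature_meta, instance_meta) {
  values <- as.matrix(values)
  if (nrow(feature_meta) != ncol(values))
    stop("`feature_meta` must have one row per feature column")
  if (nrow(instance_meta) != nrow(values))
    stop("`instance_meta` must have one row per instance")
  if (is.null(feature_meta$feature))
    feature_meta$feature <- paste0("f", seq_len(ncol(values)))
  colnames(values) <- feature_meta$feature
  structure(list(values = values, feature_meta = feature_meta,
                 instance_meta = instance_meta),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d instances x %d features\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$feature_meta$method))
    cat("  methods:", paste(unique(x$feature_meta$method), collapse = ", "), "\n")
  if (!is.null(x$instance_meta$group))
    cat("  groups: ", paste(names(table(x$instance_meta$group)),
                            table(x$instance_meta$group),
                            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Subset a feature matrix
#'
#' @param fm a `feature_matrix`.
#' @param rows,cols row / column index vectors (any base-R indexing form).
#' @return A `feature_matrix` with metadata subset in step.
#' @export
fm_subset <- function(fm, rows = NULL, cols = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(fm$values))
  if (is.null(cols)) cols <- seq_len(ncol(fm$values))
  feature_matrix(fm$values[rows, cols, drop = FALSE],
                 fm$feature_meta[cols, , drop = FALSE],
                 fm$instance_meta[rows, , drop = FALSE])
}

#' Binary class labels of a feature matrix
#'
#' @param fm a `feature_matrix`.
#' @param positive label treated as the positive class; defaults to `"R"`
#'   if present, otherwise `"MDD"`.
#' @return Logical vector, `TRUE` for positive-class instances.
#' @export
fm_labels <- function(fm, positive = NULL) {
  g <- fm$instance_meta$group
  if (is.null(positive))
    positive <- if ("R" %in% g) "R" else if ("MDD" %in% g) "MDD" else
      sort(unique(g))[1]
  if (length(unique(g)) != 2)
    stop("feature matrix labels must be binary (found: ",
         paste(unique(g), collapse = ", "), ")")
  g == positive
}
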