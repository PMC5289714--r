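#' Write a cohort to plain-text files
#'
#' One CSV per recording (columns = channels with label header, rows =
#' samples, values in microvolts) plus a `metadata.csv` listing subject,
#' group, sex, questionnaire scores, condition, sampling rate and file
#' name — a portable plain-text exchange format for the synthetic
#' cohorts.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the metadata table including file names.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort$recordings, function(rec) {
    file <- sprintf("%s_%s.csv", rec$subject_id, rec$condition)
    write.csv(t(rec$data), file.path(dir, file), row.names = FALSE)
    md <- cohort$metadata[cohort$metadata$subject_id == rec$subject_id, ]
    data.frame(subject_id = rec$subject_id, group = rec$group,
               sex = rec$sex, pre_bdi = md$pre_bdi, post_bdi = md$post_bdi,
               condition = rec$condition, fs = rec$fs, file = file,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort from plain-text files
#'
#' Inverse of [write_cohort_csv()].
#'
#' @param dir directory containing `metadata.csv` and the per-recording
#'   CSVs.
#' @return A list with `recordings` and `metadata`, as from
#'   [generate_cohort()].
#' @export
read_cohort_csv <- function(dir) {
  manifest <- read.csv(file.path(dir, "metadata.csv"),
                       stringsAsFactors = FALSE,
                       colClasses = c(sex = "character",
                                      group = "character"))
  recordings <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    x <- as.matrix(read.csv(file.path(dir, m$file), check.names = FALSE))
    eeg_recording(t(x), fs = m$fs, channel_labels = colnames(x),
                  subject_id = m$subject_id, group = m$group, sex = m$sex,
                  condition = m$condition)
  })
  metadata <- unique(manifest[, c("subject_id", "group", "sex",
                                  "pre_bdi", "post_bdi")])
  rownames(metadata) <- NULL
  list(recordings = recordings, metadata = metadata)
}
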