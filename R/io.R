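# Plain-text fixture format for recordings: a samples-by-channels TSV plus a
# JSON sidecar carrying sampling rate, channel labels, ids and the marker
# table. Field names are fixed here and relied on by load_recordings().

#' Write a recording to the fixture format
#'
#' Produces `<stem>_data.tsv` (samples x channels, header row of channel
#' labels, 15 significant digits) and `<stem>_meta.json` with fields
#' `sampling_rate`, `channel_labels`, `subject_id`, `session_id`,
#' `mi_duration`, and `markers` (records with `onset` [0-based sample],
#' `phase`, `speed`, `trial`).
#'
#' @param recording A `recording`.
#' @param stem Output path stem (no extension).
#' @return The two file paths, invisibly.
#' @export
write_recording_fixture <- function(recording, stem) {
  data_path <- paste0(stem, "_data.tsv")
  meta_path <- paste0(stem, "_meta.json")
  df <- as.data.frame(signif(t(recording$data), 15))
  names(df) <- recording$channel_labels
  utils::write.table(df, data_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  meta <- list(sampling_rate = recording$sampling_rate,
               channel_labels = recording$channel_labels,
               subject_id = recording$subject_id,
               session_id = recording$session_id,
               mi_duration = recording$mi_duration,
               markers = recording$markers)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "rows", na = "null")
  invisible(c(data_path, meta_path))
}

#' Read a recording from the fixture format
#'
#' @param stem Path stem used by [write_recording_fixture()].
#' @param expected_channels Optional channel count to validate against.
#' @return A `recording`.
#' @export
read_recording_fixture <- function(stem, expected_channels = NULL) {
  data_path <- paste0(stem, "_data.tsv")
  meta_path <- paste0(stem, "_meta.json")
  if (!file.exists(data_path) || !file.exists(meta_path)) {
    abort("fixture not found at stem '%s'", stem)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  mat <- as.matrix(utils::read.table(data_path, header = TRUE, sep = "\t",
                                     check.names = FALSE))
  if (ncol(mat) != length(meta$channel_labels)) {
    abort("fixture '%s' has %d data columns but %d channel labels",
          stem, ncol(mat), length(meta$channel_labels))
  }
  if (!is.null(expected_channels) && ncol(mat) != expected_channels) {
    abort("fixture '%s' has %d channels, expected %d",
          stem, ncol(mat), expected_channels)
  }
  markers <- as.data.frame(meta$markers)
  known <- c("baseline", "beep", "no_action", "mi")
  bad <- setdiff(unique(markers$phase), known)
  if (length(bad)) {
    abort("fixture '%s' has unknown marker phases: %s", stem,
          paste(bad, collapse = ", "))
  }
  markers$onset <- as.integer(markers$onset)
  markers$trial <- as.integer(markers$trial)
  markers$speed <- as.character(markers$speed)
  data <- t(mat)
  rownames(data) <- meta$channel_labels
  structure(list(data = data,
                 sampling_rate = as.numeric(meta$sampling_rate),
                 channel_labels = meta$channel_labels,
                 markers = markers,
                 mi_duration = as.numeric(meta$mi_duration %||% 10),
                 session_id = meta$session_id,
                 subject_id = meta$subject_id),
            class = "recording")
}

#' Load recordings from disk
#'
#' @param stems Character vector of fixture path stems.
#' @param format Only `"fixture"` (TSV + JSON sidecar) is supported; EDF is
#'   not implemented in this package.
#' @param expected_channels Optional channel-count check applied to each file.
#' @return List of `recording` objects.
#' @export
load_recordings <- function(stems, format = c("fixture", "edf"),
                            expected_channels = NULL) {
  format <- match.arg(format)
  if (format == "edf") {
    abort("EDF input is not supported; convert to the TSV+JSON fixture format")
  }
  lapply(stems, read_recording_fixture, expected_channels = expected_channels)
}

#' Write a study evaluation table as delimited text
#' @param eval_rows Data frame of per-fold results.
#' @param path Output TSV path.
#' @export
write_eval_table <- function(eval_rows, path) {
  utils::write.table(eval_rows, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a study evaluation table
#' @param path TSV written by [write_eval_table()].
#' @export
read_eval_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
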