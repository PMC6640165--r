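# Plain-text readers/writers for the pipeline's interchange formats:
# BIDS-style events.tsv, per-signal CSV streams, EEG CSV dialect, cohort and
# task-log CSVs.

#' Write / read an events table (BIDS-style TSV)
#'
#' Tab-separated with columns `onset`, `duration`, `trial_type` and (when
#' present) `stimulus_valence`.
#'
#' @param events event data.frame.
#' @param path file path.
#' @return `read_events_tsv` returns the events data.frame (class
#'   `event_timeline`).
#' @export
write_events_tsv <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("onset", "duration", "trial_type") %in% names(out)))
  class(out) <- c("event_timeline", "data.frame")
  out
}

#' Write / read a single wristband stream (CSV: time_s, value)
#'
#' @param stream data.frame with `time_s` and one value column.
#' @param path file path.
#' @export
write_stream_csv <- function(stream, path) {
  write.csv(stream, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stream_csv
#' @export
read_stream_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read an EEG recording (CSV dialect)
#'
#' Columns: `time_s`, one column per scalp channel (uV), and `sync`. The
#' sampling rate is recovered from the time column on read.
#'
#' @param rec an `eeg_recording`.
#' @param path file path.
#' @export
write_eeg_csv <- function(rec, path) {
  n <- nrow(rec$data)
  df <- data.frame(time_s = seq_len(n) / rec$sampling_rate)
  df <- cbind(df, as.data.frame(rec$data))
  df$sync <- rec$sync
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eeg_csv
#' @export
read_eeg_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot("time_s" %in% names(df), "sync" %in% names(df))
  ch <- setdiff(names(df), c("time_s", "sync"))
  sr <- round(1 / stats::median(diff(df$time_s)))
  structure(
    list(data = as.matrix(df[ch]), sync = df$sync, sampling_rate = sr,
         montage = ch, ground_truth = NULL),
    class = "eeg_recording"
  )
}

#' Write cohort panels as CSV
#'
#' Wide layout: participant_id, condition, `pre_<measure>`,
#' `post_<measure>`.
#'
#' @param cohort a `cohort_table`.
#' @param path file path.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  pre_cols <- grep("^pre_", names(df), value = TRUE)
  post_cols <- grep("^post_", names(df), value = TRUE)
  measures <- sub("^pre_", "", pre_cols)
  stopifnot(identical(measures, sub("^post_", "", post_cols)))
  pre <- as.matrix(df[pre_cols]); colnames(pre) <- measures
  post <- as.matrix(df[post_cols]); colnames(post) <- measures
  structure(
    list(participants = df[c("participant_id", "condition")],
         measures = measures, pre = pre, post = post),
    class = "cohort_table"
  )
}
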