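## Event tables are plain data.frames carrying one row per droplet with a
## `droplet_id`, a `duration_samples` column and one `mean_<channel>` column
## per fluorescence channel; downstream stages add boolean gate/call columns.
## The S3 class is a thin validation veneer, not a new container.

#' Construct / validate an event table
#'
#' @param x A data.frame with columns `droplet_id`, `duration_samples` and at
#'   least one `mean_<channel>` column.
#' @return `x` with class `c("event_table", "data.frame")`.
#' @export
as_event_table <- function(x) {
  stopifnot(is.data.frame(x))
  for (col in c("droplet_id", "duration_samples")) {
    if (!col %in% names(x)) stop("event table is missing column '", col, "'")
  }
  chans <- event_channels(x)
  if (length(chans) == 0L) {
    stop("event table has no 'mean_<channel>' fluorescence columns")
  }
  for (ch in chans) {
    v <- x[[paste0("mean_", ch)]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      stop("non-numeric or non-finite fluorescence in channel '", ch, "'")
    }
  }
  if (anyDuplicated(x$droplet_id)) stop("duplicate droplet_id values")
  class(x) <- unique(c("event_table", class(x)))
  x
}

#' Channels present in an event table
#' @param events An event table.
#' @return Character vector of channel names (the `mean_` prefixes stripped).
#' @export
event_channels <- function(events) {
  sub("^mean_", "", grep("^mean_", names(events), value = TRUE))
}

## Fluorescence sub-matrix, rows = events, cols = channels (unprefixed names).
event_fluorescence <- function(events, channels = event_channels(events)) {
  m <- as.matrix(events[, paste0("mean_", channels), drop = FALSE])
  colnames(m) <- channels
  m
}

#' Read an event table from CSV
#'
#' Validates the schema and reports the first missing column by name.
#'
#' @param path Path to a CSV written by [write_event_table()] or following
#'   its schema.
#' @return An event table.
#' @export
read_event_table <- function(path) {
  x <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  as_event_table(x)
}

#' Write an event table to CSV
#' @param events An event table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' Write a trace record as a columnar CSV
#'
#' Columns are `time_s` followed by one column per channel; the sampling
#' rate is recoverable from the time column.
#'
#' @param trace A [trace_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "trace_record"))
  df <- data.frame(time_s = (seq_len(nrow(trace$samples)) - 1L) / trace$sampling_rate)
  df <- cbind(df, as.data.frame(trace$samples))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a columnar trace CSV back into a trace record
#'
#' @param path Path to a CSV written by [write_trace()].
#' @param detection_channel Detection channel label; defaults to the first
#'   fluorescence column.
#' @return A [trace_record()].
#' @export
read_trace <- function(path, detection_channel = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) stop("trace file is missing column 'time_s'")
  if (nrow(df) < 2L) stop("trace file must contain at least two samples")
  dt <- diff(df$time_s[1:2])
  samples <- as.matrix(df[, setdiff(names(df), "time_s"), drop = FALSE])
  if (is.null(detection_channel)) detection_channel <- colnames(samples)[1L]
  trace_record(samples, sampling_rate = 1 / dt,
               detection_channel = detection_channel)
}
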