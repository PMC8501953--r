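#' Multi-channel photodetector time trace
#'
#' Container for a sampled fluorescence trace from a droplet detector: a
#' time-ordered numeric matrix (rows = samples, columns = channels), the
#' sampling rate, and the channel used to find droplets against the carrier
#' oil.
#'
#' @param samples Numeric matrix or data.frame, one column per channel;
#'   column names are the channel labels. All values must be finite.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param detection_channel Label of the channel used for droplet detection;
#'   defaults to the first channel.
#' @return An object of class `trace_record`.
#' @examples
#' tr <- trace_record(cbind(green = c(0, 1, 1, 0)), sampling_rate = 1000)
#' @export
trace_record <- function(samples, sampling_rate,
                         detection_channel = colnames(samples)[1L]) {
  samples <- as.matrix(samples)
  if (ncol(samples) < 1L) stop("trace must have at least one channel")
  if (is.null(colnames(samples))) {
    colnames(samples) <- paste0("ch", seq_len(ncol(samples)))
  }
  if (!is.numeric(samples) || any(!is.finite(samples))) {
    stop("trace samples must be finite numbers")
  }
  if (!is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("'sampling_rate' must be a positive frequency in Hz")
  }
  if (!detection_channel %in% colnames(samples)) {
    stop("detection channel '", detection_channel, "' not among trace channels")
  }
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         channel_names = colnames(samples),
         detection_channel = detection_channel),
    class = "trace_record"
  )
}

#' @export
print.trace_record <- function(x, ...) {
  cat(sprintf("Trace: %d samples x %d channels (%s) at %g Hz; detection on '%s'\n",
              nrow(x$samples), ncol(x$samples),
              paste(x$channel_names, collapse = ", "),
              x$sampling_rate, x$detection_channel))
  invisible(x)
}

#' Detect droplet events in a time trace by fixed thresholding
#'
#' A droplet event is a maximal run of consecutive samples whose
#' detection-channel value exceeds `threshold` (strictly: samples equal to
#' the threshold belong to the oil) and whose length is at least
#' `min_width`. Per-channel mean fluorescence is computed over each run.
#' Runs are reported 0-based and half-open: `start` inclusive, `end`
#' exclusive.
#'
#' @param trace A [trace_record()].
#' @param threshold Fluorescence level separating droplets from the carrier
#'   oil; must sit above the oil baseline.
#' @param min_width Minimum run length in samples (>= 1) retained as an
#'   event; shorter threshold crossings are treated as noise.
#' @return An event table (data.frame) with columns `droplet_id`, `start`,
#'   `end`, `duration_samples`, and one `mean_<channel>` column per channel,
#'   sorted by `start`.
#' @examples
#' tr <- trace_record(cbind(g = c(0, 0, 1, 1, 1, 0, 1, 1, 0)), 1000)
#' detect_events(tr, threshold = 0.5, min_width = 2)
#' @export
detect_events <- function(trace, threshold, min_width = 3L) {
  stopifnot(inherits(trace, "trace_record"))
  if (nrow(trace$samples) == 0L) stop("trace is empty")
  if (!is.finite(threshold)) stop("'threshold' must be finite")
  if (!is.finite(min_width) || min_width < 1) stop("'min_width' must be >= 1")
  above <- trace$samples[, trace$detection_channel] > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)                    # 1-based inclusive run ends
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_width
  starts <- starts[keep]
  ends <- ends[keep]
  out <- data.frame(
    droplet_id = seq_along(starts),
    start = starts - 1L,                       # 0-based inclusive
    end = ends,                                # exclusive
    duration_samples = ends - starts + 1L
  )
  for (ch in trace$channel_names) {
    out[[paste0("mean_", ch)]] <- vapply(
      seq_along(starts),
      function(i) mean(trace$samples[starts[i]:ends[i], ch]),
      numeric(1)
    )
  }
  as_event_table(out)
}

#' Summarize a trace's droplet stream
#'
#' Runs [detect_events()] and reports the droplet count, the event rate in
#' Hz (count divided by the trace's time span) and duration quantiles in
#' seconds.
#'
#' @inheritParams detect_events
#' @param probs Quantile probabilities for the duration summary.
#' @return A list with `n_events`, `rate_hz`, `span_s` and
#'   `duration_quantiles_s`.
#' @export
summarize_trace <- function(trace, threshold, min_width = 3L,
                            probs = c(0.25, 0.5, 0.75)) {
  ev <- detect_events(trace, threshold, min_width)
  span <- nrow(trace$samples) / trace$sampling_rate
  qs <- if (nrow(ev)) {
    stats::quantile(ev$duration_samples / trace$sampling_rate, probs = probs)
  } else {
    stats::setNames(rep(NA_real_, length(probs)), paste0(probs * 100, "%"))
  }
  list(n_events = nrow(ev), rate_hz = nrow(ev) / span, span_s = span,
       duration_quantiles_s = qs)
}
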