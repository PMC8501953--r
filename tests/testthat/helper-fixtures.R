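# Shared fixtures and independent oracles used across the suite.

# Two-class mixture emulating an ERBB2 assay: a negative line whose
# amplification probability equals the false positive rate and a positive
# line at the true positive rate.
mixture_model <- function(p_positive = 0.1, tpr = 0.971, fpr = 2e-4,
                          seed = 1L, ...) {
  assay_model(
    classes = list(
      cell_class("NEG", c(ERBB2 = fpr), stain_level = 1000),
      cell_class("POS", c(ERBB2 = tpr), stain_level = 1000)
    ),
    proportions = c(1 - p_positive, p_positive),
    fpr_per_marker = fpr,
    seed = seed,
    ...
  )
}

# Rectangular-pulse trace on a zero baseline: pulse i has the given width
# and height, separated by `gap` oil samples.
rect_trace <- function(widths, heights = rep(1, length(widths)), gap = 20,
                       sampling_rate = 1e5, channel = "det") {
  n <- sum(widths) + gap * (length(widths) + 1L)
  v <- numeric(n)
  pos <- gap
  for (i in seq_along(widths)) {
    v[(pos + 1L):(pos + widths[i])] <- heights[i]
    pos <- pos + widths[i] + gap
  }
  m <- matrix(v, ncol = 1, dimnames = list(NULL, channel))
  trace_record(m, sampling_rate = sampling_rate)
}

# Brute-force event detector: label every sample by comparison to the
# threshold and merge runs with an explicit per-sample scan.
brute_force_events <- function(trace, threshold, min_width) {
  v <- trace$samples[, trace$detection_channel]
  events <- list()
  i <- 1L
  n <- length(v)
  while (i <= n) {
    if (v[i] > threshold) {
      j <- i
      while (j < n && v[j + 1L] > threshold) j <- j + 1L
      if (j - i + 1L >= min_width) {
        # 0-based half-open: start = i-1, exclusive end = j
        events[[length(events) + 1L]] <- c(start = i - 1L, end = j)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(events) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  as.data.frame(do.call(rbind, events))
}

# Minimal hand-built event table.
toy_events <- function(values, channel = "det", durations = NULL) {
  n <- length(values)
  if (is.null(durations)) durations <- rep(10L, n)
  df <- data.frame(droplet_id = seq_len(n), duration_samples = durations)
  df[[paste0("mean_", channel)]] <- values
  as_event_table(df)
}

# Three-SD binomial half-width for a proportion estimate.
binom_3sd <- function(p, n) 3 * sqrt(p * (1 - p) / n)
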