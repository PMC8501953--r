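#' Gating configuration
#'
#' Parameters of the programmatic gating cascade. Defaults follow common
#' droplet-cytometry practice for this assay family: trim the top and bottom
#' 8% of events by droplet size, call an event a cell when its stain-channel
#' fluorescence exceeds 2.8-fold the population median, down-sample to
#' 10,000 cells for cross-sample comparability, and call amplification
#' positive above 2.8-fold the empty-droplet median.
#'
#' @param size_trim_fraction Fraction removed from each duration tail
#'   (0 <= trim < 0.5).
#' @param stain_channel Channel carrying the live-cell stain.
#' @param stain_fold Fold over the median stain fluorescence defining the
#'   cell gate (> 1).
#' @param downsample_n Number of cell events retained (>= 1).
#' @param amp_fold Fold over the empty-droplet median defining amplification
#'   positivity (> 1).
#' @param seed RNG seed used by the down-sampling step.
#' @return An object of class `gate_config`.
#' @export
gate_config <- function(size_trim_fraction = 0.08,
                        stain_channel = "stain",
                        stain_fold = 2.8,
                        downsample_n = 10000,
                        amp_fold = 2.8,
                        seed = 1L) {
  if (size_trim_fraction < 0 || size_trim_fraction >= 0.5) {
    stop("'size_trim_fraction' must lie in [0, 0.5)")
  }
  if (stain_fold <= 1 || amp_fold <= 1) stop("gate folds must exceed 1")
  if (downsample_n < 1) stop("'downsample_n' must be >= 1")
  structure(
    list(size_trim_fraction = size_trim_fraction,
         stain_channel = stain_channel, stain_fold = stain_fold,
         downsample_n = as.integer(downsample_n), amp_fold = amp_fold,
         seed = as.integer(seed)),
    class = "gate_config"
  )
}

#' Spectral compensation matrix
#'
#' Square spillover matrix mapping true per-channel signal to observed
#' signal; compensation applies its inverse. Must have a unit diagonal and
#' be invertible.
#'
#' @param matrix Square numeric matrix, channels x channels.
#' @param channels Channel labels in matrix order; defaults to the matrix
#'   dimnames.
#' @return An object of class `compensation_matrix`.
#' @export
compensation_matrix <- function(matrix, channels = colnames(matrix)) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix)) stop("spillover matrix must be square")
  if (is.null(channels)) stop("channel labels are required")
  if (any(abs(diag(matrix) - 1) > 1e-9)) {
    stop("spillover matrix must have a unit diagonal")
  }
  d <- det(matrix)
  if (!is.finite(d) || abs(d) < 1e-12) stop("spillover matrix is singular")
  dimnames(matrix) <- list(channels, channels)
  structure(list(matrix = matrix, channels = channels),
            class = "compensation_matrix")
}

#' Remove spectral crosstalk from an event table
#'
#' Replaces each event's fluorescence vector by `M^-1 %*% observed`, where
#' `M` is the spillover matrix. Durations and all non-fluorescence columns
#' are untouched. Negative compensated values are retained, not clipped, so
#' downstream medians stay unbiased.
#'
#' @param events An event table.
#' @param comp A [compensation_matrix()] whose channels match the event
#'   table's channels.
#' @return The compensated event table.
#' @export
compensate <- function(events, comp) {
  events <- as_event_table(events)
  stopifnot(inherits(comp, "compensation_matrix"))
  chans <- event_channels(events)
  if (!setequal(chans, comp$channels)) {
    stop("compensation channels (", paste(comp$channels, collapse = ", "),
         ") do not match event channels (", paste(chans, collapse = ", "), ")")
  }
  obs <- event_fluorescence(events, comp$channels)
  corrected <- t(solve(comp$matrix, t(obs)))
  for (ch in comp$channels) events[[paste0("mean_", ch)]] <- corrected[, ch]
  events
}

#' Estimate a spillover matrix from single-positive controls
#'
#' For each channel `j`, a control population positive only in `j` is
#' supplied; the spillover entry (i, j) is the median ratio of channel-i to
#' channel-j signal among those events, after subtracting the per-channel
#' baseline (median of `baseline` events if given, else 0). The diagonal
#' is 1.
#'
#' @param controls Named list of event tables, one per channel; names are
#'   the channel each control is positive in.
#' @param baseline Optional event table of blank (all-negative) events whose
#'   per-channel medians are subtracted before taking ratios.
#' @return A [compensation_matrix()].
#' @export
estimate_compensation <- function(controls, baseline = NULL) {
  chans <- names(controls)
  if (is.null(chans) || any(!nzchar(chans))) {
    stop("'controls' must be a named list, one entry per channel")
  }
  base <- stats::setNames(rep(0, length(chans)), chans)
  if (!is.null(baseline)) {
    bl <- event_fluorescence(as_event_table(baseline), chans)
    base <- apply(bl, 2, stats::median)
  }
  m <- diag(length(chans))
  dimnames(m) <- list(chans, chans)
  for (j in chans) {
    ev <- as_event_table(controls[[j]])
    if (nrow(ev) == 0L) stop("control for channel '", j, "' has no events")
    fl <- sweep(event_fluorescence(ev, chans), 2, base[chans])
    for (i in setdiff(chans, j)) {
      m[i, j] <- stats::median(fl[, i] / fl[, j])
    }
  }
  compensation_matrix(m, chans)
}

#' Size gate: trim extreme droplet durations
#'
#' Ranks events by `duration_samples` and removes `floor(trim * n)` events
#' from each tail, mirroring removal of excessively small and large
#' droplets. Ties in duration are broken by `droplet_id`; survivor order is
#' preserved.
#'
#' @param events An event table (non-empty).
#' @param trim Per-tail trim fraction in \[0, 0.5).
#' @return The trimmed event table.
#' @export
size_gate <- function(events, trim = 0.08) {
  events <- as_event_table(events)
  if (nrow(events) == 0L) stop("size gate applied to an empty event table")
  if (trim < 0 || trim >= 0.5) stop("'trim' must lie in [0, 0.5)")
  k <- floor(trim * nrow(events))
  if (k == 0L) return(events)
  ord <- order(events$duration_samples, events$droplet_id)
  drop <- c(ord[seq_len(k)], ord[seq.int(nrow(events) - k + 1L, nrow(events))])
  events[-drop, , drop = FALSE]
}

#' Cell gate: split events into cell-containing and empty droplets
#'
#' An event is a cell iff its stain-channel mean exceeds
#' `stain_fold x median(stain)` over all input events. Returns the
#' partition; the two parts together are exactly the input.
#'
#' @param events An event table.
#' @param config A [gate_config()] supplying `stain_channel` and
#'   `stain_fold`.
#' @return A list with event tables `cells` and `empties`.
#' @export
cell_gate <- function(events, config = gate_config()) {
  events <- as_event_table(events)
  ch <- paste0("mean_", config$stain_channel)
  if (!ch %in% names(events)) {
    stop("stain channel '", config$stain_channel, "' not in event table")
  }
  cutoff <- config$stain_fold * stats::median(events[[ch]])
  is_cell <- events[[ch]] > cutoff
  list(cells = events[is_cell, , drop = FALSE],
       empties = events[!is_cell, , drop = FALSE],
       cutoff = cutoff)
}

#' Down-sample an event table without replacement
#'
#' Uniform random subset of `n` events, reproducible from `seed`; if the
#' table already has `n` or fewer events it is returned unchanged.
#'
#' @param events An event table.
#' @param n Events to retain (>= 1).
#' @param seed RNG seed.
#' @return The down-sampled event table (input row order preserved).
#' @export
downsample_events <- function(events, n = 10000, seed = 1L) {
  events <- as_event_table(events)
  if (n < 1) stop("'n' must be >= 1")
  if (nrow(events) <= n) return(events)
  set.seed(seed)
  keep <- sort(sample.int(nrow(events), n))
  events[keep, , drop = FALSE]
}

#' Amplification-positivity threshold from the empty-droplet population
#'
#' Returns `fold x median(channel mean over empties)`; events above this
#' level in that channel are called amplification-positive. The median of
#' an even-sized set is the mean of the two central values.
#'
#' @param empties Event table of empty (stain-negative) droplets; non-empty.
#' @param channel Channel name.
#' @param fold Fold over the empty median (default 2.8).
#' @return The fluorescence threshold.
#' @export
amplification_threshold <- function(empties, channel, fold = 2.8) {
  empties <- as_event_table(empties)
  if (nrow(empties) == 0L) stop("empty-droplet population has no events")
  ch <- paste0("mean_", channel)
  if (!ch %in% names(empties)) stop("channel '", channel, "' not in event table")
  fold * stats::median(empties[[ch]])
}

#' Call per-marker amplification positivity
#'
#' Adds one boolean column `call_<marker>` per supplied threshold; a call is
#' positive iff the channel mean strictly exceeds its threshold.
#'
#' @param cells An event table.
#' @param thresholds Named numeric vector, channel -> threshold.
#' @return The event table with call columns appended.
#' @export
classify_positive <- function(cells, thresholds) {
  cells <- as_event_table(cells)
  if (is.null(names(thresholds)) || any(!nzchar(names(thresholds)))) {
    stop("'thresholds' must be a named vector of per-channel cutoffs")
  }
  for (ch in names(thresholds)) {
    col <- paste0("mean_", ch)
    if (!col %in% names(cells)) stop("no threshold channel '", ch, "' in events")
    cells[[paste0("call_", ch)]] <- cells[[col]] > thresholds[[ch]]
  }
  cells
}

#' Fraction of events called positive for a marker
#'
#' @param calls Event table with a `call_<marker>` column; non-empty.
#' @param marker Marker/channel name.
#' @return Positive fraction in \[0, 1\].
#' @export
percent_positive <- function(calls, marker) {
  col <- paste0("call_", marker)
  if (!col %in% names(calls)) stop("no call column for marker '", marker, "'")
  if (nrow(calls) == 0L) stop("cannot compute a positive fraction of 0 events")
  mean(calls[[col]])
}

#' Two-marker quadrant counts
#'
#' Classifies each event by its x/y marker calls into the four quadrants
#' (-,-), (+,-), (-,+), (+,+).
#'
#' @param calls Event table with call columns for both markers.
#' @param marker_x,marker_y Marker names.
#' @return Named integer vector `c("--", "+-", "-+", "++")`; sums to the
#'   table size.
#' @export
quadrant_counts <- function(calls, marker_x, marker_y) {
  cx <- paste0("call_", marker_x)
  cy <- paste0("call_", marker_y)
  for (col in c(cx, cy)) {
    if (!col %in% names(calls)) stop("missing call column '", col, "'")
  }
  x <- calls[[cx]]
  y <- calls[[cy]]
  c("--" = sum(!x & !y), "+-" = sum(x & !y),
    "-+" = sum(!x & y), "++" = sum(x & y))
}
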