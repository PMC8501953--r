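#' Read a pipeline configuration from a YAML file
#'
#' The file has one section per stage. `gate:` holds [gate_config()] fields;
#' `markers:` lists the assayed marker channels; an optional `model:`
#' section describes an [assay_model()] for simulation (fields `classes`
#' — a list of name/expression/stain_level/proportion entries — plus any
#' scalar model parameter); an optional `logic:` section gives a Boolean
#' expression over the markers. Every gating constant (size trim 0.08,
#' 2.8-fold rules, 10,000-event down-sample) is a named default here,
#' never hard-coded in the stages.
#'
#' @param path Path to a YAML config file.
#' @return A list with `gate` (a [gate_config()]), `markers`, optional
#'   `model` (an [assay_model()]) and optional `circuit`
#'   (a [logic_circuit()]).
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  gate_args <- cfg$gate %||% list()
  gate <- do.call(gate_config, gate_args)
  out <- list(gate = gate, markers = cfg$markers)
  if (!is.null(cfg$model)) {
    mc <- cfg$model
    classes <- lapply(mc$classes, function(cl) {
      cell_class(cl$name, unlist(cl$expression),
                 stain_level = cl$stain_level %||% 1000)
    })
    props <- vapply(mc$classes, function(cl) cl$proportion %||% NA_real_,
                    numeric(1))
    if (all(is.na(props))) props <- rep(1 / length(classes), length(classes))
    args <- mc[setdiff(names(mc), "classes")]
    args$classes <- classes
    args$proportions <- props
    out$model <- do.call(assay_model, args)
  }
  if (!is.null(cfg$logic)) out$circuit <- parse_logic_expression(cfg$logic)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full gating pipeline on an event table or trace
#'
#' Applies the cascade in a fixed order: optional spectral compensation,
#' size gate (trim extreme durations), cell gate (stain fold-over-median),
#' down-sampling of the cell population, amplification thresholds computed
#' from the size-gated stain-negative empty population, and per-marker
#' positivity calls. Thresholds are computed from the empties *before* the
#' cells are down-sampled, so they do not depend on the down-sampling draw.
#' If a logic circuit is supplied, each cell's marker calls are fed through
#' it and the ON fraction is reported.
#'
#' @param input An event table, or a [trace_record()] (then
#'   `trace_threshold` is required and events are detected first).
#' @param markers Marker channels to threshold and call; defaults to every
#'   channel except the stain channel.
#' @param config A [gate_config()].
#' @param comp Optional [compensation_matrix()].
#' @param circuit Optional [logic_circuit()] over the marker names.
#' @param trace_threshold,trace_min_width Event-detection parameters when
#'   `input` is a trace.
#' @return A `dropgate_report`: counts at each gate, the thresholds used,
#'   percent positive per marker, quadrant counts for the first marker
#'   pair, the called cell table, and the removal bookkeeping (counts
#'   removed at every stage sum to the input count).
#' @examples
#' m <- assay_model(list(cell_class("A", c(M = 0.9))), seed = 3)
#' sim <- simulate_event_table(m, 2000)
#' rep <- run_pipeline(sim$events, config = gate_config(downsample_n = 500))
#' rep$percent_positive
#' @export
run_pipeline <- function(input, markers = NULL, config = gate_config(),
                         comp = NULL, circuit = NULL,
                         trace_threshold = NULL, trace_min_width = 3L) {
  if (inherits(input, "trace_record")) {
    if (is.null(trace_threshold)) {
      stop("'trace_threshold' is required when the input is a raw trace")
    }
    events <- detect_events(input, trace_threshold, trace_min_width)
  } else {
    events <- as_event_table(input)
  }
  if (is.null(markers)) {
    markers <- setdiff(event_channels(events), config$stain_channel)
  }
  n_in <- nrow(events)
  if (!is.null(comp)) events <- compensate(events, comp)

  sized <- size_gate(events, config$size_trim_fraction)
  n_size_removed <- n_in - nrow(sized)

  parts <- cell_gate(sized, config)
  cells <- parts$cells
  empties <- parts$empties

  thresholds <- vapply(markers, function(mk) {
    amplification_threshold(empties, mk, config$amp_fold)
  }, numeric(1))

  n_cells_pre <- nrow(cells)
  cells <- downsample_events(cells, config$downsample_n, config$seed)
  n_down_removed <- n_cells_pre - nrow(cells)

  cells <- classify_positive(cells, thresholds)
  pp <- vapply(markers, function(mk) percent_positive(cells, mk), numeric(1))

  quadrants <- if (length(markers) >= 2L) {
    quadrant_counts(cells, markers[1L], markers[2L])
  } else {
    NULL
  }

  logic_fraction <- NULL
  if (!is.null(circuit)) {
    miss <- setdiff(circuit$inputs, markers)
    if (length(miss)) {
      stop("circuit input(s) not among assayed markers: ",
           paste(miss, collapse = ", "))
    }
    on <- vapply(seq_len(nrow(cells)), function(i) {
      a <- as.logical(unlist(cells[i, paste0("call_", circuit$inputs)]))
      names(a) <- circuit$inputs
      any(eval_boolean(circuit, a))
    }, logical(1))
    cells$call_logic <- on
    logic_fraction <- mean(on)
  }

  structure(
    list(
      n_input = n_in,
      n_removed_size_gate = n_size_removed,
      n_cells = n_cells_pre,
      n_empties = nrow(empties),
      n_removed_downsample = n_down_removed,
      n_analyzed = nrow(cells),
      stain_cutoff = parts$cutoff,
      thresholds = thresholds,
      percent_positive = pp,
      quadrants = quadrants,
      logic_fraction = logic_fraction,
      cells = cells
    ),
    class = "dropgate_report"
  )
}

#' @export
print.dropgate_report <- function(x, ...) {
  cat("Droplet gating report\n")
  cat(sprintf("  input events:        %d\n", x$n_input))
  cat(sprintf("  removed (size gate): %d\n", x$n_removed_size_gate))
  cat(sprintf("  cell gate:           %d cells / %d empties (stain cutoff %.3g)\n",
              x$n_cells, x$n_empties, x$stain_cutoff))
  cat(sprintf("  removed (down-sample): %d  ->  %d analyzed\n",
              x$n_removed_downsample, x$n_analyzed))
  for (mk in names(x$thresholds)) {
    cat(sprintf("  %s: threshold %.4g, %.2f%% positive\n",
                mk, x$thresholds[[mk]], 100 * x$percent_positive[[mk]]))
  }
  if (!is.null(x$quadrants)) {
    cat("  quadrants:", paste(names(x$quadrants), x$quadrants,
                              sep = "=", collapse = "  "), "\n")
  }
  if (!is.null(x$logic_fraction)) {
    cat(sprintf("  logic circuit ON: %.2f%%\n", 100 * x$logic_fraction))
  }
  invisible(x)
}

#' Serialize a pipeline report to CSV
#'
#' Writes a two-column key/value CSV of every scalar in the report, so a
#' run is reproducible from the logged thresholds and the input table
#' alone.
#'
#' @param report A `dropgate_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "dropgate_report"))
  rows <- list(
    c("n_input", report$n_input),
    c("n_removed_size_gate", report$n_removed_size_gate),
    c("n_cells", report$n_cells),
    c("n_empties", report$n_empties),
    c("n_removed_downsample", report$n_removed_downsample),
    c("n_analyzed", report$n_analyzed),
    c("stain_cutoff", report$stain_cutoff)
  )
  for (mk in names(report$thresholds)) {
    rows <- c(rows, list(c(paste0("threshold_", mk), report$thresholds[[mk]]),
                         c(paste0("percent_positive_", mk),
                           report$percent_positive[[mk]])))
  }
  if (!is.null(report$quadrants)) {
    for (q in names(report$quadrants)) {
      rows <- c(rows, list(c(paste0("quadrant_", q), report$quadrants[[q]])))
    }
  }
  if (!is.null(report$logic_fraction)) {
    rows <- c(rows, list(c("logic_fraction", report$logic_fraction)))
  }
  df <- data.frame(key = vapply(rows, `[`, "", 1L),
                   value = vapply(rows, `[`, "", 2L))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
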