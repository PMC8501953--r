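#' Define a cell class for droplet simulation
#'
#' A cell class names a population (e.g. an ERBB2-overexpressing line) and
#' gives, for each assayed marker, the probability that the marker amplifies
#' in a droplet containing one cell of this class. For a marker the class
#' truly expresses this probability is the assay's true positive rate; for a
#' marker it lacks it is typically the per-droplet false positive rate.
#'
#' @param name Class label.
#' @param expression Named numeric vector, marker name -> per-cell
#'   amplification probability in \[0, 1\].
#' @param stain_level Mean stain-channel fluorescence of a live cell of this
#'   class (arbitrary units, > 0 for stained classes).
#' @return An object of class `cell_class`.
#' @examples
#' cell_class("SKBR3", c(ERBB2 = 0.971), stain_level = 1000)
#' @export
cell_class <- function(name, expression, stain_level = 1000) {
  stopifnot(is.character(name), length(name) == 1L)
  if (is.null(names(expression)) || any(!nzchar(names(expression)))) {
    stop("'expression' must be a named vector of marker probabilities")
  }
  if (any(!is.finite(expression)) || any(expression < 0) || any(expression > 1)) {
    stop("marker amplification probabilities must lie in [0, 1]")
  }
  if (!is.finite(stain_level) || stain_level <= 0) {
    stop("'stain_level' must be a positive fluorescence level")
  }
  structure(
    list(name = name, expression = expression, stain_level = stain_level),
    class = "cell_class"
  )
}

#' Generative model of a droplet single-cell amplification assay
#'
#' Bundles everything needed to simulate droplet events or raw detector
#' traces with known ground truth: the cell classes present and their mixture
#' proportions, Poisson cell loading, per-marker false positive rate for
#' empty droplets, detector timing, fluorescence levels, spectral crosstalk,
#' noise, and nucleus-spike artifacts.
#'
#' Defaults reflect a droplet cytometer running at 300 droplets per second
#' with roughly one cell per ten droplets (`loading_rate = 0.105`, so
#' P(occupied) = 1 - exp(-0.105) ~= 0.0997) and an empty-droplet false
#' positive rate of 0.02%. Amplified droplets default to 10x the empty
#' baseline so a 2.8-fold-over-median threshold separates the populations
#' cleanly.
#'
#' @param classes List of [cell_class()] objects (all must share marker names).
#' @param proportions Mixture weights over `classes`; must sum to 1.
#' @param loading_rate Mean cells per droplet (Poisson lambda).
#' @param fpr_per_marker Probability that an empty droplet registers positive
#'   for a marker. Scalar or named per-marker vector.
#' @param droplet_rate Droplets per second traversing the detector.
#' @param sampling_rate Detector sampling rate in Hz (traces only).
#' @param duration_mean Mean in-laser droplet duration in samples.
#' @param duration_cv Coefficient of variation of the lognormal duration
#'   distribution.
#' @param empty_baseline Mean per-channel fluorescence of an empty droplet.
#' @param amp_signal Fluorescence added to a marker channel when the marker
#'   amplifies.
#' @param crosstalk Square spillover matrix (channels x channels, unit
#'   diagonal, non-negative) mapping true to observed fluorescence, or `NULL`
#'   for no crosstalk. Channel order is markers then `"stain"`.
#' @param noise_sd Per-channel additive Gaussian noise SD.
#' @param spike_rate Probability a droplet carries a nucleus-like spike
#'   artifact on the detection channel. Default 0 (the false positive rate is
#'   already modelled by `fpr_per_marker`; enable spikes to study the
#'   artifact mechanism itself).
#' @param spike_amplitude Spike fluorescence; default 5x `amp_signal`.
#' @param seed Integer RNG seed making simulations reproducible.
#' @return An object of class `assay_model`.
#' @examples
#' m <- assay_model(
#'   classes = list(
#'     cell_class("MOLT4", c(ERBB2 = 0.0002)),
#'     cell_class("SKBR3", c(ERBB2 = 0.971))
#'   ),
#'   proportions = c(0.9, 0.1), seed = 1
#' )
#' @export
assay_model <- function(classes,
                        proportions = rep(1 / length(classes), length(classes)),
                        loading_rate = 0.105,
                        fpr_per_marker = 2e-4,
                        droplet_rate = 300,
                        sampling_rate = 1e5,
                        duration_mean = 100,
                        duration_cv = 0.1,
                        empty_baseline = 100,
                        amp_signal = 10 * empty_baseline,
                        crosstalk = NULL,
                        noise_sd = 5,
                        spike_rate = 0,
                        spike_amplitude = 5 * amp_signal,
                        seed = 1L) {
  if (!is.list(classes) || length(classes) == 0L ||
      !all(vapply(classes, inherits, logical(1), "cell_class"))) {
    stop("'classes' must be a non-empty list of cell_class objects")
  }
  markers <- names(classes[[1L]]$expression)
  for (cl in classes) {
    if (!identical(sort(names(cl$expression)), sort(markers))) {
      stop("all cell classes must define the same marker set")
    }
  }
  if (length(proportions) != length(classes) || any(proportions < 0) ||
      abs(sum(proportions) - 1) > 1e-8) {
    stop("'proportions' must be non-negative and sum to 1")
  }
  if (!is.finite(loading_rate) || loading_rate < 0) {
    stop("'loading_rate' must be a non-negative Poisson mean")
  }
  if (length(fpr_per_marker) == 1L) {
    fpr_per_marker <- stats::setNames(rep(fpr_per_marker, length(markers)), markers)
  }
  fpr_per_marker <- fpr_per_marker[markers]
  if (any(!is.finite(fpr_per_marker)) || any(fpr_per_marker < 0) ||
      any(fpr_per_marker > 1)) {
    stop("'fpr_per_marker' must lie in [0, 1]")
  }
  if (spike_rate < 0 || spike_rate > 1) stop("'spike_rate' must lie in [0, 1]")
  channels <- c(markers, "stain")
  if (is.null(crosstalk)) {
    crosstalk <- diag(length(channels))
    dimnames(crosstalk) <- list(channels, channels)
  } else {
    crosstalk <- as.matrix(crosstalk)
    if (nrow(crosstalk) != length(channels) || ncol(crosstalk) != length(channels)) {
      stop("'crosstalk' must be a ", length(channels), "x", length(channels),
           " matrix over channels ", paste(channels, collapse = ", "))
    }
    if (any(abs(diag(crosstalk) - 1) > 1e-12) || any(crosstalk < 0)) {
      stop("'crosstalk' must have a unit diagonal and non-negative entries")
    }
    dimnames(crosstalk) <- list(channels, channels)
  }
  vals <- c(droplet_rate, sampling_rate, duration_mean, duration_cv,
            empty_baseline, amp_signal, noise_sd, spike_amplitude)
  if (any(!is.finite(vals))) stop("model parameters must be finite")
  if (sampling_rate / droplet_rate < duration_mean) {
    stop("droplet_rate, sampling_rate and duration_mean are inconsistent: ",
         "droplets would overlap (no room for oil gaps)")
  }
  structure(
    list(
      classes = classes, proportions = proportions, markers = markers,
      channels = channels, loading_rate = loading_rate,
      fpr_per_marker = fpr_per_marker, droplet_rate = droplet_rate,
      sampling_rate = sampling_rate, duration_mean = duration_mean,
      duration_cv = duration_cv, empty_baseline = empty_baseline,
      amp_signal = amp_signal, crosstalk = crosstalk, noise_sd = noise_sd,
      spike_rate = spike_rate, spike_amplitude = spike_amplitude,
      seed = as.integer(seed)
    ),
    class = "assay_model"
  )
}

#' @export
print.assay_model <- function(x, ...) {
  cat("Droplet assay model\n")
  cat("  classes:   ", paste(sprintf("%s (%.3g)",
                                     vapply(x$classes, `[[`, "", "name"),
                                     x$proportions), collapse = ", "), "\n")
  cat("  markers:   ", paste(x$markers, collapse = ", "), "\n")
  cat("  loading:   lambda =", x$loading_rate,
      sprintf("(P(occupied) = %.4f)", 1 - exp(-x$loading_rate)), "\n")
  cat("  detector:  ", x$droplet_rate, "droplets/s at", x$sampling_rate, "Hz\n")
  invisible(x)
}

## Lognormal parameterized by mean and CV on the natural scale.
rlnorm_meancv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

## Draw ground truth for n droplets: occupancy, class, true marker states,
## stain level, spike flag. A doublet's marker state is the OR over its cells.
draw_ground_truth <- function(model, n_droplets) {
  k <- length(model$markers)
  cell_count <- stats::rpois(n_droplets, model$loading_rate)
  class_name <- rep(NA_character_, n_droplets)
  stain <- numeric(n_droplets)
  states <- matrix(FALSE, n_droplets, k,
                   dimnames = list(NULL, model$markers))
  occ <- which(cell_count > 0L)
  class_names <- vapply(model$classes, `[[`, "", "name")
  for (i in occ) {
    idx <- sample.int(length(model$classes), cell_count[i],
                      replace = TRUE, prob = model$proportions)
    # label by the first cell; doublet composition is recoverable from states
    class_name[i] <- class_names[idx[1L]]
    stain[i] <- sum(vapply(model$classes[idx], `[[`, 0, "stain_level"))
    for (j in idx) {
      p <- model$classes[[j]]$expression[model$markers]
      states[i, ] <- states[i, ] | (stats::runif(k) < p)
    }
  }
  empty <- which(cell_count == 0L)
  if (length(empty)) {
    fp <- matrix(stats::runif(length(empty) * k), ncol = k) <
      matrix(model$fpr_per_marker, length(empty), k, byrow = TRUE)
    states[empty, ] <- fp
  }
  spike <- stats::runif(n_droplets) < model$spike_rate
  data.frame(
    droplet_id = seq_len(n_droplets),
    cell_count = cell_count,
    cell_class = class_name,
    states, spike = spike,
    stain_level = stain,
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
}

## True (pre-crosstalk, pre-noise) per-channel fluorescence per droplet.
true_fluorescence <- function(model, truth) {
  n <- nrow(truth)
  k <- length(model$markers)
  fl <- matrix(model$empty_baseline, n, k + 1L,
               dimnames = list(NULL, model$channels))
  st <- as.matrix(truth[, model$markers, drop = FALSE])
  fl[, seq_len(k)] <- fl[, seq_len(k)] + st * model$amp_signal
  fl[, "stain"] <- fl[, "stain"] + truth$stain_level
  # nucleus-like artifact hits the detection (first marker) channel
  fl[truth$spike, 1L] <- fl[truth$spike, 1L] + model$spike_amplitude
  fl
}

#' Simulate a per-droplet event table with known ground truth
#'
#' Draws droplets from the generative model: cell occupancy is Poisson,
#' classes follow the mixture proportions, each marker amplifies with its
#' class probability in occupied droplets (a doublet's state is the OR over
#' its cells) and with the false positive rate in empty ones. Observed
#' fluorescence is baseline + amplification signal, mixed through the
#' crosstalk matrix, plus Gaussian noise. Reproducible from the model seed.
#'
#' @param model An [assay_model()].
#' @param n_droplets Number of droplets to simulate (>= 1).
#' @return A list with `events` (an event table: `droplet_id`,
#'   `duration_samples`, one `mean_<channel>` column per channel) and
#'   `truth` (per-droplet ground truth: cell count, class, true marker
#'   states, spike flag).
#' @examples
#' m <- assay_model(list(cell_class("A", c(M = 0.97))), seed = 7)
#' sim <- simulate_event_table(m, 500)
#' head(sim$events)
#' @export
simulate_event_table <- function(model, n_droplets) {
  stopifnot(inherits(model, "assay_model"))
  if (!is.finite(n_droplets) || n_droplets < 1) stop("'n_droplets' must be >= 1")
  n_droplets <- as.integer(n_droplets)
  set.seed(model$seed)
  truth <- draw_ground_truth(model, n_droplets)
  fl <- true_fluorescence(model, truth)
  obs <- fl %*% t(model$crosstalk)
  if (model$noise_sd > 0) {
    obs <- obs + matrix(stats::rnorm(length(obs), 0, model$noise_sd),
                        nrow(obs), ncol(obs))
  }
  dur <- round(rlnorm_meancv(n_droplets, model$duration_mean, model$duration_cv))
  dur <- pmax(dur, 3)
  events <- data.frame(droplet_id = truth$droplet_id,
                       duration_samples = as.integer(dur))
  for (ch in model$channels) events[[paste0("mean_", ch)]] <- obs[, ch]
  list(events = as_event_table(events), truth = truth)
}

#' Simulate a raw multi-channel detector trace
#'
#' Lays the droplets of [simulate_event_table()] out in time: near-zero oil
#' gaps separate droplet plateaus whose per-channel heights equal the
#' event-level fluorescence. Spike artifacts appear as short high-amplitude
#' transients inside their droplet. Ground truth records the plateau
#' boundaries, so event detection can be validated exactly.
#'
#' @inheritParams simulate_event_table
#' @return A list with `trace` (a [trace_record()]), `truth` (ground truth
#'   with `start`/`end` sample columns, 0-based half-open), and `events`
#'   (the noiseless event-level table used to build the plateaus).
#' @export
simulate_traces <- function(model, n_droplets) {
  stopifnot(inherits(model, "assay_model"))
  if (!is.finite(n_droplets) || n_droplets < 1) stop("'n_droplets' must be >= 1")
  n_droplets <- as.integer(n_droplets)
  set.seed(model$seed)
  truth <- draw_ground_truth(model, n_droplets)
  fl <- true_fluorescence(model, truth)
  heights <- fl %*% t(model$crosstalk)

  dur <- pmax(round(rlnorm_meancv(n_droplets, model$duration_mean,
                                  model$duration_cv)), 3L)
  period <- model$sampling_rate / model$droplet_rate
  gap_mean <- period - model$duration_mean
  if (gap_mean < 2) stop("droplet rate leaves no oil gap between droplets")
  gaps <- pmax(round(rlnorm_meancv(n_droplets + 1L, gap_mean, model$duration_cv)), 2L)

  total <- sum(dur) + sum(gaps)
  k <- length(model$channels)
  samples <- matrix(0, total, k, dimnames = list(NULL, model$channels))
  start <- integer(n_droplets)
  pos <- gaps[1L]                      # 0-based index of first plateau sample
  for (i in seq_len(n_droplets)) {
    start[i] <- pos
    idx <- (pos + 1L):(pos + dur[i])   # 1-based rows
    samples[idx, ] <- matrix(heights[i, ], dur[i], k, byrow = TRUE)
    if (truth$spike[i]) {
      # transient rides on top of the plateau for <= 3 samples mid-droplet
      w <- min(3L, dur[i])
      off <- (dur[i] - w) %/% 2L
      samples[(pos + off + 1L):(pos + off + w), 1L] <-
        samples[(pos + off + 1L):(pos + off + w), 1L] + model$spike_amplitude
    }
    pos <- pos + dur[i] + gaps[i + 1L]
  }
  if (model$noise_sd > 0) {
    samples <- samples + matrix(stats::rnorm(length(samples), 0, model$noise_sd),
                                nrow(samples), ncol(samples))
  }
  truth$start <- start
  truth$end <- start + dur
  events <- data.frame(droplet_id = truth$droplet_id,
                       duration_samples = as.integer(dur))
  for (ch in model$channels) events[[paste0("mean_", ch)]] <- heights[, ch]
  list(
    trace = trace_record(samples, sampling_rate = model$sampling_rate,
                         detection_channel = model$channels[1L]),
    truth = truth,
    events = as_event_table(events)
  )
}
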