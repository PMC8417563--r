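#' Run configuration for the WBP analysis pipeline
#'
#' Collects every scalar parameter of the pipeline with its default. The
#' defaults are the standard operating point of the method: a 2nd-order
#' 15 Hz Butterworth lowpass, downsampling to 90 samples/s, a 0.3 ml/s
#' detection threshold, a 20% (max 100 ms) back-shift of the breath window,
#' duration-domain edges at 0, 0.2, 0.5, 1.2 and 4 s, a 90% PCA variance
#' target, a 30-cluster elbow scan, 20-breath annotation windows with a
#' >51% majority rule, and a 300 s (final 5 min) ventilation metric window.
#'
#' @param filter_order Butterworth filter order.
#' @param filter_cutoff_hz Lowpass cutoff (Hz); must stay below the Nyquist
#'   frequency of the raw trace.
#' @param zero_phase Apply the lowpass forward-backward (zero phase)? The
#'   default is single-pass causal filtering so that onset timing reflects
#'   the documented -3 dB prototype response.
#' @param target_rate Analysis sampling rate after resampling (samples/s).
#' @param detect_threshold_mls Threshold on flow (ml/s) for breath
#'   detection; crossings are then moved back to the preceding
#'   zero-crossing.
#' @param backshift_fraction Fraction of the breath length by which the
#'   breath window is shifted back.
#' @param backshift_cap_s Upper bound (s) on the back-shift.
#' @param domain_edges_s Strictly increasing duration-domain edges (s);
#'   bins are half-open `[lo, hi)`, breaths at or beyond the last edge are
#'   flagged out-of-range.
#' @param variance_target Fraction of variance the retained principal
#'   components must (strictly) exceed, in (0, 1).
#' @param max_clusters_scan Largest cluster count scanned by the elbow rule.
#' @param window_breaths Number of consecutive breaths per annotation
#'   window.
#' @param majority_pct Majority percentage (strictly exceeded) required to
#'   annotate a window; in (50, 100].
#' @param metric_window_s Length (s) of the per-period window (taken from
#'   the period end) over which rate and tidal volume are computed.
#' @param invert_flow Multiply the raw trace by -1 (for recordings whose
#'   polarity makes inspiration negative)?
#' @param linkage_cap Maximum number of waveforms per domain clustered
#'   exactly; above this the tree is fitted on a seeded subsample and the
#'   remainder assigned by nearest centroid.
#' @param rng_seed Integer seed used for any stochastic step (subsampling).
#'
#' @return A list of class `run_config`.
#' @export
#' @examples
#' cfg <- run_config()
#' cfg$detect_threshold_mls
run_config <- function(filter_order = 2,
                       filter_cutoff_hz = 15,
                       zero_phase = FALSE,
                       target_rate = 90,
                       detect_threshold_mls = 0.3,
                       backshift_fraction = 0.2,
                       backshift_cap_s = 0.1,
                       domain_edges_s = c(0, 0.2, 0.5, 1.2, 4.0),
                       variance_target = 0.90,
                       max_clusters_scan = 30,
                       window_breaths = 20,
                       majority_pct = 51,
                       metric_window_s = 300,
                       invert_flow = FALSE,
                       linkage_cap = 200000,
                       rng_seed = 1L) {
  cfg <- list(
    filter_order = as.integer(filter_order),
    filter_cutoff_hz = filter_cutoff_hz,
    zero_phase = isTRUE(zero_phase),
    target_rate = target_rate,
    detect_threshold_mls = detect_threshold_mls,
    backshift_fraction = backshift_fraction,
    backshift_cap_s = backshift_cap_s,
    domain_edges_s = as.numeric(domain_edges_s),
    variance_target = variance_target,
    max_clusters_scan = as.integer(max_clusters_scan),
    window_breaths = as.integer(window_breaths),
    majority_pct = majority_pct,
    metric_window_s = metric_window_s,
    invert_flow = isTRUE(invert_flow),
    linkage_cap = as.integer(linkage_cap),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "run_config"
  validate_run_config(cfg)
}

#' Validate a run configuration
#'
#' @param cfg A `run_config` list (or plain list with the same fields).
#' @return The validated config, invisibly classed as `run_config`.
#' @export
validate_run_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (!is.numeric(cfg$filter_order) || cfg$filter_order < 1)
    stop("filter_order must be a positive integer", call. = FALSE)
  if (!is.numeric(cfg$filter_cutoff_hz) || cfg$filter_cutoff_hz <= 0)
    stop("filter_cutoff_hz must be > 0", call. = FALSE)
  if (!is.numeric(cfg$target_rate) || cfg$target_rate <= 0)
    stop("target_rate must be > 0", call. = FALSE)
  if (!is.numeric(cfg$detect_threshold_mls) || cfg$detect_threshold_mls <= 0)
    stop("detect_threshold_mls must be > 0", call. = FALSE)
  if (cfg$backshift_fraction < 0 || cfg$backshift_fraction >= 1)
    stop("backshift_fraction must be in [0, 1)", call. = FALSE)
  if (cfg$backshift_cap_s < 0)
    stop("backshift_cap_s must be >= 0", call. = FALSE)
  edges <- cfg$domain_edges_s
  if (length(edges) < 2 || any(diff(edges) <= 0))
    stop("domain_edges_s must be strictly increasing", call. = FALSE)
  if (cfg$variance_target <= 0 || cfg$variance_target >= 1)
    stop("variance_target must be in (0, 1)", call. = FALSE)
  if (cfg$max_clusters_scan < 1)
    stop("max_clusters_scan must be >= 1", call. = FALSE)
  if (cfg$window_breaths < 1)
    stop("window_breaths must be >= 1", call. = FALSE)
  if (cfg$majority_pct <= 50 || cfg$majority_pct > 100)
    stop("majority_pct must be in (50, 100]", call. = FALSE)
  if (cfg$metric_window_s <= 0)
    stop("metric_window_s must be > 0", call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("WBP run configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}
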