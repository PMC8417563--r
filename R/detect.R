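#' Detect inspiration onsets by threshold crossing
#'
#' Finds upward crossings of the detection threshold and moves each back
#' to the preceding zero-crossing (the last sample at or below zero) to
#' mark the true beginning of inspiration. Consecutive crossings with no
#' intervening sub-zero sample collapse to a single onset, so flutter
#' around the threshold cannot double-count a breath. The threshold is
#' deliberately above zero (default 0.3 ml/s) so noise fluctuations around
#' zero are not detected.
#'
#' @param trace A preprocessed [flow_trace()] at the analysis rate.
#' @param threshold Detection threshold (ml/s), > 0.
#' @return Numeric vector of onset times (s), strictly increasing; empty
#'   for an all-zero (or never-crossing) trace.
#' @export
detect_onsets <- function(trace, threshold = 0.3) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be > 0", call. = FALSE)
  s <- trace$samples
  n <- length(s)
  above <- s >= threshold
  cross <- which(above & !c(FALSE, above[-n]))   # upward crossings
  if (length(cross) == 0) return(numeric(0))
  nonpos <- which(s <= 0)
  # index of the last non-positive sample before each crossing (0 if none)
  prev_np <- findInterval(cross, nonpos)
  onset_idx <- ifelse(prev_np == 0L, 1L, nonpos[pmax(prev_np, 1L)])
  # crossings sharing the same preceding zero-crossing collapse to one
  onset_idx <- onset_idx[!duplicated(onset_idx)]
  (onset_idx - 1) / trace$rate
}

#' Segment a trace into onset-to-onset breaths
#'
#' Breath `i` runs from onset `i` to onset `i + 1`; its total duration
#' `t_tot` is the raw onset-to-onset interval. To capture the full
#' inspiratory effort (including any pre-inspiratory negative deflection),
#' each breath's window start is shifted back by
#' `min(backshift_fraction * t_tot, backshift_cap_s)` (defaults: 20%,
#' 100 ms), clipped at the trace start. The final onset has no successor
#' and yields no breath. Each breath is assigned its duration domain, its
#' tidal volume (cumulative flow integral maximum) and an expiratory
#' duration estimate.
#'
#' @param trace Preprocessed [flow_trace()].
#' @param onsets Onset times from [detect_onsets()].
#' @param cfg A [run_config()].
#' @return A `data.frame` (class `breath_set`) with one row per breath:
#'   `onset_s` (window start), `raw_onset_s`, `t_tot_s`, `duration_s`
#'   (alias of `t_tot_s`), `n_samples` (true waveform length),
#'   `domain_id` (`NA` when out of range), `v_t_ml`, `t_e_s`,
#'   `cluster_id` (`NA` until fitted), `period_label`, `subject_id`, and a
#'   `samples` list column holding the windowed flow snippet. The analysis
#'   rate is stored in attribute `rate`.
#' @export
segment_breaths <- function(trace, onsets, cfg = run_config()) {
  rate <- trace$rate
  if (length(onsets) < 2) return(empty_breath_set(rate, cfg$domain_edges_s))
  m <- length(onsets) - 1
  raw_idx <- round(onsets * rate) + 1L
  t_tot <- diff(onsets)
  shift <- pmin(cfg$backshift_fraction * t_tot, cfg$backshift_cap_s)
  start_s <- pmax(onsets[-length(onsets)] - shift, 0)
  start_idx <- pmax(round(start_s * rate) + 1L, 1L)
  samples <- vector("list", m)
  v_t <- numeric(m)
  t_e <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    end_idx <- raw_idx[i + 1] - 1L
    snip <- trace$samples[start_idx[i]:end_idx]
    samples[[i]] <- snip
    v_t[i] <- integrate_tidal_volume(snip, rate)
    t_e[i] <- expiratory_time(trace$samples, raw_idx[i], end_idx, rate,
                              t_tot[i])
  }
  b <- data.frame(
    onset_s = (start_idx - 1) / rate,
    raw_onset_s = onsets[-length(onsets)],
    t_tot_s = t_tot,
    duration_s = t_tot,
    n_samples = lengths(samples),
    domain_id = assign_domain(t_tot, cfg$domain_edges_s),
    v_t_ml = v_t,
    t_e_s = t_e,
    cluster_id = NA_integer_,
    period_label = period_at(trace, onsets[-length(onsets)]),
    subject_id = trace$subject_id,
    stringsAsFactors = FALSE
  )
  b$samples <- samples
  attr(b, "rate") <- rate
  attr(b, "domain_edges_s") <- cfg$domain_edges_s
  class(b) <- c("breath_set", "data.frame")
  b
}

empty_breath_set <- function(rate, edges) {
  b <- data.frame(onset_s = numeric(0), raw_onset_s = numeric(0),
                  t_tot_s = numeric(0), duration_s = numeric(0),
                  n_samples = integer(0), domain_id = integer(0),
                  v_t_ml = numeric(0), t_e_s = numeric(0),
                  cluster_id = integer(0), period_label = character(0),
                  subject_id = character(0), stringsAsFactors = FALSE)
  b$samples <- list()
  attr(b, "rate") <- rate
  attr(b, "domain_edges_s") <- edges
  class(b) <- c("breath_set", "data.frame")
  b
}

# T_E = t_tot - inspiratory time; inspiratory time ends at the last
# positive-flow sample before sustained (>= 50 ms) non-positive flow.
expiratory_time <- function(s, raw_idx, end_idx, rate, t_tot) {
  seg <- s[raw_idx:end_idx]
  run <- ceiling(0.05 * rate)
  nonpos <- seg <= 0
  if (length(seg) < run + 1) return(NA_real_)
  r <- rle(nonpos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- which(r$values & r$lengths >= run & starts > 1)
  insp_end <- if (length(cand) > 0) starts[cand[1]] - 1 else {
    pos <- which(seg > 0)
    if (length(pos) == 0) 1L else max(pos)
  }
  max(t_tot - insp_end / rate, 0)
}

#' Assign breath durations to duration domains
#'
#' Bins are half-open `[lo, hi)` against the ordered edge list (defaults
#' 0, 0.2, 0.5, 1.2, 4 s, giving four domains: sniffing, short tidal,
#' long tidal, very long). Durations at or beyond the last edge are
#' out-of-range and return `NA` (kept in counts, excluded from
#' clustering).
#'
#' @param t_tot_s Numeric vector of breath durations (s).
#' @param edges Strictly increasing edge vector (s).
#' @return Integer vector of domain ids (1-based), `NA` when out of range.
#' @export
assign_domain <- function(t_tot_s, edges = c(0, 0.2, 0.5, 1.2, 4.0)) {
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing",
                                  call. = FALSE)
  k <- findInterval(t_tot_s, edges)
  k[k < 1 | k >= length(edges)] <- NA_integer_
  as.integer(k)
}

#' Tidal volume of a breath snippet
#'
#' The flow waveform is integrated (cumulative trapezoid) and the tidal
#' volume taken as the maximum of the running integral - i.e. the inspired
#' volume before net expiration dominates. Always non-negative: an
#' all-expiratory snippet has `V_T = 0`.
#'
#' @param samples Flow values (ml/s) at `rate`.
#' @param rate Sampling rate (samples/s).
#' @return Tidal volume (ml).
#' @export
integrate_tidal_volume <- function(samples, rate) {
  if (length(samples) < 2) return(0)
  cum <- pracma::cumtrapz(seq_along(samples) / rate, samples)
  max(c(0, cum))
}
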