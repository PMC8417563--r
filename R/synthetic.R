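#' Default breath templates for the synthetic WBP generator
#'
#' Parametric per-class breath shapes emulating rat plethysmography:
#' half-sine inspiration (biphasic for the augmented-breath/sigh class),
#' exponential-decay expiratory flow, and an optional post-breath apnea
#' tail (sigh and apneic classes). Durations and tidal volumes are drawn
#' per breath from truncated normals; defaults are rat-plausible (tidal
#' V_T around 1.6-2.2 ml, sniff cycles under 0.2 s, sighs of roughly
#' double tidal volume). Noiseless sniff realizations always fall in
#' duration domain 1, tidal ones in domains 2-3, and sigh/apneic ones in
#' domain 4.
#'
#' Template fields: `label`; `duration_s` `(mean, sd)` with hard
#' `duration_range` clamps (keeps classes inside their nominal domains);
#' `insp_frac` (inspiratory time as a fraction of the *nominal* mean
#' duration - rate depression stretches expiration, not inspiration);
#' `v_t_ml` `(mean, sd)`; `n_phases` (2 = biphasic inspiration);
#' `phase2_rel` (second-phase amplitude ratio); `apnea_frac` (final
#' fraction of the cycle with zero flow).
#'
#' @return Named list of `breath_template` objects.
#' @export
breath_templates <- function() {
  tpl <- list(
    sniff = list(label = "sniff", duration_s = c(0.15, 0.015),
                 duration_range = c(0.11, 0.19), insp_frac = 0.5,
                 v_t_ml = c(0.30, 0.04), n_phases = 1, phase2_rel = NA,
                 apnea_frac = 0),
    tidal_short = list(label = "tidal_short", duration_s = c(0.35, 0.04),
                       duration_range = c(0.25, 0.48), insp_frac = 0.4,
                       v_t_ml = c(1.6, 0.20), n_phases = 1,
                       phase2_rel = NA, apnea_frac = 0),
    tidal_long = list(label = "tidal_long", duration_s = c(0.80, 0.08),
                      duration_range = c(0.55, 1.15), insp_frac = 0.4,
                      v_t_ml = c(2.2, 0.25), n_phases = 1, phase2_rel = NA,
                      apnea_frac = 0),
    sigh = list(label = "sigh", duration_s = c(2.5, 0.30),
                duration_range = c(1.7, 3.5), insp_frac = 0.20,
                v_t_ml = c(4.5, 0.50), n_phases = 2, phase2_rel = 1.5,
                apnea_frac = 0.45),
    apneic_tidal = list(label = "apneic_tidal", duration_s = c(2.0, 0.30),
                        duration_range = c(1.4, 3.2), insp_frac = 0.16,
                        v_t_ml = c(2.2, 0.25), n_phases = 1,
                        phase2_rel = NA, apnea_frac = 0.5)
  )
  lapply(tpl, function(t) structure(t, class = "breath_template"))
}

#' Build a state schedule for the synthetic generator
#'
#' A schedule is an ordered list of behavioral states; each state has a
#' duration, a template mixture, and rate/amplitude multipliers. The rate
#' multiplier scales breathing frequency by stretching the expiratory
#' (and apneic) portion of each cycle - inspiratory timing is preserved -
#' while the amplitude multiplier scales flow, so tidal volume tracks the
#' amplitude multiplier and respiratory rate tracks the rate multiplier.
#'
#' @param ... One or more state lists with fields `label`, `duration_s`,
#'   `weights` (named, summing to 1, over template names), `rate_mult`,
#'   `amp_mult`.
#' @return A list of class `state_schedule`.
#' @export
state_schedule <- function(...) {
  states <- list(...)
  for (s in states) {
    stopifnot(is.character(s$label), s$duration_s > 0,
              !is.null(names(s$weights)))
    if (abs(sum(s$weights) - 1) > 1e-9)
      stop("state '", s$label, "': weights must sum to 1", call. = FALSE)
    if (s$rate_mult <= 0 || s$amp_mult <= 0)
      stop("state '", s$label, "': multipliers must be > 0", call. = FALSE)
  }
  structure(states, class = "state_schedule")
}

#' Two-state baseline-to-depressed demo schedule
#'
#' Baseline: a tidal mixture (short and long tidal breaths in equal
#' measure) with occasional sighs (weight 0.01, about one per minute).
#' Depressed: the same tidal mixture with breathing rate and flow
#' amplitude both halved and sighs absent - the canonical opioid-like
#' depression pattern the annotation and ventilation metrics are meant to
#' resolve.
#'
#' @param baseline_s,depressed_s State durations (s).
#' @param rate_mult,amp_mult Depressed-state multipliers (defaults 0.5).
#' @return A [state_schedule()].
#' @export
two_state_schedule <- function(baseline_s = 600, depressed_s = 600,
                               rate_mult = 0.5, amp_mult = 0.5) {
  state_schedule(
    list(label = "baseline", duration_s = baseline_s,
         weights = c(tidal_short = 0.495, tidal_long = 0.495,
                     sigh = 0.01),
         rate_mult = 1, amp_mult = 1),
    list(label = "depressed", duration_s = depressed_s,
         weights = c(tidal_short = 0.5, tidal_long = 0.5),
         rate_mult = rate_mult, amp_mult = amp_mult)
  )
}

#' Multi-behavior baseline schedule (sniffing, tidal, sighs, apneas)
#'
#' A single richer state exercising all four duration domains, for
#' clustering and annotation tests.
#'
#' @param duration_s State duration (s).
#' @return A [state_schedule()].
#' @export
multi_behavior_schedule <- function(duration_s = 600) {
  state_schedule(
    list(label = "baseline", duration_s = duration_s,
         weights = c(sniff = 0.25, tidal_short = 0.30, tidal_long = 0.35,
                     sigh = 0.04, apneic_tidal = 0.06),
         rate_mult = 1, amp_mult = 1)
  )
}

# one noiseless breath realization; returns samples and realized params
realize_breath <- function(tpl, rate, rate_mult = 1, amp_mult = 1) {
  dur_nom <- clamp(stats::rnorm(1, tpl$duration_s[1], tpl$duration_s[2]),
                   tpl$duration_range[1], tpl$duration_range[2])
  dur_tot <- dur_nom / rate_mult
  v_t <- max(stats::rnorm(1, tpl$v_t_ml[1], tpl$v_t_ml[2]),
             0.25 * tpl$v_t_ml[1]) * amp_mult
  t_i <- min(tpl$insp_frac * tpl$duration_s[1], 0.9 * dur_tot)
  n <- round(dur_tot * rate)
  t <- (seq_len(n) - 1) / rate
  flow <- numeric(n)
  if (tpl$n_phases == 2) {
    half <- t_i / 2
    a1 <- v_t * pi / (t_i * (1 + tpl$phase2_rel))
    p1 <- t < half
    p2 <- t >= half & t < t_i
    flow[p1] <- a1 * sin(pi * t[p1] / half)
    flow[p2] <- tpl$phase2_rel * a1 * sin(pi * (t[p2] - half) / half)
    a_peak <- tpl$phase2_rel * a1
  } else {
    a_peak <- v_t * pi / (2 * t_i)
    p1 <- t < t_i
    flow[p1] <- a_peak * sin(pi * t[p1] / t_i)
  }
  # expiration: exponential decay of negative flow, then optional apnea
  exp_end <- dur_tot * (1 - tpl$apnea_frac)
  if (exp_end <= t_i) exp_end <- min(dur_tot, t_i + 0.05)
  te <- exp_end - t_i
  tau <- te / 4
  b <- min(v_t / (tau * (1 - exp(-te / tau))), 1.2 * a_peak)
  pe <- t >= t_i & t < exp_end
  flow[pe] <- -b * exp(-(t[pe] - t_i) / tau)
  list(samples = flow, duration_s = n / rate, v_t_ml = v_t,
       label = tpl$label)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic WBP flow trace with ground truth
#'
#' Concatenates per-breath realizations following the state schedule and
#' adds Gaussian sensor noise. Every breath's true onset, duration, class
#' label, state and analytic tidal volume are returned alongside the
#' trace, whose `periods` table mirrors the state boundaries. Identical
#' seeds give bit-identical output; the caller's RNG state is left
#' untouched.
#'
#' @param schedule A [state_schedule()].
#' @param templates Template list (default [breath_templates()]).
#' @param rate Sampling rate (samples/s), default 500.
#' @param noise_sd Additive Gaussian noise SD (ml/s), default 0.05.
#' @param seed Integer seed (required for reproducibility).
#' @param subject_id Subject identifier for the trace.
#' @return List with `trace` (a [flow_trace()]) and `truth` (a
#'   `data.frame`: `onset_s`, `duration_s`, `label`, `state`, `v_t_ml`).
#' @export
generate_trace <- function(schedule, templates = breath_templates(),
                           rate = 500, noise_sd = 0.05, seed = 1L,
                           subject_id = "sim") {
  stopifnot(inherits(schedule, "state_schedule"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  all_samples <- vector("list", length(schedule))
  truth <- list()
  periods <- data.frame(label = character(0), start_s = numeric(0),
                        end_s = numeric(0), stringsAsFactors = FALSE)
  t0 <- 0
  for (st in schedule) {
    n_state <- round(st$duration_s * rate)
    buf <- numeric(n_state)
    cursor <- 0L
    n_breaths <- 0L
    repeat {
      tpl <- templates[[sample(names(st$weights), 1, prob = st$weights)]]
      br <- realize_breath(tpl, rate, st$rate_mult, st$amp_mult)
      nb <- length(br$samples)
      if (cursor + nb > n_state) break
      buf[(cursor + 1):(cursor + nb)] <- br$samples
      truth[[length(truth) + 1]] <- data.frame(
        onset_s = t0 + cursor / rate, duration_s = br$duration_s,
        label = br$label, state = st$label, v_t_ml = br$v_t_ml,
        stringsAsFactors = FALSE)
      cursor <- cursor + nb
      n_breaths <- n_breaths + 1L
    }
    if (n_breaths == 0L)
      stop("state '", st$label, "' is shorter than one breath",
           call. = FALSE)
    all_samples[[length(all_samples) + 1]] <- buf
    periods <- rbind(periods, data.frame(label = st$label, start_s = t0,
                                         end_s = t0 + n_state / rate,
                                         stringsAsFactors = FALSE))
    t0 <- t0 + n_state / rate
  }
  samples <- unlist(all_samples)
  if (noise_sd > 0) samples <- samples + stats::rnorm(length(samples),
                                                      0, noise_sd)
  list(trace = flow_trace(samples, rate = rate, subject_id = subject_id,
                          periods = periods),
       truth = do.call(rbind, truth))
}

#' Generate a labeled waveform benchmark with controlled separation
#'
#' Produces `n_classes * n_per_class` equal-length waveforms for
#' clustering benchmarks. Class mean waveforms are displaced along a
#' smooth base shape; within-class variability is Gaussian along a few
#' smooth modes (waveform variation in practice is smooth, not white).
#' `separation` is the distance between adjacent class means in units of
#' the total within-class standard deviation, so expected clustering
#' difficulty is tunable: large separation gives trivially recoverable
#' classes, 0 collapses all classes onto one distribution.
#'
#' @param n_classes Number of classes.
#' @param separation Adjacent-class mean distance / within-class SD.
#' @param n_per_class Waveforms per class.
#' @param n_samples Waveform length (samples), default 40.
#' @param noise_sd Per-mode within-class SD, default 1.
#' @param n_noise_modes Number of smooth within-class variation modes,
#'   default 3.
#' @param seed Integer seed.
#' @return List with `mat` (waveform matrix, rows grouped by class) and
#'   `labels` (integer class labels, exactly `n_per_class` each).
#' @export
generate_cluster_benchmark <- function(n_classes, separation, n_per_class,
                                       n_samples = 40, noise_sd = 1,
                                       n_noise_modes = 3, seed = 1L) {
  if (separation < 0) stop("separation must be >= 0", call. = FALSE)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  L <- n_samples
  t <- seq_len(L)
  basis <- sapply(seq_len(n_noise_modes + 1), function(j) {
    v <- sin(j * pi * t / (L + 1)); v / sqrt(sum(v^2))
  })
  delta <- separation * noise_sd * sqrt(n_noise_modes)
  mu <- outer((seq_len(n_classes) - 1) * delta, basis[, 1])
  labels <- rep(seq_len(n_classes), each = n_per_class)
  z <- matrix(stats::rnorm(length(labels) * n_noise_modes), ncol =
                n_noise_modes)
  mat <- mu[labels, , drop = FALSE] +
    noise_sd * z %*% t(basis[, -1, drop = FALSE])
  list(mat = mat, labels = labels)
}
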