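#' Construct a flow trace
#'
#' A `flow_trace` is a uniformly sampled airflow record: flow values in
#' ml/s (inspiration positive), a constant sampling rate, a subject
#' identifier, and an ordered table of experimental periods (e.g. baseline,
#' drug, rescue) given as `[start_s, end_s)` intervals.
#'
#' @param samples Numeric vector of flow values (ml/s).
#' @param rate Sampling rate (samples/s), > 0.
#' @param subject_id Identifier string.
#' @param periods Optional `data.frame` with columns `label`, `start_s`,
#'   `end_s`; intervals must be non-overlapping, ordered, and within
#'   `[0, duration]`.
#' @return An object of class `flow_trace`.
#' @export
#' @examples
#' tr <- flow_trace(sin(seq(0, 2 * pi, length.out = 500)), rate = 500)
#' trace_duration(tr)
flow_trace <- function(samples, rate, subject_id = "subject",
                       periods = NULL) {
  if (!is.numeric(samples) || length(samples) == 0)
    stop("samples must be a nonempty numeric vector", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0)
    stop("rate must be a single value > 0", call. = FALSE)
  x <- structure(
    list(samples = as.numeric(samples), rate = as.numeric(rate),
         subject_id = as.character(subject_id), periods = periods),
    class = "flow_trace")
  validate_flow_trace(x)
}

validate_flow_trace <- function(x) {
  dur <- length(x$samples) / x$rate
  p <- x$periods
  if (!is.null(p)) {
    stopifnot(is.data.frame(p),
              all(c("label", "start_s", "end_s") %in% names(p)))
    if (any(p$end_s <= p$start_s))
      stop("period intervals must have end_s > start_s", call. = FALSE)
    if (any(p$start_s < 0) || any(p$end_s > dur + 1e-9))
      stop("period intervals must lie within [0, duration]", call. = FALSE)
    if (nrow(p) > 1) {
      o <- order(p$start_s)
      p <- p[o, , drop = FALSE]
      if (any(p$start_s[-1] < p$end_s[-nrow(p)] - 1e-9))
        stop("period intervals must not overlap", call. = FALSE)
    }
    x$periods <- p
  }
  x
}

#' Duration of a flow trace in seconds
#' @param trace A `flow_trace`.
#' @return Duration (s), `n_samples / rate`.
#' @export
trace_duration <- function(trace) length(trace$samples) / trace$rate

#' Time base of a flow trace
#' @param trace A `flow_trace`.
#' @return Numeric vector of sample times (s), starting at 0.
#' @export
trace_times <- function(trace) (seq_along(trace$samples) - 1) / trace$rate

#' @export
print.flow_trace <- function(x, ...) {
  cat(sprintf("flow_trace: subject '%s', %d samples at %g samples/s (%.2f s)\n",
              x$subject_id, length(x$samples), x$rate, trace_duration(x)))
  if (!is.null(x$periods)) {
    cat("periods:\n")
    print(x$periods, row.names = FALSE)
  }
  invisible(x)
}

#' Look up the period label at given times
#'
#' @param trace A `flow_trace` with a `periods` table.
#' @param times_s Numeric vector of times (s).
#' @return Character vector of period labels (`NA` outside all periods).
#'   Period intervals are treated as `[start_s, end_s)`.
#' @export
period_at <- function(trace, times_s) {
  p <- trace$periods
  if (is.null(p)) return(rep(NA_character_, length(times_s)))
  out <- rep(NA_character_, length(times_s))
  for (i in seq_len(nrow(p))) {
    sel <- times_s >= p$start_s[i] & times_s < p$end_s[i]
    out[sel] <- p$label[i]
  }
  out
}
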