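#' @export
`[.breath_set` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "rate") <- attr(x, "rate")
    attr(out, "domain_edges_s") <- attr(x, "domain_edges_s")
    class(out) <- class(x)
  }
  out
}

#' @export
print.breath_set <- function(x, ...) {
  cat(sprintf("breath_set: %d breaths at %g samples/s\n", nrow(x),
              attr(x, "rate")))
  if (nrow(x) > 0) {
    dom <- table(factor(x$domain_id, levels = seq_len(
      length(attr(x, "domain_edges_s")) - 1)), useNA = "ifany")
    cat("per-domain counts:", paste(dom, collapse = " / "), "\n")
    df <- as.data.frame(x)[, setdiff(names(x), "samples"), drop = FALSE]
    print(utils::head(df), row.names = FALSE)
    if (nrow(x) > 6) cat("...\n")
  }
  invisible(x)
}

#' Attach period labels from a trace to a breath set
#'
#' @param breaths A `breath_set`.
#' @param trace A [flow_trace()] carrying a `periods` table (or a periods
#'   `data.frame` itself).
#' @return The breath set with `period_label` filled by each breath's raw
#'   onset time.
#' @export
label_periods <- function(breaths, trace) {
  if (is.data.frame(trace))
    trace <- list(periods = trace)
  breaths$period_label <- period_at(trace, breaths$raw_onset_s)
  breaths
}
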