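# Build a breath_set directly from waveform matrices (one matrix per
# duration domain), bypassing detection, for clustering-layer tests.
fake_breath_set <- function(mats, domains, rate = 90,
                            subject_id = "subj1", period = "baseline") {
  edges <- c(0, 0.2, 0.5, 1.2, 4)
  rows <- list()
  onset <- 0
  for (j in seq_along(mats)) {
    m <- mats[[j]]
    d <- domains[j]
    t_tot <- mean(edges[d:(d + 1)])
    for (i in seq_len(nrow(m))) {
      rows[[length(rows) + 1]] <- list(samples = as.numeric(m[i, ]),
                                       t_tot = t_tot, domain = d)
      onset <- onset + t_tot
    }
  }
  n <- length(rows)
  t_tots <- vapply(rows, `[[`, numeric(1), "t_tot")
  onsets <- cumsum(c(0, t_tots[-n]))
  b <- data.frame(onset_s = onsets, raw_onset_s = onsets,
                  t_tot_s = t_tots, duration_s = t_tots,
                  n_samples = vapply(rows, function(r)
                    length(r$samples), integer(1)),
                  domain_id = vapply(rows, function(r)
                    as.integer(r$domain), integer(1)),
                  v_t_ml = NA_real_, t_e_s = NA_real_,
                  cluster_id = NA_integer_,
                  period_label = period,
                  subject_id = if (length(subject_id) == n) subject_id
                               else rep(subject_id, n),
                  stringsAsFactors = FALSE)
  b$samples <- lapply(rows, `[[`, "samples")
  attr(b, "rate") <- rate
  attr(b, "domain_edges_s") <- edges
  class(b) <- c("breath_set", "data.frame")
  b
}

# concatenate two breath_sets (list-column-safe rbind keeping attributes)
rbind_breaths <- function(a, b) {
  out <- rbind(as.data.frame(a), as.data.frame(b))
  attr(out, "rate") <- attr(a, "rate")
  attr(out, "domain_edges_s") <- attr(a, "domain_edges_s")
  class(out) <- c("breath_set", "data.frame")
  out
}

# breath_set with prescribed cluster ids and period labels only (for the
# annotation layer, which never touches the waveforms)
labeled_breaths <- function(cluster_id, period = "baseline",
                            t_tot = 0.5, subject_id = "subj1") {
  n <- length(cluster_id)
  onsets <- cumsum(c(0, rep(t_tot, n - 1)))
  b <- data.frame(onset_s = onsets, raw_onset_s = onsets,
                  t_tot_s = rep(t_tot, n), duration_s = rep(t_tot, n),
                  n_samples = 10L, domain_id = 2L,
                  v_t_ml = 1.0, t_e_s = NA_real_,
                  cluster_id = as.integer(cluster_id),
                  period_label = if (length(period) == n) period
                                 else rep(period, n),
                  subject_id = if (length(subject_id) == n) subject_id
                               else rep(subject_id, n),
                  stringsAsFactors = FALSE)
  b$samples <- replicate(n, numeric(10), simplify = FALSE)
  attr(b, "rate") <- 90
  attr(b, "domain_edges_s") <- c(0, 0.2, 0.5, 1.2, 4)
  class(b) <- c("breath_set", "data.frame")
  b
}
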