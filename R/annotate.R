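#' Split tidal clusters into common and uncommon sets
#'
#' Computes the prevalence of each tidal-duration cluster among the
#' baseline-period tidal breaths and marks the clusters occurring strictly
#' above the average prevalence (which equals `1 / n_tidal_clusters`) as
#' "common tidal"; the remainder are "uncommon tidal". With uniform
#' prevalences no cluster is strictly above average and the common set is
#' empty.
#'
#' @param breaths A `breath_set` with `cluster_id` and `period_label`.
#' @param tidal_clusters Integer vector of tidal cluster ids (typically
#'   all clusters of the two tidal duration domains).
#' @param baseline_label Period label defining baseline (default
#'   `"baseline"`).
#' @return List with `common`, `uncommon` (integer id vectors partitioning
#'   `tidal_clusters`) and `prevalence` (named numeric).
#' @export
derive_common_tidal <- function(breaths, tidal_clusters,
                                baseline_label = "baseline") {
  if (length(tidal_clusters) == 0)
    stop("tidal_clusters must be nonempty", call. = FALSE)
  base <- !is.na(breaths$period_label) &
    breaths$period_label == baseline_label
  if (!any(base))
    stop("no breaths in baseline period '", baseline_label, "'",
         call. = FALSE)
  tid <- base & breaths$cluster_id %in% tidal_clusters
  if (!any(tid))
    stop("no baseline breaths in the given tidal clusters", call. = FALSE)
  counts <- table(factor(breaths$cluster_id[tid], levels = tidal_clusters))
  prev <- as.numeric(counts) / sum(counts)
  names(prev) <- tidal_clusters
  common <- tidal_clusters[prev > 1 / length(tidal_clusters)]
  list(common = common,
       uncommon = setdiff(tidal_clusters, common),
       prevalence = prev)
}

#' Annotate the record in fixed-size breath windows by cluster majority
#'
#' Consecutive non-overlapping blocks of `window_breaths` breaths are
#' labeled with the behavioral category (e.g. sniffing, common tidal,
#' uncommon tidal, augmented) whose member clusters account for strictly
#' more than `majority_pct`% of the block; blocks where no category
#' reaches that majority - mixed behavior - are left `"unannotated"`, as
#' is a trailing partial block.
#'
#' @param breaths A `breath_set`, ordered by onset, with `cluster_id`.
#' @param category_map Named list mapping category label to a vector of
#'   cluster ids; categories must be disjoint.
#' @param window_breaths Breaths per window (default 20).
#' @param majority_pct Majority threshold in percent (default 51; at
#'   window size 20 a label requires >= 11 member breaths).
#' @return A `data.frame` (class `annotation_track`) with `start_s`,
#'   `end_s`, `label`, `majority_fraction`, `n_breaths` per window.
#' @export
annotate_windows <- function(breaths, category_map, window_breaths = 20,
                             majority_pct = 51) {
  ids <- unlist(category_map, use.names = FALSE)
  if (anyDuplicated(ids))
    stop("category_map cluster sets must be disjoint", call. = FALSE)
  if (is.unsorted(breaths$onset_s))
    breaths <- breaths[order(breaths$onset_s), ]
  n <- nrow(breaths)
  n_win <- n %/% window_breaths
  trailing <- n %% window_breaths
  rows <- vector("list", n_win + (trailing > 0))
  for (w in seq_len(n_win)) {
    sel <- ((w - 1) * window_breaths + 1):(w * window_breaths)
    cl <- breaths$cluster_id[sel]
    counts <- vapply(category_map, function(s) sum(cl %in% s, na.rm = TRUE),
                     numeric(1))
    frac <- counts / window_breaths
    best <- which.max(frac)
    lab <- if (frac[best] > majority_pct / 100) names(category_map)[best]
           else "unannotated"
    rows[[w]] <- data.frame(
      start_s = breaths$onset_s[sel[1]],
      end_s = breaths$raw_onset_s[sel[window_breaths]] +
        breaths$t_tot_s[sel[window_breaths]],
      label = lab,
      majority_fraction = unname(frac[best]),
      n_breaths = window_breaths,
      stringsAsFactors = FALSE)
  }
  if (trailing > 0) {
    sel <- (n_win * window_breaths + 1):n
    rows[[n_win + 1]] <- data.frame(
      start_s = breaths$onset_s[sel[1]],
      end_s = breaths$raw_onset_s[sel[length(sel)]] +
        breaths$t_tot_s[sel[length(sel)]],
      label = "unannotated",
      majority_fraction = NA_real_,
      n_breaths = length(sel),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(start_s = numeric(0),
                                      end_s = numeric(0),
                                      label = character(0),
                                      majority_fraction = numeric(0),
                                      n_breaths = integer(0))
  class(out) <- c("annotation_track", "data.frame")
  out
}

#' Cluster prevalence per period (or any grouping)
#'
#' Each cell is the proportion of the row group's breaths that fall in a
#' given global cluster; rows sum to 1. Breaths without a cluster id
#' (out-of-range durations, skipped domains) are counted under a reserved
#' `"unassigned"` column so nothing is dropped.
#'
#' @param breaths A `breath_set` with `cluster_id`.
#' @param by Grouping column name(s), default `"period_label"`; several
#'   names give a group-by-period style interaction.
#' @return A matrix (class `prevalence_table`) with one row per group and
#'   one column per cluster id (plus `"unassigned"` when needed). Groups
#'   with zero breaths are flagged in attribute `empty_groups`.
#' @export
prevalence_table <- function(breaths, by = "period_label") {
  stopifnot(all(by %in% names(breaths)))
  grp <- interaction(as.data.frame(breaths)[, by, drop = FALSE],
                     sep = ":", drop = FALSE)
  cl <- ifelse(is.na(breaths$cluster_id), "unassigned",
               as.character(breaths$cluster_id))
  lev <- unique(cl)
  num <- suppressWarnings(as.integer(lev))
  lev <- c(as.character(sort(num[!is.na(num)])),
           if (any(is.na(num))) "unassigned")
  tab <- table(grp, factor(cl, levels = lev))
  counts <- matrix(tab, nrow = nrow(tab),
                   dimnames = list(rownames(tab), colnames(tab)))
  totals <- rowSums(counts)
  prop <- counts / ifelse(totals == 0, 1, totals)
  structure(prop, class = c("prevalence_table", class(prop)),
            empty_groups = rownames(counts)[totals == 0])
}

#' Ventilation metrics per experimental period
#'
#' Respiratory rate is the number of detected breaths whose onset falls in
#' the final `metric_window_s` seconds of the period divided by the window
#' duration in minutes; tidal volume is the mean integrated `v_t_ml` of
#' those breaths; minute ventilation is their product. A period shorter
#' than the metric window is used in full (with a message). Metrics can be
#' expressed as a percentage of a baseline period.
#'
#' @param breaths A `breath_set` with `v_t_ml`.
#' @param periods Periods `data.frame` (`label`, `start_s`, `end_s`) or a
#'   [flow_trace()] carrying one.
#' @param metric_window_s Window length (s), default 300 (final 5 min).
#' @param normalize_to Optional period label; when given, columns
#'   `rr_pct`, `v_t_pct`, `v_e_pct` express each metric relative to that
#'   period (= 100).
#' @return A `data.frame` with one row per period: `period_label`,
#'   `n_breaths`, `rr_bpm`, `v_t_ml`, `v_e_ml_min` (and `_pct` columns if
#'   normalized). `v_t_ml` and `v_e_ml_min` are `NA` when the window
#'   holds no breaths (`rr_bpm` is 0).
#' @export
ventilation_summary <- function(breaths, periods, metric_window_s = 300,
                                normalize_to = NULL) {
  if (inherits(periods, "flow_trace")) periods <- periods$periods
  stopifnot(is.data.frame(periods))
  out <- data.frame(period_label = periods$label,
                    n_breaths = NA_integer_, rr_bpm = NA_real_,
                    v_t_ml = NA_real_, v_e_ml_min = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(periods))) {
    p0 <- periods$start_s[i]; p1 <- periods$end_s[i]
    w <- metric_window_s
    if (p1 - p0 < w) {
      message(sprintf("period '%s' (%.1f s) is shorter than the %g s window; using the entire period",
                      periods$label[i], p1 - p0, w))
      w <- p1 - p0
    }
    sel <- breaths$raw_onset_s >= p1 - w & breaths$raw_onset_s < p1
    n <- sum(sel)
    rr <- n / (w / 60)
    vt <- if (n > 0) mean(breaths$v_t_ml[sel]) else NA_real_
    out$n_breaths[i] <- n
    out$rr_bpm[i] <- rr
    out$v_t_ml[i] <- vt
    out$v_e_ml_min[i] <- if (n > 0) rr * vt else NA_real_
  }
  if (!is.null(normalize_to)) {
    b <- match(normalize_to, out$period_label)
    if (is.na(b)) stop("normalize_to period not found", call. = FALSE)
    out$rr_pct <- 100 * out$rr_bpm / out$rr_bpm[b]
    out$v_t_pct <- 100 * out$v_t_ml / out$v_t_ml[b]
    out$v_e_pct <- 100 * out$v_e_ml_min / out$v_e_ml_min[b]
  }
  out
}

#' Peri-event raster table
#'
#' One row per breath with onset times shifted so each subject's alignment
#' event (e.g. the rescue injection) is time zero - ready for plotting
#' cluster-colored raster ticks. Subjects without an alignment event are
#' skipped with a warning.
#'
#' @param breaths A `breath_set` with `subject_id` and `cluster_id`.
#' @param align_events Named numeric vector: subject id -> event time (s).
#' @return A `data.frame` with `subject_id`, `aligned_s`
#'   (`raw_onset_s - event`), `cluster_id`, ordered by subject then time.
#' @export
raster_export <- function(breaths, align_events) {
  subs <- unique(breaths$subject_id)
  missing <- setdiff(subs, names(align_events))
  if (length(missing) > 0)
    warning("no alignment event for subject(s): ",
            paste(missing, collapse = ", "), "; skipped", call. = FALSE)
  keep <- breaths$subject_id %in% names(align_events)
  b <- breaths[keep, , drop = FALSE]
  out <- data.frame(
    subject_id = b$subject_id,
    aligned_s = b$raw_onset_s - unname(align_events[b$subject_id]),
    cluster_id = b$cluster_id,
    stringsAsFactors = FALSE)
  out[order(out$subject_id, out$aligned_s), , drop = FALSE]
}
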