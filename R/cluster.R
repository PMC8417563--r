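#' Build the zero-padded waveform matrix for one duration domain
#'
#' All breaths of a domain are stacked into one matrix, each row
#' zero-padded at the tail to the length of the longest waveform in the
#' domain so the columns are commensurate for PCA. Row order follows
#' breath onset order across subjects.
#'
#' @param breaths A `breath_set`.
#' @param domain_id Domain to extract.
#' @return A list of class `domain_matrix` with `domain_id`, `mat`
#'   (n x L), `breath_rows` (row indices into `breaths`), `true_lengths`
#'   (unpadded sample counts), or `NULL` when the domain is empty.
#' @export
build_domain_matrix <- function(breaths, domain_id) {
  rows <- which(!is.na(breaths$domain_id) & breaths$domain_id == domain_id)
  if (length(rows) == 0) return(NULL)
  waves <- breaths$samples[rows]
  L <- max(lengths(waves))
  mat <- matrix(0, nrow = length(rows), ncol = L)
  for (i in seq_along(waves)) mat[i, seq_along(waves[[i]])] <- waves[[i]]
  structure(list(domain_id = domain_id, mat = mat, breath_rows = rows,
                 true_lengths = lengths(waves)),
            class = "domain_matrix")
}

#' Fit PCA on a domain matrix and retain components to a variance target
#'
#' Column-mean-centered, unscaled PCA (all columns share units of ml/s).
#' Components are retained in order until the cumulative explained
#' variance fraction strictly exceeds `variance_target`; `n_retained` is
#' minimal with that property. For reproducibility each eigenvector is
#' oriented so its largest-magnitude loading is positive. A matrix of
#' (numerically) identical rows has no variance to explain and returns a
#' single component with explained fraction defined as 1.
#'
#' @param mat Numeric matrix (>= 2 rows) or a `domain_matrix`.
#' @param variance_target Fraction in (0, 1), default 0.90.
#' @return List with `eigenvectors` (L x n_retained, orthonormal),
#'   `explained` (all per-component fractions, non-increasing),
#'   `n_retained`, `col_means`, and `scores` (n x n_retained retained-PC
#'   coordinates).
#' @export
fit_pca <- function(mat, variance_target = 0.90) {
  if (inherits(mat, "domain_matrix")) mat <- mat$mat
  if (nrow(mat) < 2) stop("PCA requires at least 2 rows", call. = FALSE)
  mu <- colMeans(mat)
  centered <- sweep(mat, 2, mu)
  tot <- sum(centered^2)
  if (tot < 1e-24) {
    ev <- matrix(0, ncol(mat), 1); ev[1, 1] <- 1
    return(list(eigenvectors = ev, explained = 1, n_retained = 1L,
                col_means = mu,
                scores = matrix(0, nrow(mat), 1)))
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  n_ret <- which(cumsum(expl) > variance_target)[1]
  if (is.na(n_ret)) n_ret <- length(expl)
  ev <- pc$rotation[, seq_len(n_ret), drop = FALSE]
  # deterministic sign: largest |loading| positive
  for (j in seq_len(ncol(ev))) {
    i <- which.max(abs(ev[, j]))
    if (ev[i, j] < 0) ev[, j] <- -ev[, j]
  }
  list(eigenvectors = ev, explained = expl, n_retained = as.integer(n_ret),
       col_means = mu, scores = centered %*% ev)
}

#' Ward agglomerative linkage on retained PC coordinates
#'
#' Bottom-up clustering: every waveform starts as its own cluster and the
#' pair whose merger least increases the within-cluster sum of squares
#' (inner squared Euclidean distance, Ward's criterion) is joined at each
#' step. Merge heights are the standard `sqrt(2 * delta-ESS)` Ward
#' distances and are non-decreasing.
#'
#' @param scores Numeric matrix of per-breath retained-PC coordinates
#'   (>= 2 rows).
#' @return An `hclust` object (method `ward.D2`).
#' @export
build_linkage <- function(scores) {
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 1)
  if (nrow(scores) < 2) stop("linkage requires at least 2 rows",
                             call. = FALSE)
  stats::hclust(stats::dist(scores), method = "ward.D2")
}

#' Merge-height curve d(k) of a linkage tree
#'
#' `d(k)` is the height of the merge that produces `k` clusters (the step
#' from `k + 1` to `k`); it is non-increasing in `k` and large only while
#' genuinely distinct groups are being joined.
#'
#' @param linkage An `hclust` tree.
#' @param k_max Largest cluster count of interest; capped at `n - 1`.
#' @return Numeric vector `d` with `d[k]` for `k = 1..k_max`.
#' @export
merge_height_curve <- function(linkage, k_max = 30) {
  n <- length(linkage$height) + 1
  k_max <- min(k_max, n - 1)
  linkage$height[n - seq_len(k_max)]
}

#' Choose the cluster count by the elbow of the merge-height curve
#'
#' Plots (conceptually) the merge height `d(k)` against the cluster count
#' `k` and returns the `k` with maximal vertical deviation below the
#' straight chord joining `(1, d(1))` and `(k_max, d(k_max))` - the point
#' where adding clusters stops substantially reducing between-cluster
#' distance. Ties (including a perfectly flat curve) resolve toward the
#' smallest `k`, so degenerate one-group data yields `k = 1`.
#'
#' @param linkage An `hclust` tree with at least `k_max` leaves (fewer
#'   leaves simply cap the scan).
#' @param k_max Scan limit (default 30).
#' @return Integer cluster count.
#' @export
choose_k <- function(linkage, k_max = 30) {
  d <- merge_height_curve(linkage, k_max)
  k_max <- length(d)
  if (k_max == 1) return(1L)
  # numerically degenerate tree: every merge height is at rounding scale,
  # so the leaves are one group of (effectively) identical points
  if (d[1] <= 1e-8) return(1L)
  chord <- d[1] + (d[k_max] - d[1]) * (seq_len(k_max) - 1) / (k_max - 1)
  deviation <- chord - d
  as.integer(which.max(deviation))
}

#' Cut a linkage tree into k clusters with global numbering
#'
#' @param linkage An `hclust` tree.
#' @param k Cluster count (from [choose_k()] or a user override).
#' @param global_offset Starting global cluster number for this domain;
#'   domains are numbered consecutively in duration order so ids are
#'   unique across the whole model.
#' @return Integer vector of global cluster ids, one per leaf, in
#'   `[global_offset, global_offset + k - 1]`.
#' @export
assign_clusters <- function(linkage, k, global_offset = 1L) {
  n <- length(linkage$height) + 1
  if (k > n) stop("k exceeds the number of leaves", call. = FALSE)
  as.integer(stats::cutree(linkage, k = k) + global_offset - 1L)
}

#' Per-cluster mean waveforms and display lengths
#'
#' The centroid is the per-sample mean of the member rows (zero-padded
#' space). The display length reported for plotting is the mean plus one
#' sample standard deviation (n - 1 denominator; 0 for singletons) of the
#' members' true (unpadded) lengths.
#'
#' @param mat n x L waveform matrix (padded).
#' @param labels Cluster label per row.
#' @param true_lengths Unpadded sample count per row (defaults to L).
#' @return List with `waveforms` (k x L matrix, rownames = cluster ids,
#'   in increasing id order) and `display_length` (samples).
#' @export
compute_centroids <- function(mat, labels, true_lengths = NULL) {
  if (is.null(true_lengths)) true_lengths <- rep(ncol(mat), nrow(mat))
  ids <- sort(unique(labels))
  waveforms <- matrix(0, length(ids), ncol(mat),
                      dimnames = list(ids, NULL))
  display <- numeric(length(ids))
  for (i in seq_along(ids)) {
    sel <- labels == ids[i]
    waveforms[i, ] <- colMeans(mat[sel, , drop = FALSE])
    len <- true_lengths[sel]
    display[i] <- mean(len) + if (length(len) > 1) stats::sd(len) else 0
  }
  list(waveforms = waveforms, display_length = display)
}

#' Fit the full per-domain waveform cluster model
#'
#' For every duration domain with at least two member breaths: build the
#' zero-padded matrix, run PCA to the variance target, construct the Ward
#' tree on the retained PC scores, choose the cluster count by the elbow
#' rule (unless overridden), cut the tree, and compute centroids. Global
#' cluster numbers are consecutive across domains in duration order
#' (domain 1 starts at 1). Domains above `linkage_cap` waveforms are
#' fitted on a seeded uniform subsample and the remaining breaths assigned
#' by nearest centroid.
#'
#' @param breaths A `breath_set` with domains assigned.
#' @param cfg A [run_config()] (supplies `variance_target`,
#'   `max_clusters_scan`, `domain_edges_s`, `linkage_cap`, `rng_seed`).
#' @param k_override Optional named list/vector mapping domain id to a
#'   fixed cluster count.
#' @return A `cluster_model`: per-domain fits plus `assignments`, the
#'   global cluster id per input breath row (`NA` for out-of-range breaths
#'   and skipped domains).
#' @export
fit_waveform_clusters <- function(breaths, cfg = run_config(),
                                  k_override = NULL) {
  n_domains <- length(cfg$domain_edges_s) - 1
  domains <- list()
  assignments <- rep(NA_integer_, nrow(breaths))
  offset <- 1L
  for (d in seq_len(n_domains)) {
    dm <- build_domain_matrix(breaths, d)
    if (is.null(dm) || nrow(dm$mat) < 2) next
    fit <- fit_domain(dm, cfg, k_override_for(k_override, d), offset)
    assignments[dm$breath_rows] <- fit$labels
    fit$domain <- c(fit$domain, list(domain_id = d, n = nrow(dm$mat),
                                     global_offset = offset))
    domains[[length(domains) + 1]] <- fit$domain
    offset <- offset + fit$domain$k
  }
  structure(list(rate = attr(breaths, "rate"),
                 variance_target = cfg$variance_target,
                 domain_edges_s = cfg$domain_edges_s,
                 domains = domains,
                 assignments = assignments),
            class = "cluster_model")
}

k_override_for <- function(k_override, d) {
  if (is.null(k_override)) return(NULL)
  v <- k_override[[as.character(d)]]
  if (is.null(v) || is.na(v)) NULL else as.integer(v)
}

fit_domain <- function(dm, cfg, k_fixed, offset) {
  mat <- dm$mat
  n <- nrow(mat)
  sub <- seq_len(n)
  if (n > cfg$linkage_cap) {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(cfg$rng_seed)
    sub <- sort(sample.int(n, cfg$linkage_cap))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  pca <- fit_pca(mat[sub, , drop = FALSE], cfg$variance_target)
  hc <- build_linkage(pca$scores)
  k <- if (is.null(k_fixed)) choose_k(hc, cfg$max_clusters_scan)
       else k_fixed
  labels_sub <- assign_clusters(hc, k, offset)
  cen <- compute_centroids(mat[sub, , drop = FALSE], labels_sub,
                           dm$true_lengths[sub])
  ids <- as.integer(rownames(cen$waveforms))
  centroids_pc <- sweep(cen$waveforms, 2, pca$col_means) %*%
    pca$eigenvectors
  labels <- rep(NA_integer_, n)
  labels[sub] <- labels_sub
  if (length(sub) < n) {
    rest <- setdiff(seq_len(n), sub)
    sc <- sweep(mat[rest, , drop = FALSE], 2, pca$col_means) %*%
      pca$eigenvectors
    nn <- nearest_row(sc, centroids_pc)
    labels[rest] <- ids[nn]
  }
  list(labels = labels,
       domain = list(row_length = ncol(mat),
                     col_means = pca$col_means,
                     eigenvectors = pca$eigenvectors,
                     explained = pca$explained,
                     n_retained = pca$n_retained,
                     merge = hc$merge,
                     height = hc$height,
                     k = as.integer(k),
                     scan_d = merge_height_curve(hc, cfg$max_clusters_scan),
                     cluster_ids = ids,
                     centroids_wave = cen$waveforms,
                     centroids_pc = centroids_pc,
                     display_length = cen$display_length))
}

nearest_row <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") -
    2 * x %*% t(centers)
  max.col(-d2, ties.method = "first")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: %d fitted domain(s), analysis rate %g S/s\n",
              length(x$domains), x$rate))
  for (d in x$domains) {
    cat(sprintf(
      "  domain %d: n = %d, %d PCs (>%.0f%% var), k = %d, clusters %d-%d\n",
      d$domain_id, d$n, d$n_retained, 100 * x$variance_target, d$k,
      d$global_offset, d$global_offset + d$k - 1))
  }
  invisible(x)
}

#' Classify new breaths against a fitted cluster model
#'
#' Each breath is binned to its duration domain, padded (or truncated,
#' with a warning) to the model's row length for that domain, centered
#' with the model's column means, projected onto the retained
#' eigenvectors, and assigned the global id of the nearest centroid in PC
#' space. This lets a training set from prior experiments serve as a fixed
#' framework of established clusters for new recordings.
#'
#' @param breaths A `breath_set`.
#' @param model A fitted `cluster_model`.
#' @return Integer vector of global cluster ids (`NA` for out-of-range
#'   breaths or domains absent from the model).
#' @export
classify_new <- function(breaths, model) {
  out <- rep(NA_integer_, nrow(breaths))
  dom_ids <- vapply(model$domains, function(d) d$domain_id, integer(1))
  dom <- assign_domain(breaths$t_tot_s, model$domain_edges_s)
  truncated <- 0L
  for (j in seq_along(model$domains)) {
    md <- model$domains[[j]]
    rows <- which(!is.na(dom) & dom == md$domain_id)
    if (length(rows) == 0) next
    L <- md$row_length
    mat <- matrix(0, length(rows), L)
    for (i in seq_along(rows)) {
      w <- breaths$samples[[rows[i]]]
      if (length(w) > L) { truncated <- truncated + 1L; w <- w[seq_len(L)] }
      mat[i, seq_along(w)] <- w
    }
    sc <- sweep(mat, 2, md$col_means) %*% md$eigenvectors
    ids <- if (!is.null(md$cluster_ids)) as.integer(md$cluster_ids)
           else as.integer(rownames(md$centroids_wave))
    out[rows] <- ids[nearest_row(sc, md$centroids_pc)]
  }
  if (truncated > 0)
    warning(truncated, " waveform(s) longer than the model row length ",
            "were truncated", call. = FALSE)
  out
}
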