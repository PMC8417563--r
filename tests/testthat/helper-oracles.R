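# Independent reference implementations used to cross-check the package.

# Brute-force per-sample state machine for threshold/zero-crossing breath
# onset detection. Walks every sample: a crossing fires when the flow
# reaches the threshold while "armed"; arming requires a non-positive
# sample since the last firing; the onset is placed at the last
# non-positive sample seen (trace start if none).
detect_onsets_oracle <- function(samples, rate, threshold) {
  armed <- TRUE
  last_nonpos <- 0L
  onsets <- integer(0)
  for (i in seq_along(samples)) {
    if (samples[i] <= 0) {
      armed <- TRUE
      last_nonpos <- i
    } else if (armed && samples[i] >= threshold) {
      onsets <- c(onsets, max(last_nonpos, 1L))
      armed <- FALSE
    }
  }
  (unique(onsets) - 1) / rate
}

# O(n^3) Ward agglomeration: at every step recompute all pairwise Ward
# distances sqrt(2 * ni * nj / (ni + nj)) * ||ci - cj|| from scratch and
# merge the minimum. Returns heights and the partition after each merge.
ward_oracle <- function(X) {
  n <- nrow(X)
  members <- as.list(seq_len(n))
  centers <- lapply(seq_len(n), function(i) X[i, ])
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(n - 1)
  parts <- vector("list", n - 1)
  for (m in seq_len(n - 1)) {
    best <- c(NA, NA); bd <- Inf
    for (a in seq_along(active)) {
      for (b in seq_len(a - 1)) {
        i <- active[a]; j <- active[b]
        d <- sqrt(2 * sizes[i] * sizes[j] / (sizes[i] + sizes[j])) *
          sqrt(sum((centers[[i]] - centers[[j]])^2))
        if (d < bd) { bd <- d; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    k <- length(sizes) + 1
    centers[[k]] <- (sizes[i] * centers[[i]] + sizes[j] * centers[[j]]) /
      (sizes[i] + sizes[j])
    sizes[k] <- sizes[i] + sizes[j]
    members[[k]] <- c(members[[i]], members[[j]])
    active <- c(setdiff(active, c(i, j)), k)
    heights[m] <- bd
    parts[[m]] <- lapply(active, function(x) sort(members[[x]]))
  }
  list(heights = heights, parts = parts)
}

# canonical string form of a partition (list of index vectors)
partition_key <- function(part) {
  sort(vapply(part, function(p) paste(p, collapse = ","), character(1)))
}

hclust_partition <- function(hc, k) {
  ct <- stats::cutree(hc, k)
  unname(lapply(split(seq_along(ct), ct), sort))
}

# random band-limited-ish flow-like trace for detector fuzzing: a few
# sinusoids plus noise, amplitude spanning the detection threshold
random_trace <- function(n = 400, rate = 90) {
  t <- (seq_len(n) - 1) / rate
  f <- runif(3, 0.3, 6)
  a <- runif(3, 0.1, 1.5)
  ph <- runif(3, 0, 2 * pi)
  x <- a[1] * sin(2 * pi * f[1] * t + ph[1]) +
    a[2] * sin(2 * pi * f[2] * t + ph[2]) +
    a[3] * sin(2 * pi * f[3] * t + ph[3]) +
    rnorm(n, 0, 0.2)
  flow_trace(x, rate = rate)
}

# nearest-truth matching: index of the closest true onset per detection
match_truth <- function(detected, truth_onsets) {
  vapply(detected, function(t) which.min(abs(truth_onsets - t)),
         integer(1))
}

# simple ARI fallback-free wrapper (mclust is available in the test env)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
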