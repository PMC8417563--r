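test_that("domain matrices are zero-padded to the longest waveform", {
  w1 <- rnorm(18) + 2
  w2 <- rnorm(27) + 2
  b <- fake_breath_set(list(rbind(c(w1, rep(0, 9)), w2)), domains = 2)
  b$samples <- list(w1, w2)   # true, unpadded lengths
  b$n_samples <- c(18L, 27L)
  dm <- build_domain_matrix(b, 2)
  expect_equal(dim(dm$mat), c(2, 27))
  expect_equal(dm$mat[1, 19:27], rep(0, 9))
  expect_equal(dm$mat[1, 1:18], w1)
  # un-padding recovers the waveform when its last sample is nonzero
  expect_equal(dm$mat[2, ], w2)

  # single waveform: 1 x L identity
  b1 <- b[1, ]
  dm1 <- build_domain_matrix(b1, 2)
  expect_equal(as.numeric(dm1$mat), w1)
  # empty domain
  expect_null(build_domain_matrix(b, 4))
})

test_that("PCA retains the minimal component set exceeding the variance target", {
  set.seed(3)
  # rank-1 structure: one shape under random scaling
  shape <- sin(seq(0, pi, length.out = 30))
  m <- outer(runif(40, 0.5, 2), shape) + matrix(rnorm(1200, 0, 1e-8),
                                                40)
  fit <- fit_pca(m, 0.9)
  expect_equal(fit$n_retained, 1L)

  # isotropic 5-dim Gaussian: every component explains ~ 0.2
  m5 <- matrix(rnorm(5 * 2000), ncol = 5)
  fit5 <- fit_pca(m5, 0.9)
  expect_equal(fit5$n_retained, 5L)
  expect_true(all(diff(fit5$explained) <= 1e-12))

  # retained reconstruction captures > 90% of total variance; minimality
  bm <- generate_cluster_benchmark(3, 6, 40, seed = 8)
  f <- fit_pca(bm$mat, 0.9)
  expect_gt(sum(f$explained[seq_len(f$n_retained)]), 0.9)
  if (f$n_retained > 1)
    expect_lte(sum(f$explained[seq_len(f$n_retained - 1)]), 0.9)
  # orthonormal eigenvectors
  g <- crossprod(f$eigenvectors)
  expect_lt(max(abs(g - diag(ncol(g)))), 1e-8)
  # deterministic sign: largest loading positive
  for (j in seq_len(ncol(f$eigenvectors)))
    expect_gt(f$eigenvectors[which.max(abs(f$eigenvectors[, j])), j], 0)

  # all-identical rows
  same <- matrix(1, 5, 10)
  fs <- fit_pca(same, 0.9)
  expect_equal(fs$n_retained, 1L)
  expect_equal(fs$explained, 1)
})

test_that("Ward linkage joins nearest groups and matches the O(n^3) oracle", {
  # three points: the near pair merges first
  X <- rbind(c(0, 0), c(0, 1), c(10, 0))
  hc <- build_linkage(X)
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))

  set.seed(12)
  for (rep in 1:10) {
    n <- sample(5:10, 1)
    Y <- matrix(rnorm(n * 3), n, 3)
    hc <- build_linkage(Y)
    orc <- ward_oracle(Y)
    expect_equal(sort(hc$height), sort(orc$heights), tolerance = 1e-10)
    for (k in seq_len(n - 1))
      expect_identical(partition_key(hclust_partition(hc, k)),
                       partition_key(orc$parts[[n - k]]))
  }

  # permuting rows leaves every partition unchanged (up to labels)
  bm <- generate_cluster_benchmark(3, 6, 15, seed = 2)
  hc1 <- build_linkage(fit_pca(bm$mat, 0.9)$scores)
  perm <- sample(nrow(bm$mat))
  hc2 <- build_linkage(fit_pca(bm$mat[perm, ], 0.9)$scores)
  for (k in c(2, 3, 5)) {
    p1 <- stats::cutree(hc1, k)
    p2 <- stats::cutree(hc2, k)[order(perm)]
    expect_equal(ari(p1, p2), 1)
  }
})

test_that("the elbow rule recovers well-separated blob counts and flat curves give k = 1", {
  for (k_true in c(2, 3)) {
    bm <- generate_cluster_benchmark(k_true, 10, 30, seed = 40 + k_true)
    hc <- build_linkage(fit_pca(bm$mat, 0.9)$scores)
    expect_equal(choose_k(hc, 30), k_true)
  }
  # all points identical up to 1e-12 noise: flat curve -> 1
  set.seed(5)
  flat <- matrix(1, 40, 10) + matrix(rnorm(400, 0, 1e-12), 40)
  expect_equal(choose_k(build_linkage(flat), 30), 1L)
})

test_that("cluster assignment is exact on separated blobs and numbers globally", {
  bm <- generate_cluster_benchmark(3, 10, 30, seed = 9)
  pca <- fit_pca(bm$mat, 0.9)
  hc <- build_linkage(pca$scores)
  expect_error(assign_clusters(hc, 1000), "leaves")
  expect_equal(length(unique(assign_clusters(hc, 1))), 1)
  lab <- assign_clusters(hc, 3, global_offset = 5)
  expect_true(all(lab %in% 5:7))
  expect_equal(ari(lab, bm$labels), 1)

  # consecutive global numbering across domains, e.g. counts 4/4/7/6
  offsets <- cumsum(c(1, c(4, 4, 7, 6)))
  expect_equal(offsets[1:4], c(1, 5, 9, 16))
  # and in a fitted two-domain model
  b <- fake_breath_set(list(generate_cluster_benchmark(2, 10, 20,
                                                       seed = 1)$mat,
                            generate_cluster_benchmark(3, 10, 20,
                                                       seed = 2)$mat),
                       domains = c(2, 3))
  m <- fit_waveform_clusters(b, run_config())
  offs <- vapply(m$domains, function(d) d$global_offset, integer(1))
  ks <- vapply(m$domains, function(d) d$k, integer(1))
  expect_equal(offs, cumsum(c(1L, ks[-length(ks)])))
  got <- sort(unique(m$assignments))
  expect_equal(got, seq_len(sum(ks)))
})

test_that("centroids are member means with mean + 1 SD display length", {
  w <- sin(seq(0, pi, length.out = 20))
  mat <- rbind(w, w, w)
  cen <- compute_centroids(mat, c(1, 1, 1), c(20, 20, 20))
  expect_equal(as.numeric(cen$waveforms[1, ]), w)
  expect_equal(cen$display_length, 20)

  # sample SD (n - 1): lengths 50 and 70 -> 60 + 14.14
  cen2 <- compute_centroids(rbind(w, w), c(1, 1), c(50, 70))
  expect_equal(cen2$display_length, 60 + stats::sd(c(50, 70)))

  # singleton cluster: centroid is the member, SD is 0
  cen3 <- compute_centroids(rbind(w, 2 * w), c(1, 2), c(20, 18))
  expect_equal(as.numeric(cen3$waveforms[2, ]), 2 * w)
  expect_equal(cen3$display_length[2], 18)
})

test_that("amplitude scaling of all waveforms leaves partitions unchanged", {
  bm <- generate_cluster_benchmark(3, 6, 25, seed = 13)
  m1 <- fit_waveform_clusters(fake_breath_set(list(bm$mat), 2),
                              run_config())
  m2 <- fit_waveform_clusters(fake_breath_set(list(3.7 * bm$mat), 2),
                              run_config())
  expect_equal(ari(m1$assignments, m2$assignments), 1)
})

test_that("nearest-centroid classification reproduces training structure", {
  bm <- generate_cluster_benchmark(3, 8, 30, seed = 17)
  b <- fake_breath_set(list(bm$mat), domains = 2)
  model <- fit_waveform_clusters(b, run_config())

  # centroids classify to themselves
  dom <- model$domains[[1]]
  cb <- fake_breath_set(list(dom$centroids_wave), domains = 2)
  expect_equal(classify_new(cb, model), as.integer(dom$cluster_ids))

  # training breaths agree with their training assignment
  agree <- mean(classify_new(b, model) == model$assignments)
  expect_gte(agree, 0.9)

  # an all-zero breath gets a determinate cluster
  zb <- fake_breath_set(list(matrix(0, 1, ncol(bm$mat))), domains = 2)
  expect_false(is.na(classify_new(zb, model)))

  # longer-than-model waveforms are truncated with a warning
  long <- fake_breath_set(list(matrix(rnorm(ncol(bm$mat) + 10), 1)),
                          domains = 2)
  expect_warning(classify_new(long, model), "truncated")
})

test_that("clusters generalize across subjects sharing generator parameters", {
  cfg <- run_config()
  all_b <- NULL
  for (s in 1:4) {
    sim <- generate_trace(multi_behavior_schedule(120), seed = 100 + s,
                          subject_id = paste0("rat", s))
    pre <- preprocess_trace(sim$trace, cfg)
    b <- segment_breaths(pre, detect_onsets(pre), cfg)
    all_b <- if (is.null(all_b)) b else rbind_breaths(all_b, b)
  }
  m <- fit_waveform_clusters(all_b, cfg)
  all_b$cluster_id <- m$assignments
  by_cluster <- split(all_b$subject_id, all_b$cluster_id)
  n_subjects <- vapply(by_cluster, function(s) length(unique(s)),
                       integer(1))
  sizes <- lengths(by_cluster)
  # every recurrent cluster (>= 3 breaths) spans several subjects;
  # singleton outlier clusters are excluded from the claim
  expect_true(all(n_subjects[sizes >= 3] >= 2))
  expect_gte(sum(sizes[n_subjects >= 2]) / sum(sizes), 0.95)
})
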