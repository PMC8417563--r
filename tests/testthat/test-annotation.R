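test_that("common tidal clusters are those above mean baseline prevalence", {
  # 100 baseline breaths over 11 tidal clusters with prevalences
  # .30 .20 .15 .10 .05 .05 .05 .04 .03 .02 .01 -> mean 1/11 ~ .0909
  counts <- c(30, 20, 15, 10, 5, 5, 5, 4, 3, 2, 1)
  b <- labeled_breaths(rep(1:11, counts))
  ct <- derive_common_tidal(b, 1:11)
  expect_equal(ct$common, 1:4)
  expect_equal(ct$uncommon, 5:11)
  expect_equal(sort(c(ct$common, ct$uncommon)), 1:11)
  expect_equal(unname(ct$prevalence), counts / 100)

  # uniform prevalences: nothing is strictly above the mean
  bu <- labeled_breaths(rep(1:5, each = 10))
  expect_length(derive_common_tidal(bu, 1:5)$common, 0)

  # no baseline breaths -> configuration error
  bd <- labeled_breaths(rep(1:3, 5), period = "drug")
  expect_error(derive_common_tidal(bd, 1:3), "baseline")
})

test_that("20-breath windows take the strict cluster-majority label", {
  cats <- list(sniffing = 1:3, common_tidal = 5:6, augmented = 19)

  # 12/20 sniffing = 60% > 51% -> sniffing
  cl <- c(rep(1, 12), rep(5, 8))
  tr <- annotate_windows(labeled_breaths(cl), cats)
  expect_equal(tr$label, "sniffing")
  expect_equal(tr$majority_fraction, 0.6)

  # 10/20 everywhere: no strict majority -> unannotated
  cl2 <- c(rep(1, 10), rep(5, 10))
  expect_equal(annotate_windows(labeled_breaths(cl2), cats)$label,
               "unannotated")

  # 11/20 = 55% is the smallest annotatable count at the 51% default
  cl3 <- c(rep(19, 11), rep(1, 5), rep(5, 4))
  expect_equal(annotate_windows(labeled_breaths(cl3), cats)$label,
               "augmented")

  # a full window of one category reaches fraction 1.0
  tr4 <- annotate_windows(labeled_breaths(rep(19, 20)), cats)
  expect_equal(tr4$label, "augmented")
  expect_equal(tr4$majority_fraction, 1.0)

  # trailing partial block stays unannotated; coverage is exact
  cl5 <- c(rep(1, 40), rep(5, 7))
  tr5 <- annotate_windows(labeled_breaths(cl5), cats)
  expect_equal(nrow(tr5), 3)
  expect_equal(tr5$label, c("sniffing", "sniffing", "unannotated"))
  expect_equal(sum(tr5$n_breaths), 47)

  # overlapping category sets are rejected
  expect_error(annotate_windows(labeled_breaths(cl),
                                list(a = 1:3, b = 3:5)), "disjoint")
})

test_that("prevalence tables are row-normalized proportions", {
  b <- labeled_breaths(c(1, 1, 2, 2))
  p <- prevalence_table(b)
  expect_equal(as.numeric(p), c(0.5, 0.5))

  # adding a new cluster renormalizes, rows still sum to 1
  b2 <- labeled_breaths(c(1, 1, 2, 2, 7))
  p2 <- prevalence_table(b2)
  expect_equal(sum(p2), 1)
  expect_equal(p2[1, "7"], 0.2)

  # unassigned breaths get the reserved column
  b3 <- labeled_breaths(c(1, NA, 2, NA))
  p3 <- prevalence_table(b3)
  expect_equal(p3[1, "unassigned"], 0.5)
  expect_equal(sum(p3), 1)

  # recomputing from the exported CSV matches the in-memory table
  b4 <- labeled_breaths(sample(c(1:4, NA), 60, replace = TRUE),
                        period = sample(c("baseline", "drug"), 60,
                                        replace = TRUE))
  f <- withr::local_tempfile(fileext = ".csv")
  write_breath_table(b4, f)
  back <- read_breath_table(f)
  class(back) <- c("breath_set", "data.frame")
  expect_equal(unclass(prevalence_table(back)),
               unclass(prevalence_table(b4[order(b4$onset_s), ])),
               ignore_attr = TRUE)
})

test_that("ventilation metrics: RR from counts, V_E = RR x V_T, baseline at 100%", {
  # 500 breaths with onsets inside a 300 s window -> 100 breaths/min
  n <- 500
  b <- labeled_breaths(rep(1, n), t_tot = 0.55)  # spans 0..274.45 s
  b$v_t_ml <- rep(2, n)
  periods <- data.frame(label = c("baseline", "drug"),
                        start_s = c(0, 300), end_s = c(300, 600))
  vs <- ventilation_summary(b, periods, 300)
  expect_equal(vs$rr_bpm[1], 100)
  expect_equal(vs$v_t_ml[1], 2)
  expect_equal(vs$v_e_ml_min[1], 200)
  expect_equal(vs$v_e_ml_min, vs$rr_bpm * vs$v_t_ml, tolerance = 1e-9)

  vsn <- ventilation_summary(b, periods[1, , drop = FALSE], 300,
                             normalize_to = "baseline")
  expect_equal(vsn$rr_pct, 100)
  expect_equal(vsn$v_t_pct, 100)
  expect_equal(vsn$v_e_pct, 100)

  # a period shorter than the window is used in full, with a message
  short <- data.frame(label = "rescue", start_s = 0, end_s = 120)
  expect_message(vshort <- ventilation_summary(b, short, 300),
                 "entire period")
  expect_equal(vshort$rr_bpm,
               sum(b$raw_onset_s < 120) / 2)
})

test_that("raster export aligns onsets to per-subject events", {
  b <- labeled_breaths(rep(1, 6), t_tot = 10,
                       subject_id = rep(c("a", "b", "c"), each = 2))
  ev <- c(a = 600, b = 5)
  expect_warning(r <- raster_export(b, ev), "c")
  expect_equal(nrow(r), 4)              # subject c skipped
  # event at 600 s, onset at 590 s -> aligned -10 s  (synthetic check)
  b2 <- labeled_breaths(1, subject_id = "a")
  b2$raw_onset_s <- 590
  expect_equal(raster_export(b2, c(a = 600))$aligned_s, -10)
  # per-subject onset order is preserved under the time shift
  for (s in unique(r$subject_id))
    expect_false(is.unsorted(r$aligned_s[r$subject_id == s]))
})
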