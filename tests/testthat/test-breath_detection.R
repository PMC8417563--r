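half_sine_pulse <- function(at_s, dur_s, peak, n, rate) {
  x <- numeric(n)
  idx <- round(at_s * rate):round((at_s + dur_s) * rate)
  idx <- idx[idx >= 0 & idx < n]
  x[idx + 1] <- peak * sin(pi * (idx / rate - at_s) / dur_s)
  x
}

test_that("onsets fire at threshold crossings moved to the previous zero-crossing", {
  rate <- 90

  # sub-threshold noise never fires
  set.seed(1)
  noise <- flow_trace(pmin(pmax(rnorm(900, 0, 0.1), -0.25), 0.25), rate)
  expect_length(detect_onsets(noise, 0.3), 0)

  # single pulse rising from zero at t = 1.0 s
  x <- half_sine_pulse(1.0, 0.4, 1.0, 450, rate)
  on <- detect_onsets(flow_trace(x, rate), 0.3)
  expect_length(on, 1)
  expect_lt(abs(on - 1.0), 1 / rate + 1e-9)

  # two pulses with a sub-zero dip between them
  x2 <- half_sine_pulse(1.0, 0.4, 1.0, 450, rate) +
    half_sine_pulse(2.0, 0.4, 1.0, 450, rate)
  x2[round(1.6 * rate):round(1.8 * rate)] <- -0.2
  on2 <- detect_onsets(flow_trace(x2, rate), 0.3)
  expect_length(on2, 2)
  expect_lt(max(abs(on2 - c(1.0, 2.0))), 2 / rate + 1e-9)

  # all-zero trace: empty result, not an error
  expect_length(detect_onsets(flow_trace(rep(0, 100), rate)), 0)

  # flutter around the threshold without a sub-zero dip collapses
  x3 <- c(rep(0, 10), rep(c(0.5, 0.2), 20), rep(0, 10))
  expect_length(detect_onsets(flow_trace(x3, rate), 0.3), 1)
})

test_that("detector matches the per-sample state machine and is monotone in threshold", {
  set.seed(7)
  for (rep in 1:50) {
    tr <- random_trace(n = sample(200:600, 1))
    got <- detect_onsets(tr, 0.3)
    ref <- detect_onsets_oracle(tr$samples, tr$rate, 0.3)
    expect_equal(got, ref)
  }
  # raising the threshold never yields more onsets
  for (rep in 1:20) {
    tr <- random_trace()
    counts <- vapply(c(0.1, 0.3, 0.6, 1.0, 1.5),
                     function(th) length(detect_onsets(tr, th)),
                     numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("breath windows are back-shifted 20% capped at 100 ms and clipped at 0", {
  rate <- 100
  cfg <- run_config(target_rate = rate)
  mk <- function(onsets, n = 400) {
    x <- numeric(n)
    for (o in onsets) x <- x + half_sine_pulse(o, 0.15, 1.0, n, rate)
    flow_trace(x, rate)
  }
  # t_tot 0.4 s -> shift 80 ms
  b <- segment_breaths(mk(c(1.0, 1.4)), c(1.0, 1.4), cfg)
  expect_equal(nrow(b), 1)
  expect_equal(b$onset_s, 0.92, tolerance = 1 / rate)
  expect_equal(b$t_tot_s, 0.4)

  # t_tot 1.2 s -> shift capped at 100 ms
  b2 <- segment_breaths(mk(c(1.0, 2.2)), c(1.0, 2.2), cfg)
  expect_equal(b2$onset_s, 0.9, tolerance = 1 / rate)

  # first onset near the trace start clips at 0
  b3 <- segment_breaths(mk(c(0.05, 1.0)), c(0.05, 1.0), cfg)
  expect_equal(b3$onset_s, 0.0)

  # the final onset yields no breath; < 2 onsets yield none
  expect_equal(nrow(segment_breaths(mk(1.0), 1.0, cfg)), 0)
})

test_that("breaths tile the record onset-to-onset", {
  sim <- generate_trace(multi_behavior_schedule(90), seed = 21)
  cfg <- run_config()
  pre <- preprocess_trace(sim$trace, cfg)
  on <- detect_onsets(pre)
  b <- segment_breaths(pre, on, cfg)
  expect_equal(nrow(b), length(on) - 1)
  # consecutive raw onsets are exactly one t_tot apart
  expect_equal(b$raw_onset_s[-1], b$raw_onset_s[-nrow(b)] +
                 b$t_tot_s[-nrow(b)])
  expect_equal(sum(b$t_tot_s), max(on) - min(on), tolerance = 1e-9)
  # every breath has one domain or the out-of-range flag
  expect_equal(sum(!is.na(b$domain_id)) + sum(is.na(b$domain_id)),
               nrow(b))
})

test_that("duration domains are half-open lower-closed bins", {
  edges <- c(0, 0.2, 0.5, 1.2, 4)
  expect_equal(assign_domain(0.15, edges), 1L)   # sniffing: below 0.2 s
  expect_equal(assign_domain(0.2, edges), 2L)    # boundary goes up
  expect_equal(assign_domain(c(0.49999, 0.5, 1.19, 1.2, 3.999), edges),
               c(2L, 3L, 3L, 4L, 4L))
  expect_true(is.na(assign_domain(5.0, edges)))  # out-of-range flag
  expect_true(is.na(assign_domain(4.0, edges)))
  # exhaustive scan: findInterval semantics against a manual loop
  durs <- seq(0.01, 5, by = 0.01)
  manual <- vapply(durs, function(d) {
    for (k in 1:4) if (d >= edges[k] && d < edges[k + 1]) return(k)
    NA_integer_
  }, integer(1))
  expect_equal(assign_domain(durs, edges), manual)
})

test_that("tidal volume is the running-integral maximum of flow", {
  rate <- 500
  t <- (0:(rate - 1)) / rate
  # half-sine inspiration peaking at pi over 1 s integrates to 2 ml
  insp <- pi * sin(pi * t)
  expect_equal(integrate_tidal_volume(c(insp, rep(0, 100)), rate), 2,
               tolerance = 0.01)
  # pure expiration -> V_T = 0
  expect_equal(integrate_tidal_volume(-abs(rnorm(200)), rate), 0)
  # linearity
  v1 <- integrate_tidal_volume(insp, rate)
  expect_equal(integrate_tidal_volume(2 * insp, rate), 2 * v1)
})
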