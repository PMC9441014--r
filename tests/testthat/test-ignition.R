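test_that("phase_lock_value implements the exponential phase-distance kernel", {
  expect_equal(phase_lock_value(1.3, 1.3), 1)
  expect_equal(phase_lock_value(0, pi), exp(-3 * pi))       # ~8.07e-5
  # wrapped distance: 3.0 vs -3.0 differ by 2*pi - 6 ~ 0.2832
  expect_equal(phase_lock_value(3, -3), exp(-3 * (2 * pi - 6)),
               tolerance = 1e-12)
  expect_equal(phase_lock_value(3, -3), 0.4276, tolerance = 1e-4)
  # vectorised, always in (0, 1]
  set.seed(1)
  v <- phase_lock_value(runif(100, -pi, pi), runif(100, -pi, pi))
  expect_true(all(v > 0 & v <= 1))
})

test_that("instantaneous_phases track the frequency of an in-band sinusoid", {
  tr <- 2; f0 <- 0.05
  t <- seq(0, by = tr, length.out = 400)
  ts <- parcellated_ts(cbind(sin(2 * pi * f0 * t), cos(2 * pi * f0 * t)), tr)
  ph <- instantaneous_phases(ts, band = c(0.04, 0.07))
  expect_equal(dim(ph$phases), dim(ts$values))
  expect_true(all(ph$phases > -pi & ph$phases <= pi + 1e-12))
  inner <- 60:340
  slope <- mean(diff(unwrap_for_test(ph$phases[inner, 1]))) / tr
  expect_lt(abs(slope - 2 * pi * f0) / (2 * pi * f0), 0.05)
  expect_error(instantaneous_phases(ts, band = c(0.04, 0.3)), "Nyquist")
})

test_that("detect_events marks rising threshold crossings once per excursion", {
  # single smooth bump on a flat noisy background
  set.seed(8)
  x <- rnorm(200, sd = 0.1)
  x[100:110] <- x[100:110] + dnorm(seq(-2, 2, length.out = 11)) * 10
  ts <- parcellated_ts(cbind(x, rnorm(200)), 1)
  ev <- detect_events(ts)
  expect_equal(sum(ev$events[, 1]), 1)
  expect_true(which(ev$events[, 1] == 1) %in% 99:111)

  # constant region: flagged, zero events
  ts2 <- parcellated_ts(cbind(rnorm(50), rep(1, 50)), 1)
  expect_warning(ev2 <- detect_events(ts2), "zero variance")
  expect_true(ev2$flagged[2])
  expect_equal(sum(ev2$events[, 2]), 0)
})

test_that("white-noise event counts match the up-crossing expectation", {
  # P(z_t > 1, z_{t-1} <= 1) for iid standard normals
  p_cross <- pnorm(1, lower.tail = FALSE) * pnorm(1)
  n <- 20000
  set.seed(12)
  ts <- parcellated_ts(matrix(rnorm(2 * n), n, 2), 1)
  ev <- detect_events(ts)
  counts <- colSums(ev$events)
  expected <- (n - 1) * p_cross
  sdev <- sqrt((n - 1) * p_cross * (1 - p_cross))
  expect_true(all(abs(counts - expected) < 3 * sdev))
})

test_that("integration matches brute-force connected components", {
  ph <- block_phases()
  # two blocks of 5 and 3: largest component 5 of 8
  expect_equal(integration_for_event(ph, 1, 1:8, 4, 0.5), 5 / 8)
  # fully synchronised: 1; no pair above threshold: singleton component
  sync <- ph; sync$phases[] <- 0.3
  expect_equal(integration_for_event(sync, 1, 1:8, 4, 0.5), 1)
  spread <- ph
  spread$phases <- matrix(rep(seq(0, pi, length.out = 8), each = 8), 8, 8)
  expect_equal(integration_for_event(spread, 1, 1:8, 4, 1e-6 + exp(-3 * 0.01)),
               1 / 8)

  # randomized oracle check against an independent BFS implementation
  set.seed(3)
  for (rep in 1:20) {
    phases <- matrix(runif(4 * 7, -pi, pi), 4, 7)
    ps <- structure(list(phases = phases, band_hz = c(0.04, 0.07),
                         tr_seconds = 2), class = "phase_series")
    thr <- runif(1, 0.2, 0.9)
    got <- integration_for_event(ps, 1, 1:7, 4, thr)
    want <- mean(vapply(1:4, function(t) {
      P <- exp(-3 * wrap_phase_distance_for_test(outer(phases[t, ], phases[t, ], `-`)))
      brute_largest_component(P >= thr)
    }, numeric(1))) / 7
    expect_equal(got, want)
  }
})

test_that("integration is monotone in the binarisation threshold and subset-consistent", {
  set.seed(5)
  phases <- matrix(runif(6 * 10, -pi, pi), 6, 10)
  ps <- structure(list(phases = phases, band_hz = c(0.04, 0.07),
                       tr_seconds = 2), class = "phase_series")
  thr <- sort(runif(5, 0.1, 0.95))
  ints <- vapply(thr, function(th) integration_for_event(ps, 1, 1:10, 4, th),
                 numeric(1))
  expect_true(all(diff(ints) <= 1e-12))
  expect_true(all(ints > 0 & ints <= 1))

  # computing on a subset == restricting the matrix before components
  sub <- c(2, 4, 5, 9)
  got <- integration_for_event(ps, 2, sub, 3, 0.5)
  want <- mean(vapply(2:4, function(t) {
    P <- exp(-3 * wrap_phase_distance_for_test(outer(phases[t, ], phases[t, ], `-`)))
    brute_largest_component(P[sub, sub] >= 0.5)
  }, numeric(1))) / length(sub)
  expect_equal(got, want)

  expect_error(integration_for_event(ps, 1, integer(0), 4), "empty")
  expect_true(is.na(integration_for_event(ps, 5, 1:10, 4)))  # window overflow
})

test_that("ignition_profile is exact on fully synchronised signals", {
  ts <- simulate_phase_signals(6, 1, 300, 2, seed = 2)
  prof <- ignition_profile(ts, window_trs = 4)
  expect_equal(prof$window_trs, 4L)
  has_events <- prof$n_events >= 1
  expect_true(any(has_events))
  expect_true(all(abs(prof$idmi[has_events] - 1) < 1e-12))
  expect_true(all(prof$metastability[prof$n_events >= 2] < 1e-12))
})

test_that("alternating synchrony produces strictly positive metastability", {
  hi <- simulate_phase_signals(6, 1, 120, 2, seed = 4)
  lo <- simulate_phase_signals(6, 0, 120, 2, seed = 5)
  vals <- rbind(hi$values, lo$values, hi$values, lo$values)
  ts <- parcellated_ts(vals, 2)
  prof <- ignition_profile(ts)
  ok <- prof$n_events >= 2
  expect_true(any(ok))
  expect_gt(max(prof$metastability[ok]), 0)
})

test_that("compare_ignition detects a consistent metastability decrease", {
  # constructed profiles: post-session event-integration variance halved
  set.seed(42)
  n_sub <- 17
  mk <- function(meta, id, ses) {
    new_ignition_profile(idmi = rep(0.6, 5), metastability = meta,
                         n_events = rep(10L, 5), subject_id = id,
                         session_label = ses)
  }
  pre <- post <- list()
  for (i in seq_len(n_sub)) {
    base <- runif(5, 0.15, 0.25)        # per-region integration SD, pre
    pre[[i]] <- mk(base, sprintf("S%02d", i), "pre")
    post[[i]] <- mk(base / sqrt(2) * runif(5, 0.9, 1.1), sprintf("S%02d", i),
                    "post")
  }
  cmp <- compare_ignition(pre, post, paired = TRUE)
  expect_lt(cmp$metastability$p_value, 0.05)
  expect_equal(cmp$metastability$direction, "a")   # pre larger
  expect_true(cmp$idmi$p_value >= 0 && cmp$idmi$p_value <= 1)

  # identical lists: non-significant by construction
  same <- compare_ignition(pre, pre, paired = TRUE)
  expect_gte(same$metastability$p_value, 0.99)
  expect_gte(same$idmi$p_value, 0.99)

  expect_error(compare_ignition(pre[1:3], post[1:2], paired = TRUE),
               "equally many")
})
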