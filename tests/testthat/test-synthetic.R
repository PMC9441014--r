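test_that("random_sc_mask hits the requested density exactly", {
  m <- random_sc_mask(116, 1.0, seed = 1)
  expect_equal(sum(m$mask), 116 * 115)          # all off-diagonal cells
  expect_true(all(diag(m$mask) == 0))

  m30 <- random_sc_mask(116, 0.30, symmetric = TRUE, seed = 2)
  pairs <- sum(m30$mask[upper.tri(m30$mask)])
  expect_equal(pairs, round(0.30 * 116 * 115 / 2))  # 2001 undirected pairs
  expect_equal(sum(m30$mask), 2 * pairs)            # 4002 directed entries
  expect_identical(m30$mask, t(m30$mask))
  expect_true(all(diag(m30$mask) == 0))

  expect_error(random_sc_mask(116, 0), "density")
  expect_error(random_sc_mask(116, 1.2), "density")
})

test_that("random_sc_mask is seed-deterministic", {
  a <- random_sc_mask(30, 0.2, seed = 42)
  b <- random_sc_mask(30, 0.2, seed = 42)
  c <- random_sc_mask(30, 0.2, seed = 43)
  expect_identical(a$mask, b$mask)
  expect_false(identical(a$mask, c$mask))
})

test_that("simulate_mou matches the stationary OU variance and is reproducible", {
  n <- 4
  model <- mou_model(matrix(0, n, n), rep(1, n), 1, sc_mask(matrix(0, n, n)))
  ts <- simulate_mou(model, duration_seconds = 10000, dt_seconds = 0.05,
                     tr_seconds = 1, seed = 9)
  expect_equal(nrow(ts$values), 10000)
  v <- apply(ts$values, 2, var)
  # closed form: sigma * tau / 2 = 0.5
  expect_true(all(abs(v - 0.5) / 0.5 < 0.05))

  a <- simulate_mou(model, 100, 0.05, 1, seed = 4)
  b <- simulate_mou(model, 100, 0.05, 1, seed = 4)
  expect_identical(a$values, b$values)

  ts2 <- simulate_mou(model, 480, 0.1, 2, seed = 1)
  expect_equal(nrow(ts2$values), 240)
})

test_that("simulate_mou reproduces the OU lag-1 autocovariance", {
  model <- mou_model(matrix(0, 2, 2), c(1, 1), 2, sc_mask(matrix(0, 2, 2)))
  ts <- simulate_mou(model, 40000, dt_seconds = 0.1, tr_seconds = 2, seed = 3)
  cp <- covariance_pair(ts, 1)
  expect_lt(abs(cp$q1[1, 1] / cp$q0[1, 1] - exp(-1)), 0.02 + 3 / sqrt(20000))
})

test_that("simulate_mou refuses an unstable model", {
  ec <- matrix(c(0, 5, 5, 0), 2, 2)   # strong reciprocal coupling
  m <- mou_model(ec, c(1, 1), 2, check_stability = FALSE)
  expect_false(is_stable(m))
  expect_error(simulate_mou(m, 100, 0.1, 2, seed = 1), "unstable")
})

test_that("stationary covariance of a coupled simulation matches the Lyapunov solution", {
  model <- random_mou_model(5, density = 0.4, tau_seconds = 1, seed = 3)
  ts <- simulate_mou(model, 10000, dt_seconds = 0.05, tr_seconds = 1, seed = 8)
  emp <- covariance_pair(ts, 1)
  ana <- model_covariances(model, 1, 1)
  expect_gt(cor(as.vector(emp$q0), as.vector(ana$q0)), 0.95)
})

test_that("generate_cohort respects the design and the ground truth", {
  spec <- cohort_spec(n_group_a = 3, n_group_b = 2, n_regions = 20,
                      n_volumes = 40, n_perturbed_edges = 3,
                      perturbation_scale = 1, seed = 5)
  coh <- generate_cohort(spec)
  expect_length(coh$dataset, 10)      # (3 + 2) subjects x 2 sessions
  expect_equal(nrow(coh$truth$perturbed_edges), 3)
  expect_identical(unname(coh$truth$group_labels),
                   c("A", "A", "A", "B", "B"))

  # group A post models differ from pre exactly at the planted edges
  pe <- coh$truth$perturbed_edges
  idx <- (pe[, 2] - 1) * 20 + pe[, 1]
  for (s in c("A01", "A02", "A03")) {
    d <- coh$truth$true_models[[paste0(s, "_post")]]$ec -
      coh$truth$true_models[[paste0(s, "_pre")]]$ec
    expect_identical(sort(which(d != 0)), sort(as.integer(idx)))
    expect_true(all(d[idx] > 0))
  }
  # group B sessions share one model
  for (s in c("B01", "B02")) {
    expect_identical(coh$truth$true_models[[paste0(s, "_pre")]]$ec,
                     coh$truth$true_models[[paste0(s, "_post")]]$ec)
  }
  # but no two sessions share a noise realisation
  vals <- sapply(coh$dataset, function(ts) ts$values[1, 1])
  expect_equal(length(unique(vals)), 10)
})

test_that("zero perturbation makes pre and post models identical for everyone", {
  spec <- cohort_spec(n_group_a = 2, n_group_b = 1, n_regions = 15,
                      n_volumes = 30, perturbation_scale = 0, seed = 2)
  coh <- generate_cohort(spec)
  for (s in names(coh$truth$group_labels)) {
    expect_identical(coh$truth$true_models[[paste0(s, "_pre")]]$ec,
                     coh$truth$true_models[[paste0(s, "_post")]]$ec)
  }
})

test_that("explicit perturbed edges are validated against the mask", {
  expect_error(
    generate_cohort(cohort_spec(n_group_a = 1, n_group_b = 1, n_regions = 10,
                                n_volumes = 30,
                                perturbed_edges = cbind(1, 1), seed = 1)),
    "outside the SC mask")
})

test_that("simulate_phase_signals couples phases monotonically", {
  plv_mean <- function(coupling) {
    ts <- simulate_phase_signals(6, coupling, 300, 2, seed = 21)
    ph <- instantaneous_phases(ts)$phases
    pr <- combn(6, 2)
    mean(vapply(seq_len(ncol(pr)), function(k) {
      mean(phase_lock_value(ph[, pr[1, k]], ph[, pr[2, k]]))
    }, numeric(1)))
  }
  p0 <- plv_mean(0); p5 <- plv_mean(0.5); p1 <- plv_mean(1)
  expect_lt(p0, 0.5)                 # independent phases: mean exp(-3|d|) small
  expect_true(p0 < p5 && p5 < p1)    # monotone in coupling
  expect_gt(p1, 0.999)               # full coupling: identical phases

  ts <- simulate_phase_signals(4, 1, 100, 2, seed = 3)
  ph <- instantaneous_phases(ts)$phases
  d <- wrap_phase_distance_for_test(ph[, 1] - ph[, 3])
  expect_lt(max(d), 1e-8)

  a <- simulate_phase_signals(4, 0.3, 50, 2, seed = 5)
  b <- simulate_phase_signals(4, 0.3, 50, 2, seed = 5)
  expect_identical(a$values, b$values)

  expect_error(simulate_phase_signals(4, 0.5, 50, 2, band = c(0.1, 0.3)),
               "band")
  expect_error(simulate_phase_signals(4, 1.5, 50, 2), "coupling")
})
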