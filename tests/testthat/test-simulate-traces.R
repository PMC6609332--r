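test_that("identical seed and parameters reproduce traces exactly", {
  pr <- default_protocol()
  p <- trace_sim_params(noise_sd = 0.05, seed = 11)
  t1 <- simulate_nprr_traces(pr, p)
  t2 <- simulate_nprr_traces(pr, p)
  expect_identical(tibble::as_tibble(t1), tibble::as_tibble(t2))
  t3 <- simulate_nprr_traces(pr, trace_sim_params(noise_sd = 0.05, seed = 12))
  expect_false(identical(t1$f, t3$f))
})

test_that("release-blocked (TNT) mode produces a flat zero trace", {
  pr <- default_protocol()
  tr <- simulate_nprr_traces(pr, trace_sim_params(mode = "tnt", n_rois = 2))
  expect_true(all(tr$dff_true == 0))
  expect_true(all(tr$f == trace_sim_params()$baseline_f))
})

test_that("noiseless traces show the tri-phasic shape at every trial", {
  pr <- default_protocol()
  tr <- simulate_nprr_traces(pr, trace_sim_params(n_rois = 1))
  model <- attr(tr, "ground_truth")
  for (k in seq_len(nrow(pr))) {
    w <- model$time_s >= pr$onset_s[k] & model$time_s <= pr$offset_s[k]
    lat <- model$time_s[w][which.max(model$dff[w])] - pr$onset_s[k]
    expect_gte(lat, 0.5)
    expect_lte(lat, 5)
    # decline begins before stimulus offset
    peak_t <- pr$onset_s[k] + lat
    at_offset <- model$dff[model$time_s == pr$offset_s[k]]
    expect_lt(at_offset, max(model$dff[w]))
    expect_lt(peak_t, pr$offset_s[k])
    # sub-baseline undershoot in the following interval, recovering later
    nxt <- if (k < nrow(pr)) pr$onset_s[k + 1] else attr(pr, "extent_s")
    iw <- model$time_s >= pr$offset_s[k] & model$time_s <= nxt
    expect_lt(min(model$dff[iw]), 0)
    expect_gt(model$dff[iw][sum(iw)], min(model$dff[iw]))
  }
})

test_that("the integrator matches a 100x-finer-step oracle within 1%", {
  pr <- default_protocol()
  p <- trace_sim_params(n_rois = 1)
  model <- attr(simulate_nprr_traces(pr, p), "ground_truth")
  fine <- oracle_nprr_dff(pr, p, refine = 100)
  expect_lt(max(abs(model$dff - fine)) / max(abs(fine)), 0.01)
})

test_that("trial gain schedules modulate per-trial responses", {
  pr <- default_protocol()
  p <- trace_sim_params(trial_gain_schedule = c(0.5, 1, 1, 1), n_rois = 1)
  model <- attr(simulate_nprr_traces(pr, p), "ground_truth")
  peaks <- vapply(seq_len(4), function(k) {
    w <- model$time_s >= pr$onset_s[k] & model$time_s <= pr$offset_s[k]
    max(model$dff[w])
  }, numeric(1))
  expect_lt(peaks[1], peaks[2])
  expect_error(
    simulate_nprr_traces(pr, trace_sim_params(trial_gain_schedule = c(1, 1))),
    "schedule")
})

test_that("calcium-control traces peak immediately and never undershoot", {
  pr <- default_protocol()
  tr <- simulate_gcamp_traces(pr, trace_sim_params(n_rois = 1))
  model <- attr(tr, "ground_truth")
  expect_true(all(model$dff >= 0))
  for (k in seq_len(nrow(pr))) {
    w <- which(model$time_s >= pr$onset_s[k] & model$time_s <= pr$offset_s[k])
    first_max <- model$time_s[w][which.max(model$dff[w])]
    expect_lte(first_max - pr$onset_s[k], 2 * attr(pr, "frame_interval_s"))
  }
  # every inter-stimulation integral is non-negative, unlike the release
  # reporter's
  dff <- compute_dff(tr)
  ii <- interval_integrals(dff)
  expect_true(all(ii$integral[ii$window == "interval"] >= 0))

  flat <- simulate_gcamp_traces(pr, trace_sim_params(release_gain_per_hz = 0,
                                                     n_rois = 1))
  expect_true(all(flat$dff_true == 0))
})

test_that("generator parameters are validated", {
  expect_error(trace_sim_params(pool_replenish_tau = -1), "positive")
  expect_error(trace_sim_params(noise_sd = -0.1), "non-negative")
  expect_error(trace_sim_params(n_rois = 0), "n_rois")
})
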