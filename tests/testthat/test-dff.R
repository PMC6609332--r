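test_that("dF/F normalises to the pre-stimulation background", {
  pr <- make_protocol(1, 18, 42, 70, pre_window = 10, post_window = 10)
  times <- protocol_frames(pr)

  const <- manual_traces(times, rep(100, length(times)))
  expect_true(all(compute_dff(const, pr)$dff == 0))

  f <- rep(100, length(times))
  f[times == 15] <- 150
  expect_equal(compute_dff(manual_traces(times, f), pr)$dff[times == 15], 0.5)
})

test_that("dF/F recovers the simulator ground truth and is scale-invariant", {
  pr <- default_protocol()
  tr <- simulate_nprr_traces(pr, trace_sim_params(n_rois = 2))
  dff <- compute_dff(tr)
  expect_equal(dff$dff, tr$dff_true, tolerance = 1e-12)

  scaled <- tr
  scaled$f <- scaled$f * 7.3
  expect_equal(compute_dff(scaled, pr)$dff, dff$dff, tolerance = 1e-12)
})

test_that("degenerate baselines are rejected", {
  pr <- default_protocol()
  times <- protocol_frames(pr)
  tr <- manual_traces(times, rep(100, length(times)))
  expect_error(compute_dff(tr, pr, baseline_window = c(0, 1)), "3 frames")
  expect_error(compute_dff(tr, pr, baseline_window = c(5, 4)), "increasing")
  expect_error(compute_dff(tr, pr, baseline_window = c(0, 40)),
               "precede the first trial onset")
  zero <- manual_traces(times, rep(0, length(times)))
  expect_error(compute_dff(zero, pr), "> 0")
})

test_that("per-trial baseline correction zeroes pre-trial means and is idempotent", {
  pr <- default_protocol()
  times <- protocol_frames(pr)
  # drifting baseline: slow ramp plus trial-locked bumps
  base <- 0.002 * times
  bump <- numeric(length(times))
  for (k in seq_len(4)) {
    w <- times >= pr$onset_s[k] & times <= pr$offset_s[k]
    bump[w] <- 0.5
  }
  dff <- manual_dff(times, base + bump, pr)
  corr <- correct_trial_baseline(dff, pr, pre_span = 5)
  for (k in seq_len(4)) {
    pre <- corr$time_s >= pr$onset_s[k] - 5 & corr$time_s < pr$onset_s[k]
    expect_lt(abs(mean(corr$dff[pre])), 1e-12)
  }
  corr2 <- correct_trial_baseline(corr, pr, pre_span = 5)
  expect_equal(corr2$dff, corr$dff, tolerance = 1e-12)
})

test_that("trial baseline correction shifts by exactly the pre-trial mean", {
  pr <- make_protocol(1, 18, 42, 70, pre_window = 10, post_window = 10)
  times <- protocol_frames(pr)
  x <- rep(0.2, length(times))          # constant pre-trial level 0.2
  dff <- manual_dff(times, x, pr)
  corr <- correct_trial_baseline(dff, pr, pre_span = 5)
  in_trial <- times >= pr$onset_s[1]
  expect_equal(corr$dff[in_trial], x[in_trial] - 0.2, tolerance = 1e-12)

  zero <- manual_dff(times, ifelse(times >= pr$onset_s[1], 0.4, 0), pr)
  corr0 <- correct_trial_baseline(zero, pr, pre_span = 5)
  expect_equal(corr0$dff, zero$dff, tolerance = 1e-12)

  short <- make_protocol(1, 18, 42, 70, pre_window = 2, post_window = 10)
  sdff <- manual_dff(protocol_frames(short),
                     numeric(length(protocol_frames(short))), short)
  expect_error(correct_trial_baseline(sdff, short, pre_span = 5), "Trial 1")
})

test_that("mean and s.e.m. aggregation matches brute-force statistics", {
  pr <- make_protocol(1, 18, 12, 70, pre_window = 10, post_window = 10)
  times <- protocol_frames(pr)
  nt <- length(times)

  same <- dplyr::bind_rows(
    manual_dff(times, sin(times / 5), pr, roi_id = "a"),
    manual_dff(times, sin(times / 5), pr, roi_id = "b"))
  agg <- aggregate_mean_sem(same)
  expect_equal(agg$mean_dff, sin(times / 5))
  expect_true(all(agg$sem_dff == 0))

  two <- dplyr::bind_rows(
    manual_dff(times, rep(0, nt), pr, roi_id = "a"),
    manual_dff(times, rep(1, nt), pr, roi_id = "b"))
  agg2 <- aggregate_mean_sem(two)
  expect_true(all(agg2$mean_dff == 0.5))
  expect_true(all(agg2$sem_dff == 0.5))

  set.seed(42)
  mats <- matrix(rnorm(5 * nt), 5, nt)
  rand <- dplyr::bind_rows(lapply(1:5, function(i) {
    manual_dff(times, mats[i, ], pr, roi_id = paste0("r", i))
  }))
  agg3 <- aggregate_mean_sem(rand)
  expect_equal(agg3$mean_dff, colMeans(mats))
  expect_equal(agg3$sem_dff, apply(mats, 2, sd) / sqrt(5))

  # order invariance
  perm <- rand[order(rand$roi_id, decreasing = TRUE), ]
  expect_equal(aggregate_mean_sem(perm)$mean_dff, agg3$mean_dff)

  expect_warning(single <- aggregate_mean_sem(rand[rand$roi_id == "r1", ]),
                 "s.e.m")
  expect_true(all(single$sem_dff == 0))

  shifted <- rand
  shifted$time_s[shifted$roi_id == "r1"] <-
    shifted$time_s[shifted$roi_id == "r1"] + 0.5
  expect_error(aggregate_mean_sem(shifted), "frame vector")
})

test_that("fold-change screening applies the 2-fold rule inclusively", {
  sc <- fold_change_screen(c(200, 100, 199), 100)
  expect_equal(sc$fold, c(2, 1, 1.99))
  expect_equal(sc$pass, c(TRUE, FALSE, FALSE))
  expect_error(fold_change_screen(100, 0), "positive")
  expect_equal(fold_change_screen(150, 100, threshold = 1.5)$pass, TRUE)
})
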