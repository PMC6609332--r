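test_that("trial peaks and latencies follow the in-stimulation maximum", {
  pr <- make_protocol(1, 18, 42, 70, pre_window = 10, post_window = 20)
  times <- protocol_frames(pr)

  flat <- manual_dff(times, numeric(length(times)), pr)
  pk <- trial_peaks(flat, pr)
  expect_equal(pk$peak, 0)
  expect_equal(pk$latency_s, 0)  # tie resolved to the earliest frame

  # triangular bump reaching 1.2 at onset + 6 s
  tri <- pmax(0, 1.2 * (1 - abs(times - (pr$onset_s[1] + 6)) / 6))
  pk2 <- trial_peaks(manual_dff(times, tri, pr), pr)
  expect_equal(pk2$peak, 1.2)
  expect_equal(pk2$latency_s, 6)

  # a larger post-offset excursion is ignored
  late <- tri
  late[times == pr$offset_s[1] + 5] <- 3
  expect_equal(trial_peaks(manual_dff(times, late, pr), pr)$peak, 1.2)

  short <- manual_dff(times[times < 20], numeric(sum(times < 20)), pr)
  expect_error(trial_peaks(short, pr), "outside the recorded extent")
})

test_that("noiseless simulated peaks match the fine-grid oracle within 1%", {
  pr <- default_protocol()
  p <- trace_sim_params(n_rois = 1)
  dff <- compute_dff(simulate_nprr_traces(pr, p))
  pk <- trial_peaks(dff)
  fine <- oracle_nprr_dff(pr, p, refine = 100)
  times <- protocol_frames(pr)
  for (k in seq_len(4)) {
    w <- times >= pr$onset_s[k] & times <= pr$offset_s[k]
    expect_equal(pk$peak[pk$trial == k], max(fine[w]), tolerance = 0.01)
  }
})

test_that("window integrals are exact trapezoids on frame times", {
  pr <- make_protocol(1, 18, 42, 70, pre_window = 10, post_window = 20)
  times <- protocol_frames(pr)

  const <- manual_dff(times, rep(0.3, length(times)), pr)
  ii <- interval_integrals(const, pr)
  expect_equal(ii$integral[ii$window == "trial"], 0.3 * 18)
  expect_equal(ii$integral_per_s[ii$window == "trial"], 0.3)

  ramp <- manual_dff(times, 0.01 * times, pr)
  ir <- interval_integrals(ramp, pr)
  on <- pr$onset_s[1]; off <- pr$offset_s[1]
  expect_equal(ir$integral[ir$window == "trial"],
               0.01 * (off^2 - on^2) / 2)  # closed form for a linear ramp
})

test_that("release and calcium-control interval integrals have opposite character", {
  pr <- default_protocol()
  nprr <- compute_dff(simulate_nprr_traces(pr, trace_sim_params(n_rois = 1)))
  gc <- compute_dff(simulate_gcamp_traces(pr, trace_sim_params(n_rois = 1)))
  i_n <- interval_integrals(nprr)
  i_g <- interval_integrals(gc)
  expect_true(all(i_n$integral[i_n$window == "interval"] < 0))
  expect_true(all(i_g$integral[i_g$window == "interval"] >= 0))
})

test_that("phase segmentation recovers constructed breakpoints within a frame", {
  pr <- stim_protocol(
    tibble::tibble(trial = 1L, onset_s = 10, offset_s = 28, duration_s = 18,
                   frequency_hz = 70, pulse_width_ms = 1),
    pre_window = 10, post_window = 27, frame_interval = 1)
  times <- protocol_frames(pr)
  dff <- numeric(length(times))
  rise <- times >= 10 & times <= 14
  dff[rise] <- (times[rise] - 10) / 4           # rise 0 -> 1 over 4 s
  dff[times > 14 & times <= 20] <- 1            # plateau
  fall <- times > 20 & times <= 28
  dff[fall] <- 1 - 1.3 * (times[fall] - 20) / 8 # fall to -0.3 at offset
  dff[times > 28 & times <= 35] <- -0.3         # undershoot floor
  rec <- times > 35 & times <= 45
  dff[rec] <- -0.3 * (45 - times[rec]) / 10     # recovery to 0
  seg <- segment_phases(manual_dff(times, dff, pr), pr)
  expect_true(seg$phases_defined)
  expect_lte(abs(seg$peak_time_s - 14), 1)
  expect_lte(abs(seg$falling_onset_s - 20), 1)
  expect_lte(abs(seg$undershoot_start_s - 28), 1)
  expect_lte(abs(seg$undershoot_end_s - 44), 1)
  expect_true(seg$recovery)

  flat <- segment_phases(manual_dff(times, numeric(length(times)), pr), pr)
  expect_false(flat$phases_defined)
  expect_true(is.na(flat$peak_time_s))
})

test_that("simulated release traces begin declining before stimulus offset", {
  pr <- default_protocol()
  dff <- compute_dff(simulate_nprr_traces(pr, trace_sim_params(n_rois = 1)))
  seg <- segment_phases(dff)
  expect_true(all(seg$phases_defined))
  expect_true(all(seg$falling_lead_s > 0))
  expect_true(all(!is.na(seg$undershoot_start_s)))
})

test_that("frequency normalisation is anchored at the reference", {
  fr <- normalize_frequency_response(
    tibble::tibble(frequency_hz = c(70, 35), peak = c(0.8, 0.4)))
  expect_equal(fr$norm_pct[fr$frequency_hz == 70], 100)
  expect_equal(fr$norm_pct[fr$frequency_hz == 35], 50)
  expect_error(normalize_frequency_response(
    tibble::tibble(frequency_hz = c(35, 50), peak = c(0.4, 0.5))), "absent")
  expect_error(normalize_frequency_response(
    tibble::tibble(frequency_hz = c(35, 70), peak = c(0.4, 0))), "positive")
  expect_error(normalize_frequency_response(
    tibble::tibble(frequency_hz = c(70, 70), peak = c(1, 1))), "unique")
})

test_that("a frequency titration of the generator yields a monotone response", {
  freqs <- c(1, 5, 10, 20, 30, 50, 70)
  peaks <- vapply(freqs, function(f) {
    pr <- make_protocol(1, 18, 42, f, pre_window = 10, post_window = 30)
    dff <- compute_dff(simulate_nprr_traces(pr, trace_sim_params(n_rois = 1)))
    trial_peaks(dff)$peak
  }, numeric(1))
  fr <- normalize_frequency_response(
    tibble::tibble(frequency_hz = freqs, peak = peaks))
  expect_true(all(diff(fr$norm_pct) >= 0))
  expect_equal(max(fr$norm_pct), 100)
})

test_that("metrics scale linearly in dF/F; normalised responses do not", {
  pr <- default_protocol()
  dff <- compute_dff(simulate_nprr_traces(pr, trace_sim_params(n_rois = 1)))
  sc <- dff
  sc$dff <- sc$dff * 2.5
  expect_equal(trial_peaks(sc, pr)$peak, 2.5 * trial_peaks(dff, pr)$peak)
  expect_equal(interval_integrals(sc, pr)$integral,
               2.5 * interval_integrals(dff, pr)$integral)
  pk <- trial_peaks(dff, pr)$peak
  f1 <- normalize_frequency_response(
    tibble::tibble(frequency_hz = c(10, 35, 70), peak = pk[1:3] + 0.5))
  f2 <- normalize_frequency_response(
    tibble::tibble(frequency_hz = c(10, 35, 70), peak = 2.5 * (pk[1:3] + 0.5)))
  expect_equal(f1$norm_pct, f2$norm_pct)
})

test_that("bouton/inter-bouton contrast matches frame-wise recomputation", {
  pr <- make_protocol(2, 18, 12, 70, pre_window = 10, post_window = 10)
  times <- protocol_frames(pr)
  nt <- length(times)

  both <- dplyr::bind_rows(
    manual_dff(times, rep(2, nt), pr, roi_id = "b1"),
    manual_dff(times, rep(2, nt), pr, roi_id = "b2"),
    manual_dff(times, rep(1, nt), pr, roi_id = "i1", roi_class = "inter_bouton"))
  r <- bouton_ibi_ratio(both, pr)
  expect_equal(r$ratio, c(2, 2))
  expect_equal(r$frac_excluded, c(0, 0))

  same <- dplyr::bind_rows(
    manual_dff(times, rep(0.5, nt), pr, roi_id = "b1"),
    manual_dff(times, rep(0.5, nt), pr, roi_id = "i1",
               roi_class = "inter_bouton"))
  expect_equal(bouton_ibi_ratio(same, pr)$ratio, c(1, 1))

  set.seed(9)
  bmat <- matrix(runif(3 * nt, 0, 1), 3, nt)
  imat <- matrix(runif(2 * nt, -0.05, 0.4), 2, nt)
  rand <- dplyr::bind_rows(
    lapply(1:3, function(i) manual_dff(times, bmat[i, ], pr,
                                       roi_id = paste0("b", i))),
    lapply(1:2, function(i) manual_dff(times, imat[i, ], pr,
                                       roi_id = paste0("i", i),
                                       roi_class = "inter_bouton")))
  got <- bouton_ibi_ratio(rand, pr, floor = 0.01)
  for (k in 1:2) {
    w <- which(times >= pr$onset_s[k] & times <= pr$offset_s[k])
    bm <- colMeans(bmat)[w]
    im <- colMeans(imat)[w]
    keep <- im >= 0.01
    expect_equal(got$ratio[k], mean(bm[keep] / im[keep]))
    expect_equal(got$n_excluded[k], sum(!keep))
  }

  # all frames excluded -> undefined flag, not an error
  neg <- dplyr::bind_rows(
    manual_dff(times, rep(1, nt), pr, roi_id = "b1"),
    manual_dff(times, rep(-0.2, nt), pr, roi_id = "i1",
               roi_class = "inter_bouton"))
  u <- bouton_ibi_ratio(neg, pr)
  expect_true(all(!u$defined))
  expect_true(all(is.na(u$ratio)))

  expect_error(bouton_ibi_ratio(both[both$roi_class == "bouton", ], pr),
               "inter_bouton")
})
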