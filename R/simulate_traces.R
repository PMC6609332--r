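#' Parameters for the synthetic fluorescence-trace generator
#'
#' The generator is a phenomenological releasable-pool model that reproduces
#' the qualitative kinetics of a DCV-fusion reporter at the larval NMJ:
#' a delayed in-stimulation peak, a decline that begins before stimulus
#' offset as the releasable pool depletes, a sub-baseline undershoot during
#' the inter-stimulation intervals, and slow recovery as the pool is
#' replenished from the axon.
#'
#' Per ROI, with pool `P` (P(0) = 1) and released-signal `R` (R(0) = 0):
#' during stimulation at frequency `f`, `dP/dt = -pool_depletion_rate *
#' drive * P`; otherwise `dP/dt = (1 - P) / pool_replenish_tau`; always
#' `dR/dt = release_gain_per_hz * f * drive * P - R / signal_clearance_tau`,
#' where `drive = plogis((f - freq_threshold) * freq_slope) * trial_gain`.
#' The cumulative unreplenished release is `D = 1 - P` and
#' `dF/F(t) = R(t) - undershoot_coupling * D(t) +` Gaussian noise.
#' Raw fluorescence is `baseline_f * (1 + dF/F)`.
#'
#' @param baseline_f Resting fluorescence, arbitrary units.
#' @param release_gain_per_hz Fluorescence gain per Hz of drive (dimensionless).
#' @param pool_depletion_rate Releasable-pool depletion rate at full drive, 1/s.
#' @param pool_replenish_tau Pool replenishment time constant, s.
#' @param signal_clearance_tau Clearance (diffusion) time constant of released
#'   reporter signal, s.
#' @param undershoot_coupling Fraction of the cumulative unreplenished release
#'   subtracted from baseline (sets undershoot depth).
#' @param trial_gain_schedule Per-trial multiplicative drive factors (length 1
#'   or one per trial); lets the first trial be weaker or successive trials
#'   decline, as observed for different reporters.
#' @param freq_threshold,freq_slope Centre (Hz) and slope of the logistic
#'   frequency dependence of drive.
#' @param noise_sd Gaussian noise sd added to dF/F per frame.
#' @param n_rois Number of ROIs to simulate.
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @param mode Preset: `"type_iii"` (default; small responses below 30 Hz),
#'   `"type_ib"` (responsive from 10 to 20 Hz), or `"tnt"` (fusion blocked:
#'   release gain and undershoot coupling forced to 0).
#'
#' @return A list of class `trace_sim_params`.
#' @export
trace_sim_params <- function(baseline_f = 100,
                             release_gain_per_hz = 0.012,
                             pool_depletion_rate = 0.35,
                             pool_replenish_tau = 25,
                             signal_clearance_tau = 2,
                             undershoot_coupling = 0.12,
                             trial_gain_schedule = 1,
                             freq_threshold = 40,
                             freq_slope = 0.15,
                             noise_sd = 0,
                             n_rois = 8,
                             seed = NULL,
                             mode = c("type_iii", "type_ib", "tnt")) {
  mode <- match.arg(mode)
  if (mode == "type_ib") {
    if (missing(freq_threshold)) freq_threshold <- 12
    if (missing(freq_slope)) freq_slope <- 0.25
  }
  if (mode == "tnt") {
    release_gain_per_hz <- 0
    undershoot_coupling <- 0
  }
  p <- list(
    baseline_f = baseline_f,
    release_gain_per_hz = release_gain_per_hz,
    pool_depletion_rate = pool_depletion_rate,
    pool_replenish_tau = pool_replenish_tau,
    signal_clearance_tau = signal_clearance_tau,
    undershoot_coupling = undershoot_coupling,
    trial_gain_schedule = trial_gain_schedule,
    freq_threshold = freq_threshold,
    freq_slope = freq_slope,
    noise_sd = noise_sd,
    n_rois = n_rois,
    seed = seed,
    mode = mode
  )
  validate_trace_sim_params(p)
  structure(p, class = "trace_sim_params")
}

validate_trace_sim_params <- function(p) {
  pos <- c("baseline_f", "pool_depletion_rate", "pool_replenish_tau",
           "signal_clearance_tau", "freq_slope")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] <= 0) {
      stop(sprintf("`%s` must be a single positive number.", nm), call. = FALSE)
    }
  }
  nonneg <- c("release_gain_per_hz", "undershoot_coupling", "noise_sd")
  for (nm in nonneg) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] < 0) {
      stop(sprintf("`%s` must be a single non-negative number.", nm),
           call. = FALSE)
    }
  }
  if (p$n_rois < 1 || p$n_rois != round(p$n_rois)) {
    stop("`n_rois` must be a positive integer.", call. = FALSE)
  }
  if (any(p$trial_gain_schedule < 0)) {
    stop("`trial_gain_schedule` must be non-negative.", call. = FALSE)
  }
  invisible(p)
}

trial_gains <- function(params, n_trials) {
  g <- params$trial_gain_schedule
  if (length(g) == 1) g <- rep(g, n_trials)
  if (length(g) != n_trials) {
    stop("`trial_gain_schedule` must have length 1 or one entry per trial.",
         call. = FALSE)
  }
  g
}

# Deterministic dF/F of the pool-depletion model at the protocol's frame
# times. Classical RK4 with `substeps` sub-steps per frame; drive is the
# piecewise definition evaluated at each stage time.
nprr_model_dff <- function(protocol, params, substeps = 10) {
  times <- protocol_frames(protocol)
  n_trials <- nrow(protocol)
  gains <- trial_gains(params, n_trials)
  onsets <- protocol$onset_s
  offsets <- protocol$offset_s
  freqs <- protocol$frequency_hz

  drive_at <- function(t) {
    k <- which(t >= onsets & t < offsets)
    if (length(k)) {
      k <- k[1]
      c(stats::plogis((freqs[k] - params$freq_threshold) * params$freq_slope) *
          gains[k], freqs[k])
    } else {
      c(0, 0)
    }
  }
  # Drive is piecewise constant; it is frozen at the substep midpoint so no
  # RK4 stage samples across a stimulation on/off boundary (substeps are
  # aligned with frame times, and trial boundaries fall on frames in the
  # protocols used here).
  rhs <- function(st, dv) {
    dP <- if (dv[1] > 0) {
      -params$pool_depletion_rate * dv[1] * st[1]
    } else {
      (1 - st[1]) / params$pool_replenish_tau
    }
    dR <- params$release_gain_per_hz * dv[2] * dv[1] * st[1] -
      st[2] / params$signal_clearance_tau
    c(dP, dR)
  }

  nt <- length(times)
  P <- R <- numeric(nt)
  st <- c(1, 0)
  P[1] <- st[1]; R[1] <- st[2]
  for (i in seq_len(nt - 1L)) {
    h <- (times[i + 1L] - times[i]) / substeps
    t0 <- times[i]
    for (j in seq_len(substeps)) {
      dv <- drive_at(t0 + (j - 0.5) * h)
      k1 <- rhs(st, dv)
      k2 <- rhs(st + h / 2 * k1, dv)
      k3 <- rhs(st + h / 2 * k2, dv)
      k4 <- rhs(st + h * k3, dv)
      st <- st + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    P[i + 1L] <- st[1]; R[i + 1L] <- st[2]
  }
  tibble::tibble(
    time_s = times,
    pool = P,
    released = R,
    dff = R - params$undershoot_coupling * (1 - P)
  )
}

as_roi_traces <- function(df, protocol, params, ground_truth) {
  structure(
    df,
    protocol = protocol,
    params = params,
    ground_truth = ground_truth,
    class = c("roi_traces", class(tibble::tibble()))
  )
}

#' Simulate NPRR-like fluorescence traces
#'
#' Generates a long-form ROI trace table from the pool-depletion release
#' model described in [trace_sim_params()]. Noiseless output satisfies the
#' tri-phasic shape constraints (delayed in-stimulation peak, decline before
#' stimulus offset, sub-baseline undershoot with later recovery); with
#' `mode = "tnt"` the deterministic trace is identically zero.
#'
#' @param protocol A [stim_protocol][make_protocol].
#' @param params A [trace_sim_params()] list.
#' @param roi_class ROI class label for all simulated ROIs (`"bouton"`,
#'   `"inter_bouton"` or `"whole"`).
#' @param condition Condition label stored with every sample (e.g. reporter
#'   and intervention).
#' @return A `roi_traces` tibble with columns `time_s`, `roi_id`,
#'   `roi_class`, `condition`, `f` (raw fluorescence) and `dff_true`
#'   (noiseless model dF/F), carrying the protocol, parameters, and the
#'   ground-truth model trace as attributes.
#' @examples
#' pr <- make_protocol(2, 18, 42, 70, pre_window = 30, post_window = 30)
#' tr <- simulate_nprr_traces(pr, trace_sim_params(noise_sd = 0.02, seed = 1))
#' head(tr)
#' @export
simulate_nprr_traces <- function(protocol, params = trace_sim_params(),
                                 roi_class = "bouton", condition = "NPRR") {
  validate_trace_sim_params(params)
  roi_class <- match.arg(roi_class, c("bouton", "inter_bouton", "whole"))
  if (!is.null(params$seed)) set.seed(params$seed)
  model <- nprr_model_dff(protocol, params)
  build_trace_table(model$time_s, model$dff, params, roi_class, condition,
                    protocol, ground_truth = model)
}

#' Simulate GCaMP-like control traces
#'
#' Cytosolic calcium-indicator control: dF/F rises to a plateau within one
#' frame of trial onset (so the in-trial maximum is first attained at most
#' two frames after onset), stays at plateau through the trial, and decays
#' exponentially with `signal_clearance_tau` after offset. The deterministic
#' trace never falls below zero, so every inter-stimulation integral is
#' non-negative -- the defining contrast with the release-reporter model.
#' The plateau is `release_gain_per_hz * frequency * signal_clearance_tau *
#' trial_gain` (linear in frequency: the calcium control responds in a graded
#' fashion at frequencies well below the release threshold).
#'
#' @inheritParams simulate_nprr_traces
#' @return A `roi_traces` tibble; see [simulate_nprr_traces()].
#' @export
simulate_gcamp_traces <- function(protocol, params = trace_sim_params(),
                                  roi_class = "bouton", condition = "GCaMP6s") {
  validate_trace_sim_params(params)
  roi_class <- match.arg(roi_class, c("bouton", "inter_bouton", "whole"))
  if (!is.null(params$seed)) set.seed(params$seed)
  times <- protocol_frames(protocol)
  gains <- trial_gains(params, nrow(protocol))
  rise_time <- attr(protocol, "frame_interval_s")
  dff <- numeric(length(times))
  for (k in seq_len(nrow(protocol))) {
    plateau <- params$release_gain_per_hz * protocol$frequency_hz[k] *
      params$signal_clearance_tau * gains[k]
    on <- protocol$onset_s[k]
    off <- protocol$offset_s[k]
    rising <- times >= on & times < on + rise_time
    dff[rising] <- pmax(dff[rising], plateau * (times[rising] - on) / rise_time)
    high <- times >= on + rise_time & times <= off
    dff[high] <- pmax(dff[high], plateau)
    after <- times > off
    dff[after] <- pmax(dff[after],
                       plateau * exp(-(times[after] - off) /
                                       params$signal_clearance_tau))
  }
  model <- tibble::tibble(time_s = times, dff = dff)
  build_trace_table(times, dff, params, roi_class, condition, protocol,
                    ground_truth = model)
}

build_trace_table <- function(times, dff_true, params, roi_class, condition,
                              protocol, ground_truth) {
  nt <- length(times)
  df <- tidyr::expand_grid(
    roi_id = sprintf("roi%02d", seq_len(params$n_rois)),
    time_s = times
  )
  df$roi_class <- roi_class
  df$condition <- condition
  df$dff_true <- rep(dff_true, times = params$n_rois)
  noise <- if (params$noise_sd > 0) {
    stats::rnorm(nrow(df), 0, params$noise_sd)
  } else {
    0
  }
  df$f <- params$baseline_f * (1 + df$dff_true + noise)
  df <- df[, c("time_s", "roi_id", "roi_class", "condition", "f", "dff_true")]
  as_roi_traces(df, protocol, params, ground_truth)
}
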