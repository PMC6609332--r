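#' Per-trial dF/F peaks and latencies
#'
#' The in-stimulation peak of each trial is the maximum dF/F over
#' `[onset, offset]`; latency is the time of that maximum minus the onset
#' (ties resolved to the earliest frame). Post-offset maxima are ignored:
#' the read-out is the in-stimulation response.
#'
#' @param dff A `dff_traces` tibble (or any tibble with `time_s`, `roi_id`,
#'   `dff`).
#' @param protocol A [stim_protocol][make_protocol]; defaults to the one
#'   carried by `dff`.
#' @return A tibble with one row per ROI x trial: `roi_id`, `trial`,
#'   `peak`, `peak_time_s`, `latency_s`.
#' @export
trial_peaks <- function(dff, protocol = NULL) {
  protocol <- protocol %||% attr(dff, "protocol")
  check_trace_columns(dff, c("time_s", "roi_id", "dff"))
  check_windows_recorded(dff, protocol)
  purrr::map_dfr(seq_len(nrow(protocol)), function(k) {
    w <- dff$time_s >= protocol$onset_s[k] & dff$time_s <= protocol$offset_s[k]
    dff |>
      dplyr::filter(w) |>
      dplyr::arrange(.data$time_s) |>
      dplyr::summarise(
        trial = protocol$trial[k],
        peak = max(.data$dff),
        peak_time_s = .data$time_s[which.max(.data$dff)],
        .by = "roi_id"
      ) |>
      dplyr::mutate(latency_s = .data$peak_time_s - protocol$onset_s[k])
  }) |>
    dplyr::arrange(.data$roi_id, .data$trial)
}

check_windows_recorded <- function(dff, protocol) {
  if (is.null(protocol)) {
    stop("Supply `protocol` (the trace table carries none).", call. = FALSE)
  }
  if (!nrow(protocol)) return(invisible(protocol))
  tmin <- min(dff$time_s); tmax <- max(dff$time_s)
  if (min(protocol$onset_s) < tmin || max(protocol$offset_s) > tmax) {
    stop("Trial windows fall outside the recorded extent.", call. = FALSE)
  }
  invisible(protocol)
}

#' Trial and inter-stimulation dF/F integrals
#'
#' Trapezoidal integrals of dF/F over each stimulation trial window
#' `[onset, offset]` and each inter-stimulation interval `[offset, next
#' onset]`, on the actual frame times (robust to slightly irregular
#' sampling). A negative interval integral is the undershoot read-out.
#' Both the raw integral (dF/F x s) and the window-duration-normalised
#' value per second are reported.
#'
#' @inheritParams trial_peaks
#' @return Tibble with one row per ROI x window: `roi_id`, `window`
#'   (`"trial"`/`"interval"`), `index`, `start_s`, `end_s`, `integral`
#'   (dF/F x s), `integral_per_s`.
#' @export
interval_integrals <- function(dff, protocol = NULL) {
  protocol <- protocol %||% attr(dff, "protocol")
  check_trace_columns(dff, c("time_s", "roi_id", "dff"))
  check_windows_recorded(dff, protocol)
  windows <- protocol_windows(protocol)
  purrr::map_dfr(seq_len(nrow(windows)), function(i) {
    w <- dff$time_s >= windows$start_s[i] & dff$time_s <= windows$end_s[i]
    dff |>
      dplyr::filter(w) |>
      dplyr::arrange(.data$time_s) |>
      dplyr::summarise(
        window = windows$window[i],
        index = windows$index[i],
        start_s = windows$start_s[i],
        end_s = windows$end_s[i],
        integral = pracma::trapz(.data$time_s, .data$dff),
        .by = "roi_id"
      ) |>
      dplyr::mutate(integral_per_s = .data$integral /
                      (windows$end_s[i] - windows$start_s[i]))
  }) |>
    dplyr::arrange(.data$roi_id, .data$start_s, .data$window)
}

#' Tri-phasic segmentation of trial responses
#'
#' Segments each trial's response into the three phases of a release
#' reporter on a moving-average-smoothed trace: a rising phase from onset to
#' the in-stimulation peak; a falling onset, the first post-peak time from
#' which the smoothed trace declines monotonically for at least two frames
#' (for a release reporter this precedes stimulus offset as the releasable
#' pool depletes); an undershoot interval, the maximal contiguous span of
#' the following inter-stimulation interval with smoothed dF/F < `-eps`
#' (may be empty); and a recovery flag set when the trace re-enters
#' `[-eps, eps]` after the undershoot begins and before the next onset.
#' A degenerate trial (in-trial range below `eps`) is flagged undefined
#' rather than raising an error.
#'
#' @inheritParams trial_peaks
#' @param smooth_span Moving-average span in frames (odd; default 3).
#' @param eps dF/F tolerance around baseline (default 0.01).
#' @return Tibble with one row per ROI x trial: phase times (`peak_time_s`,
#'   `falling_onset_s`, `falling_lead_s` = offset - falling onset,
#'   `undershoot_start_s`, `undershoot_end_s`), `recovery` and
#'   `phases_defined`.
#' @export
segment_phases <- function(dff, protocol = NULL, smooth_span = 3, eps = 0.01) {
  protocol <- protocol %||% attr(dff, "protocol")
  check_trace_columns(dff, c("time_s", "roi_id", "dff"))
  check_windows_recorded(dff, protocol)
  if (smooth_span < 1 || smooth_span %% 2 != 1) {
    stop("`smooth_span` must be a positive odd number of frames.",
         call. = FALSE)
  }
  fi <- attr(protocol, "frame_interval_s") %||% 1
  if (nrow(protocol) &&
      any(protocol$duration_s < 5 * fi)) {
    stop("Each trial needs >= 5 frames for phase segmentation.",
         call. = FALSE)
  }
  post <- attr(protocol, "post_window_s") %||% 0
  extent <- attr(protocol, "extent_s") %||% max(dff$time_s)

  dff |>
    dplyr::arrange(.data$roi_id, .data$time_s) |>
    dplyr::group_split(.data$roi_id) |>
    purrr::map_dfr(function(tr) {
      sm <- smooth_ma(tr$dff, smooth_span)
      purrr::map_dfr(seq_len(nrow(protocol)), function(k) {
        segment_one_trial(tr$time_s, sm, protocol, k, eps, post, extent) |>
          dplyr::mutate(roi_id = tr$roi_id[1], .before = 1)
      })
    })
}

smooth_ma <- function(x, span) {
  if (span == 1) return(x)
  k <- rep(1 / span, span)
  sm <- stats::filter(x, k, sides = 2)
  sm <- as.numeric(sm)
  # shrink the window at the edges instead of dropping to NA
  half <- (span - 1) / 2
  n <- length(x)
  for (i in which(is.na(sm))) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    sm[i] <- mean(x[lo:hi])
  }
  sm
}

segment_one_trial <- function(times, sm, protocol, k, eps, post, extent) {
  onset <- protocol$onset_s[k]
  offset <- protocol$offset_s[k]
  next_onset <- if (k < nrow(protocol)) protocol$onset_s[k + 1] else
    min(offset + post, extent)
  in_trial <- which(times >= onset & times <= offset)
  undefined <- tibble::tibble(
    trial = protocol$trial[k], phases_defined = FALSE,
    peak_time_s = NA_real_, falling_onset_s = NA_real_,
    falling_lead_s = NA_real_, undershoot_start_s = NA_real_,
    undershoot_end_s = NA_real_, recovery = NA
  )
  if (length(in_trial) < 2 ||
      diff(range(sm[in_trial])) < eps) {
    return(undefined)
  }
  pk <- in_trial[which.max(sm[in_trial])]
  # first post-peak index from which the smoothed trace declines for >= 2
  # consecutive frames
  fall_idx <- NA_integer_
  post_peak <- which(times > times[pk] & times <= next_onset)
  for (i in post_peak) {
    if (i + 2 <= length(sm) && sm[i + 1] < sm[i] && sm[i + 2] < sm[i + 1]) {
      fall_idx <- i
      break
    }
  }
  interval_idx <- which(times >= offset & times <= next_onset)
  under <- interval_idx[sm[interval_idx] < -eps]
  if (length(under)) {
    # maximal contiguous run containing the deepest excursion
    runs <- split(under, cumsum(c(1, diff(under) != 1)))
    depth <- vapply(runs, function(r) min(sm[r]), numeric(1))
    run <- runs[[which.min(depth)]]
    u_start <- times[run[1]]
    u_end <- times[run[length(run)]]
    after <- interval_idx[times[interval_idx] > u_start]
    recovery <- any(abs(sm[after]) <= eps)
  } else {
    u_start <- NA_real_
    u_end <- NA_real_
    recovery <- NA
  }
  tibble::tibble(
    trial = protocol$trial[k], phases_defined = TRUE,
    peak_time_s = times[pk],
    falling_onset_s = if (is.na(fall_idx)) NA_real_ else times[fall_idx],
    falling_lead_s = if (is.na(fall_idx)) NA_real_ else offset - times[fall_idx],
    undershoot_start_s = u_start, undershoot_end_s = u_end,
    recovery = recovery
  )
}

#' Normalise peak responses across stimulation frequencies
#'
#' Expresses in-stimulation response peaks measured at a series of
#' stimulation frequencies as a percentage of the peak at a reference
#' frequency (70 Hz by default), enabling direct comparison across
#' preparations.
#'
#' @param peaks Data frame with columns `frequency_hz` and `peak`
#'   (one row per frequency; frequencies must be unique).
#' @param reference Reference frequency in Hz (must be present with a
#'   positive peak).
#' @return A `freq_response` tibble with `frequency_hz`, `peak`,
#'   `norm_pct` (100 at the reference), ordered by frequency; the reference
#'   is stored as attribute `reference_hz`.
#' @examples
#' normalize_frequency_response(
#'   tibble::tibble(frequency_hz = c(35, 70), peak = c(0.4, 0.8)))
#' @export
normalize_frequency_response <- function(peaks, reference = 70) {
  if (!all(c("frequency_hz", "peak") %in% names(peaks))) {
    stop("`peaks` needs columns `frequency_hz` and `peak`.", call. = FALSE)
  }
  if (anyDuplicated(peaks$frequency_hz)) {
    stop("Frequencies must be unique.", call. = FALSE)
  }
  ref_idx <- which(peaks$frequency_hz == reference)
  if (!length(ref_idx)) {
    stop(sprintf("Reference frequency %g Hz is absent.", reference),
         call. = FALSE)
  }
  ref_peak <- peaks$peak[ref_idx]
  if (!is.finite(ref_peak) || ref_peak <= 0) {
    stop("The reference-frequency peak must be positive.", call. = FALSE)
  }
  out <- peaks |>
    tibble::as_tibble() |>
    dplyr::mutate(norm_pct = 100 * .data$peak / ref_peak) |>
    dplyr::arrange(.data$frequency_hz)
  structure(out, reference_hz = reference,
            class = c("freq_response", class(tibble::tibble())))
}

#' Bouton / inter-bouton dF/F contrast ratio
#'
#' For each stimulation trial, the frame-wise ratio of the mean bouton dF/F
#' to the mean inter-bouton dF/F is averaged over the frames of the trial
#' window, using only frames where the denominator is at least `floor`
#' (near-zero denominators are excluded and the excluded fraction
#' reported). A ratio near 1 indicates a signal that does not distinguish
#' boutons (as for a cytosolic calcium indicator); a high ratio indicates a
#' bouton-enriched signal, as expected where DCVs reside.
#'
#' @param dff A `dff_traces` tibble whose `roi_class` column contains both
#'   `"bouton"` and `"inter_bouton"` ROIs.
#' @inheritParams trial_peaks
#' @param floor Minimum inter-bouton mean dF/F for a frame to enter the
#'   ratio (default 0.01).
#' @return Tibble with one row per trial: `trial`, `ratio`, `n_frames`,
#'   `n_excluded`, `frac_excluded`, `defined` (FALSE when every frame was
#'   excluded, in which case `ratio` is `NA`).
#' @export
bouton_ibi_ratio <- function(dff, protocol = NULL, floor = 0.01) {
  protocol <- protocol %||% attr(dff, "protocol")
  check_trace_columns(dff, c("time_s", "roi_id", "roi_class", "dff"))
  check_windows_recorded(dff, protocol)
  classes <- unique(dff$roi_class)
  if (!all(c("bouton", "inter_bouton") %in% classes)) {
    stop("Need at least one `bouton` and one `inter_bouton` trace.",
         call. = FALSE)
  }
  by_frame <- dff |>
    dplyr::filter(.data$roi_class %in% c("bouton", "inter_bouton")) |>
    dplyr::summarise(mean_dff = mean(.data$dff),
                     .by = c("time_s", "roi_class")) |>
    tidyr::pivot_wider(names_from = "roi_class", values_from = "mean_dff")

  purrr::map_dfr(seq_len(nrow(protocol)), function(k) {
    fr <- by_frame |>
      dplyr::filter(.data$time_s >= protocol$onset_s[k],
                    .data$time_s <= protocol$offset_s[k])
    keep <- !is.na(fr$inter_bouton) & fr$inter_bouton >= floor
    n_excl <- sum(!keep)
    tibble::tibble(
      trial = protocol$trial[k],
      ratio = if (any(keep)) {
        mean(fr$bouton[keep] / fr$inter_bouton[keep])
      } else {
        NA_real_
      },
      n_frames = nrow(fr),
      n_excluded = n_excl,
      frac_excluded = n_excl / nrow(fr),
      defined = any(keep)
    )
  })
}
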