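#' Convert raw ROI fluorescence to dF/F
#'
#' Normalises each ROI's raw fluorescence to its pre-stimulation background:
#' `dF/F(t) = (F(t) - F0) / F0` with `F0` the mean raw fluorescence over the
#' baseline window. By default the baseline window runs from the start of
#' the recording to 2 s before the first trial onset (the whole
#' pre-stimulation background span minus a guard).
#'
#' @param traces Long-form trace table with columns `time_s`, `roi_id` and
#'   `f` (raw fluorescence); typically a `roi_traces` tibble from the
#'   simulators or [read_trace_table()].
#' @param protocol A [stim_protocol][make_protocol]; taken from the trace
#'   attributes when omitted.
#' @param baseline_window Length-2 numeric `[start, end]` in seconds, or
#'   `NULL` for the default window.
#' @return A `dff_traces` tibble: the input plus a `dff` column, with the
#'   per-ROI baselines (`roi_id`, `f0`) and the window stored as attributes
#'   `baseline` and `baseline_window`.
#' @examples
#' pr <- make_protocol()
#' tr <- simulate_nprr_traces(pr, trace_sim_params())
#' dff <- compute_dff(tr)
#' attr(dff, "baseline_window")
#' @export
compute_dff <- function(traces, protocol = NULL, baseline_window = NULL) {
  protocol <- protocol %||% attr(traces, "protocol")
  if (is.null(protocol)) {
    stop("Supply `protocol` (the trace table carries none).", call. = FALSE)
  }
  check_trace_columns(traces, c("time_s", "roi_id", "f"))
  if (is.null(baseline_window)) {
    first_onset <- if (nrow(protocol)) min(protocol$onset_s) else
      attr(protocol, "extent_s")
    baseline_window <- c(0, first_onset - 2)
  }
  if (length(baseline_window) != 2 ||
      baseline_window[2] <= baseline_window[1]) {
    stop("`baseline_window` must be an increasing [start, end] pair.",
         call. = FALSE)
  }
  if (nrow(protocol) && baseline_window[2] > min(protocol$onset_s)) {
    stop("The baseline window must precede the first trial onset.",
         call. = FALSE)
  }

  in_win <- traces$time_s >= baseline_window[1] &
    traces$time_s <= baseline_window[2]
  baseline <- traces |>
    dplyr::filter(in_win) |>
    dplyr::summarise(f0 = mean(.data$f), n_frames = dplyr::n(),
                     .by = "roi_id")
  if (!nrow(baseline) || any(baseline$n_frames < 3)) {
    stop("Degenerate baseline: the window must contain >= 3 frames per ROI.",
         call. = FALSE)
  }
  if (any(baseline$f0 <= 0)) {
    stop("Degenerate baseline: mean baseline fluorescence must be > 0.",
         call. = FALSE)
  }

  out <- traces |>
    dplyr::left_join(baseline[, c("roi_id", "f0")], by = "roi_id") |>
    dplyr::mutate(dff = (.data$f - .data$f0) / .data$f0) |>
    dplyr::select(-"f0")
  as_dff_traces(out, protocol,
                baseline = baseline[, c("roi_id", "f0")],
                baseline_window = baseline_window,
                source = traces)
}

as_dff_traces <- function(df, protocol, baseline = NULL,
                          baseline_window = NULL, source = NULL) {
  structure(
    tibble::as_tibble(df),
    protocol = protocol,
    baseline = baseline %||% attr(source, "baseline"),
    baseline_window = baseline_window %||% attr(source, "baseline_window"),
    params = attr(source, "params"),
    ground_truth = attr(source, "ground_truth"),
    class = c("dff_traces", class(tibble::tibble()))
  )
}

check_trace_columns <- function(traces, cols) {
  missing <- setdiff(cols, names(traces))
  if (length(missing)) {
    stop("Trace table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(traces)
}

#' Per-trial baseline correction of dF/F
#'
#' Re-references each trial to its own immediate pre-stimulation level:
#' for every trial, the mean dF/F over the `pre_span` seconds just before
#' onset is subtracted from all samples from that onset up to the next
#' trial's onset (through the end of the recording for the last trial).
#' Samples before the first trial are unchanged. This is the correction
#' used when successive trials ride on a drifting baseline, so that peak
#' heights are measured above the pre-stimulation level of their own trial.
#' Subtraction (not division) keeps dF/F units and remains stable when the
#' pre-trial mean sits near zero after an undershoot.
#'
#' @details
#' Each trial's corrected segment runs from the start of its own pre-onset
#' window to the start of the next trial's pre-onset window (through the end
#' of the recording for the last trial), so that after correction every
#' trial's 5 s pre-onset mean is exactly zero and re-applying the correction
#' changes nothing. Samples before the first trial's pre-onset window are
#' unchanged.
#'
#' @param dff A `dff_traces` tibble from [compute_dff()].
#' @param protocol A [stim_protocol][make_protocol]; defaults to the one
#'   carried by `dff`.
#' @param pre_span Seconds of pre-onset dF/F averaged per trial (default 5).
#' @return A `dff_traces` tibble with corrected `dff`; the per-ROI,
#'   per-trial offsets are stored as attribute `trial_baseline`.
#' @export
correct_trial_baseline <- function(dff, protocol = NULL, pre_span = 5) {
  protocol <- protocol %||% attr(dff, "protocol")
  check_trace_columns(dff, c("time_s", "roi_id", "dff"))
  if (pre_span <= 0) stop("`pre_span` must be > 0.", call. = FALSE)
  if (!nrow(protocol)) return(dff)
  times <- sort(unique(dff$time_s))
  offsets <- list()
  out <- dff
  n <- nrow(protocol)
  seg_start <- protocol$onset_s - pre_span
  for (k in seq_len(n)) {
    onset <- protocol$onset_s[k]
    pre_idx <- dff$time_s >= seg_start[k] & dff$time_s < onset
    if (!any(pre_idx) || min(times) > seg_start[k]) {
      stop(sprintf(
        "Trial %d lacks %.3g s of pre-onset recording for baseline correction.",
        protocol$trial[k], pre_span), call. = FALSE)
    }
    base_k <- dff |>
      dplyr::filter(pre_idx) |>
      dplyr::summarise(offset = mean(.data$dff), .by = "roi_id") |>
      dplyr::mutate(trial = protocol$trial[k])
    offsets[[k]] <- base_k
    upper <- if (k < n) seg_start[k + 1] else Inf
    span_idx <- out$time_s >= seg_start[k] & out$time_s < upper
    shift <- base_k$offset[match(out$roi_id[span_idx], base_k$roi_id)]
    out$dff[span_idx] <- out$dff[span_idx] - shift
  }
  attr(out, "trial_baseline") <- dplyr::bind_rows(offsets)
  out
}

#' Average dF/F traces across ROIs
#'
#' Per-frame mean and standard error across a set of dF/F traces sharing a
#' frame vector, as used for the averaged-bouton trace with its s.e.m.
#' envelope. The standard error uses the n-1 sample standard deviation; a
#' single-trace input returns `sem = 0` with a warning (flagged in the
#' `single_trace` attribute) rather than failing.
#'
#' @param dff A `dff_traces` (or any tibble with `time_s`, `roi_id`, `dff`).
#' @return Tibble with `time_s`, `mean_dff`, `sem_dff`, `n_roi`.
#' @export
aggregate_mean_sem <- function(dff) {
  check_trace_columns(dff, c("time_s", "roi_id", "dff"))
  frames <- dff |>
    dplyr::summarise(key = paste(.data$time_s, collapse = ","),
                     .by = "roi_id")
  if (length(unique(frames$key)) > 1) {
    stop("All ROIs must share the same frame vector.", call. = FALSE)
  }
  single <- length(unique(dff$roi_id)) == 1
  if (single) {
    warning("Only one ROI: s.e.m. reported as 0.", call. = FALSE)
  }
  out <- dff |>
    dplyr::summarise(
      mean_dff = mean(.data$dff),
      sem_dff = if (dplyr::n() > 1) {
        stats::sd(.data$dff) / sqrt(dplyr::n())
      } else {
        0
      },
      n_roi = dplyr::n(),
      .by = "time_s"
    ) |>
    dplyr::arrange(.data$time_s)
  attr(out, "single_trace") <- single
  attr(out, "protocol") <- attr(dff, "protocol")
  out
}

#' Fold-change expression screen
#'
#' Screening rule for reporter candidates: a candidate passes when its
#' fluorescence reaches at least `threshold`-fold the reference level
#' (background autofluorescence for expression screening, the mean
#' pre-stimulation baseline for functional screening).
#'
#' @param signal Candidate fluorescence (vectorised).
#' @param reference Reference fluorescence (> 0; recycled).
#' @param threshold Fold-change required to pass (default 2).
#' @return Tibble with `signal`, `reference`, `fold`, `pass`.
#' @export
fold_change_screen <- function(signal, reference, threshold = 2) {
  if (any(!is.finite(reference)) || any(reference <= 0)) {
    stop("`reference` must be positive.", call. = FALSE)
  }
  tibble::tibble(
    signal = signal,
    reference = rep_len(reference, length(signal)),
    fold = signal / rep_len(reference, length(signal)),
    pass = signal / rep_len(reference, length(signal)) >= threshold
  )
}
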