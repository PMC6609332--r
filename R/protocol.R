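#' Build a stimulation protocol
#'
#' A stimulation protocol is the time base for every downstream analysis: an
#' ordered set of electrical stimulation trials (onset, duration, frequency,
#' pulse width) flanked by a pre-stimulation window (used for the baseline)
#' and a post-stimulation window, sampled at a fixed frame interval.
#'
#' Trial `k` (1-based) starts at `pre_window + (k - 1) * (stim_duration +
#' interval)`. The total recording extent is `pre_window + n_trials *
#' stim_duration + (n_trials - 1) * interval + post_window` (for zero trials,
#' `pre_window + post_window`).
#'
#' @param n_trials Number of stimulation trials (>= 0).
#' @param stim_duration Duration of each trial in seconds.
#' @param interval Inter-stimulation interval (offset to next onset), seconds.
#' @param frequency Stimulation frequency in Hz, recycled across trials.
#' @param pre_window Seconds of recording before the first onset.
#' @param post_window Seconds of recording after the last offset.
#' @param frame_interval Sampling interval in seconds (1 s for 1 fps imaging).
#' @param pulse_width Stimulation pulse width in milliseconds.
#'
#' @return A `stim_protocol`: a tibble with one row per trial (`trial`,
#'   `onset_s`, `offset_s`, `duration_s`, `frequency_hz`, `pulse_width_ms`)
#'   and attributes `pre_window_s`, `post_window_s`, `frame_interval_s`,
#'   `extent_s`.
#' @examples
#' make_protocol(4, 18, 42, 70, pre_window = 30, post_window = 30)
#' @export
make_protocol <- function(n_trials = 4, stim_duration = 18, interval = 42,
                          frequency = 70, pre_window = 30, post_window = 30,
                          frame_interval = 1, pulse_width = 1) {
  if (length(n_trials) != 1 || is.na(n_trials) || n_trials < 0 ||
      n_trials != round(n_trials)) {
    stop("`n_trials` must be a single non-negative integer.", call. = FALSE)
  }
  if (pre_window < 0 || post_window < 0) {
    stop("`pre_window` and `post_window` must be >= 0.", call. = FALSE)
  }
  if (frame_interval <= 0) {
    stop("`frame_interval` must be > 0.", call. = FALSE)
  }
  if (n_trials > 0) {
    if (any(stim_duration <= 0)) stop("`stim_duration` must be > 0.", call. = FALSE)
    if (any(interval < 0)) stop("`interval` must be >= 0.", call. = FALSE)
    if (any(frequency <= 0)) stop("`frequency` must be > 0.", call. = FALSE)
    if (any(pulse_width <= 0)) stop("`pulse_width` must be > 0.", call. = FALSE)
  }

  if (n_trials == 0) {
    trials <- tibble::tibble(
      trial = integer(), onset_s = double(), offset_s = double(),
      duration_s = double(), frequency_hz = double(), pulse_width_ms = double()
    )
    extent <- pre_window + post_window
  } else {
    onset <- pre_window + (seq_len(n_trials) - 1) * (stim_duration + interval)
    trials <- tibble::tibble(
      trial = seq_len(n_trials),
      onset_s = onset,
      offset_s = onset + stim_duration,
      duration_s = rep_len(stim_duration, n_trials),
      frequency_hz = rep_len(frequency, n_trials),
      pulse_width_ms = rep_len(pulse_width, n_trials)
    )
    extent <- pre_window + n_trials * stim_duration +
      (n_trials - 1) * interval + post_window
  }
  stim_protocol(trials, pre_window = pre_window, post_window = post_window,
                frame_interval = frame_interval, extent = extent)
}

#' Construct a stimulation protocol from a trial table
#'
#' Lower-level constructor used by [make_protocol()] and by readers of
#' protocol files; validates ordering and non-overlap of trials.
#'
#' @param trials Data frame with columns `trial`, `onset_s`, `offset_s`,
#'   `duration_s`, `frequency_hz`, `pulse_width_ms` (irregular spacing and
#'   per-trial frequencies are allowed).
#' @param pre_window,post_window,frame_interval See [make_protocol()].
#' @param extent Total recording extent in seconds; computed from the trial
#'   table and windows when `NULL`.
#' @return A `stim_protocol` tibble.
#' @export
stim_protocol <- function(trials, pre_window = 30, post_window = 30,
                          frame_interval = 1, extent = NULL) {
  trials <- tibble::as_tibble(trials)
  needed <- c("trial", "onset_s", "offset_s", "duration_s", "frequency_hz",
              "pulse_width_ms")
  missing <- setdiff(needed, names(trials))
  if (length(missing)) {
    stop("Protocol trial table lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(trials) > 0) {
    if (is.unsorted(trials$onset_s, strictly = TRUE) && nrow(trials) > 1) {
      stop("Trials must be sorted by onset.", call. = FALSE)
    }
    if (any(trials$duration_s <= 0) || any(trials$frequency_hz <= 0)) {
      stop("Trial durations and frequencies must be > 0.", call. = FALSE)
    }
    if (nrow(trials) > 1 &&
        any(trials$offset_s[-nrow(trials)] > trials$onset_s[-1])) {
      stop("Stimulation trials must not overlap.", call. = FALSE)
    }
  }
  if (is.null(extent)) {
    extent <- if (nrow(trials)) max(trials$offset_s) + post_window else
      pre_window + post_window
  }
  structure(
    trials,
    pre_window_s = pre_window,
    post_window_s = post_window,
    frame_interval_s = frame_interval,
    extent_s = extent,
    class = c("stim_protocol", class(tibble::tibble()))
  )
}

#' Frame times implied by a protocol
#'
#' @param protocol A `stim_protocol`.
#' @return Numeric vector of sample times in seconds, starting at 0 and
#'   spaced by the protocol's frame interval up to the recording extent.
#' @export
protocol_frames <- function(protocol) {
  fi <- attr(protocol, "frame_interval_s")
  extent <- attr(protocol, "extent_s")
  fi * seq.int(0L, floor(extent / fi + 1e-9))
}

#' Trial and inter-stimulation analysis windows
#'
#' Returns the windows the release metrics integrate over: one `trial` window
#' per stimulation trial (`[onset, offset]`) and one `interval` window per
#' inter-stimulation interval (`[offset, next onset]`; the last interval runs
#' from the final offset to the end of the post-stimulation window, capped at
#' the recording extent).
#'
#' @param protocol A `stim_protocol`.
#' @return Tibble with columns `window` (`"trial"`/`"interval"`), `index`,
#'   `start_s`, `end_s`.
#' @export
protocol_windows <- function(protocol) {
  if (nrow(protocol) == 0) {
    return(tibble::tibble(window = character(), index = integer(),
                          start_s = double(), end_s = double()))
  }
  extent <- attr(protocol, "extent_s")
  post <- attr(protocol, "post_window_s")
  n <- nrow(protocol)
  trial_w <- tibble::tibble(
    window = "trial", index = protocol$trial,
    start_s = protocol$onset_s, end_s = protocol$offset_s
  )
  int_end <- c(if (n > 1) protocol$onset_s[-1],
               min(protocol$offset_s[n] + post, extent))
  int_w <- tibble::tibble(
    window = "interval", index = protocol$trial,
    start_s = protocol$offset_s, end_s = int_end
  )
  dplyr::arrange(dplyr::bind_rows(trial_w, int_w), .data$start_s, .data$window)
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf(
    "<stim_protocol> %d trial(s), extent %.5g s (pre %.5g s, post %.5g s, frame %.5g s)\n",
    nrow(x), attr(x, "extent_s"), attr(x, "pre_window_s"),
    attr(x, "post_window_s"), attr(x, "frame_interval_s")))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}
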