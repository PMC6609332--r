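# Shared fixtures: the study's stimulation layout (four 70 Hz trials of
# 18 s separated by 42 s, 1 fps) and a hand-buildable trace table.

default_protocol <- function(...) {
  make_protocol(4, 18, 42, 70, pre_window = 30, post_window = 30,
                frame_interval = 1, ...)
}

# A single-ROI dff_traces object built from an explicit dff vector.
manual_dff <- function(times, dff, protocol, roi_id = "roi01",
                       roi_class = "bouton") {
  df <- tibble::tibble(
    time_s = times, roi_id = roi_id, roi_class = roi_class,
    condition = "manual", f = 100 * (1 + dff), dff = dff
  )
  structure(df, protocol = protocol,
            class = c("dff_traces", class(tibble::tibble())))
}

# Raw-trace tibble from an explicit fluorescence vector.
manual_traces <- function(times, f, roi_id = "roi01") {
  tibble::tibble(time_s = times, roi_id = roi_id, roi_class = "bouton",
                 condition = "manual", f = f)
}
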