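# Readers/writers for the package's plain-text exchange formats: long-form
# tab-delimited trace tables, JSON protocols/annotations/reports. Times are
# seconds, EM coordinates nm, areas um^2 throughout.

#' Read and write long-form ROI trace tables
#'
#' Trace tables are tab-delimited text with header columns `time_s`,
#' `roi_id`, `roi_class`, `condition`, `f` (raw fluorescence, arbitrary
#' units); a `dff_true` ground-truth column from the simulator is preserved
#' when present. On reading, sample times must be strictly increasing
#' within each ROI and fluorescence finite and non-negative.
#'
#' @param traces A trace tibble (e.g. from [simulate_nprr_traces()]).
#' @param path File path.
#' @return `read_trace_table()` returns a tibble; `write_trace_table()`
#'   returns `path` invisibly.
#' @export
write_trace_table <- function(traces, path) {
  check_trace_columns(traces, c("time_s", "roi_id", "roi_class",
                                "condition", "f"))
  readr::write_tsv(tibble::as_tibble(traces), path)
  invisible(path)
}

#' @rdname write_trace_table
#' @export
read_trace_table <- function(path) {
  tr <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_trace_columns(tr, c("time_s", "roi_id", "roi_class", "condition", "f"))
  if (any(!is.finite(tr$f)) || any(tr$f < 0)) {
    stop("Column `f` must be finite and >= 0.", call. = FALSE)
  }
  bad <- tr |>
    dplyr::summarise(ok = !is.unsorted(.data$time_s, strictly = TRUE),
                     .by = "roi_id")
  if (any(!bad$ok)) {
    stop("Sample times must be strictly increasing within each ROI.",
         call. = FALSE)
  }
  tr
}

#' Read and write stimulation protocols as JSON
#'
#' @param protocol A [stim_protocol][make_protocol].
#' @param path File path.
#' @return `read_protocol_json()` returns a `stim_protocol`;
#'   `write_protocol_json()` returns `path` invisibly.
#' @export
write_protocol_json <- function(protocol, path) {
  obj <- list(
    units = list(time = "s", frequency = "Hz", pulse_width = "ms"),
    pre_window_s = attr(protocol, "pre_window_s"),
    post_window_s = attr(protocol, "post_window_s"),
    frame_interval_s = attr(protocol, "frame_interval_s"),
    extent_s = attr(protocol, "extent_s"),
    trials = tibble::as_tibble(protocol)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_protocol_json
#' @export
read_protocol_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  trials <- tibble::as_tibble(obj$trials)
  if (!nrow(trials)) {
    trials <- tibble::tibble(trial = integer(), onset_s = double(),
                             offset_s = double(), duration_s = double(),
                             frequency_hz = double(), pulse_width_ms = double())
  }
  stim_protocol(trials,
                pre_window = obj$pre_window_s,
                post_window = obj$post_window_s,
                frame_interval = obj$frame_interval_s,
                extent = obj$extent_s)
}

#' Read and write EM annotations as JSON
#'
#' The JSON layout mirrors [em_annotation()]: point lists for gold and DCV
#' centres (nm), the bouton outline polygon (nm, `null` for control
#' images), the image area (um^2) and the stereological radii.
#'
#' @param ann An [em_annotation()].
#' @param path File path.
#' @return `read_em_annotation_json()` returns an `em_annotation`;
#'   the writer returns `path` invisibly.
#' @export
write_em_annotation_json <- function(ann, path) {
  stopifnot(inherits(ann, "em_annotation"))
  obj <- list(
    units = list(coordinates = "nm", area = "um^2"),
    image_id = ann$image_id,
    image_area_um2 = ann$image_area,
    dcv_disc_radius_nm = ann$dcv_disc_radius,
    membrane_band_halfwidth_nm = ann$membrane_band_halfwidth,
    gold = ann$gold,
    dcv_centers = ann$dcv_centers,
    bouton_outline = if (is.null(ann$bouton_outline)) NULL else
      as.data.frame(ann$bouton_outline) |>
        stats::setNames(c("x_nm", "y_nm"))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_em_annotation_json
#' @export
read_em_annotation_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  gold <- tibble::as_tibble(obj$gold)
  if (!nrow(gold)) gold <- tibble::tibble(x_nm = double(), y_nm = double())
  dcv <- tibble::as_tibble(obj$dcv_centers)
  if (!nrow(dcv)) dcv <- tibble::tibble(x_nm = double(), y_nm = double())
  em_annotation(
    gold = gold,
    dcv_centers = dcv,
    bouton_outline = if (is.null(obj$bouton_outline) ||
                         !length(obj$bouton_outline)) NULL else
      as.matrix(as.data.frame(obj$bouton_outline)),
    image_area = obj$image_area_um2,
    image_id = obj$image_id,
    dcv_disc_radius = obj$dcv_disc_radius_nm,
    membrane_band_halfwidth = obj$membrane_band_halfwidth_nm
  )
}

#' Write a density report as JSON
#'
#' @param report A [density_report()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_density_report_json <- function(report, path) {
  stopifnot(inherits(report, "density_report"))
  obj <- list(
    units = list(density = "gold/um^2", area = "um^2"),
    pooling = report$pooling,
    subtract_dcv_area = report$subtract_dcv_area,
    bouton_area_method = report$bouton_area_method,
    n_images = report$n_images,
    dcv_over_bouton = report$dcv_over_bouton,
    ratios = report$ratios,
    compartments = report$compartments,
    per_image = report$per_image,
    background = report$background
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      stop(sprintf("Config file `%s` does not exist.", config), call. = FALSE)
    }
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) {
    stop("`config` must be a list or the path to a JSON file.", call. = FALSE)
  }
  config
}

config_protocol <- function(config) {
  if (!is.null(config$protocol_file)) {
    read_protocol_json(config$protocol_file)
  } else {
    do.call(make_protocol, config$protocol %||% list())
  }
}

write_manifest <- function(out_dir, stage, config, files) {
  manifest <- list(stage = stage, seed = config$seed,
                   options = config[setdiff(names(config), "out_dir")],
                   files = files)
  path <- file.path(out_dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest
}

#' Run the trace-simulation stage from a configuration
#'
#' Generates a stimulation protocol and a synthetic ROI trace set, writing
#' the trace table (`traces.tsv`), the protocol (`protocol.json`) and a
#' ground-truth sidecar (`ground_truth.json`, the full generator parameter
#' set plus the noiseless model trace) into the output directory, together
#' with a manifest echoing all options for provenance. Identical config and
#' seed produce identical files.
#'
#' @param config A list or path to a JSON file with elements `protocol`
#'   (arguments to [make_protocol()]) or `protocol_file`, `params`
#'   (arguments to [trace_sim_params()]), `mode` (`"nprr"`, `"gcamp"` or
#'   `"tnt"`), `seed`, and optionally `roi_class` and `condition`.
#' @param out_dir Output directory (created if needed); defaults to
#'   `config$out_dir`.
#' @return The manifest list, invisibly.
#' @export
run_simulate_traces <- function(config, out_dir = NULL) {
  config <- load_config(config)
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("No output directory given.", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  protocol <- config_protocol(config)
  mode <- config$mode %||% "nprr"
  par_args <- as.list(config$params %||% list())
  if (!is.null(config$seed) && is.null(par_args$seed)) {
    par_args$seed <- config$seed
  }
  if (mode == "tnt") par_args$mode <- "tnt"
  params <- do.call(trace_sim_params, par_args)
  traces <- if (mode == "gcamp") {
    simulate_gcamp_traces(protocol, params,
                          roi_class = config$roi_class %||% "bouton",
                          condition = config$condition %||% "GCaMP6s")
  } else {
    simulate_nprr_traces(protocol, params,
                         roi_class = config$roi_class %||% "bouton",
                         condition = config$condition %||%
                           switch(mode, tnt = "NPRR+TNT", "NPRR"))
  }

  files <- list(
    traces = file.path(out_dir, "traces.tsv"),
    protocol = file.path(out_dir, "protocol.json"),
    ground_truth = file.path(out_dir, "ground_truth.json")
  )
  write_trace_table(traces, files$traces)
  write_protocol_json(protocol, files$protocol)
  jsonlite::write_json(
    list(params = unclass(attr(traces, "params")), mode = mode,
         model_trace = attr(traces, "ground_truth")),
    files$ground_truth, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(write_manifest(out_dir, "simulate_traces", config, files))
}

#' Run the dF/F metrics stage from a configuration
#'
#' Reads a trace table and protocol, computes dF/F against the
#' pre-stimulation baseline (optionally followed by per-trial baseline
#' correction), and writes the dF/F table, per-trial peak/latency and
#' integral tables, the tri-phasic segmentation, the ROI-averaged
#' mean +/- s.e.m. trace, and a JSON report (including a frequency-response
#' normalisation when trials span several frequencies, and the comparison
#' of inter-stimulation undershoot integrals against zero).
#'
#' @param config A list or JSON path with `traces` (path), `protocol_file`
#'   or `protocol`, and optional `baseline_window`, `trial_baseline`
#'   (logical), `pre_span`, `smooth_span`, `eps`, `floor`,
#'   `reference_frequency`, `seed`.
#' @param out_dir Output directory; defaults to `config$out_dir`.
#' @return The manifest list, invisibly.
#' @export
run_metrics <- function(config, out_dir = NULL) {
  config <- load_config(config)
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("No output directory given.", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config$traces)) stop("`config$traces` is required.", call. = FALSE)

  traces <- read_trace_table(config$traces)
  if (!nrow(traces)) stop("Empty trace table.", call. = FALSE)
  protocol <- config_protocol(config)

  dff <- compute_dff(traces, protocol,
                     baseline_window = config$baseline_window)
  if (isTRUE(config$trial_baseline)) {
    dff <- correct_trial_baseline(dff, protocol,
                                  pre_span = config$pre_span %||% 5)
  }
  peaks <- trial_peaks(dff, protocol)
  integrals <- interval_integrals(dff, protocol)
  phases <- segment_phases(dff, protocol,
                           smooth_span = config$smooth_span %||% 3,
                           eps = config$eps %||% 0.01)
  avg <- suppressWarnings(aggregate_mean_sem(dff))

  freq_resp <- NULL
  if (length(unique(protocol$frequency_hz)) > 1) {
    by_freq <- peaks |>
      dplyr::left_join(tibble::as_tibble(protocol)[, c("trial", "frequency_hz")],
                       by = "trial") |>
      dplyr::summarise(peak = mean(.data$peak), .by = "frequency_hz")
    freq_resp <- normalize_frequency_response(
      by_freq, reference = config$reference_frequency %||% 70)
  }

  undershoot <- integrals |>
    dplyr::filter(.data$window == "interval") |>
    dplyr::summarise(total = sum(.data$integral), .by = "roi_id")
  undershoot_test <- if (nrow(undershoot) >= 2 &&
                         stats::sd(undershoot$total) > 0) {
    tidy.nprr_comparison(one_sample_t(undershoot$total, mu0 = 0))
  } else {
    NULL
  }

  files <- list(
    dff = file.path(out_dir, "dff.tsv"),
    mean_sem = file.path(out_dir, "dff_mean_sem.tsv"),
    trial_metrics = file.path(out_dir, "trial_metrics.tsv"),
    integrals = file.path(out_dir, "interval_integrals.tsv"),
    phases = file.path(out_dir, "phase_segmentation.tsv"),
    report = file.path(out_dir, "metrics.json")
  )
  readr::write_tsv(tibble::as_tibble(dff), files$dff)
  readr::write_tsv(avg, files$mean_sem)
  readr::write_tsv(peaks, files$trial_metrics)
  readr::write_tsv(integrals, files$integrals)
  readr::write_tsv(phases, files$phases)
  jsonlite::write_json(
    list(
      options = list(
        baseline_window = attr(dff, "baseline_window"),
        trial_baseline = isTRUE(config$trial_baseline),
        pre_span = config$pre_span %||% 5,
        smooth_span = config$smooth_span %||% 3,
        eps = config$eps %||% 0.01,
        reference_frequency = config$reference_frequency %||% 70,
        seed = config$seed,
        baseline_statistic = "mean"
      ),
      trial_peaks = peaks,
      undershoot_vs_zero = undershoot_test,
      frequency_response = if (!is.null(freq_resp))
        tibble::as_tibble(freq_resp)
    ),
    files$report, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(write_manifest(out_dir, "metrics", config, files))
}

#' Run the stereology stage from a configuration
#'
#' Reads EM annotation JSON files, assembles the labelling-density report
#' (with background estimation from control annotations when given) and
#' writes `density_report.json` plus a per-compartment summary table.
#'
#' @param config A list or JSON path with `annotations` (character vector
#'   of annotation JSON paths; may be empty when only controls are given),
#'   optional `controls` (control annotation paths), `pooling`,
#'   `subtract_dcv_area`, `bouton_area_method`, `grid_spacing_nm`,
#'   `background_threshold`, `seed`.
#' @param out_dir Output directory; defaults to `config$out_dir`.
#' @return The manifest list, invisibly.
#' @export
run_stereology <- function(config, out_dir = NULL) {
  config <- load_config(config)
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("No output directory given.", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  read_all <- function(paths) {
    lapply(paths, function(p) {
      if (!file.exists(p)) {
        stop(sprintf("Annotation file `%s` does not exist.", p), call. = FALSE)
      }
      tryCatch(read_em_annotation_json(p), error = function(e) {
        stop(sprintf("Invalid annotation `%s`: %s", p, conditionMessage(e)),
             call. = FALSE)
      })
    })
  }
  anns <- read_all(config$annotations %||% character())
  controls <- read_all(config$controls %||% character())
  if (!length(anns) && !length(controls)) {
    stop("No annotation or control files given.", call. = FALSE)
  }

  bg <- if (length(controls)) {
    background_density(controls,
                       threshold = config$background_threshold %||% 0.6)
  } else {
    NULL
  }

  files <- list(report = file.path(out_dir, "density_report.json"))
  if (length(anns)) {
    report <- density_report(
      anns,
      pooling = config$pooling %||% "pooled",
      subtract_dcv_area = config$subtract_dcv_area %||% TRUE,
      bouton_area_method = config$bouton_area_method %||% "polygon",
      grid_spacing_nm = config$grid_spacing_nm %||% 50,
      background = if (!is.null(bg)) bg$density
    )
    files$summary <- file.path(out_dir, "density_summary.tsv")
    readr::write_tsv(report$per_image, files$summary)
    write_density_report_json(report, files$report)
  } else {
    jsonlite::write_json(list(background = bg), files$report,
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  if (!is.null(bg)) {
    files$background <- file.path(out_dir, "background.tsv")
    readr::write_tsv(bg, files$background)
  }
  invisible(write_manifest(out_dir, "stereology", config, files))
}
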