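#' Assign gold particles to stereological compartments
#'
#' Each particle receives exactly one compartment label by priority:
#' within the DCV counting-disc radius of any DCV centre -> `dcv`; else
#' within the membrane-band half-width of the bouton outline (on either
#' side) -> `membrane`; else inside the outline -> `cytoplasm`; else
#' `outside`. The DCV disc wins where regions overlap because gold within
#' the counting disc of a DCV centre is its own category.
#'
#' @param ann An [em_annotation()].
#' @return The annotation's `gold` tibble with an added `compartment`
#'   factor (`dcv`, `membrane`, `cytoplasm`, `outside`).
#' @export
assign_gold_compartments <- function(ann) {
  stopifnot(inherits(ann, "em_annotation"))
  if (is.null(ann$bouton_outline)) {
    stop(sprintf("Annotation `%s` has no bouton outline; ", ann$image_id),
         "compartments cannot be assigned (control image?).", call. = FALSE)
  }
  gold <- ann$gold
  lv <- c("dcv", "membrane", "cytoplasm", "outside")
  if (!nrow(gold)) {
    gold$compartment <- factor(character(), levels = lv)
    return(gold)
  }
  x <- gold$x_nm; y <- gold$y_nm
  in_dcv <- rep(FALSE, nrow(gold))
  if (nrow(ann$dcv_centers)) {
    for (i in seq_len(nrow(ann$dcv_centers))) {
      in_dcv <- in_dcv |
        ((x - ann$dcv_centers$x_nm[i])^2 + (y - ann$dcv_centers$y_nm[i])^2 <=
           ann$dcv_disc_radius^2)
    }
  }
  near_mem <- dist_to_polygon_boundary(x, y, ann$bouton_outline) <=
    ann$membrane_band_halfwidth
  inside <- points_in_polygon(x, y, ann$bouton_outline)
  lab <- ifelse(in_dcv, "dcv",
                ifelse(near_mem, "membrane",
                       ifelse(inside, "cytoplasm", "outside")))
  gold$compartment <- factor(lab, levels = lv)
  gold
}

compartment_summary <- function(ann, subtract_dcv_area = TRUE,
                                bouton_area_method = c("polygon", "grid"),
                                grid_spacing_nm = 50) {
  bouton_area_method <- match.arg(bouton_area_method)
  labelled <- assign_gold_compartments(ann)
  counts <- table(labelled$compartment)
  a_bouton_nm2 <- if (bouton_area_method == "grid") {
    grid_area_estimate(ann$bouton_outline, grid_spacing_nm) * 1e6
  } else {
    polygon_area(ann$bouton_outline)
  }
  perim <- polygon_perimeter(ann$bouton_outline)
  h <- ann$membrane_band_halfwidth
  a_dcv <- nrow(ann$dcv_centers) * pi * ann$dcv_disc_radius^2
  a_cyt <- a_bouton_nm2 - perim * h - if (subtract_dcv_area) a_dcv else 0
  a_out <- ann$image_area * 1e6 - a_bouton_nm2 - perim * h
  tibble::tibble(
    image_id = ann$image_id,
    compartment = factor(c("dcv", "membrane", "cytoplasm", "outside"),
                         levels = c("dcv", "membrane", "cytoplasm", "outside")),
    count = as.integer(counts[c("dcv", "membrane", "cytoplasm", "outside")]),
    area_um2 = c(a_dcv, perim * 2 * h, a_cyt, a_out) / 1e6
  )
}

#' Stereological labelling-density report
#'
#' Estimates the immunogold labelling density (particles per um^2) of each
#' compartment across a set of annotated micrographs, and the headline
#' DCV-over-cytoplasm density ratio that quantifies enrichment of the
#' antigen on dense-core vesicles.
#'
#' Areas follow the stereological conventions: the DCV compartment area is
#' `n_dcv * pi * radius^2`; the membrane band area is `perimeter x 2 x
#' half-width` (the band extends the half-width to each side of the
#' outline, curvature ignored at these scales); the cytoplasm area is the
#' bouton area minus the inner half of the band and, by default, minus the
#' DCV disc area (an unsubtracted variant is also reported); the outside
#' area is the image remainder. Bouton area comes from the outline polygon
#' (exact shoelace) or from a grid-intersection estimate.
#'
#' Two pooling schemes are computed: `pooled` sums counts and areas across
#' images before dividing (the default headline number) and
#' `per_image_mean` averages the per-image ratios; both appear in the
#' report so either convention can be compared.
#'
#' @param annotations A list of [em_annotation()] objects (a single
#'   annotation is accepted).
#' @param pooling Which scheme provides the headline `dcv_over_bouton`
#'   ratio: `"pooled"` (default) or `"per_image_mean"`.
#' @param subtract_dcv_area Subtract the DCV disc area from the cytoplasm
#'   area (default `TRUE`).
#' @param bouton_area_method `"polygon"` (exact outline area, default) or
#'   `"grid"` (stereological point count).
#' @param grid_spacing_nm Grid pitch when `bouton_area_method = "grid"`.
#' @param background Optional background density in gold/um^2 (e.g. from
#'   [background_density()]) carried into the report.
#' @return A `density_report`: list with `compartments` (pooled per-
#'   compartment `count`, `area_um2`, `density`), `per_image` (the same per
#'   micrograph), `ratios` (tibble of `dcv_over_bouton` under both pooling
#'   schemes and both cytoplasm-area conventions), `dcv_over_bouton` (the
#'   headline number under the requested scheme), `n_images`, `background`.
#'   A zero cytoplasm count under `per_image_mean` yields an infinite
#'   per-image ratio, flagged rather than raised as an error.
#' @examples
#' anns <- lapply(1:3, function(s)
#'   simulate_em_annotation(em_sim_params(seed = s), image_id = paste0("im", s)))
#' rep <- density_report(anns)
#' rep$dcv_over_bouton
#' @export
density_report <- function(annotations, pooling = c("pooled", "per_image_mean"),
                           subtract_dcv_area = TRUE,
                           bouton_area_method = c("polygon", "grid"),
                           grid_spacing_nm = 50,
                           background = NULL) {
  pooling <- match.arg(pooling)
  bouton_area_method <- match.arg(bouton_area_method)
  if (inherits(annotations, "em_annotation")) annotations <- list(annotations)
  if (!length(annotations)) {
    stop("Need at least one annotation.", call. = FALSE)
  }

  per_image_tbl <- function(subtract) {
    purrr::imap_dfr(annotations, function(ann, i) {
      compartment_summary(ann, subtract_dcv_area = subtract,
                          bouton_area_method = bouton_area_method,
                          grid_spacing_nm = grid_spacing_nm) |>
        dplyr::mutate(image = i, .before = 1)
    }) |>
      dplyr::mutate(density = .data$count / .data$area_um2)
  }
  per_image_sub <- per_image_tbl(TRUE)
  per_image_raw <- per_image_tbl(FALSE)
  per_image <- if (subtract_dcv_area) per_image_sub else per_image_raw

  pooled_tbl <- function(per_image) {
    per_image |>
      dplyr::summarise(count = sum(.data$count),
                       area_um2 = sum(.data$area_um2),
                       .by = "compartment") |>
      dplyr::mutate(density = .data$count / .data$area_um2)
  }
  pooled_ratio <- function(pooled) {
    d <- pooled$density[match(c("dcv", "cytoplasm"), pooled$compartment)]
    d[1] / d[2]
  }
  image_ratios <- function(per_image) {
    per_image |>
      tidyr::pivot_wider(id_cols = "image", names_from = "compartment",
                         values_from = "density") |>
      dplyr::mutate(ratio = .data$dcv / .data$cytoplasm)
  }

  pooled_sub <- pooled_tbl(per_image_sub)
  pooled_raw <- pooled_tbl(per_image_raw)
  ratios_img_sub <- image_ratios(per_image_sub)$ratio
  ratios_img_raw <- image_ratios(per_image_raw)$ratio
  ratios <- tibble::tibble(
    pooling = rep(c("pooled", "per_image_mean"), each = 2),
    cytoplasm_area = rep(c("dcv_subtracted", "unsubtracted"), 2),
    dcv_over_bouton = c(pooled_ratio(pooled_sub), pooled_ratio(pooled_raw),
                        mean(ratios_img_sub), mean(ratios_img_raw))
  )
  headline <- ratios$dcv_over_bouton[
    ratios$pooling == pooling &
      ratios$cytoplasm_area ==
        if (subtract_dcv_area) "dcv_subtracted" else "unsubtracted"]

  structure(
    list(
      compartments = if (subtract_dcv_area) pooled_sub else pooled_raw,
      per_image = per_image,
      ratios = ratios,
      dcv_over_bouton = headline,
      infinite_image_ratio = any(!is.finite(ratios_img_sub)),
      pooling = pooling,
      subtract_dcv_area = subtract_dcv_area,
      bouton_area_method = bouton_area_method,
      n_images = length(annotations),
      background = background
    ),
    class = "density_report"
  )
}

#' @export
print.density_report <- function(x, ...) {
  cat(sprintf("<density_report> %d image(s); DCV/bouton density ratio %.4g (%s, %s)\n",
              x$n_images, x$dcv_over_bouton, x$pooling,
              if (x$subtract_dcv_area) "DCV area subtracted" else
                "DCV area not subtracted"))
  print(x$compartments, ...)
  if (!is.null(x$background)) {
    cat(sprintf("background: %.4g gold/um^2\n", x$background))
  }
  invisible(x)
}

#' @rdname density_report
#' @param x A `density_report`.
#' @param ... Unused.
#' @export
tidy.density_report <- function(x, ...) {
  x$compartments
}

#' @rdname density_report
#' @export
glance.density_report <- function(x, ...) {
  tibble::tibble(
    dcv_over_bouton = x$dcv_over_bouton,
    pooling = x$pooling,
    n_images = x$n_images,
    total_gold = sum(x$compartments$count),
    background = x$background %||% NA_real_
  )
}

#' Background labelling density from control images
#'
#' Pools control annotations (blank resin, muscle fibres, or a non-expressing
#' genotype) and estimates the background labelling density as total gold
#' over total image area, compared against a quality ceiling (0.6 gold/um^2
#' by default).
#'
#' @param control_annotations List of [em_annotation()] objects (bouton
#'   outlines and DCV centres may be empty).
#' @param threshold Ceiling in gold/um^2 the background is compared against.
#' @return Tibble with `density` (gold/um^2), `total_gold`,
#'   `total_area_um2`, `n_images`, `threshold`, `below_threshold`.
#' @export
background_density <- function(control_annotations, threshold = 0.6) {
  if (inherits(control_annotations, "em_annotation")) {
    control_annotations <- list(control_annotations)
  }
  if (!length(control_annotations)) {
    stop("Need at least one control annotation.", call. = FALSE)
  }
  area <- sum(vapply(control_annotations, function(a) a$image_area, numeric(1)))
  if (area <= 0) stop("Total control area must be > 0.", call. = FALSE)
  gold <- sum(vapply(control_annotations, function(a) nrow(a$gold), numeric(1)))
  dens <- gold / area
  tibble::tibble(
    density = dens, total_gold = gold, total_area_um2 = area,
    n_images = length(control_annotations),
    threshold = threshold, below_threshold = dens < threshold
  )
}
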