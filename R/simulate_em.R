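#' Parameters for the synthetic immuno-EM micrograph generator
#'
#' The generator emulates an annotated micrograph of a bouton cross-section
#' with immunogold labelling: a convex bouton outline occupying a set
#' fraction of the image, non-overlapping dense-core-vesicle (DCV) discs
#' inside it, and gold particles placed as independent Poisson counts with
#' compartment-specific densities (DCV discs, plasma-membrane band,
#' remaining cytoplasm, and the area outside the bouton), uniformly within
#' each compartment.
#'
#' @param image_area Micrograph area in um^2.
#' @param bouton_fraction Fraction of the image occupied by the bouton
#'   outline (0 < fraction < 1).
#' @param n_dcv Number of DCV discs.
#' @param dcv_disc_radius DCV disc radius in nm (the stereological counting
#'   disc around each DCV centre).
#' @param membrane_band_halfwidth Half-width of the plasma-membrane band in
#'   nm (the band spans this distance on each side of the outline).
#' @param density_dcv,density_cytoplasm,density_membrane_band,density_outside
#'   Gold densities (particles per um^2) in each compartment.
#' @param seed Integer seed (`NULL` for the current RNG state).
#' @return A list of class `em_sim_params`.
#' @export
em_sim_params <- function(image_area = 4,
                          bouton_fraction = 0.35,
                          n_dcv = 12,
                          dcv_disc_radius = 50,
                          membrane_band_halfwidth = 20,
                          density_dcv = 30,
                          density_cytoplasm = 2,
                          density_membrane_band = 8,
                          density_outside = 0.5,
                          seed = NULL) {
  p <- list(image_area = image_area, bouton_fraction = bouton_fraction,
            n_dcv = n_dcv, dcv_disc_radius = dcv_disc_radius,
            membrane_band_halfwidth = membrane_band_halfwidth,
            density_dcv = density_dcv, density_cytoplasm = density_cytoplasm,
            density_membrane_band = density_membrane_band,
            density_outside = density_outside, seed = seed)
  if (image_area <= 0) stop("`image_area` must be > 0.", call. = FALSE)
  if (bouton_fraction <= 0 || bouton_fraction >= 1) {
    stop("`bouton_fraction` must lie strictly between 0 and 1.", call. = FALSE)
  }
  if (n_dcv < 0 || n_dcv != round(n_dcv)) {
    stop("`n_dcv` must be a non-negative integer.", call. = FALSE)
  }
  if (dcv_disc_radius <= 0 || membrane_band_halfwidth <= 0) {
    stop("Radii must be > 0.", call. = FALSE)
  }
  dens <- c(density_dcv, density_cytoplasm, density_membrane_band,
            density_outside)
  if (any(dens < 0)) stop("Densities must be >= 0.", call. = FALSE)
  structure(p, class = "em_sim_params")
}

#' Construct an EM annotation
#'
#' The unit conventions follow the field's: coordinates in nm, areas in um^2.
#'
#' @param gold Data frame with columns `x_nm`, `y_nm` (one row per gold
#'   particle); extra columns are kept.
#' @param dcv_centers Data frame with columns `x_nm`, `y_nm` of DCV centres.
#' @param bouton_outline Matrix or data frame of outline vertices (nm),
#'   implicitly closed; may be `NULL` for control images without a bouton
#'   (usable with [background_density()] but not with compartment
#'   assignment).
#' @param image_area Micrograph area, um^2.
#' @param image_id Identifier string.
#' @param dcv_disc_radius,membrane_band_halfwidth Stereological radii in nm.
#' @return A list of class `em_annotation`.
#' @export
em_annotation <- function(gold, dcv_centers, bouton_outline, image_area,
                          image_id = "image", dcv_disc_radius = 50,
                          membrane_band_halfwidth = 20) {
  gold <- tibble::as_tibble(gold)
  dcv_centers <- tibble::as_tibble(dcv_centers)
  for (df in list(gold, dcv_centers)) {
    if (!all(c("x_nm", "y_nm") %in% names(df))) {
      stop("Point tables need `x_nm` and `y_nm` columns.", call. = FALSE)
    }
    if (nrow(df) && !all(is.finite(df$x_nm) & is.finite(df$y_nm))) {
      stop("All coordinates must be finite.", call. = FALSE)
    }
  }
  outline <- if (is.null(bouton_outline)) NULL else as_polygon(bouton_outline)
  if (image_area <= 0) stop("`image_area` must be > 0.", call. = FALSE)
  if (dcv_disc_radius <= 0 || membrane_band_halfwidth <= 0) {
    stop("Radii must be > 0.", call. = FALSE)
  }
  structure(
    list(image_id = image_id, image_area = image_area, gold = gold,
         dcv_centers = dcv_centers, bouton_outline = outline,
         dcv_disc_radius = dcv_disc_radius,
         membrane_band_halfwidth = membrane_band_halfwidth),
    class = "em_annotation"
  )
}

#' @export
print.em_annotation <- function(x, ...) {
  cat(sprintf(
    "<em_annotation> %s: %.3g um^2, %d gold, %d DCV centres, %s\n",
    x$image_id, x$image_area, nrow(x$gold), nrow(x$dcv_centers),
    if (is.null(x$bouton_outline)) "no outline (control)" else
      sprintf("%d-vertex outline", nrow(x$bouton_outline))))
  invisible(x)
}

# Convex blob: regular polygon with radially perturbed vertices, closed by a
# convex hull and rescaled to the requested area, centred at `centre`.
convex_blob <- function(centre, target_area_nm2, n_vertices = 14,
                        roughness = 0.25) {
  theta <- sort(stats::runif(n_vertices, 0, 2 * pi))
  r <- 1 + roughness * (stats::runif(n_vertices) - 0.5)
  pts <- cbind(cos(theta) * r, sin(theta) * r)
  hull <- grDevices::chull(pts)
  pts <- pts[hull, , drop = FALSE]
  scale <- sqrt(target_area_nm2 / polygon_area(pts))
  sweep(pts * scale, 2, centre, `+`)
}

runif_in_disc <- function(n, centre, radius) {
  r <- radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(centre[1] + r * cos(th), centre[2] + r * sin(th))
}

# Rejection-sample `n` points satisfying `accept(x, y)` within a bounding box.
sample_region <- function(n, bbox, accept, max_batches = 1000) {
  out <- matrix(numeric(0), 0, 2)
  batches <- 0
  while (nrow(out) < n && batches < max_batches) {
    m <- max(100, 4 * (n - nrow(out)))
    x <- stats::runif(m, bbox[1], bbox[2])
    y <- stats::runif(m, bbox[3], bbox[4])
    ok <- accept(x, y)
    out <- rbind(out, cbind(x[ok], y[ok]))
    batches <- batches + 1
  }
  if (nrow(out) < n) {
    stop("Rejection sampling failed to fill a compartment; ",
         "check that its area is positive.", call. = FALSE)
  }
  out[seq_len(n), , drop = FALSE]
}

#' Simulate an annotated immuno-EM micrograph
#'
#' Builds a square micrograph containing a convex bouton outline occupying
#' `bouton_fraction` of the image, `n_dcv` DCV centres with pairwise
#' distance >= 2 disc radii placed so each disc clears the membrane band,
#' and gold particles drawn per compartment as Poisson counts with mean
#' density x compartment area and uniform positions within the compartment.
#' Compartments are mutually exclusive by construction, so the stored
#' ground-truth labels match the priority rule of
#' [assign_gold_compartments()] exactly.
#'
#' @param params An [em_sim_params()] list.
#' @param image_id Identifier for the simulated micrograph.
#' @param max_tries Placement attempts per DCV before giving up with a
#'   capacity error.
#' @return An [em_annotation()] whose `gold` table carries a
#'   `compartment_true` column; the generating parameters are attached as
#'   attribute `params`.
#' @examples
#' ann <- simulate_em_annotation(em_sim_params(seed = 1))
#' table(ann$gold$compartment_true)
#' @export
simulate_em_annotation <- function(params = em_sim_params(),
                                   image_id = "sim_image",
                                   max_tries = 2000) {
  if (!inherits(params, "em_sim_params")) {
    params <- do.call(em_sim_params, params)
  }
  if (!is.null(params$seed)) set.seed(params$seed)
  side <- sqrt(params$image_area) * 1000           # nm
  centre <- c(side / 2, side / 2)
  outline <- convex_blob(centre, params$bouton_fraction * params$image_area * 1e6)
  if (any(outline < 0) || any(outline > side)) {
    stop("Bouton outline does not fit in the image; ",
         "reduce `bouton_fraction`.", call. = FALSE)
  }
  r <- params$dcv_disc_radius
  h <- params$membrane_band_halfwidth

  # DCV centres: inside outline, discs clear of the membrane band, pairwise
  # separation >= 2r (non-overlapping counting discs).
  centres <- matrix(numeric(0), 0, 2)
  bbox <- c(range(outline[, 1]), range(outline[, 2]))
  tries <- 0
  while (nrow(centres) < params$n_dcv) {
    if (tries >= max_tries * max(1, params$n_dcv)) {
      stop(sprintf(
        "Could not place %d non-overlapping DCV discs after %d attempts.",
        params$n_dcv, tries), call. = FALSE)
    }
    tries <- tries + 1
    cx <- stats::runif(1, bbox[1], bbox[2])
    cy <- stats::runif(1, bbox[3], bbox[4])
    if (!points_in_polygon(cx, cy, outline)) next
    if (dist_to_polygon_boundary(cx, cy, outline) < r + h) next
    if (nrow(centres) &&
        min((centres[, 1] - cx)^2 + (centres[, 2] - cy)^2) < (2 * r)^2) next
    centres <- rbind(centres, c(cx, cy))
  }

  areas <- compartment_areas_nm2(outline, nrow(centres), r, h,
                                 params$image_area * 1e6)
  mean_counts <- c(
    dcv = params$density_dcv * areas[["dcv"]],
    membrane = params$density_membrane_band * areas[["membrane"]],
    cytoplasm = params$density_cytoplasm * areas[["cytoplasm"]],
    outside = params$density_outside * areas[["outside"]]
  ) / 1e6
  counts <- stats::rpois(4, mean_counts)
  names(counts) <- names(mean_counts)

  pts <- list()
  if (counts[["dcv"]] > 0) {
    idx <- sample.int(nrow(centres), counts[["dcv"]], replace = TRUE)
    pts$dcv <- do.call(rbind, lapply(seq_len(counts[["dcv"]]), function(i) {
      runif_in_disc(1, centres[idx[i], ], r)
    }))
  }
  pad <- h + 1
  if (counts[["membrane"]] > 0) {
    pts$membrane <- sample_region(
      counts[["membrane"]],
      c(bbox[1] - pad, bbox[2] + pad, bbox[3] - pad, bbox[4] + pad),
      function(x, y) dist_to_polygon_boundary(x, y, outline) <= h
    )
  }
  if (counts[["cytoplasm"]] > 0) {
    pts$cytoplasm <- sample_region(
      counts[["cytoplasm"]], bbox,
      function(x, y) {
        ok <- points_in_polygon(x, y, outline) &
          dist_to_polygon_boundary(x, y, outline) > h
        if (nrow(centres)) {
          for (i in seq_len(nrow(centres))) {
            ok <- ok & ((x - centres[i, 1])^2 + (y - centres[i, 2])^2 > r^2)
          }
        }
        ok
      }
    )
  }
  if (counts[["outside"]] > 0) {
    pts$outside <- sample_region(
      counts[["outside"]], c(0, side, 0, side),
      function(x, y) !points_in_polygon(x, y, outline) &
        dist_to_polygon_boundary(x, y, outline) > h
    )
  }
  gold <- dplyr::bind_rows(lapply(names(pts), function(cmp) {
    tibble::tibble(x_nm = pts[[cmp]][, 1], y_nm = pts[[cmp]][, 2],
                   compartment_true = cmp)
  }))
  if (!nrow(gold)) {
    gold <- tibble::tibble(x_nm = double(), y_nm = double(),
                           compartment_true = character())
  }

  ann <- em_annotation(
    gold = gold,
    dcv_centers = tibble::tibble(x_nm = centres[, 1], y_nm = centres[, 2]),
    bouton_outline = outline,
    image_area = params$image_area,
    image_id = image_id,
    dcv_disc_radius = r,
    membrane_band_halfwidth = h
  )
  attr(ann, "params") <- params
  ann
}

#' Simulate a control micrograph for background estimation
#'
#' Control images (blank resin, muscle fibre, non-expressing genotype) carry
#' no bouton outline or DCVs; gold is placed as a homogeneous Poisson
#' process at the given density over the whole image.
#'
#' @param image_area Image area in um^2.
#' @param density Background gold density in gold/um^2.
#' @param seed Integer seed (`NULL` for the current RNG state).
#' @param image_id Identifier string.
#' @return An [em_annotation()] with `bouton_outline = NULL`.
#' @export
simulate_control_annotation <- function(image_area = 10, density = 0.3,
                                        seed = NULL, image_id = "control") {
  if (image_area <= 0) stop("`image_area` must be > 0.", call. = FALSE)
  if (density < 0) stop("`density` must be >= 0.", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  side <- sqrt(image_area) * 1000
  n <- stats::rpois(1, density * image_area)
  em_annotation(
    gold = tibble::tibble(x_nm = stats::runif(n, 0, side),
                          y_nm = stats::runif(n, 0, side)),
    dcv_centers = tibble::tibble(x_nm = double(), y_nm = double()),
    bouton_outline = NULL,
    image_area = image_area,
    image_id = image_id
  )
}

# Compartment areas in nm^2 under the band-area convention used throughout:
# membrane band = perimeter x 2h (h on each side of the outline); cytoplasm
# subtracts the DCV discs and the *inner* half of the band from the outline
# area; outside subtracts the outline and the outer half of the band from
# the image.
compartment_areas_nm2 <- function(outline, n_dcv, r, h, image_area_nm2) {
  a_poly <- polygon_area(outline)
  perim <- polygon_perimeter(outline)
  a_dcv <- n_dcv * pi * r^2
  c(dcv = a_dcv,
    membrane = perim * 2 * h,
    cytoplasm = a_poly - a_dcv - perim * h,
    outside = image_area_nm2 - a_poly - perim * h)
}
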