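# Planar geometry primitives for stereology: polygons are n x 2 matrices of
# vertex coordinates in nm, implicitly closed (last vertex joins the first).

#' Polygon area by the shoelace formula
#'
#' @param poly Two-column matrix (x, y) of vertices in nm, implicitly closed.
#' @return Area in nm^2 (non-negative, independent of orientation).
#' @export
polygon_area <- function(poly) {
  poly <- as_polygon(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Polygon perimeter
#'
#' @inheritParams polygon_area
#' @return Perimeter length in nm.
#' @export
polygon_perimeter <- function(poly) {
  poly <- as_polygon(poly)
  d <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE]) - poly
  sum(sqrt(rowSums(d^2)))
}

as_polygon <- function(poly) {
  if (is.data.frame(poly)) poly <- as.matrix(poly[, 1:2])
  if (!is.matrix(poly) || ncol(poly) < 2 || nrow(poly) < 3 ||
      !all(is.finite(poly))) {
    stop("A polygon must be a matrix of >= 3 finite (x, y) vertices.",
         call. = FALSE)
  }
  # drop an explicitly repeated closing vertex
  n <- nrow(poly)
  if (all(poly[1, ] == poly[n, ]) && n > 3) poly <- poly[-n, , drop = FALSE]
  poly[, 1:2, drop = FALSE]
}

#' Point-in-polygon test
#'
#' @param x,y Point coordinates (nm), vectorised.
#' @inheritParams polygon_area
#' @return Logical vector; boundary points count as inside.
#' @export
points_in_polygon <- function(x, y, poly) {
  poly <- as_polygon(poly)
  if (!length(x)) return(logical(0))
  pracma::inpolygon(x, y, poly[, 1], poly[, 2], boundary = TRUE)
}

#' Distance from points to a polygon boundary
#'
#' Minimum Euclidean distance from each point to any edge of the (closed)
#' polygon outline, irrespective of which side of the boundary the point
#' lies on.
#'
#' @inheritParams points_in_polygon
#' @return Numeric vector of distances in nm.
#' @export
dist_to_polygon_boundary <- function(x, y, poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  a <- poly
  b <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  ab <- b - a
  len2 <- rowSums(ab^2)
  d2 <- rep(Inf, length(x))
  for (i in seq_len(n)) {
    px <- x - a[i, 1]; py <- y - a[i, 2]
    tt <- if (len2[i] > 0) {
      pmin(1, pmax(0, (px * ab[i, 1] + py * ab[i, 2]) / len2[i]))
    } else {
      0
    }
    dx <- px - tt * ab[i, 1]; dy <- py - tt * ab[i, 2]
    d2 <- pmin(d2, dx^2 + dy^2)
  }
  sqrt(d2)
}

#' Grid-intersection area estimate
#'
#' Stereological point counting: a square grid of points with pitch
#' `spacing_nm` is laid over the image and the region area is estimated as
#' the number of grid points falling inside the region times the area per
#' point, `spacing_nm^2`. Grid points sit at cell centres relative to the
#' anchor: `origin + (k + 1/2) * spacing` in each axis, the usual unbiased
#' point-counting convention.
#'
#' @param poly Region outline, matrix of (x, y) vertices in nm.
#' @param spacing_nm Grid pitch in nm (> 0).
#' @param origin_nm Length-2 numeric, grid anchor.
#' @return Estimated area in um^2. A warning is issued when the spacing
#'   exceeds the region's bounding box (the estimate may then be 0).
#' @export
grid_area_estimate <- function(poly, spacing_nm, origin_nm = c(0, 0)) {
  poly <- as_polygon(poly)
  if (spacing_nm <= 0) stop("`spacing_nm` must be > 0.", call. = FALSE)
  rx <- range(poly[, 1]); ry <- range(poly[, 2])
  if (spacing_nm > diff(rx) || spacing_nm > diff(ry)) {
    warning("Grid spacing exceeds the region bounding box; ",
            "the estimate may be 0.", call. = FALSE)
  }
  ix <- seq(ceiling((rx[1] - origin_nm[1]) / spacing_nm - 0.5),
            floor((rx[2] - origin_nm[1]) / spacing_nm - 0.5))
  iy <- seq(ceiling((ry[1] - origin_nm[2]) / spacing_nm - 0.5),
            floor((ry[2] - origin_nm[2]) / spacing_nm - 0.5))
  if (!length(ix) || !length(iy)) return(0)
  gx <- origin_nm[1] + (ix + 0.5) * spacing_nm
  gy <- origin_nm[2] + (iy + 0.5) * spacing_nm
  pts <- expand.grid(x = gx, y = gy)
  inside <- points_in_polygon(pts$x, pts$y, poly)
  sum(inside) * spacing_nm^2 / 1e6
}
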