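# Planar polygon utilities used by the eddy tracker and the capture
# statistics. Contours are small (tens of km) so planar geometry in a
# local equirectangular projection is used throughout; lon/lat polygons
# are projected about their own centroid before any metric computation.

#' Point-in-polygon test (ray casting, boundary counted inside)
#'
#' Even-odd crossing rule with an explicit on-boundary check: points lying
#' on a polygon edge (within a small tolerance) are inside by convention.
#'
#' @param px,py Point coordinates (vectors).
#' @param poly Two-column matrix of polygon vertices (closed or open ring).
#' @param check_simple Reject self-intersecting polygons (O(n^2); turn off
#'   for repeated queries against a pre-validated polygon).
#' @param tol Boundary tolerance in coordinate units.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly, check_simple = FALSE,
                             tol = 1e-9) {
  poly <- close_ring(poly)
  if (nrow(poly) < 4) stop("degenerate polygon: fewer than 3 distinct vertices")
  if (check_simple && !is_simple_polygon(poly)) {
    stop("non-simple (self-intersecting) polygon rejected")
  }
  n <- nrow(poly) - 1
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    x1 <- poly[i, 1]; y1 <- poly[i, 2]
    x2 <- poly[i + 1, 1]; y2 <- poly[i + 1, 2]
    crosses <- ((y1 > py) != (y2 > py))
    xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
    inside <- xor(inside, crosses & (px < xint))
    # distance from points to the segment
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx^2 + dy^2
    tt <- if (len2 > 0) pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2)) else 0
    dseg <- sqrt((px - (x1 + tt * dx))^2 + (py - (y1 + tt * dy))^2)
    on_edge <- on_edge | dseg <= tol
  }
  inside | on_edge
}

# ensure the ring repeats its first vertex
close_ring <- function(poly) {
  poly <- as.matrix(poly)
  if (!isTRUE(all.equal(poly[1, ], poly[nrow(poly), ], check.attributes = FALSE))) {
    poly <- rbind(poly, poly[1, ])
  }
  poly
}

# brute-force self-intersection check on a closed ring
is_simple_polygon <- function(poly) {
  n <- nrow(poly) - 1
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- cross2(p4 - p3, p1 - p3); d2 <- cross2(p4 - p3, p2 - p3)
    d3 <- cross2(p2 - p1, p3 - p1); d4 <- cross2(p2 - p1, p4 - p1)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (seg_int(poly[i, ], poly[i + 1, ], poly[j, ], poly[j + 1, ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

cross2 <- function(a, b) a[1] * b[2] - a[2] * b[1]

#' Polygon area and centroid on the sphere (local-plane approximation)
#'
#' Projects the lon/lat ring to a tangent plane about its vertex mean,
#' then applies the shoelace formula.
#'
#' @param poly Two-column lon/lat matrix.
#' @return List with `area_km2`, `centroid` (lon, lat) and the projected
#'   ring `xy_km` with its origin `origin`.
#' @export
polygon_geometry <- function(poly) {
  poly <- close_ring(poly)
  lon0 <- mean(poly[-nrow(poly), 1]); lat0 <- mean(poly[-nrow(poly), 2])
  xy <- local_xy_km(poly[, 1], poly[, 2], lon0, lat0)
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  cr <- x[-n] * y[-1] - x[-1] * y[-n]
  a <- sum(cr) / 2
  cx <- sum((x[-n] + x[-1]) * cr) / (6 * a)
  cy <- sum((y[-n] + y[-1]) * cr) / (6 * a)
  list(area_km2 = abs(a),
       centroid = c(lon = lon0 + cx / (m_per_deg_lon(lat0) / 1000),
                    lat = lat0 + cy / (m_per_deg_lat(lat0) / 1000)),
       xy_km = xy, origin = c(lon0, lat0))
}

# Kasa algebraic least-squares circle fit; xy a two-column matrix (km)
circle_fit <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- qr.solve(A, b)
  list(cx = sol[1], cy = sol[2], r = sqrt(sol[3] + sol[1]^2 + sol[2]^2))
}

#' Shape error of a contour against its best-fit circle
#'
#' 100 x area(symmetric difference between the polygon and the least-squares
#' fitted circle) / area(circle). The symmetric difference is evaluated from
#' the polygon's angular radius function about the fitted centre
#' (`integral |r(theta)^2 - a^2| / 2 dtheta`), exact for polygons that are
#' star-shaped about that centre -- the case for closed SSH contours around
#' a single extremum.
#'
#' @param poly Two-column lon/lat matrix (an open or closed ring).
#' @param n_theta Angular sampling resolution.
#' @return Shape error in percent.
#' @export
shape_error <- function(poly, n_theta = 1024) {
  geo <- polygon_geometry(poly)
  xy <- geo$xy_km[-nrow(geo$xy_km), , drop = FALSE]
  fit <- circle_fit(xy)
  th <- atan2(xy[, 2] - fit$cy, xy[, 1] - fit$cx)
  rr <- sqrt((xy[, 1] - fit$cx)^2 + (xy[, 2] - fit$cy)^2)
  ord <- order(th)
  th <- th[ord]; rr <- rr[ord]
  # periodic linear interpolation of r(theta)
  th_ext <- c(th[length(th)] - 2 * pi, th, th[1] + 2 * pi)
  rr_ext <- c(rr[length(rr)], rr, rr[1])
  tq <- seq(-pi, pi, length.out = n_theta + 1)[-1]
  rq <- stats::approx(th_ext, rr_ext, xout = tq, ties = "ordered")$y
  dth <- 2 * pi / n_theta
  sym_diff <- sum(abs(rq^2 - fit$r^2) / 2) * dth
  100 * sym_diff / (pi * fit$r^2)
}
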