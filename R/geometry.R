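# Planar polygon primitives. Polygons are n x 2 numeric matrices of vertices
# (an implicitly closed ring) in micrometers, x rightward, y downward as stored
# in the image; all angles are axial, in degrees, in [0, 180), measured from
# the +x axis. No polygon library ships with this toolchain, so the handful of
# primitives needed (shoelace area, even-odd containment, segment distance,
# convex-hull Feret diameters) are implemented here and cross-checked against
# brute-force oracles in the test suite.

#' Signed polygon area (shoelace formula)
#' @param poly n x 2 matrix of vertices
#' @return signed area; positive when the ring is counterclockwise in the
#'   stored (y-down) frame
#' @keywords internal
polygon_area_signed <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

#' Polygon area in square micrometers
#'
#' Absolute shoelace area, well-defined (even-odd sense) also for rings with
#' incidental self-intersections.
#'
#' @param poly n x 2 matrix of vertices (closed ring, last vertex need not
#'   repeat the first)
#' @return area (um^2)
#' @export
polygon_area <- function(poly) abs(polygon_area_signed(poly))

#' Polygon centroid
#'
#' Area-weighted centroid; falls back to the vertex mean for (near-)degenerate
#' rings.
#'
#' @inheritParams polygon_area
#' @return length-2 numeric (x, y)
#' @export
polygon_centroid <- function(poly) {
  a <- polygon_area_signed(poly)
  if (abs(a) < 1e-12) return(colMeans(poly[, 1:2, drop = FALSE]))
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * a)
}

#' Even-odd point-in-polygon test
#'
#' Vectorized ray-casting containment test. Points on an edge may land on
#' either side at floating precision; callers needing boundary semantics
#' should use [dist_to_boundary()].
#'
#' @param pts m x 2 matrix of query points
#' @param poly n x 2 matrix of vertices
#' @return logical vector of length m
#' @export
point_in_polygon <- function(pts, poly) {
  pts <- rbind(pts)
  px <- pts[, 1]; py <- pts[, 2]
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Distance from points to a polygon boundary
#'
#' Minimum Euclidean distance from each query point to the polygon's edges
#' (the boundary curve, ignoring interior/exterior).
#'
#' @inheritParams point_in_polygon
#' @return numeric vector of distances (um)
#' @export
dist_to_boundary <- function(pts, poly) {
  pts <- rbind(pts)
  px <- pts[, 1]; py <- pts[, 2]
  n <- nrow(poly)
  d2 <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    ax <- poly[j, 1]; ay <- poly[j, 2]
    bx <- poly[i, 1]; by <- poly[i, 2]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      t <- 0
    } else {
      t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
    }
    ex <- px - (ax + t * dx); ey <- py - (ay + t * dy)
    d2 <- pmin(d2, ex * ex + ey * ey)
    j <- i
  }
  sqrt(d2)
}

#' Distance from points to a polygon (zero inside)
#'
#' @inheritParams point_in_polygon
#' @return numeric vector; 0 for points inside or on the polygon
#' @export
dist_to_polygon <- function(pts, poly) {
  d <- dist_to_boundary(pts, poly)
  d[point_in_polygon(pts, poly)] <- 0
  d
}

#' Shape metrics of a polygon: Feret diameters and major-axis orientation
#'
#' The major-axis orientation is the direction of the maximum Feret (caliper)
#' diameter of the convex hull, the standard "Feret angle" of image-analysis
#' toolkits; ties (e.g. the two diagonals of a square) are broken to the
#' smallest axial angle. The minimum Feret diameter is the rotating-calipers
#' minimum width, and their ratio is the aspect ratio used to flag
#' near-isotropic cells whose orientation is unreliable.
#'
#' @param poly n x 2 vertex matrix
#' @param low_anisotropy_threshold aspect ratios below this flag the
#'   orientation as unreliable (default 1.1)
#' @return list with `orientation_deg` in \[0, 180), `max_feret`, `min_feret`,
#'   `aspect_ratio`, `low_anisotropy`
#' @export
shape_metrics <- function(poly, low_anisotropy_threshold = 1.1) {
  if (nrow(poly) < 3 || polygon_area(poly) <= 1e-12)
    stop("undefined orientation: degenerate (zero-area) polygon", call. = FALSE)
  h <- poly[grDevices::chull(poly[, 1], poly[, 2]), , drop = FALSE]
  m <- nrow(h)
  # max Feret: realized by a pair of hull vertices; hulls of segmented cells
  # are small, so all-pairs enumeration is exact and cheap
  ij <- utils::combn(m, 2)
  dx <- h[ij[2, ], 1] - h[ij[1, ], 1]
  dy <- h[ij[2, ], 2] - h[ij[1, ], 2]
  d <- sqrt(dx * dx + dy * dy)
  dmax <- max(d)
  cand <- which(d >= dmax * (1 - 1e-12))
  angs <- mod180(atan2(dy[cand], dx[cand]) * 180 / pi)
  orientation <- min(angs)
  # min Feret: minimum over hull edges of the support width normal to the edge
  wmin <- Inf
  for (k in seq_len(m)) {
    k2 <- if (k == m) 1L else k + 1L
    ex <- h[k2, 1] - h[k, 1]; ey <- h[k2, 2] - h[k, 2]
    len <- sqrt(ex * ex + ey * ey)
    if (len == 0) next
    w <- max(abs((h[, 1] - h[k, 1]) * (-ey / len) + (h[, 2] - h[k, 2]) * (ex / len)))
    wmin <- min(wmin, w)
  }
  aspect <- if (wmin > 0) dmax / wmin else Inf
  list(orientation_deg = orientation, max_feret = dmax, min_feret = wmin,
       aspect_ratio = aspect,
       low_anisotropy = is.finite(aspect) && aspect < low_anisotropy_threshold)
}

#' Major-axis orientation of a polygon
#'
#' `method = "feret"` (default) returns the axial angle of the maximum Feret
#' diameter of the convex hull. `method = "moment"` returns the orientation of
#' the principal axis of the polygon's second area moments (an ellipse-moment
#' fit), provided as a cross-check; the two agree for elliptical cells but can
#' differ for elongated rectangles, whose maximum caliper diameter is a
#' diagonal.
#'
#' @param poly n x 2 vertex matrix
#' @param method "feret" or "moment"
#' @return axial angle in degrees in \[0, 180), measured from the +x axis
#' @export
orientation_from_polygon <- function(poly, method = c("feret", "moment")) {
  method <- match.arg(method)
  if (method == "feret") return(shape_metrics(poly)$orientation_deg)
  if (nrow(poly) < 3 || polygon_area(poly) <= 1e-12)
    stop("undefined orientation: degenerate (zero-area) polygon", call. = FALSE)
  cen <- polygon_centroid(poly)
  x <- poly[, 1] - cen[1]; y <- poly[, 2] - cen[2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  ixx <- sum(cr * (y^2 + y * y2 + y2^2)) / 12
  iyy <- sum(cr * (x^2 + x * x2 + x2^2)) / 12
  ixy <- sum(cr * (x * y2 + 2 * x * y + 2 * x2 * y2 + x2 * y)) / 24
  s <- sign(polygon_area_signed(poly))
  ixx <- s * ixx; iyy <- s * iyy; ixy <- s * ixy
  mod180(0.5 * atan2(2 * ixy, iyy - ixx) * 180 / pi)
}

#' Vertices of an ellipse polygon
#'
#' @param center length-2 (x, y) in um
#' @param area ellipse area (um^2)
#' @param aspect_ratio major/minor semi-axis ratio (>= 1)
#' @param orientation_deg axial angle of the major axis
#' @param n_vertices number of polygon vertices (default 24)
#' @return n x 2 vertex matrix
#' @export
ellipse_polygon <- function(center, area, aspect_ratio = 1,
                            orientation_deg = 0, n_vertices = 24) {
  a <- sqrt(area * aspect_ratio / pi)
  b <- a / aspect_ratio
  t <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  th <- orientation_deg * pi / 180
  x <- a * cos(t); y <- b * sin(t)
  cbind(center[1] + x * cos(th) - y * sin(th),
        center[2] + x * sin(th) + y * cos(th))
}

#' Axis-aligned rectangle polygon
#' @param xlim,ylim length-2 ranges
#' @return 4 x 2 vertex matrix
#' @export
rect_polygon <- function(xlim, ylim) {
  cbind(c(xlim[1], xlim[2], xlim[2], xlim[1]),
        c(ylim[1], ylim[1], ylim[2], ylim[2]))
}
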