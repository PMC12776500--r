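# Fixture builders and independent brute-force oracles used across tests.

# cell_set of small ellipses at given centroids/orientations
make_cells <- function(x, y, theta, area = 50, aspect = 3, id = NULL,
                       annotation_id = "a1", class_label = NA_character_) {
  polys <- lapply(seq_along(x), function(i)
    ellipse_polygon(c(x[i], y[i]), area, aspect, theta[i]))
  cell_set(polys, id = id, annotation_id = annotation_id,
           class_label = class_label)
}

# O(n^2) brute-force neighbor adjacency matrix: 0 < d <= radius
bf_adjacency <- function(x, y, radius) {
  D <- as.matrix(stats::dist(cbind(x, y)))
  D > 0 & D <= radius
}

# direct double-loop LMS oracle
bf_lms <- function(x, y, theta, radius, min_neighbors = 1, folded = TRUE) {
  A <- bf_adjacency(x, y, radius)
  n <- length(x)
  raw <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ])
    if (length(nb) >= min_neighbors && length(nb) > 0) {
      d <- numeric(length(nb))
      for (k in seq_along(nb)) {
        dd <- abs(theta[i] - theta[nb[k]]) %% 180
        d[k] <- min(dd, 180 - dd)
      }
      raw[i] <- mean(d)
    }
  }
  if (folded) 45 - abs(45 - raw) else raw
}

rbind_cells <- function(a, b) {
  out <- rbind(as.data.frame(a), as.data.frame(b))
  class(out) <- c("cell_set", "data.frame")
  out
}

# LMS through the package path on bare centroids/orientations (no polygons)
lms_scores_theta <- function(x, y, theta, radius = 30, fold = "folded") {
  df <- data.frame(id = sprintf("c%04d", seq_along(x)), x = x, y = y,
                   orientation_deg = theta, stringsAsFactors = FALSE)
  class(df) <- c("cell_set", "data.frame")
  lms_scores(df, lms_config(radius, fold_mode = fold))$lms_deg
}

# scalar point-to-polygon distance oracle (explicit edge loop)
bf_dist_to_polygon <- function(pt, poly) {
  if (point_in_polygon(rbind(pt), poly)) return(0)
  n <- nrow(poly)
  best <- Inf
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1 else i + 1, ]
    ab <- b - a
    t <- sum((pt - a) * ab) / sum(ab * ab)
    t <- min(1, max(0, t))
    p <- a + t * ab
    best <- min(best, sqrt(sum((pt - p)^2)))
  }
  best
}

# rotate polygon vertices about a point
rotate_poly <- function(poly, delta_deg, center = c(0, 0)) {
  th <- delta_deg * pi / 180
  x <- poly[, 1] - center[1]; y <- poly[, 2] - center[2]
  cbind(center[1] + x * cos(th) - y * sin(th),
        center[2] + x * sin(th) + y * cos(th))
}

# tiny QuPath-style GeoJSON written by hand (tests dialect variants)
write_qupath_fixture <- function(path) {
  ring <- function(coords) lapply(seq_len(nrow(coords)), function(i) coords[i, ])
  sq <- function(cx, cy, h = 10) {
    m <- rbind(c(cx - h, cy - h), c(cx + h, cy - h), c(cx + h, cy + h),
               c(cx - h, cy + h), c(cx - h, cy - h))
    list(type = "Polygon", coordinates = list(ring(m)))
  }
  feats <- list(
    list(type = "Feature", id = "d1", geometry = sq(20, 20),
         properties = list(objectType = "detection",
                           classification = list(name = "chondrocyte"),
                           measurements = list(Sox9 = 41.5, Col2 = 120),
                           annotation_id = "element_1")),
    list(type = "Feature", id = "d2", geometry = sq(60, 20),
         properties = list(objectType = "detection",
                           classification = "myocyte",
                           measurements = list(list(name = "Sox9", value = 7.25)))),
    # degenerate: 2-vertex "polygon"
    list(type = "Feature", id = "bad", geometry = list(
      type = "Polygon",
      coordinates = list(list(c(0, 0), c(1, 1)))),
      properties = list()),
    list(type = "Feature", id = "d3", geometry = sq(20, 60),
         properties = list(measurements = NULL)),
    # non-polygonal feature
    list(type = "Feature", id = "pt", geometry = list(
      type = "Point", coordinates = c(5, 5)), properties = list())
  )
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 8)
  path
}
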