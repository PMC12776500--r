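# Sequential marker-region cell classification and hypertrophic-zone (HZ)
# distance zoning. Region membership is decided by centroid containment.
# Labels form a closed vocabulary and every cell receives exactly one:
#   chondro-hyper : centroid in a Col2 region AND a ColX region
#   chondrocyte   : else, centroid in a Col2 region
#   myocyte       : else, centroid in a muscle region
#   other         : negative for all
# chondro-PZ is assigned afterwards, only to chondrocytes within a distance
# window of the HZ.

CLASS_LABELS <- c("chondrocyte", "chondro-hyper", "myocyte", "chondro-PZ", "other")

#' Sequential marker-region classification
#'
#' Applies the precedence chondro-hyper > chondrocyte > myocyte > other based
#' on centroid containment in marker regions. A `marker:Col2` region is
#' required; absent `marker:ColX` or `muscle` regions are treated as empty
#' (no cell can receive the corresponding label), with a message.
#'
#' @param cells a `cell_set`
#' @param regions a `region_set` carrying roles `marker:Col2`, `marker:ColX`,
#'   `muscle`
#' @return `cells` with `class_label` filled in
#' @export
classify_by_regions <- function(cells, regions) {
  col2 <- regions_with_role(regions, "marker:Col2")
  colx <- regions_with_role(regions, "marker:ColX")
  musc <- regions_with_role(regions, "muscle")
  if (length(col2) == 0)
    stop("configuration error: no region with role 'marker:Col2'", call. = FALSE)
  if (length(colx) == 0) message("no 'marker:ColX' region; no cell will be chondro-hyper")
  if (length(musc) == 0) message("no 'muscle' region; no cell will be myocyte")
  pts <- cbind(cells$x, cells$y)
  in_col2 <- in_any_polygon(pts, col2)
  in_colx <- in_any_polygon(pts, colx)
  in_musc <- in_any_polygon(pts, musc)
  lab <- rep("other", nrow(cells))
  lab[in_musc] <- "myocyte"
  lab[in_col2] <- "chondrocyte"
  lab[in_col2 & in_colx] <- "chondro-hyper"
  cells$class_label <- lab
  cells
}

#' Distance from each cell to the hypertrophic zone
#'
#' Euclidean distance from the cell centroid to the nearest point of any
#' HZ-role polygon; 0 for centroids inside the HZ.
#'
#' @param cells a `cell_set`
#' @param regions a `region_set` with at least one role-`hz` region
#' @return named numeric vector (cell id -> distance, um)
#' @export
distance_to_hz <- function(cells, regions) {
  hz <- regions_with_role(regions, "hz")
  if (length(hz) == 0)
    stop("configuration error: no region with role 'hz'", call. = FALSE)
  pts <- cbind(cells$x, cells$y)
  d <- do.call(pmin, lapply(hz, function(p) dist_to_polygon(pts, p)))
  stats::setNames(d, cells$id)
}

#' Relabel chondrocytes near the HZ as chondro-PZ
#'
#' Chondrocytes whose HZ distance d satisfies `lo <= d < hi` (half-open
#' window, default \[0, 400) um) are relabeled `chondro-PZ`; `chondro-hyper`
#' and all other labels are never touched. Idempotent.
#'
#' @param cells a classified `cell_set`
#' @param distances named distances from [distance_to_hz()]
#' @param window length-2 numeric `c(lo, hi)` in um
#' @return `cells` with updated labels
#' @export
assign_pz <- function(cells, distances, window = c(0, 400)) {
  if (window[1] >= window[2]) stop("window must satisfy lo < hi", call. = FALSE)
  d <- distances[cells$id]
  sel <- cells$class_label == "chondrocyte" & d >= window[1] & d < window[2]
  cells$class_label[sel] <- "chondro-PZ"
  cells
}

#' Bin scores by distance from the HZ
#'
#' Aggregates a per-cell score into half-open distance bins
#' `[k*w, (k+1)*w)`. Cells with undefined (NA) scores are excluded; empty
#' bins are reported with count 0 and NA aggregates.
#'
#' @param scores numeric scores named by cell id (NA = undefined)
#' @param distances named distances (um), same ids
#' @param bin_width bin width in um (> 0)
#' @return a `distance_profile` data.frame: `bin_lo`, `bin_hi`, `n`, `mean`,
#'   `median`
#' @export
bin_by_distance <- function(scores, distances, bin_width) {
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  ids <- intersect(names(scores), names(distances))
  s <- scores[ids]; d <- distances[ids]
  def <- !is.na(s)
  if (!any(def)) stop("empty input: no defined scores to bin", call. = FALSE)
  s <- s[def]; d <- d[def]
  k <- floor(d / bin_width)
  kmax <- max(k)
  out <- data.frame(bin_lo = (0:kmax) * bin_width,
                    bin_hi = (1:(kmax + 1)) * bin_width)
  out$n <- as.integer(tabulate(k + 1, nbins = kmax + 1))
  out$mean <- out$median <- NA_real_
  agg_m <- tapply(s, k, mean)
  agg_md <- tapply(s, k, stats::median)
  idx <- as.integer(names(agg_m)) + 1
  out$mean[idx] <- as.numeric(agg_m)
  out$median[idx] <- as.numeric(agg_md)
  class(out) <- c("distance_profile", "data.frame")
  out
}

#' Edge and size filtering of cells
#'
#' Drops cells whose centroid lies within `edge_margin` of the cartilage
#' region boundary (edge-located cells have truncated neighborhoods) and
#' cells whose area falls outside `[min_area, max_area]`. Cells dropped for
#' both reasons are counted once, as edge.
#'
#' @param cells a `cell_set`
#' @param cartilage a `region_set` (its role-`cartilage` polygons are used),
#'   or a list of polygons; may be `NULL` when `edge_margin = 0`
#' @param edge_margin margin in um (>= 0)
#' @param min_area,max_area area window in um^2
#' @return the retained subset, with attribute `exclusions` =
#'   c(edge, area_small, area_large)
#' @export
filter_cells <- function(cells, cartilage = NULL, edge_margin = 0,
                         min_area = 0, max_area = Inf) {
  if (min_area > max_area) stop("min_area must be <= max_area", call. = FALSE)
  if (edge_margin < 0) stop("edge_margin must be >= 0", call. = FALSE)
  polys <- if (inherits(cartilage, "region_set")) {
    regions_with_role(cartilage, "cartilage")
  } else {
    cartilage
  }
  edge <- rep(FALSE, nrow(cells))
  if (edge_margin > 0) {
    if (length(polys) == 0)
      stop("configuration error: edge filtering needs a cartilage region",
           call. = FALSE)
    pts <- cbind(cells$x, cells$y)
    db <- do.call(pmin, lapply(polys, function(p) dist_to_boundary(pts, p)))
    edge <- db < edge_margin
  }
  small <- !edge & cells$area < min_area
  large <- !edge & cells$area > max_area
  keep <- !(edge | small | large)
  out <- cells[keep, ]
  attr(out, "exclusions") <- c(edge = sum(edge), area_small = sum(small),
                               area_large = sum(large))
  out
}
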