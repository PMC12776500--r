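# Axial orientation statistics. Cell long axes are undirected, so all angle
# arithmetic is modulo 180 degrees; the smallest difference between two
# orientations lives in [0, 90]. Two per-cell scores are derived:
#
#  * GOA (global orientation angle): deviation of the cell's major axis from
#    the tissue's proximal-distal axis, in [0, 90]; 0 = parallel.
#  * LMS (local misalignment score): mean axial difference between a cell and
#    its neighbors within a fixed radius, folded to [0, 45] so that a
#    neighborhood with completely random orientations scores 45 in the
#    large-neighborhood limit, and perfect local alignment scores 0.

#' Smallest axial angular difference
#'
#' Reduces both angles modulo 180 (axial symmetry: a long axis has no head or
#' tail) and returns the smaller of the two arc differences, in \[0, 90\].
#'
#' @param a,b angles in degrees (any finite reals; vectorized, recycled)
#' @return difference in degrees in \[0, 90\]
#' @export
axial_diff <- function(a, b) {
  stop_if_not_finite(a, "a"); stop_if_not_finite(b, "b")
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Global orientation angle (GOA)
#'
#' Axial deviation of an orientation from the tissue axis, in \[0, 90\]:
#' values near 0 indicate alignment parallel to the proximal-distal axis,
#' values near 90 perpendicular orientation.
#'
#' @param orientation_deg cell major-axis angles (degrees)
#' @param axis_deg tissue-axis angle(s) (degrees)
#' @return GOA in degrees in \[0, 90\]
#' @export
goa <- function(orientation_deg, axis_deg) axial_diff(orientation_deg, axis_deg)

#' LMS configuration
#'
#' @param radius neighborhood radius in um (default 30). In tissue the radius
#'   is chosen case-by-case so each cell has on the order of 10-20 neighbors.
#' @param min_neighbors minimum neighbor count for a defined LMS (default 1);
#'   cells with fewer neighbors get an undefined (NA) score
#' @param fold_mode `"folded"` (default; scores in \[0, 45\]) or `"raw"` (the
#'   unfolded mean difference in \[0, 90\], for sensitivity analyses)
#' @return an `lms_config` list
#' @export
lms_config <- function(radius = 30, min_neighbors = 1,
                       fold_mode = c("folded", "raw")) {
  fold_mode <- match.arg(fold_mode)
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0", call. = FALSE)
  if (min_neighbors < 1) stop("min_neighbors must be >= 1", call. = FALSE)
  structure(list(radius = radius, min_neighbors = as.integer(min_neighbors),
                 fold_mode = fold_mode), class = "lms_config")
}

#' Fold a mean angular difference onto the LMS scale
#'
#' The per-cell mean axial difference lies in \[0, 90\] with expectation 45
#' under independent uniform orientations. The fold `45 - |45 - m|`
#' (equivalently `min(m, 90 - m)`) remaps it to \[0, 45\] so that random
#' neighborhoods score 45 (in the large-neighborhood limit, where the mean
#' concentrates at 45) and 45 is the attainable maximum. `mode = "raw"`
#' returns the input unchanged.
#'
#' @param mean_diff mean angular difference(s) in \[0, 90\]
#' @param mode `"folded"` or `"raw"`
#' @return folded score(s)
#' @export
fold_to_lms <- function(mean_diff, mode = c("folded", "raw")) {
  mode <- match.arg(mode)
  ok <- is.na(mean_diff) | (mean_diff >= -1e-9 & mean_diff <= 90 + 1e-9)
  if (!all(ok)) stop("mean_diff out of [0, 90]", call. = FALSE)
  if (mode == "raw") return(mean_diff)
  45 - abs(45 - mean_diff)
}

#' Radius-limited neighbor graph over cell centroids
#'
#' Cells i and j are adjacent iff their centroid distance d satisfies
#' 0 < d <= radius (boundary inclusive). Built with a sorted-sweep spatial
#' index whose output equals the brute-force all-pairs rule.
#'
#' @param cells a `cell_set`, or an n x 2 matrix of centroids (um)
#' @param radius neighborhood radius in um (> 0)
#' @return a `neighbor_graph`: list with `ids`, `edges` (2-column integer
#'   matrix of adjacent index pairs, i < j), `radius`, `n`
#' @export
build_neighbor_graph <- function(cells, radius) {
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0)
    stop("radius must be a single value > 0", call. = FALSE)
  if (inherits(cells, "cell_set")) {
    xy <- cbind(cells$x, cells$y); ids <- cells$id
  } else {
    xy <- rbind(cells); ids <- as.character(seq_len(nrow(xy)))
  }
  n <- nrow(xy)
  if (n < 1) stop("empty input: no cells", call. = FALSE)
  ord <- order(xy[, 1])
  xs <- xy[ord, 1]; ys <- xy[ord, 2]
  r2 <- radius^2
  ei <- vector("list", n)
  hi <- 1L
  for (k in seq_len(n)) {
    # window of sorted points with x within radius, ahead of k
    hi <- max(hi, k)
    while (hi < n && xs[hi + 1] - xs[k] <= radius) hi <- hi + 1L
    if (hi == k) next
    j <- (k + 1L):hi
    dx <- xs[j] - xs[k]; dy <- ys[j] - ys[k]
    keep <- dx * dx + dy * dy <= r2 + 1e-9
    # exclude exactly coincident centroids (no self-loops at distance 0)
    keep <- keep & (dx != 0 | dy != 0)
    if (any(keep)) ei[[k]] <- cbind(ord[k], ord[j[keep]])
  }
  edges <- do.call(rbind, ei)
  if (is.null(edges)) edges <- matrix(integer(), 0, 2)
  swap <- edges[, 1] > edges[, 2]
  edges[swap, ] <- edges[swap, c(2, 1)]
  structure(list(ids = ids, edges = edges, radius = radius, n = n),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  deg <- tabulate(c(x$edges[, 1], x$edges[, 2]), nbins = x$n)
  cat(sprintf("<neighbor_graph> %d cells, %d edges, radius %g um, mean degree %.1f\n",
              x$n, nrow(x$edges), x$radius, mean(deg)))
  invisible(x)
}

#' Adjacency list of a neighbor graph
#' @param graph a `neighbor_graph`
#' @return named list: cell id -> character vector of neighbor ids
#' @export
as_adjacency <- function(graph) {
  adj <- rep(list(character()), graph$n)
  names(adj) <- graph$ids
  if (nrow(graph$edges)) {
    i <- graph$edges[, 1]; j <- graph$edges[, 2]
    nb <- split(graph$ids[c(j, i)], c(i, j))
    adj[as.integer(names(nb))] <- lapply(nb, unname)
  }
  adj
}

#' Per-cell local misalignment scores
#'
#' For each cell with at least `config$min_neighbors` neighbors, the raw score
#' is the mean axial difference between the cell's orientation and each
#' neighbor's; the LMS is that mean folded to \[0, 45\] (see
#' [fold_to_lms()]). Cells with fewer neighbors get `NA` scores and are
#' excluded from downstream summaries. Orientations enter only through
#' pairwise differences, so any common reference axis gives identical scores.
#'
#' @param cells a `cell_set` (orientations in degrees)
#' @param config an [lms_config()]
#' @param graph optional pre-built [build_neighbor_graph()] on the same cells
#'   at `config$radius`
#' @return a `score_table` data.frame: `id`, `neighbor_count`,
#'   `raw_mean_diff_deg`, `lms_deg`
#' @export
lms_scores <- function(cells, config = lms_config(), graph = NULL) {
  if (is.null(graph)) graph <- build_neighbor_graph(cells, config$radius)
  if (graph$n != nrow(cells) || !identical(graph$ids, cells$id))
    stop("graph/cells mismatch: ids differ", call. = FALSE)
  if (abs(graph$radius - config$radius) > 1e-9)
    stop("graph/config mismatch: graph built at radius ", graph$radius,
         ", config asks ", config$radius, call. = FALSE)
  n <- graph$n
  th <- cells$orientation_deg
  cnt <- tabulate(c(graph$edges[, 1], graph$edges[, 2]), nbins = n)
  sums <- numeric(n)
  if (nrow(graph$edges)) {
    d <- axial_diff(th[graph$edges[, 1]], th[graph$edges[, 2]])
    sm <- rowsum(c(d, d), group = c(graph$edges[, 1], graph$edges[, 2]))
    sums[as.integer(rownames(sm))] <- sm[, 1]
  }
  raw <- ifelse(cnt >= config$min_neighbors, sums / pmax(cnt, 1L), NA_real_)
  out <- data.frame(id = cells$id, neighbor_count = cnt,
                    raw_mean_diff_deg = raw,
                    lms_deg = fold_to_lms(raw, config$fold_mode),
                    stringsAsFactors = FALSE)
  class(out) <- c("score_table", "data.frame")
  out
}

#' Per-cell global orientation angles
#'
#' @param cells a `cell_set`
#' @param axes tissue-axis angles: a named numeric vector
#'   (annotation id -> axis angle in degrees), or a data.frame with columns
#'   `annotation_id`, `axis_deg`
#' @return numeric vector of GOA values (degrees, \[0, 90\]) aligned with
#'   `cells` rows
#' @export
goa_scores <- function(cells, axes) {
  if (is.data.frame(axes)) axes <- stats::setNames(axes$axis_deg, axes$annotation_id)
  miss <- setdiff(unique(cells$annotation_id), names(axes))
  if (length(miss))
    stop("no tissue axis configured for annotation(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  goa(cells$orientation_deg, unname(axes[cells$annotation_id]))
}

#' Score a cell set: GOA and LMS in one table
#'
#' The central scoring entry point. Restricts scoring to the requested cell
#' classes (neighborhoods are built within that subset, so excluded classes
#' never contaminate a neighborhood), builds the radius-limited neighbor
#' graph, and computes LMS and (when axes are given) GOA per cell.
#'
#' @param cells a `cell_set`
#' @param axes optional tissue axes (see [goa_scores()]); if `NULL`, GOA is NA
#' @param config an [lms_config()]
#' @param classes optional character vector of class labels to include; by
#'   default all cells are scored
#' @return an `orientation_scores` data.frame with columns `id`,
#'   `annotation_id`, `x`, `y`, `orientation_deg`, `class_label`,
#'   `neighbor_count`, `raw_mean_diff_deg`, `lms_deg`, `goa_deg`; the config
#'   and exclusion counts are attached as attributes
#' @export
orientation_scores <- function(cells, axes = NULL, config = lms_config(),
                               classes = NULL) {
  n_all <- nrow(cells)
  if (!is.null(classes)) cells <- cells[cells$class_label %in% classes, ]
  if (nrow(cells) == 0)
    stop("empty input: no cells in the selected classes", call. = FALSE)
  lt <- lms_scores(cells, config)
  out <- data.frame(id = cells$id, annotation_id = cells$annotation_id,
                    x = cells$x, y = cells$y,
                    orientation_deg = cells$orientation_deg,
                    class_label = cells$class_label,
                    neighbor_count = lt$neighbor_count,
                    raw_mean_diff_deg = lt$raw_mean_diff_deg,
                    lms_deg = lt$lms_deg,
                    goa_deg = if (is.null(axes)) NA_real_ else goa_scores(cells, axes),
                    stringsAsFactors = FALSE)
  attr(out, "config") <- config
  attr(out, "n_class_excluded") <- n_all - nrow(cells)
  attr(out, "n_undefined_lms") <- sum(is.na(out$lms_deg))
  attr(out, "polygons") <- cells$polygon
  class(out) <- c("orientation_scores", "data.frame")
  out
}

#' @export
print.orientation_scores <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<orientation_scores> %d cells; radius %g um, fold '%s'\n",
              nrow(x), cfg$radius, cfg$fold_mode))
  cat(sprintf("  LMS defined for %d cells (%d with < %d neighbor(s))\n",
              sum(!is.na(x$lms_deg)), attr(x, "n_undefined_lms"),
              cfg$min_neighbors))
  if (any(!is.na(x$lms_deg)))
    cat(sprintf("  mean LMS %.2f deg, median %.2f deg\n",
                mean(x$lms_deg, na.rm = TRUE), stats::median(x$lms_deg, na.rm = TRUE)))
  if (any(!is.na(x$goa_deg)))
    cat(sprintf("  mean GOA %.2f deg, median %.2f deg\n",
                mean(x$goa_deg, na.rm = TRUE), stats::median(x$goa_deg, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.orientation_scores <- function(object, ...) {
  def <- !is.na(object$lms_deg)
  out <- list(
    n = nrow(object),
    n_lms_defined = sum(def),
    n_class_excluded = attr(object, "n_class_excluded"),
    lms = if (any(def)) summary(object$lms_deg[def]) else NULL,
    goa = if (any(!is.na(object$goa_deg))) summary(object$goa_deg[!is.na(object$goa_deg)]) else NULL,
    mean_neighbors = mean(object$neighbor_count),
    config = attr(object, "config")
  )
  class(out) <- "summary.orientation_scores"
  out
}

#' @export
print.summary.orientation_scores <- function(x, ...) {
  cat(sprintf("Orientation scores: %d cells (%d LMS-defined, %d excluded by class)\n",
              x$n, x$n_lms_defined, x$n_class_excluded))
  cat(sprintf("Mean neighbors within %g um: %.1f\n", x$config$radius, x$mean_neighbors))
  if (!is.null(x$lms)) { cat("LMS (deg):\n"); print(x$lms) }
  if (!is.null(x$goa)) { cat("GOA (deg):\n"); print(x$goa) }
  invisible(x)
}

#' Plot orientation scores as a polygon heatmap on the current device
#' @param x an `orientation_scores` object
#' @param metric `"lms"` or `"goa"`
#' @param ... passed to [draw_heatmap()]
#' @return invisibly, `x`
#' @export
plot.orientation_scores <- function(x, metric = c("lms", "goa"), ...) {
  draw_heatmap(x, metric = match.arg(metric), ...)
  invisible(x)
}
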