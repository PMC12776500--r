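#' Pair nuclei with their enclosing cells
#'
#' Each nucleus whose centroid lies inside at least one cell polygon is paired
#' with the nearest such cell by centroid distance; nuclei contained in no
#' cell are excluded (and counted). Ties in centroid distance are broken to
#' the lexicographically smallest cell id.
#'
#' @param nuclei a `cell_set` of nucleus objects
#' @param cells a `cell_set` of cell objects in the same coordinate frame
#' @return data.frame with columns `nucleus_id`, `cell_id`; the number of
#'   excluded nuclei is attached as attribute `n_excluded`
#' @export
pair_nuclei_to_cells <- function(nuclei, cells) {
  if (is.null(cells) || nrow(cells) == 0)
    stop("empty input: no cell objects to pair against", call. = FALSE)
  if (is.null(nuclei) || nrow(nuclei) == 0)
    stop("empty input: no nuclei", call. = FALSE)
  pts <- cbind(nuclei$x, nuclei$y)
  nuc_id <- character(); cel_id <- character()
  excluded <- 0L
  # candidate cells per nucleus: bounding-box prefilter, then containment
  bb <- t(vapply(cells$polygon, function(p)
    c(min(p[, 1]), max(p[, 1]), min(p[, 2]), max(p[, 2])), numeric(4)))
  for (i in seq_len(nrow(nuclei))) {
    px <- pts[i, 1]; py <- pts[i, 2]
    cand <- which(bb[, 1] <= px & bb[, 2] >= px & bb[, 3] <= py & bb[, 4] >= py)
    cand <- cand[vapply(cand, function(j)
      point_in_polygon(c(px, py), cells$polygon[[j]]), logical(1))]
    if (length(cand) == 0) { excluded <- excluded + 1L; next }
    d <- sqrt((cells$x[cand] - px)^2 + (cells$y[cand] - py)^2)
    best <- cand[d <= min(d) + 1e-12]
    pick <- best[order(cells$id[best])][1]
    nuc_id <- c(nuc_id, nuclei$id[i])
    cel_id <- c(cel_id, cells$id[pick])
  }
  out <- data.frame(nucleus_id = nuc_id, cell_id = cel_id,
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- excluded
  out
}
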