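# Integer label-mask I/O. A label mask is a 2-D integer image, 0 background,
# each positive label one cell. Pixel (r, c) covers the unit square
# [c-1, c] x [r-1, r] in (x, y), y increasing downward; traced polygons run
# along pixel edges (lattice corners), so a 10 x 2 pixel rectangle has area
# exactly 20 px^2.

#' Trace the outer boundary polygon of a binary mask component
#'
#' Collects the unit edges separating mask from non-mask pixels, oriented with
#' the interior on the left, chains them into closed rings, and returns the
#' ring of largest absolute area (the outer boundary). At pinch corners where
#' two boundary edges leave one lattice vertex, the tighter (left-most) turn
#' is taken.
#'
#' @param mask logical matrix
#' @return n x 2 vertex matrix in pixel units (lattice-corner coordinates)
#' @keywords internal
trace_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  idx <- which(pad, arr.ind = TRUE)
  r <- idx[, 1]; c <- idx[, 2]
  # directed edges (x1,y1)->(x2,y2), corners in original pixel coords
  up    <- !pad[cbind(r - 1, c)]
  down  <- !pad[cbind(r + 1, c)]
  left  <- !pad[cbind(r, c - 1)]
  right <- !pad[cbind(r, c + 1)]
  x0 <- c - 2; y0 <- r - 2  # top-left corner of pixel in 0-based lattice coords
  e <- rbind(
    cbind(x0[up], y0[up], x0[up] + 1, y0[up]),            # top: left -> right
    cbind(x0[right] + 1, y0[right], x0[right] + 1, y0[right] + 1), # right: down
    cbind(x0[down] + 1, y0[down] + 1, x0[down], y0[down] + 1),     # bottom
    cbind(x0[left], y0[left] + 1, x0[left], y0[left])     # left: up
  )
  if (nrow(e) == 0) stop("empty mask", call. = FALSE)
  key <- function(x, y) x * (max(nr, nc) + 3) + y
  from <- key(e[, 1], e[, 2])
  ord <- order(from)
  e <- e[ord, , drop = FALSE]; from <- from[ord]
  first <- match(unique(from), from)
  lookup <- stats::setNames(first, unique(from))
  used <- rep(FALSE, nrow(e))
  dirs <- cbind(e[, 3] - e[, 1], e[, 4] - e[, 2])

  next_edge <- function(v, indir) {
    i0 <- lookup[as.character(v)]
    if (is.na(i0)) return(NA_integer_)
    cands <- integer()
    i <- i0
    while (i <= nrow(e) && from[i] == v) {
      if (!used[i]) cands <- c(cands, i)
      i <- i + 1L
    }
    if (length(cands) == 0) return(NA_integer_)
    if (length(cands) == 1) return(cands)
    # prefer the left turn relative to the incoming direction
    crossz <- indir[1] * dirs[cands, 2] - indir[2] * dirs[cands, 1]
    cands[which.max(crossz)]
  }

  best <- NULL; best_area <- -1
  for (start in seq_len(nrow(e))) {
    if (used[start]) next
    ring <- matrix(0, 0, 2)
    i <- start
    repeat {
      used[i] <- TRUE
      ring <- rbind(ring, e[i, 1:2])
      v <- key(e[i, 3], e[i, 4])
      if (v == key(e[start, 1], e[start, 2])) break
      i <- next_edge(v, dirs[i, ])
      if (is.na(i)) break
    }
    if (nrow(ring) >= 4) {
      a <- polygon_area(ring)
      if (a > best_area) { best_area <- a; best <- ring }
    }
  }
  if (is.null(best)) stop("boundary tracing failed", call. = FALSE)
  best
}

#' Read segmented cells from an integer label-mask TIFF
#'
#' One cell per positive label; the polygon is the traced outer boundary of
#' the label's largest connected component (smaller fragments are dropped with
#' a warning). Pixel coordinates are converted to micrometers via the
#' calibration.
#'
#' @param path TIFF file path (integer-valued, 2-D)
#' @param calibration a [pixel_calibration()] (or bare um/px number)
#' @param orientation_method passed to [cell_set()]
#' @return a [cell_set()] with ids `lab_<label>`
#' @export
read_cells_labelmask <- function(path, calibration,
                                 orientation_method = c("feret", "moment")) {
  mpp <- as_mpp(calibration)
  img <- tryCatch(tiff::readTIFF(path, as.is = TRUE, info = TRUE),
                  error = function(e) stop("cannot read TIFF '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(dim(img)) != 2)
    stop("label mask must be a single-channel 2-D image", call. = FALSE)
  # float TIFFs read "as is" come back bit-reinterpreted; cross-check against
  # the normalized read to reject non-integer images
  bits <- attr(img, "bits.per.sample") %||% 16
  norm <- tiff::readTIFF(path)
  if (any(img < 0) || any(abs(img - round(norm * (2^bits - 1))) > 0.5) ||
      (is.double(img) && any(img != round(img))))
    stop("label mask must be integer-valued", call. = FALSE)
  img <- matrix(as.integer(round(img)), nrow(img), ncol(img))
  labs <- sort(unique(img[img > 0]))
  if (length(labs) == 0)
    stop("empty input: label mask is all background", call. = FALSE)
  split_labels <- integer()
  polys <- vector("list", length(labs))
  for (k in seq_along(labs)) {
    m <- img == labs[k]
    cc <- EBImage::bwlabel(m)
    ncomp <- max(cc)
    if (ncomp > 1) {
      sizes <- tabulate(cc[cc > 0], nbins = ncomp)
      m <- cc == which.max(sizes)
      split_labels <- c(split_labels, labs[k])
    }
    polys[[k]] <- trace_boundary(m) * mpp
  }
  if (length(split_labels))
    warning("label(s) ", paste(split_labels, collapse = ", "),
            " split into multiple components; largest kept")
  cell_set(polys, id = sprintf("lab_%d", labs),
           orientation_method = match.arg(orientation_method))
}

#' Rasterize cells into an integer label mask
#'
#' Pixels whose centers fall inside a cell polygon receive that cell's label
#' (1-based row order); where cells overlap, the later id wins, with a
#' warning. Round-trippable through [read_cells_labelmask()].
#'
#' @param cells a `cell_set` (um coordinates)
#' @param calibration a [pixel_calibration()] (or bare um/px number)
#' @param dims optional c(nrow, ncol) in pixels; default covers all polygons
#' @return integer matrix (0 = background)
#' @export
render_labelmask <- function(cells, calibration, dims = NULL) {
  mpp <- as_mpp(calibration)
  if (is.null(cells) || nrow(cells) == 0) {
    if (is.null(dims)) stop("dims required for an empty cell list", call. = FALSE)
    return(matrix(0L, dims[1], dims[2]))
  }
  if (is.null(dims)) {
    mx <- max(vapply(cells$polygon, function(p) max(p[, 1]), numeric(1)))
    my <- max(vapply(cells$polygon, function(p) max(p[, 2]), numeric(1)))
    dims <- c(ceiling(my / mpp) + 1L, ceiling(mx / mpp) + 1L)
  }
  mask <- matrix(0L, dims[1], dims[2])
  overlap <- FALSE
  for (i in seq_len(nrow(cells))) {
    p <- cells$polygon[[i]] / mpp
    cmin <- max(1L, floor(min(p[, 1])) ); cmax <- min(dims[2], ceiling(max(p[, 1])) + 1L)
    rmin <- max(1L, floor(min(p[, 2])) ); rmax <- min(dims[1], ceiling(max(p[, 2])) + 1L)
    if (cmin > cmax || rmin > rmax) next
    cc <- cmin:cmax; rr <- rmin:rmax
    grid <- cbind(rep(cc - 0.5, each = length(rr)), rep(rr - 0.5, length(cc)))
    ins <- point_in_polygon(grid, p)
    if (!any(ins)) next
    rows <- rep(rr, length(cc))[ins]
    cols <- rep(cc, each = length(rr))[ins]
    ij <- cbind(rows, cols)
    if (any(mask[ij] != 0L)) overlap <- TRUE
    mask[ij] <- i
  }
  if (overlap) warning("overlapping cells rasterized; later id wins")
  mask
}

#' Write an integer label mask as a 16-bit TIFF
#' @param mask integer matrix with values in 0..65535
#' @param path output path
#' @return `path`, invisibly
#' @export
write_labelmask <- function(mask, path) {
  if (max(mask) > 65535) stop("more than 65535 labels not supported", call. = FALSE)
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16)
  invisible(path)
}
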