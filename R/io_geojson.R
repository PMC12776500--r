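# GeoJSON I/O in the QuPath export dialect: a FeatureCollection of polygonal
# detections whose "properties" may carry a "classification" (object with
# $name, or plain string), "measurements" (named object, or the older list of
# {name, value} pairs), and plumbing fields (annotation_id, compartment).
# Coordinates on disk are in pixels; everything in memory is micrometers.

#' Pixel calibration
#' @param microns_per_pixel strictly positive um/px scale
#' @return a `pixel_calibration` scalar
#' @export
pixel_calibration <- function(microns_per_pixel) {
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1 ||
      !is.finite(microns_per_pixel) || microns_per_pixel <= 0)
    stop("microns_per_pixel must be a single finite value > 0", call. = FALSE)
  structure(microns_per_pixel, class = "pixel_calibration")
}

as_mpp <- function(calibration) {
  if (inherits(calibration, "pixel_calibration")) return(unclass(calibration))
  unclass(pixel_calibration(calibration))
}

geojson_feature_polygon <- function(feat) {
  g <- feat$geometry
  if (is.null(g) || is.null(g$type)) return(NULL)
  ring <- switch(g$type,
    Polygon = g$coordinates[[1]],
    MultiPolygon = {
      rings <- lapply(g$coordinates, function(pp) pp[[1]])
      areas <- vapply(rings, function(r) {
        m <- do.call(rbind, lapply(r, unlist))
        if (is.null(dim(m)) || nrow(m) < 3) 0 else polygon_area(m)
      }, numeric(1))
      rings[[which.max(areas)]]
    },
    return(NULL)
  )
  m <- do.call(rbind, lapply(ring, unlist))
  if (is.null(dim(m)) || ncol(m) < 2) return(NULL)
  m <- m[, 1:2, drop = FALSE]
  # drop a closing vertex that repeats the first
  if (nrow(m) > 1 && all(m[nrow(m), ] == m[1, ])) m <- m[-nrow(m), , drop = FALSE]
  m
}

geojson_classification <- function(props) {
  cl <- props$classification
  if (is.null(cl)) return(NA_character_)
  if (is.list(cl)) return(as.character(cl$name %||% NA_character_))
  as.character(cl)
}

geojson_measurements <- function(props) {
  meas <- props$measurements
  if (is.null(meas) || length(meas) == 0) return(NULL)
  if (!is.null(names(meas)) && all(nzchar(names(meas)))) {
    return(vapply(meas, function(v) as.numeric(v[[1]]), numeric(1)))
  }
  # older QuPath exports: list of {name, value}
  vals <- vapply(meas, function(m) as.numeric(m$value), numeric(1))
  names(vals) <- vapply(meas, function(m) as.character(m$name), character(1))
  vals
}

#' Read segmented cells from a QuPath-dialect GeoJSON file
#'
#' One `Cell` row per polygonal feature. File coordinates are assumed to be in
#' pixels and are converted to micrometers via `calibration` at read time.
#' Classification strings, marker measurements, annotation ids and compartment
#' tags are carried through when present. Features that are not polygons, or
#' have fewer than 3 distinct vertices, are skipped with a warning.
#'
#' @param path GeoJSON file path
#' @param calibration a [pixel_calibration()] (or bare um/px number)
#' @param orientation_method passed to [cell_set()]
#' @return a [cell_set()]
#' @export
read_cells_geojson <- function(path, calibration,
                               orientation_method = c("feret", "moment")) {
  mpp <- as_mpp(calibration)
  gj <- tryCatch(jsonlite::read_json(path),
                 error = function(e) stop("cannot parse GeoJSON file '", path,
                                          "': ", conditionMessage(e), call. = FALSE))
  feats <- gj$features %||% list()
  polys <- list(); ids <- character(); ann <- character()
  comp <- character(); cls <- character(); marks <- list()
  skipped <- 0L
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    m <- geojson_feature_polygon(f)
    if (is.null(m) || nrow(m[!duplicated(m), , drop = FALSE]) < 3) {
      skipped <- skipped + 1L
      next
    }
    props <- f$properties %||% list()
    polys[[length(polys) + 1L]] <- m * mpp
    ids <- c(ids, as.character(f$id %||% props$id %||% sprintf("cell_%05d", k)))
    ann <- c(ann, as.character(props$annotation_id %||% props$parent %||%
                                 props$name %||% NA_character_))
    comp <- c(comp, as.character(props$compartment %||% "cell"))
    cls <- c(cls, geojson_classification(props))
    marks[[length(marks) + 1L]] <- geojson_measurements(props)
  }
  if (length(polys) == 0)
    stop("empty input: no polygonal features in '", path, "'", call. = FALSE)
  if (skipped > 0)
    warning(skipped, " non-polygonal or degenerate feature(s) skipped in '",
            path, "'")
  cell_set(polys, id = ids, annotation_id = ann, compartment = comp,
           markers = marks, class_label = cls,
           orientation_method = match.arg(orientation_method))
}

#' Write a cell set as QuPath-dialect GeoJSON
#'
#' Inverse of [read_cells_geojson()]: micrometer coordinates are divided by
#' the calibration so files are in pixel space.
#'
#' @param cells a `cell_set`
#' @param path output path
#' @param calibration a [pixel_calibration()] (or bare um/px number)
#' @return `path`, invisibly
#' @export
write_cells_geojson <- function(cells, path, calibration) {
  mpp <- as_mpp(calibration)
  feats <- lapply(seq_len(nrow(cells)), function(i) {
    p <- cells$polygon[[i]] / mpp
    ring <- lapply(seq_len(nrow(p)), function(j) c(p[j, 1], p[j, 2]))
    ring[[length(ring) + 1L]] <- ring[[1]]
    props <- list(objectType = "detection",
                  annotation_id = cells$annotation_id[i],
                  compartment = cells$compartment[i])
    if (!is.na(cells$class_label[i]))
      props$classification <- list(name = cells$class_label[i])
    mk <- cells$markers[[i]]
    if (!is.null(mk) && length(mk)) props$measurements <- as.list(mk)
    list(type = "Feature", id = cells$id[i],
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10, pretty = FALSE)
  invisible(path)
}

#' Read annotation regions from GeoJSON
#'
#' Each polygonal feature becomes one region; the role tag is read from
#' `properties$role` (falling back to `properties$classification$name`) and
#' must belong to the closed role vocabulary; the region name from
#' `properties$name` (falling back to `<role>_<k>`).
#'
#' @inheritParams read_cells_geojson
#' @return a [region_set()]
#' @export
read_regions_geojson <- function(path, calibration) {
  mpp <- as_mpp(calibration)
  gj <- tryCatch(jsonlite::read_json(path),
                 error = function(e) stop("cannot parse GeoJSON file '", path,
                                          "': ", conditionMessage(e), call. = FALSE))
  feats <- gj$features %||% list()
  polys <- list(); nms <- character(); roles <- character()
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    m <- geojson_feature_polygon(f)
    if (is.null(m) || nrow(m) < 3) next
    props <- f$properties %||% list()
    role <- as.character(props$role %||% geojson_classification(props))
    if (is.na(role)) stop("region feature ", k, " in '", path,
                          "' has no role tag", call. = FALSE)
    polys[[length(polys) + 1L]] <- m * mpp
    roles <- c(roles, role)
    nms <- c(nms, as.character(props$name %||% sprintf("%s_%d", role, k)))
  }
  if (length(polys) == 0)
    stop("empty input: no polygonal regions in '", path, "'", call. = FALSE)
  if (anyDuplicated(nms)) nms <- make.unique(nms, sep = "_")
  region_set(polys, name = nms, role = roles)
}

#' Write a region set as GeoJSON
#' @param regions a `region_set`
#' @param path output path
#' @param calibration a [pixel_calibration()] (or bare um/px number)
#' @return `path`, invisibly
#' @export
write_regions_geojson <- function(regions, path, calibration) {
  mpp <- as_mpp(calibration)
  feats <- lapply(seq_len(nrow(regions)), function(i) {
    p <- regions$polygon[[i]] / mpp
    ring <- lapply(seq_len(nrow(p)), function(j) c(p[j, 1], p[j, 2]))
    ring[[length(ring) + 1L]] <- ring[[1]]
    list(type = "Feature", id = regions$name[i],
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = list(objectType = "annotation", name = regions$name[i],
                           role = regions$role[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10, pretty = FALSE)
  invisible(path)
}
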