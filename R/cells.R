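# Containers. A `cell_set` is a data.frame (one row per segmented cell) with
# plain columns for derived geometry and two list-columns: `polygon` (n x 2
# vertex matrices, um) and `markers` (named numeric of mean marker
# intensities, possibly NULL). A `region_set` is a data.frame of named
# annotation polygons with a role tag from a closed vocabulary.

REGION_ROLES_FIXED <- c("cartilage", "hz", "muscle", paste0("element:", 0:5))

#' Validate a region role tag
#'
#' Roles come from a closed vocabulary: `cartilage`, `hz`, `muscle`,
#' `element:0` .. `element:5`, or `marker:<name>` (e.g. `marker:Col2`,
#' `marker:ColX`).
#'
#' @param role character vector of role tags
#' @return invisibly, the validated roles; errors on unknown tags
#' @export
validate_region_role <- function(role) {
  ok <- role %in% REGION_ROLES_FIXED | grepl("^marker:.+$", role)
  if (!all(ok))
    stop("unknown region role(s): ", paste(unique(role[!ok]), collapse = ", "),
         call. = FALSE)
  invisible(role)
}

#' Construct a cell set from polygons
#'
#' Derives centroid, area, major-axis orientation (Feret angle), aspect ratio
#' and the low-anisotropy flag for each polygon. Polygons with fewer than 3
#' distinct vertices or zero area are dropped with a warning.
#'
#' @param polygons list of n x 2 vertex matrices in um
#' @param id character ids (default `cell_00001`, ...)
#' @param annotation_id parent annotation/bone-element id per cell (recycled)
#' @param compartment `"cell"` or `"nucleus"` (recycled)
#' @param markers optional list of named numeric marker means per cell
#' @param class_label optional character labels (recycled)
#' @param orientation_method `"feret"` or `"moment"` (see
#'   [orientation_from_polygon()])
#' @return a `cell_set` data.frame
#' @export
cell_set <- function(polygons, id = NULL, annotation_id = NA_character_,
                     compartment = "cell", markers = NULL,
                     class_label = NA_character_,
                     orientation_method = c("feret", "moment")) {
  orientation_method <- match.arg(orientation_method)
  n <- length(polygons)
  if (n == 0) stop("empty input: no cell polygons", call. = FALSE)
  if (is.null(id)) id <- sprintf("cell_%05d", seq_len(n))
  id <- as.character(id)
  if (anyDuplicated(id)) stop("cell ids must be unique", call. = FALSE)
  annotation_id <- rep_len(as.character(annotation_id), n)
  compartment <- rep_len(compartment, n)
  class_label <- rep_len(as.character(class_label), n)
  if (is.null(markers)) markers <- vector("list", n)

  keep <- rep(TRUE, n)
  x <- y <- area <- ori <- asp <- numeric(n)
  low <- logical(n)
  for (i in seq_len(n)) {
    p <- polygons[[i]]
    p <- p[!duplicated(round(p, 12)), , drop = FALSE]
    if (is.null(dim(p)) || nrow(p) < 3 || polygon_area(p) <= 1e-12) {
      keep[i] <- FALSE
      next
    }
    polygons[[i]] <- p
    cen <- polygon_centroid(p)
    sm <- if (orientation_method == "feret") {
      shape_metrics(p)
    } else {
      s <- shape_metrics(p)
      s$orientation_deg <- orientation_from_polygon(p, "moment")
      s
    }
    x[i] <- cen[1]; y[i] <- cen[2]
    area[i] <- polygon_area(p)
    ori[i] <- sm$orientation_deg
    asp[i] <- sm$aspect_ratio
    low[i] <- sm$low_anisotropy
  }
  if (!all(keep))
    warning(sum(!keep), " degenerate polygon(s) (<3 vertices or zero area) skipped")
  if (!any(keep)) stop("empty input: no valid cell polygons", call. = FALSE)

  out <- data.frame(
    id = id[keep], x = x[keep], y = y[keep], area = area[keep],
    orientation_deg = ori[keep], aspect_ratio = asp[keep],
    low_anisotropy = low[keep], annotation_id = annotation_id[keep],
    compartment = compartment[keep], class_label = class_label[keep],
    stringsAsFactors = FALSE
  )
  out$polygon <- polygons[keep]
  out$markers <- markers[keep]
  class(out) <- c("cell_set", "data.frame")
  out
}

#' @export
print.cell_set <- function(x, ...) {
  cat(sprintf("<cell_set> %d cells (%d nuclei), %d annotation(s)\n",
              sum(x$compartment == "cell"), sum(x$compartment == "nucleus"),
              length(unique(x$annotation_id))))
  labs <- table(x$class_label, useNA = "ifany")
  if (length(labs)) {
    cat("  classes:", paste(sprintf("%s=%d", names(labs), labs), collapse = ", "), "\n")
  }
  cat(sprintf("  area (um^2): median %.1f; orientation defined for all rows\n",
              stats::median(x$area)))
  invisible(x)
}

#' Subset a cell set, keeping its class and list-columns
#' @param x a `cell_set`
#' @param i row index
#' @param ... ignored
#' @return a `cell_set`
#' @export
`[.cell_set` <- function(x, i, ...) {
  out <- as.data.frame(x)[i, , drop = FALSE]
  class(out) <- c("cell_set", "data.frame")
  out
}

#' Construct a region set
#'
#' @param polygons list of n x 2 vertex matrices in um
#' @param name region names (unique)
#' @param role role tags (see [validate_region_role()])
#' @return a `region_set` data.frame
#' @export
region_set <- function(polygons, name, role) {
  n <- length(polygons)
  stopifnot(length(name) == n, length(role) == n)
  validate_region_role(role)
  if (anyDuplicated(name)) stop("region names must be unique", call. = FALSE)
  out <- data.frame(name = as.character(name), role = as.character(role),
                    stringsAsFactors = FALSE)
  out$polygon <- polygons
  class(out) <- c("region_set", "data.frame")
  out
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> %d region(s): %s\n", nrow(x),
              paste(sprintf("%s[%s]", x$name, x$role), collapse = ", ")))
  invisible(x)
}

#' @export
`[.region_set` <- function(x, i, ...) {
  out <- as.data.frame(x)[i, , drop = FALSE]
  class(out) <- c("region_set", "data.frame")
  out
}

#' Polygons of a region set with a given role
#' @param regions a `region_set`
#' @param role a role tag
#' @return list of polygons (possibly empty)
#' @export
regions_with_role <- function(regions, role) {
  regions$polygon[regions$role == role]
}

#' Is each point inside any polygon of a list?
#' @param pts m x 2 matrix
#' @param polys list of polygons
#' @return logical vector of length m
#' @keywords internal
in_any_polygon <- function(pts, polys) {
  if (length(polys) == 0) return(rep(FALSE, nrow(rbind(pts))))
  Reduce(`|`, lapply(polys, function(p) point_in_polygon(pts, p)))
}
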