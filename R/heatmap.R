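# Heatmap rendering: each cell polygon filled by its score on a FIXED color
# scale (0-45 for LMS, 0-90 for GOA) so heatmaps are comparable across
# samples and genotypes; autoscaling would break that comparison.

metric_limits <- function(metric) {
  switch(metric, lms = c(0, 45), goa = c(0, 90),
         stop("unknown metric '", metric, "'", call. = FALSE))
}

metric_column <- function(metric) switch(metric, lms = "lms_deg", goa = "goa_deg")

#' Draw a score heatmap on the current graphics device
#'
#' @param scores an [orientation_scores()] object (carries the cell polygons)
#' @param metric `"lms"` or `"goa"`
#' @param limits color-scale limits; fixed per metric by default
#' @param palette vector of colors (default viridis via [grDevices::hcl.colors()])
#' @param undefined_color fill for cells with undefined scores
#' @param scale_bar_um length of the embedded scale bar (um)
#' @return invisibly, `scores`
#' @export
draw_heatmap <- function(scores, metric = c("lms", "goa"), limits = NULL,
                         palette = grDevices::hcl.colors(256, "viridis"),
                         undefined_color = "grey80", scale_bar_um = 100) {
  metric <- match.arg(metric)
  col_name <- metric_column(metric)
  vals <- scores[[col_name]]
  if (all(is.na(vals)))
    stop("configuration error: metric '", metric,
         "' has no defined scores", call. = FALSE)
  if (is.null(limits)) limits <- metric_limits(metric)
  polys <- attr(scores, "polygons")
  if (is.null(polys)) stop("scores carry no polygons to draw", call. = FALSE)

  idx <- pmin(length(palette), pmax(1L, 1L + floor(
    (pmin(pmax(vals, limits[1]), limits[2]) - limits[1]) /
      diff(limits) * (length(palette) - 1e-9))))
  fill <- ifelse(is.na(vals), undefined_color, palette[idx])

  xr <- range(unlist(lapply(polys, function(p) range(p[, 1]))))
  yr <- range(unlist(lapply(polys, function(p) range(p[, 2]))))
  op <- graphics::par(mar = c(1, 1, 2, 5))
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = xr, ylim = rev(yr), asp = 1, axes = FALSE,
                 xlab = "", ylab = "",
                 main = sprintf("%s (deg)", toupper(metric)))
  for (i in seq_along(polys))
    graphics::polygon(polys[[i]][, 1], polys[[i]][, 2], col = fill[i],
                      border = NA)
  # scale bar
  graphics::segments(xr[1], yr[2], xr[1] + scale_bar_um, yr[2], lwd = 3)
  graphics::text(xr[1] + scale_bar_um / 2, yr[2], pos = 1,
                 labels = sprintf("%g um", scale_bar_um), cex = 0.7, xpd = NA)
  # color legend
  ny <- length(palette)
  lx <- xr[2] + 0.03 * diff(xr)
  lw <- 0.04 * diff(xr)
  ys <- seq(yr[2], yr[1], length.out = ny + 1)
  graphics::rect(lx, ys[-(ny + 1)], lx + lw, ys[-1], col = palette,
                 border = NA, xpd = NA)
  at <- pretty(limits)
  at <- at[at >= limits[1] & at <= limits[2]]
  ay <- yr[2] + (at - limits[1]) / diff(limits) * (yr[1] - yr[2])
  graphics::text(lx + lw, ay, labels = at, pos = 4, cex = 0.7, xpd = NA)
  invisible(scores)
}

#' Render a score heatmap to a PNG file
#'
#' Deterministic for fixed inputs: the same scores always produce the same
#' image.
#'
#' @inheritParams draw_heatmap
#' @param path output PNG path
#' @param width,height device size in pixels
#' @return `path`, invisibly
#' @export
render_heatmap <- function(scores, path, metric = c("lms", "goa"),
                           limits = NULL, undefined_color = "grey80",
                           width = 800, height = 800) {
  metric <- match.arg(metric)
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  draw_heatmap(scores, metric = metric, limits = limits,
               undefined_color = undefined_color)
  invisible(path)
}
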