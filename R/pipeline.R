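# End-to-end pipeline: read -> classify -> zone -> filter -> score ->
# summarize -> test -> render, driven by a config list or YAML file. Every
# exclusion (degenerate polygons, zero-neighbor cells, edge/size filtering,
# class restriction) is logged, because the filters materially change n.

#' Write the per-cell score table as CSV
#'
#' One row per cell, ordered by id: id, annotation_id, centroid, orientation,
#' class label, GOA, LMS, neighbor count and HZ distance. Undefined scores
#' are written as empty fields, never 0. Re-running on identical input
#' produces a byte-identical file.
#'
#' @param cells a `cell_set`
#' @param scores an [orientation_scores()] table for (a subset of) these
#'   cells, indexed by cell id
#' @param path output CSV path
#' @param distances optional named HZ distances from [distance_to_hz()]
#' @param extra optional data.frame of extra columns (e.g. group, embryo),
#'   one row per cell of `cells`, or one row recycled
#' @return `path`, invisibly
#' @export
write_score_table <- function(cells, scores, path, distances = NULL,
                              extra = NULL) {
  if (!all(scores$id %in% cells$id))
    stop("consistency error: score ids not found among cells", call. = FALSE)
  m <- match(cells$id, scores$id)
  out <- data.frame(
    id = cells$id,
    annotation_id = cells$annotation_id,
    centroid_x = cells$x, centroid_y = cells$y,
    orientation_deg = cells$orientation_deg,
    class_label = cells$class_label,
    goa_deg = scores$goa_deg[m],
    lms_deg = scores$lms_deg[m],
    neighbor_count = scores$neighbor_count[m],
    distance_to_hz = if (is.null(distances)) NA_real_ else unname(distances[cells$id]),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) out <- cbind(out, extra)
  out <- out[order(out$id), , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

default_pipeline_config <- function() {
  list(calibration = 0.5, radius_um = 30, min_neighbors = 1,
       fold_mode = "folded", classes = c("chondrocyte", "chondro-PZ"),
       pz_window_um = c(0, 400), bin_width_um = 100, edge_margin_um = 0,
       min_area_um2 = 0, max_area_um2 = Inf, metric = "goa", B = 999,
       seed = 1, heatmap_metric = "lms")
}

#' Run the full scoring pipeline over a cohort
#'
#' Executes read, classification, HZ zoning, filtering, LMS/GOA scoring,
#' embryo-level median summarization, the Wasserstein-ratio permutation test
#' (when two groups are present) and heatmap rendering, writing `scores.csv`,
#' `medians.csv`, `test.json` and `heatmap.png` to the output directory.
#'
#' @param config a list, or path to a YAML file, with keys: `manifest` (CSV
#'   with columns group, embryo, element, cells, regions, axis_deg; file
#'   paths relative to the manifest), `out_dir`, and optionally
#'   `calibration` (um/px, default 0.5), `radius_um` (30), `min_neighbors`
#'   (1), `fold_mode`, `classes` (default chondrocyte + chondro-PZ),
#'   `pz_window_um` (\[0, 400)), `edge_margin_um`, `min_area_um2`,
#'   `max_area_um2`, `metric` for the test (`"goa"` default or `"lms"`),
#'   `B`, `seed`, `heatmap_metric`
#' @param quiet suppress progress messages
#' @return invisibly, a list with the combined score table, the median table,
#'   the test result (or NULL) and output paths
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  if (is.null(cfg$manifest)) stop("config must name a manifest", call. = FALSE)
  if (is.null(cfg$out_dir)) stop("config must name an out_dir", call. = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  man <- utils::read.csv(cfg$manifest, stringsAsFactors = FALSE)
  base <- dirname(cfg$manifest)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  calib <- pixel_calibration(cfg$calibration)
  lcfg <- lms_config(cfg$radius_um, cfg$min_neighbors, cfg$fold_mode)

  all_rows <- list()
  first_scores <- NULL
  for (i in seq_len(nrow(man))) {
    stage <- sprintf("%s/%s", man$embryo[i], man$element[i])
    cells <- withCallingHandlers(
      read_cells_geojson(file.path(base, man$cells[i]), calib),
      warning = function(w) { say("[read %s] %s", stage, conditionMessage(w))
                              invokeRestart("muffleWarning") })
    regions <- read_regions_geojson(file.path(base, man$regions[i]), calib)
    cells <- classify_by_regions(cells, regions)
    dhz <- distance_to_hz(cells, regions)
    cells <- assign_pz(cells, dhz, cfg$pz_window_um)
    cells <- filter_cells(cells, regions, cfg$edge_margin_um,
                          cfg$min_area_um2, cfg$max_area_um2)
    exc <- attr(cells, "exclusions")
    say("[filter %s] edge=%d area_small=%d area_large=%d kept=%d",
        stage, exc["edge"], exc["area_small"], exc["area_large"], nrow(cells))
    axes <- stats::setNames(man$axis_deg[i], man$element[i])
    sc <- orientation_scores(cells, axes = axes, config = lcfg,
                             classes = cfg$classes)
    say("[score %s] %d scored, %d excluded by class, %d with undefined LMS",
        stage, nrow(sc), attr(sc, "n_class_excluded"), attr(sc, "n_undefined_lms"))
    if (is.null(first_scores)) first_scores <- sc
    df <- as.data.frame(sc)
    df$distance_to_hz <- unname(dhz[df$id])
    df$group <- man$group[i]; df$embryo <- man$embryo[i]
    df$element <- man$element[i]
    df$id <- sprintf("%s_%s_%s", man$embryo[i], man$element[i], df$id)
    all_rows[[i]] <- df
  }
  scores <- do.call(rbind, all_rows)

  scores_path <- file.path(cfg$out_dir, "scores.csv")
  out <- scores[order(scores$id),
                c("id", "group", "embryo", "element", "annotation_id", "x", "y",
                  "orientation_deg", "class_label", "goa_deg", "lms_deg",
                  "neighbor_count", "distance_to_hz")]
  utils::write.csv(out, scores_path, row.names = FALSE, na = "")

  metric_col <- metric_column(cfg$metric)
  med <- summarize_median(scores[[metric_col]], scores$embryo, scores$element)
  med$group <- man$group[match(med$embryo, man$embryo)]
  med_path <- file.path(cfg$out_dir, "medians.csv")
  utils::write.csv(med, med_path, row.names = FALSE, na = "")

  test <- NULL
  test_path <- file.path(cfg$out_dir, "test.json")
  if (length(unique(man$group)) == 2) {
    vals <- split(scores[[metric_col]], scores$embryo)
    vals <- lapply(vals, function(v) v[!is.na(v)])
    grp <- man$group[match(names(vals), man$embryo)]
    test <- wasserstein_ratio_test(vals, grp, B = cfg$B, seed = cfg$seed)
    jsonlite::write_json(
      list(metric = cfg$metric, statistic = test$statistic,
           p_value = test$p_value, n_permutations = test$n_permutations,
           exhaustive = test$exhaustive, B = cfg$B, seed = cfg$seed),
      test_path, auto_unbox = TRUE, digits = NA)
    say("[test] %s ratio=%.3f p=%.4g (%d permutations)", cfg$metric,
        test$statistic, test$p_value, test$n_permutations)
  }

  hm_path <- file.path(cfg$out_dir, "heatmap.png")
  render_heatmap(first_scores, hm_path, metric = cfg$heatmap_metric)

  invisible(list(scores = scores, medians = med, test = test,
                 paths = list(scores = scores_path, medians = med_path,
                              test = if (is.null(test)) NULL else test_path,
                              heatmap = hm_path)))
}
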