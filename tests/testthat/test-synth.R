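test_that("field generation is deterministic given the spec", {
  spec <- field_spec(n_cells = 80, seed = 123)
  a <- generate_field(spec)
  b <- generate_field(spec)
  expect_identical(a$cells$x, b$cells$x)
  expect_identical(a$cells$polygon, b$cells$polygon)
  expect_identical(a$cells$orientation_deg, b$cells$orientation_deg)
  c2 <- generate_field(field_spec(n_cells = 80, seed = 124))
  expect_false(identical(a$cells$x, c2$cells$x))
})

test_that("noise-free fields are perfectly aligned (zero LMS downstream)", {
  fld <- generate_field(field_spec(n_cells = 150, noise_model = "none",
                                   mean_orientation_deg = 60, seed = 6))
  expect_true(all(axial_diff(fld$cells$orientation_deg, 60) < 1e-6))
  sc <- lms_scores(fld$cells, lms_config(30))
  expect_equal(max(sc$lms_deg[!is.na(sc$lms_deg)]), 0, tolerance = 1e-9)
})

test_that("generated orientations match their stated distributions", {
  set.seed(1)
  u <- sample_axial_angles(10000, noise_model = "uniform")
  expect_gt(stats::ks.test(u / 180, "punif")$p.value, 0.001)
  for (sig in c(10, 20)) {
    th <- sample_axial_angles(10000, mean_deg = 90,
                              noise_model = "wrapped_normal", sigma_deg = sig)
    expect_true(all(th >= 0 & th < 180))
    expect_lt(abs(estimate_axial_sigma(th) - sig) / sig, 0.05)
  }
  expect_equal(sample_axial_angles(5, mean_deg = 271, noise_model = "none"),
               rep(91, 5))
})

test_that("orientation blocks override the field model inside their rectangle", {
  spec <- field_spec(n_cells = 200, width = 200, height = 200,
                     noise_model = "none", mean_orientation_deg = 90,
                     blocks = list(list(xlim = c(0, 100), ylim = c(0, 200),
                                        mean_orientation_deg = 0,
                                        noise_model = "none")),
                     seed = 11)
  fld <- generate_field(spec)
  left <- fld$cells$x < 100
  expect_true(all(axial_diff(fld$cells$orientation_deg[left], 0) < 1e-6))
  expect_true(all(axial_diff(fld$cells$orientation_deg[!left], 90) < 1e-6))
  expect_error(field_spec(blocks = list(
    list(xlim = c(0, 60), ylim = c(0, 100)),
    list(xlim = c(50, 100), ylim = c(0, 100)))), "disjoint")
})

test_that("cohorts write parseable files plus a complete manifest", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(group_labels = c("wt", "mut"), n_embryos = c(2, 3),
                      sigma = list(wt = 10, mut = 25),
                      elements = c("element_1", "element_2"),
                      n_cells = 60, seed = 42)
  man <- generate_cohort(spec, dir)
  expect_equal(nrow(man), (2 + 3) * 2)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "axes.yaml")))
  for (i in seq_len(nrow(man))) {
    expect_no_warning({
      cells <- read_cells_geojson(file.path(dir, man$cells[i]), 0.5)
      regions <- read_regions_geojson(file.path(dir, man$regions[i]), 0.5)
    })
    expect_equal(nrow(cells), 60)
    expect_setequal(regions$role, c("cartilage", "marker:Col2", "hz", "marker:ColX"))
    expect_equal(unique(cells$annotation_id), man$element[i])
  }
  # regeneration reproducibility (counter-based sub-seeds)
  dir2 <- withr::local_tempdir()
  generate_cohort(spec, dir2)
  expect_identical(readLines(file.path(dir, man$cells[1])),
                   readLines(file.path(dir2, man$cells[1])))
})

test_that("synthetic cohorts exercise classification and zoning end to end", {
  fld <- generate_field(field_spec(n_cells = 200, width = 600, height = 300,
                                   hz_width = 100, seed = 3))
  cells <- classify_by_regions(fld$cells, fld$regions)
  d <- distance_to_hz(cells, fld$regions)
  cells <- assign_pz(cells, d, c(0, 400))
  tab <- table(cells$class_label)
  expect_true(all(c("chondro-hyper", "chondro-PZ") %in% names(tab)))
  # cells in the HZ strip are ColX+ hence chondro-hyper, never relabeled
  expect_true(all(cells$class_label[cells$x < 100] == "chondro-hyper"))
  # chondrocytes beyond 400 um of the strip keep their label
  expect_true(all(cells$class_label[d >= 400 & cells$x >= 100] == "chondrocyte"))
})

test_that("label-mask rendering round-trips geometry and orientation", {
  fld <- generate_field(field_spec(n_cells = 20, width = 200, height = 200,
                                   mean_area = 200, aspect_ratio = 3, seed = 14))
  mpp <- 0.25
  mask <- render_labelmask(fld$cells, mpp)
  expect_equal(max(mask), 20)
  f <- withr::local_tempfile(fileext = ".tif")
  write_labelmask(mask, f)
  back <- read_cells_labelmask(f, mpp, orientation_method = "moment")
  expect_equal(nrow(back), 20)
  expect_lt(max(abs(back$x - fld$cells$x)), 2 * mpp)
  expect_lt(max(abs(back$y - fld$cells$y)), 2 * mpp)
  # moment fit is robust to the staircase contour of a rasterized ellipse
  expect_lt(max(axial_diff(back$orientation_deg, fld$cells$orientation_deg)), 2)
  # the max-caliper (Feret) angle feels the jagged tips more; sanity bound
  feret <- read_cells_labelmask(f, mpp)
  expect_lt(max(axial_diff(feret$orientation_deg, fld$cells$orientation_deg)), 5)
  # empty cell list renders background only
  empty <- fld$cells[0, ]
  expect_equal(max(render_labelmask(empty, 0.5, dims = c(10, 10))), 0L)
  # uniform placement respects the density bound
  expect_error(generate_field(field_spec(n_cells = 500, width = 50, height = 50,
                                         placement = "uniform", seed = 1)),
               "density")
})
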