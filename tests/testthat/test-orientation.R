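test_that("axial difference respects 180-degree periodicity", {
  expect_equal(axial_diff(10, 170), 20)
  expect_equal(axial_diff(0, 90), 90)
  expect_equal(axial_diff(30, 30), 0)
  expect_equal(axial_diff(179, 1), 2)
  expect_equal(axial_diff(-10, 10), 20)      # reduced mod 180 internally
  expect_equal(axial_diff(c(10, 0), c(170, 90)), c(20, 90))
  expect_error(axial_diff(NA, 1), "finite")
  expect_error(axial_diff(Inf, 1), "finite")
})

test_that("GOA folds to [0, 90] and is invariant under joint rotation", {
  expect_equal(goa(25, 25), 0)
  expect_equal(goa(170, 0), 10)
  expect_equal(goa(90, 0), 90)
  set.seed(12)
  th <- runif(200, 0, 180); ax <- runif(200, 0, 180); d <- runif(200, -360, 360)
  expect_equal(goa(th + d, ax + d), goa(th, ax), tolerance = 1e-9)
  expect_true(all(goa(th, ax) >= 0 & goa(th, ax) <= 90))
})

test_that("neighbor graph uses an inclusive radius and matches brute force", {
  g <- build_neighbor_graph(cbind(c(0, 30), c(0, 0)), radius = 30)
  expect_equal(nrow(g$edges), 1)
  g2 <- build_neighbor_graph(cbind(c(0, 30.5), c(0, 0)), radius = 30)
  expect_equal(nrow(g2$edges), 0)
  expect_error(build_neighbor_graph(cbind(0, 0), radius = 0), "> 0")

  set.seed(21)
  xy <- cbind(runif(200, 0, 300), runif(200, 0, 300))
  g3 <- build_neighbor_graph(xy, 30)
  A <- matrix(FALSE, 200, 200)
  A[g3$edges] <- TRUE
  A <- A | t(A)
  expect_identical(A, unname(bf_adjacency(xy[, 1], xy[, 2], 30)))
  # symmetry + no self loops via the adjacency list
  adj <- as_adjacency(g3)
  expect_true(all(vapply(seq_along(adj), function(i)
    !(g3$ids[i] %in% adj[[i]]), logical(1))))
  for (i in seq_along(adj)) for (nb in adj[[i]])
    expect_true(g3$ids[i] %in% adj[[nb]])
})

test_that("folding maps the mean difference onto the 0-45 LMS scale", {
  expect_equal(fold_to_lms(45), 45)
  expect_equal(fold_to_lms(0), 0)
  expect_equal(fold_to_lms(90), 0)
  expect_equal(fold_to_lms(60), 30)
  expect_equal(fold_to_lms(60, mode = "raw"), 60)
  expect_error(fold_to_lms(91), "out of")
  expect_error(fold_to_lms(-1), "out of")
})

test_that("LMS matches hand arithmetic on a five-cell cross", {
  # center at origin, neighbors at 25 um N/S/E/W: inter-neighbor distances
  # exceed the radius, so each neighborhood is exactly as constructed
  cells <- make_cells(x = c(0, 25, -25, 0, 0), y = c(0, 0, 0, 25, -25),
                      theta = c(0, 30, 60, 90, 120), area = 20)
  sc <- lms_scores(cells, lms_config(radius = 30))
  expect_equal(sc$neighbor_count, c(4L, 1L, 1L, 1L, 1L))
  expect_equal(sc$raw_mean_diff_deg[1], (30 + 60 + 90 + 60) / 4)
  expect_equal(sc$lms_deg[1], 30)  # 45 - |45 - 60|
})

test_that("uniform alignment gives zero LMS; isolated cells are undefined", {
  fld <- generate_field(field_spec(n_cells = 300, noise_model = "none", seed = 2))
  sc <- lms_scores(fld$cells, lms_config(30))
  def <- sc$neighbor_count >= 1
  expect_true(any(def))
  expect_equal(max(abs(sc$lms_deg[def])), 0, tolerance = 1e-9)

  cells <- make_cells(c(0, 1000), c(0, 0), c(10, 20), area = 20)
  sc2 <- lms_scores(cells, lms_config(30))
  expect_true(all(is.na(sc2$lms_deg)))
  expect_true(all(is.na(sc2$raw_mean_diff_deg)))
})

test_that("LMS equals the double-loop oracle to 1e-9 on a 300-cell field", {
  set.seed(77)
  x <- runif(300, 0, 250); y <- runif(300, 0, 250); th <- runif(300, 0, 180)
  cells <- make_cells(x, y, th, area = 20)
  for (fold in c("folded", "raw")) {
    sc <- lms_scores(cells, lms_config(30, fold_mode = fold))
    oracle <- bf_lms(x, y, cells$orientation_deg, 30, folded = fold == "folded")
    expect_equal(sc$lms_deg, oracle, tolerance = 1e-9)
  }
})

test_that("LMS is exactly invariant to global rotation, reflection and reference axis", {
  set.seed(13)
  x <- runif(150, 0, 200); y <- runif(150, 0, 200); th <- runif(150, 0, 180)
  base <- bf_lms(x, y, th, 30)
  expect_equal(lms_scores_theta(x, y, th), base, tolerance = 1e-9)
  for (delta in c(13.7, 90, 177.3)) {
    shifted <- lms_scores_theta(x, y, (th + delta) %% 180)
    expect_equal(shifted, base, tolerance = 1e-9)
  }
  reflected <- lms_scores_theta(x, y, (180 - th) %% 180)
  expect_equal(reflected, base, tolerance = 1e-9)
})

test_that("mean raw difference approaches 45 as neighborhoods grow (uniform angles)", {
  fld <- generate_field(field_spec(n_cells = 2000, width = 500, height = 500,
                                   noise_model = "uniform", seed = 4))
  sc <- lms_scores(fld$cells, lms_config(radius = 400))
  def <- !is.na(sc$lms_deg)
  expect_gt(mean(sc$neighbor_count[def]), 1000)
  expect_equal(mean(sc$raw_mean_diff_deg[def]), 45, tolerance = 1)
  expect_equal(mean(sc$lms_deg[def]), 45, tolerance = 1)
})

test_that("class-restricted scoring keeps other classes out of neighborhoods", {
  cells <- make_cells(x = c(0, 10, 5), y = c(0, 0, 8),
                      theta = c(40, 40, 130), area = 20,
                      class_label = c("chondrocyte", "chondrocyte", "myocyte"),
                      id = c("c1", "c2", "m1"))
  all_cls <- orientation_scores(cells, config = lms_config(30))
  expect_gt(all_cls$lms_deg[all_cls$id == "c1"], 0)  # myocyte contaminates
  chon <- orientation_scores(cells, config = lms_config(30),
                             classes = "chondrocyte")
  expect_equal(nrow(chon), 2)
  expect_equal(chon$lms_deg, c(0, 0), tolerance = 1e-9)
  expect_equal(attr(chon, "n_class_excluded"), 1L)
})

test_that("missing tissue axis for an annotation is a configuration error", {
  cells <- make_cells(c(0, 10), c(0, 0), c(0, 90), annotation_id = "element_2")
  expect_error(goa_scores(cells, c(element_1 = 90)), "element_2")
  sc <- orientation_scores(cells, axes = c(element_2 = 90))
  expect_equal(sc$goa_deg, goa(cells$orientation_deg, 90))
})
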