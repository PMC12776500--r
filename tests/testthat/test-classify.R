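regions_fixture <- function() {
  region_set(
    list(rect_polygon(c(0, 100), c(0, 100)),    # cartilage = Col2 domain
         rect_polygon(c(0, 100), c(0, 100)),
         rect_polygon(c(0, 30), c(0, 100)),     # ColX / HZ strip
         rect_polygon(c(0, 30), c(0, 100)),
         rect_polygon(c(120, 160), c(0, 100))), # muscle block to the right
    name = c("cart", "col2", "colx", "hz", "musc"),
    role = c("cartilage", "marker:Col2", "marker:ColX", "hz", "muscle"))
}

test_that("sequential classification follows the marker precedence", {
  regions <- regions_fixture()
  cells <- make_cells(x = c(10, 60, 140, 200), y = rep(50, 4),
                      theta = rep(0, 4), area = 20,
                      id = c("hyp", "chon", "myo", "oth"))
  out <- classify_by_regions(cells, regions)
  expect_equal(out$class_label,
               c("chondro-hyper", "chondrocyte", "myocyte", "other"))
  # partition: every cell exactly one label from the closed vocabulary
  expect_true(all(out$class_label %in%
                  c("chondrocyte", "chondro-hyper", "myocyte", "chondro-PZ", "other")))
  expect_equal(sum(table(out$class_label)), nrow(out))
})

test_that("missing Col2 region is a configuration error; absent optional roles are not", {
  cells <- make_cells(10, 10, 0, area = 20)
  no_col2 <- region_set(list(rect_polygon(c(0, 10), c(0, 10))), "hz", "hz")
  expect_error(classify_by_regions(cells, no_col2), "marker:Col2")
  col2_only <- region_set(list(rect_polygon(c(0, 100), c(0, 100))),
                          "col2", "marker:Col2")
  expect_message(out <- classify_by_regions(cells, col2_only), "chondro-hyper")
  expect_equal(out$class_label, "chondrocyte")
})

test_that("HZ distance is zero inside, exact outside, and matches the oracle", {
  regions <- regions_fixture()
  cells <- make_cells(x = c(15, 380, 50), y = c(50, 50, 50),
                      theta = rep(0, 3), area = 20, id = c("in", "far", "mid"))
  d <- distance_to_hz(cells, regions)
  expect_equal(unname(d["in"]), 0)
  expect_equal(unname(d["far"]), 350)
  expect_equal(unname(d["mid"]), 20)
  no_hz <- region_set(list(rect_polygon(c(0, 1), c(0, 1))), "c", "cartilage")
  expect_error(distance_to_hz(cells, no_hz), "hz")

  set.seed(5)
  pts <- cbind(runif(100, -50, 200), runif(100, -50, 200))
  cells2 <- make_cells(pts[, 1], pts[, 2], rep(0, 100), area = 1, aspect = 2)
  hzpoly <- regions_fixture()$polygon[[4]]
  d2 <- distance_to_hz(cells2, regions_fixture())
  oracle <- vapply(seq_len(nrow(cells2)), function(i)
    bf_dist_to_polygon(c(cells2$x[i], cells2$y[i]), hzpoly), numeric(1))
  expect_equal(unname(d2), oracle, tolerance = 1e-6)
  # translation invariance
  shift <- c(37, -12)
  cells3 <- make_cells(pts[, 1] + shift[1], pts[, 2] + shift[2],
                       rep(0, 100), area = 1, aspect = 2)
  hz_shift <- hzpoly
  hz_shift[, 1] <- hz_shift[, 1] + shift[1]; hz_shift[, 2] <- hz_shift[, 2] + shift[2]
  rs <- region_set(list(hz_shift), "hz", "hz")
  expect_equal(unname(distance_to_hz(cells3, rs)), unname(d2), tolerance = 1e-9)
})

test_that("chondro-PZ zoning uses a half-open window and is idempotent", {
  cells <- make_cells(x = 1:4 * 10, y = rep(5, 4), theta = rep(0, 4), area = 20,
                      id = c("a", "b", "c", "d"))
  cells$class_label <- c("chondrocyte", "chondrocyte", "chondrocyte", "chondro-hyper")
  d <- stats::setNames(c(350, 450, 400, 100), cells$id)
  out <- assign_pz(cells, d)
  expect_equal(out$class_label,
               c("chondro-PZ", "chondrocyte", "chondrocyte", "chondro-hyper"))
  expect_identical(assign_pz(out, d)$class_label, out$class_label)
  expect_error(assign_pz(cells, d, window = c(400, 400)), "lo < hi")
})

test_that("distance binning aggregates per half-open bin and reports empty bins", {
  s <- stats::setNames(rep(10, 4), letters[1:4])
  d <- stats::setNames(c(50, 150, 151, 420), letters[1:4])
  prof <- bin_by_distance(s, d, 100)
  expect_equal(prof$n, c(1L, 2L, 0L, 0L, 1L))
  expect_equal(prof$mean[!is.na(prof$mean)], c(10, 10, 10))
  expect_true(all(is.na(prof$mean[prof$n == 0])))

  set.seed(8)
  s2 <- stats::setNames(runif(20, 0, 45), sprintf("c%02d", 1:20))
  d2 <- stats::setNames(runif(20, 0, 500), names(s2))
  prof2 <- bin_by_distance(s2, d2, 100)
  for (k in seq_len(nrow(prof2))) {
    sel <- d2 >= prof2$bin_lo[k] & d2 < prof2$bin_hi[k]
    expect_equal(prof2$n[k], sum(sel))
    if (any(sel)) {
      expect_equal(prof2$mean[k], mean(s2[sel]))
      expect_equal(prof2$median[k], stats::median(s2[sel]))
    }
  }
  expect_error(bin_by_distance(stats::setNames(NA_real_, "a"),
                               stats::setNames(1, "a"), 100), "empty input")
})

test_that("edge/size filtering drops the right cells and accounts for every drop", {
  cart <- region_set(list(rect_polygon(c(0, 100), c(0, 100))), "c", "cartilage")
  cells <- make_cells(x = c(5, 50, 50, 50), y = c(50, 50, 5, 95),
                      theta = rep(0, 4), area = 20,
                      id = c("edge1", "mid", "edge2", "edge3"))
  out <- filter_cells(cells, cart, edge_margin = 10)
  expect_equal(out$id, "mid")
  expect_equal(unname(attr(out, "exclusions")), c(3L, 0L, 0L))

  # identity when unconstrained
  out2 <- filter_cells(cells, cart, edge_margin = 0)
  expect_equal(nrow(out2), 4)
  expect_equal(sum(attr(out2, "exclusions")), 0L)

  big <- make_cells(c(50, 52), c(50, 52), c(0, 0), area = 400, id = c("b1", "b2"))
  mixed <- rbind_cells(cells, big)
  out3 <- filter_cells(mixed, cart, edge_margin = 10, min_area = 10, max_area = 100)
  exc <- attr(out3, "exclusions")
  expect_equal(nrow(mixed) - nrow(out3), sum(exc))
  expect_equal(unname(exc["area_large"]), 2L)
  expect_error(filter_cells(cells, cart, min_area = 10, max_area = 1), "min_area")
})
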