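# Geometry core: region construction, areas, angles, clearances, diameters.

test_that("device circles polygonize to the right area and validate input", {
  circ <- make_device_circle(c(0, 0), 2.0, "burr")
  expect_equal(polygon_area(circ$ring), pi, tolerance = 1e-3)
  cath <- make_device_circle(c(1, 1), 0.9, "catheter")
  expect_equal(polygon_area(cath$ring), pi * 0.45^2, tolerance = 1e-3)
  # defaults by device kind
  expect_equal(make_device_circle(c(0, 0), kind = "wire")$diameter, 0.229)
  expect_error(make_device_circle(c(0, 0), 0, "burr"), "positive")
  expect_error(make_device_circle(c(0, 0), -1, "burr"), "positive")
  expect_error(make_device_circle(c(0, 0), kind = "burr"), "diameter")
})

test_that("polygon constructor enforces simplicity and orientation", {
  p <- polygon2d(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(polygon_area(p), 1.0)
  # clockwise input is reoriented to counter-clockwise
  q <- polygon2d(c(0, 0, 1, 1), c(0, 1, 1, 0))
  expect_gt(rotadebulk:::signed_ring_area(q), 0)
  expect_error(polygon2d(c(0, 1), c(0, 1)), ">= 3")
  expect_error(polygon2d(c(0, 3, 3, 1, 0), c(0, 0, 3, -1, 3)),
               "self-intersecting")
  expect_error(polygon2d(c(0, 1, 2), c(0, 0, 0)), "degenerate")
})

test_that("predicted region matches the two-circle lens closed form", {
  # lumen: unit circle at origin; burr: diameter 2 at (0.5, 0)
  lum_circ <- make_device_circle(c(0, 0), 2.0, "burr")
  lumen <- polygon2d(lum_circ$ring$x, lum_circ$ring$y, check_simple = FALSE)
  burr <- make_device_circle(c(0.5, 0), 2.0, "burr")
  d <- 0.5
  lens <- 2 * acos(d / 2) - (d / 2) * sqrt(4 - d^2)
  expect_equal(region_area(predicted_region(burr, lumen)), pi - lens,
               tolerance = 1e-3 / (pi - lens))
  # identical burr and lumen: nothing predicted
  expect_equal(region_area(predicted_region(lum_circ, lumen)), 0)
  # burr strictly inside the lumen: nothing predicted
  small <- make_device_circle(c(0.1, 0), 0.5, "burr")
  expect_equal(region_area(predicted_region(small, lumen)), 0)
})

test_that("actual region recovers the concentric annulus closed form", {
  mkcirc <- function(r) {
    c0 <- make_device_circle(c(0, 0), 2 * r, "burr")
    polygon2d(c0$ring$x, c0$ring$y, check_simple = FALSE)
  }
  pre <- mkcirc(1.0); post <- mkcirc(1.1)
  A <- actual_region(pre, post)
  expect_equal(region_area(A), pi * (1.1^2 - 1.0^2),
               tolerance = 1e-3 / (pi * 0.21))
  expect_equal(attr(A, "lumen_loss_area"), 0)
  # no debulking
  expect_equal(region_area(actual_region(pre, pre)), 0)
  # lumen loss (post smaller than pre) is excluded from A and surfaced
  A2 <- actual_region(post, pre)
  expect_equal(region_area(A2), 0)
  expect_equal(attr(A2, "lumen_loss_area"), pi * (1.1^2 - 1.0^2),
               tolerance = 1e-3)
})

test_that("overlap region behaves as a set intersection", {
  sq1 <- polygon2d(c(0, 1, 1, 0), c(0, 0, 1, 1))
  sq2 <- polygon2d(c(0.5, 1.5, 1.5, 0.5), c(0, 0, 1, 1))
  O <- overlap_region(sq1, sq2)
  expect_equal(region_area(O), 0.5)
  # identity
  expect_equal(region_area(overlap_region(sq1, sq1)), 1.0)
  # disjoint
  sq3 <- polygon2d(c(5, 6, 6, 5), c(0, 0, 1, 1))
  expect_equal(region_area(overlap_region(sq1, sq3)), 0)
})

test_that("region area agrees with an independent shoelace computation", {
  skip_if_not_installed("pracma")
  set.seed(101)
  for (i in 1:20) {
    p <- random_blob(runif(1, 0.5, 2))
    expect_equal(polygon_area(p), abs(pracma::polyarea(p$x, p$y)),
                 tolerance = 1e-9)
  }
  # region with a hole: ring minus inner ring
  outer_sq <- polygon2d(c(0, 4, 4, 0), c(0, 0, 4, 4))
  inner_sq <- polygon2d(c(1, 2, 2, 1), c(1, 1, 2, 2))
  holey <- rotadebulk:::region_clip(outer_sq, inner_sq, "minus")
  expect_equal(region_area(holey), 15)
})

test_that("angular extent measures sectors, wrap-around, and full coverage", {
  ctr <- c(0, 0)
  sector <- function(a0, a1, r0 = 0.5, r1 = 1) {
    th <- seq(a0, a1, length.out = 60) * pi / 180
    polygon2d(c(r0 * cos(th), rev(r1 * cos(th))),
              c(r0 * sin(th), rev(r1 * sin(th))), check_simple = FALSE)
  }
  expect_equal(angular_extent(sector(30, 90), ctr), 60, tolerance = 1e-6)
  # two disjoint sectors merging across 0/360
  r <- rotadebulk:::new_region(list(unclass(sector(0, 40)),
                                    unclass(sector(350, 360))))
  expect_equal(angular_extent(r, ctr), 50, tolerance = 1e-6)
  # full annulus
  ring_out <- make_device_circle(c(0, 0), 2, "burr")
  ring_in <- make_device_circle(c(0, 0), 1, "burr")
  annulus <- rotadebulk:::region_clip(ring_out, ring_in, "minus")
  expect_equal(angular_extent(annulus, ctr), 360)
  # empty region
  expect_equal(angular_extent(rotadebulk:::new_region(list()), ctr), 0)
  # center inside the region is degenerate
  disc <- polygon2d(ring_out$ring$x, ring_out$ring$y, check_simple = FALSE)
  expect_error(angular_extent(disc, ctr), "inside")
})

test_that("angular extent agrees with the ray-sampling oracle on random shapes", {
  set.seed(202)
  ctr <- c(0, 0)
  for (i in 1:15) {
    # a blob placed away from the center so extents vary widely
    p <- random_blob(runif(1, 0.3, 0.8), wobble = 0.2)
    shift <- runif(1, 1.0, 2.0)
    ang <- runif(1, 0, 2 * pi)
    q <- polygon2d(p$x + shift * cos(ang), p$y + shift * sin(ang),
                   check_simple = FALSE)
    expect_lt(abs(angular_extent(q, ctr) - ray_angular_extent(q, ctr)), 0.5)
  }
})

test_that("clearances are edge-to-edge, clamp at contact, and are symmetric", {
  cath <- make_device_circle(c(0, 0), 0.9, "catheter")
  wire <- make_device_circle(c(2, 0), 0.229, "wire")
  expect_equal(min_clearance(cath, wire), 2 - 0.45 - 0.1145)
  expect_equal(min_clearance(wire, cath), min_clearance(cath, wire))
  # overlapping circles are in contact
  wire2 <- make_device_circle(c(0.5, 0), 0.229, "wire")
  expect_equal(min_clearance(cath, wire2), 0)
  # device inside a lumen: gap between surface and contour
  set.seed(303)
  for (i in 1:10) {
    lum <- random_blob(1.2, 0.1)
    dev <- make_device_circle(c(runif(1, -0.3, 0.3), runif(1, -0.3, 0.3)),
                              0.9, "catheter")
    got <- min_clearance(dev, lum)
    want <- max(0, brute_min_distance(dev, lum))
    expect_equal(got, want, tolerance = 2e-3)
  }
  # polygon vs polygon
  sq1 <- polygon2d(c(0, 1, 1, 0), c(0, 0, 1, 1))
  sq2 <- polygon2d(c(3, 4, 4, 3), c(1.5, 1.5, 2.5, 2.5))
  expect_equal(min_clearance(sq1, sq2), brute_min_distance(sq1, sq2),
               tolerance = 2e-3)
  expect_equal(min_clearance(sq1, sq1), 0)
})

test_that("lumen diameters match circles, ellipses, and a dense-fan oracle", {
  circ <- make_device_circle(c(3, -2), 2.0, "burr")
  lum <- polygon2d(circ$ring$x, circ$ring$y, check_simple = FALSE)
  ld <- lumen_diameters(lum)
  expect_equal(ld$min_diameter, 2.0, tolerance = 1e-3)
  expect_equal(ld$mean_diameter, 2.0, tolerance = 1e-3)
  expect_equal(ld$area, pi, tolerance = 1e-3)
  # ellipse with semi-axes 1.5 and 1.0
  th <- 2 * pi * (0:255) / 256
  ell <- polygon2d(1.5 * cos(th), 1.0 * sin(th), check_simple = FALSE)
  lde <- lumen_diameters(ell)
  expect_equal(lde$min_diameter, 2.0, tolerance = 2e-3)
  fine <- lumen_diameters(ell, step_deg = 0.1)
  expect_equal(lde$mean_diameter, fine$mean_diameter, tolerance = 0.005)
  expect_error(lumen_diameters(polygon2d(c(0, 1e-4, 1e-4, 0),
                                         c(0, 0, 1e-4, 1e-4))), "degenerate")
})

test_that("geometric invariants hold on randomized frames", {
  set.seed(404)
  cohort <- tiny_cohort(seed = 17, n_lesions = 3)
  for (lesion in cohort) {
    for (pair in lesion$pairs) {
      pre <- pair$pre
      burr <- make_device_circle(pre$catheter$center, pre$burr_diameter, "burr")
      P <- predicted_region(burr, pre$lumen)
      A <- actual_region(pre$lumen, pair$post$lumen)
      O <- overlap_region(P, A)
      pa <- region_area(P); aa <- region_area(A); oa <- region_area(O)
      expect_lte(oa, min(pa, aa) + 1e-9)
      expect_gte(min(pa, aa, oa), 0)
      ctr <- polygon_centroid(pre$lumen)
      ang_p <- angular_extent(P, ctr); ang_a <- angular_extent(A, ctr)
      ang_o <- angular_extent(O, ctr)
      expect_lte(ang_o, min(ang_p, ang_a) + 1e-6)
      expect_lte(max(ang_p, ang_a), 360)
      # the burr circle partitions into wall part and lumen part
      inlum <- region_area(overlap_region(burr, pre$lumen))
      expect_equal(pa + inlum, polygon_area(burr$ring), tolerance = 1e-6)
      # clearance symmetry
      expect_equal(min_clearance(pre$catheter, pre$wire),
                   min_clearance(pre$wire, pre$catheter))
    }
  }
})
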