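test_that("orientation is normalized to clockwise under y-down", {
  # counterclockwise-on-screen input gets reversed; first point stays first
  ccw <- closed_contour(rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0)))
  expect_gt(shapecat:::signed_area_yup(ccw), 0)
  expect_equal(ccw$points[1, ], c(0, 0))
  cw <- unit_square()
  expect_equal(cw$points, rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
})

test_that("constructor rejects degenerate input and drops duplicates", {
  expect_error(closed_contour(rbind(c(0, 0), c(1, 1))), "at least 3")
  expect_error(closed_contour(rbind(c(0, 0), c(1, NA), c(0, 1))), "finite")
  withclose <- closed_contour(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0)))
  expect_equal(n_points(withclose), 4L)
})

test_that("perimeter matches closed forms and a brute-force edge sum", {
  expect_equal(perimeter(unit_square()), 4)
  expect_equal(perimeter(rect_contour(1, 2)), 6)
  poly <- random_star_polygon(30, seed = 5)
  p <- poly$points
  oracle <- sum(sqrt(rowSums((p[c(2:30, 1), ] - p)^2)))
  expect_equal(perimeter(poly), oracle, tolerance = 1e-12)
})

test_that("area matches closed forms and a Monte-Carlo oracle", {
  expect_equal(contour_area(unit_square()), 1)
  tri <- closed_contour(rbind(c(0, 0), c(1, 0), c(0, 1)))
  expect_equal(contour_area(tri), 0.5)
  expect_error(contour_area(bowtie_contour(), check = TRUE), "self-intersecting")

  poly <- random_star_polygon(12, seed = 3)
  set.seed(99)
  bb <- apply(poly$points, 2, range)
  pts <- cbind(stats::runif(1e6, bb[1, 1], bb[2, 1]),
               stats::runif(1e6, bb[1, 2], bb[2, 2]))
  mc <- mean(oracle_in_polygon(poly$points, pts)) *
    prod(bb[2, ] - bb[1, ])
  expect_equal(contour_area(poly), mc, tolerance = 0.005)
})

test_that("resampling is exact on corners, equal-spaced, and idempotent", {
  sq <- unit_square()
  expect_equal(resample_contour(sq, 4)$points, sq$points)

  c1000 <- circle_contour(1000)
  r360 <- resample_contour(c1000, 360)
  expect_equal(n_points(r360), 360L)
  expect_equal(perimeter(r360), 2 * pi, tolerance = 1e-3)
  # equal arc spacing: chord lengths agree closely on a near-smooth source,
  # and exactly when sample points avoid straddling source corners
  el <- sqrt(rowSums((r360$points[c(2:360, 1), ] - r360$points)^2))
  expect_lt(diff(range(el)) / mean(el), 1e-4)
  sq360 <- resample_contour(unit_square(), 360)
  el_sq <- sqrt(rowSums((sq360$points[c(2:360, 1), ] - sq360$points)^2))
  expect_lt(diff(range(el_sq)) / mean(el_sq), 1e-9)
  # starting point preserved
  expect_equal(r360$points[1, ], c1000$points[1, ])
  # idempotence
  again <- resample_contour(r360, 360)
  expect_equal(again$points, r360$points, tolerance = 1e-6)

  expect_error(resample_contour(sq, 2), "n_points")
  degen <- structure(list(points = matrix(0, 3, 2), stroke_mode = NULL),
                     class = "closed_contour")
  expect_error(resample_contour(degen), "perimeter|degenerate")
})

test_that("resampling preserves perimeter within 0.5% on smooth shapes", {
  for (n in c(180, 240, 360)) {
    r <- resample_contour(circle_contour(2000), n)
    expect_lt(abs(perimeter(r) - 2 * pi) / (2 * pi), 0.005)
  }
  blob <- generate_exemplar(3, "curved", seed = 2)$contour
  r <- resample_contour(blob, 180)
  expect_lt(abs(perimeter(r) - perimeter(blob)) / perimeter(blob), 0.005)
})

test_that("area and perimeter are rigid-motion invariant", {
  poly <- random_star_polygon(40, seed = 11)
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- closed_contour(sweep(poly$points %*% R, 2, c(13.7, -2.9), "+"))
  expect_equal(contour_area(moved), contour_area(poly), tolerance = 1e-9)
  expect_equal(perimeter(moved), perimeter(poly), tolerance = 1e-9)
})

test_that("leftmost_start_index breaks ties by min y then lowest index", {
  sq <- unit_square()
  expect_equal(leftmost_start_index(sq), 1L)      # (0,0) beats (0,1)
  shifted <- closed_contour(sq$points + 5)
  expect_equal(leftmost_start_index(shifted), 1L) # translation equivariance
  poly <- random_star_polygon(50, seed = 21)
  p <- poly$points
  oracle <- which(p[, 1] == min(p[, 1]))
  oracle <- oracle[which.min(p[oracle, 2])]
  expect_equal(leftmost_start_index(poly), oracle)
})

test_that("straight_fraction separates polygons from curves", {
  sq360 <- resample_contour(unit_square(), 360)
  expect_gte(straight_fraction(sq360), 0.9)
  expect_gte(straight_fraction(sq360, window = 1), 0.95)
  circ <- circle_contour(360)
  expect_lte(straight_fraction(circ), 0.05)
  # stroke metadata takes precedence over geometry
  circ$stroke_mode <- rep("straight", 360)
  expect_equal(straight_fraction(circ), 1)
  expect_lte(straight_fraction(circ, use_stroke = FALSE), 0.05)
})

test_that("straight_fraction approximates the analytic share on a stadium", {
  st <- resample_contour(stadium_contour(s = 2), 360)
  share <- 3 * 2 / (3 * 2 + pi * 1)           # straight sides / perimeter
  expect_lt(abs(straight_fraction(st) - share), 0.1)
  # replacing the arc by a polyline raises the fraction (monotonicity)
  sq <- resample_contour(rect_contour(2, 2), 360)
  expect_gt(straight_fraction(sq), straight_fraction(st))
})

test_that("cut_part splits the contour into complementary segments", {
  sq <- unit_square()
  cp <- cut_part(sq, 1, 3)
  expect_equal(cp$side1$length + cp$side2$length, 4L)
  expect_equal(sort(c(segment_indices(cp$side1), segment_indices(cp$side2))),
               1:4)
  expect_equal(cp$side1$length, 2L)

  # crescent: chord between the horn tips exits the polygon
  th_out <- seq(-2, 2, length.out = 40)
  th_in <- seq(1.9, -1.9, length.out = 30)
  crescent <- closed_contour(rbind(
    cbind(2 * cos(th_out), 2 * sin(th_out)),
    cbind(1.4 * cos(th_in) + 0.9, 1.4 * sin(th_in))))
  expect_error(cut_part(crescent, 1, 40), "inside")
  expect_error(cut_part(sq, 2, 2), "differ")
})

test_that("any chord of a convex polygon is accepted and partitions it", {
  poly <- resample_contour(circle_contour(60, 3), 60)
  set.seed(4)
  for (k in 1:25) {
    ij <- sample(60, 2)
    if (abs(ij[1] - ij[2]) %in% c(1, 59)) next
    cp <- cut_part(poly, ij[1], ij[2])
    idx <- c(segment_indices(cp$side1), segment_indices(cp$side2))
    expect_equal(sort(idx), 1:60)
    expect_equal(anyDuplicated(idx), 0L)
  }
})

test_that("self_intersects agrees with an all-pairs oracle", {
  expect_false(self_intersects(unit_square()))
  expect_true(self_intersects(bowtie_contour()))
  set.seed(17)
  for (k in 1:20) {
    # random polygons, some self-intersecting
    pts <- matrix(stats::runif(2 * 8), ncol = 2)
    cc <- closed_contour(pts, normalize = FALSE)
    expect_equal(self_intersects(cc), oracle_self_intersects(cc),
                 info = paste("case", k))
  }
  for (k in 1:5) {
    star <- random_star_polygon(20, seed = 100 + k)
    expect_false(self_intersects(star))
  }
})
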