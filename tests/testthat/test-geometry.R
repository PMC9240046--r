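test_that("signed distance to a line matches direct cases and the dense oracle", {
  horiz <- reference_line(point2d(-500, 0), point2d(500, 0))
  expect_equal(signed_distance_to_line(point2d(0, 100), horiz), 100)
  expect_equal(signed_distance_to_line(point2d(123, 0), horiz), 0)
  expect_equal(signed_distance_to_line(point2d(0, -50), horiz), -50)

  diag45 <- reference_line(point2d(0, 0), point2d(100, 100))
  got <- signed_distance_to_line(point2d(0, 100), diag45)
  expect_equal(abs(got), oracle_line_distance(c(0, 100), c(0, 0), c(100, 100)),
               tolerance = 1e-4)
  expect_gt(got, 0)  # point lies on the posterior side

  expect_error(reference_line(point2d(1, 2), point2d(1, 2)), "coincide")
})

test_that("curve/line intersections agree with the per-segment oracle", {
  line <- reference_line(point2d(-10, 0), point2d(10, 0))
  cv <- curve2d(c(0, 100), c(-100, 100), role = "ILM")
  got <- curve_line_intersections(cv, line)
  expect_equal(unname(got), cbind(50, 0))

  # three crossings of a tilted line
  set.seed(11)
  cx <- seq(0, 600, by = 25)
  cz <- 80 * sin(cx / 70) + rnorm(length(cx), 0, 5)
  cv <- curve2d(cx, cz, role = "ILM")
  a <- c(-50, -20); b <- c(700, 35)
  got <- curve_line_intersections(cv, reference_line(point2d(a[1], a[2]),
                                                     point2d(b[1], b[2])))
  exp <- oracle_intersections(cx, cz, a, b)
  expect_equal(nrow(got), nrow(exp))
  expect_equal(unname(got), unname(exp), tolerance = 1e-9)
  # every reported point lies on the line
  ref <- reference_line(point2d(a[1], a[2]), point2d(b[1], b[2]))
  for (i in seq_len(nrow(got))) {
    expect_lt(abs(signed_distance_to_line(got[i, ], ref)), 1e-9)
  }

  # exactly collinear overlap is an explicit error, not an answer
  flat <- curve2d(c(-100, 0, 100), c(0, 0, 0), role = "ILM")
  expect_error(curve_line_intersections(flat, line),
               class = "onh_collinear_error")
})

test_that("minimum point-to-curve distance is exact and tie-broken by smaller foot x", {
  flat <- curve2d(c(-1000, 1000), c(-200, -200), role = "ILM")
  got <- min_distance_point_to_curve(point2d(0, 0), flat)
  expect_equal(got$distance, 200)
  expect_equal(unname(got$foot), c(0, -200))

  onc <- min_distance_point_to_curve(point2d(0, -200), flat)
  expect_equal(onc$distance, 0)

  # circular-arc polyline sampled at 1 um pitch vs the dense oracle
  th <- seq(pi * 0.75, pi * 0.25, length.out = 800)
  cx <- 350 * cos(th); cz <- -350 * sin(th)  # cx already increasing
  arc <- curve2d(cx, cz, role = "ILM")
  got <- min_distance_point_to_curve(point2d(20, 30), arc)
  expect_equal(got$distance,
               oracle_min_distance(c(20, 30), arc$x, arc$z), tolerance = 0.5)

  # never larger than the distance to any vertex
  set.seed(21)
  for (i in 1:20) {
    cx <- sort(runif(15, -500, 500)); cz <- runif(15, -300, 300)
    cv <- curve2d(cx, cz, role = "ILM")
    p <- point2d(runif(1, -600, 600), runif(1, -400, 400))
    d <- min_distance_point_to_curve(p, cv)$distance
    expect_lte(d, min(sqrt((cx - p[1])^2 + (cz - p[2])^2)) + 1e-12)
  }

  # symmetric tie resolves toward the smaller foot x
  vee <- curve2d(c(-100, 0, 100), c(0, 100, 0), role = "ILM")
  tie <- min_distance_point_to_curve(point2d(0, 0), vee)
  left <- min(tie$foot[1])
  alt <- min_distance_point_to_curve(point2d(0, 0),
                                     curve2d(c(-100, 0, 100), c(0, 100, 0), "ILM"))
  expect_lt(tie$foot[1], 0)
  expect_equal(tie$distance, alt$distance)
})

test_that("perpendicular feet match the ray-marching oracle and fail cleanly", {
  horiz <- reference_line(point2d(-750, 0), point2d(750, 0))
  flat <- curve2d(c(-900, 900), c(300, 300), role = "ALCS")
  expect_equal(unname(perpendicular_foot_on_curve(point2d(0, 0), horiz, flat)),
               c(0, 300))

  # tilted line at 30 degrees over a flat curve
  tilt <- reference_line(point2d(0, 0), point2d(cos(pi / 6) * 1000,
                                                sin(pi / 6) * 1000))
  got <- perpendicular_foot_on_curve(point2d(200, 115.47), tilt, flat)
  exp <- oracle_perpendicular_foot(c(200, 115.47), c(0, 0),
                                   c(cos(pi / 6) * 1000, sin(pi / 6) * 1000),
                                   flat$x, flat$z)
  expect_equal(unname(got), exp, tolerance = 0.2)

  # curve ending short of the drop point is an explicit error
  shortc <- curve2d(c(-900, -100), c(300, 300), role = "ALCS")
  expect_error(perpendicular_foot_on_curve(point2d(0, 0), horiz, shortc),
               class = "onh_no_alcs_error")
})

test_that("distance queries are invariant under rigid motions", {
  set.seed(33)
  for (i in 1:15) {
    cx <- seq(0, 400, by = 20)
    cz <- runif(length(cx), -40, 40)  # gentle slopes keep x monotone
    p <- c(runif(1, -100, 500), runif(1, -200, 200))
    a <- c(-50, runif(1, -30, 30)); b <- c(450, runif(1, -30, 30))
    theta <- runif(1, -0.3, 0.3); shift <- runif(2, -500, 500)
    cv1 <- curve2d(cx, cz, "ILM")
    d1 <- min_distance_point_to_curve(point2d(p[1], p[2]), cv1)$distance
    s1 <- abs(signed_distance_to_line(point2d(p[1], p[2]),
                                      reference_line(point2d(a[1], a[2]),
                                                     point2d(b[1], b[2]))))
    tc <- rigid_transform(cbind(cx, cz), theta, shift)
    tp <- rigid_transform(rbind(p), theta, shift)
    ta <- rigid_transform(rbind(a), theta, shift)
    tb <- rigid_transform(rbind(b), theta, shift)
    cv2 <- curve2d(tc[, 1], tc[, 2], "ILM")
    d2 <- min_distance_point_to_curve(point2d(tp[1], tp[2]), cv2)$distance
    s2 <- abs(signed_distance_to_line(point2d(tp[1], tp[2]),
                                      reference_line(point2d(ta[1], ta[2]),
                                                     point2d(tb[1], tb[2]))))
    expect_equal(d1, d2, tolerance = 1e-6)
    expect_equal(s1, s2, tolerance = 1e-6)
  }
})

test_that("curve constructor rejects malformed polylines", {
  expect_error(curve2d(c(0, 0), c(1, 2), "ILM"), "strictly increasing")
  expect_error(curve2d(c(0), c(1), "ILM"), ">= 2")
  expect_error(curve2d(c(0, 1), c(NA, 2), "ILM"), "finite")
})
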