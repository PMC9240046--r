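flat_section <- function(hrw_t = 300, hrw_n = 320, mrw_t = 200, mrw_n = 210,
                         w = 1500, lcci = 10) {
  make_section(w = w, hrw_t = hrw_t, hrw_n = hrw_n, mrw_t = mrw_t,
               mrw_n = mrw_n, lcci = lcci, tilt_deg = 0)
}

test_that("BMO reference line width is the Euclidean opening width", {
  s <- flat_section(w = 1500)
  ref <- bmo_reference_line(s)
  expect_equal(ref$w, 1500, tolerance = 1e-9)
  # direct Pythagoras on a hand-built section with a 200 um z offset
  ilm <- curve2d(c(-800, 2300), c(-250, -250), "ILM")
  bm <- curve2d(c(-800, 0, 1500, 2300), c(-107, 0, 200, 307), "BM")
  alcs <- curve2d(c(-200, 750, 1700), c(300, 450, 520), "ALCS")
  s2 <- bscan_section("t", "central", 0L, ilm, bm, alcs,
                      point2d(0, 0), point2d(1500, 200), 30)
  expect_equal(bmo_reference_line(s2)$w, sqrt(1500^2 + 200^2))
})

test_that("HRW is the along-line distance to the rim-side ILM crossing", {
  s <- flat_section(hrw_t = 300, hrw_n = 320)
  expect_equal(compute_hrw(s, "temporal"), 300, tolerance = 1e-6)
  expect_equal(compute_hrw(s, "nasal"), 320, tolerance = 1e-6)

  # tilted reference line: constructed crossing at along-line distance 250
  st <- make_section(hrw_t = 250, hrw_n = 250, mrw_t = 120, mrw_n = 120,
                     tilt_deg = 10)
  expect_equal(compute_hrw(st, "temporal"), 250, tolerance = 0.5)
  expect_equal(compute_hrw(st, "nasal"), 250, tolerance = 0.5)

  # ILM that never crosses the line on the rim side -> unmeasurable
  ilm <- curve2d(c(-800, 2300), c(-250, -250), "ILM")  # always anterior
  bm <- curve2d(c(-800, 0, 1500, 2300), rep(0, 4), "BM")
  alcs <- curve2d(c(-200, 750, 1700), c(300, 450, 300), "ALCS")
  s2 <- bscan_section("t", "central", 0L, ilm, bm, alcs,
                      point2d(0, 0), point2d(1500, 0), 30)
  expect_true(is.na(compute_hrw(s2, "temporal")))
  expect_match(measure_section(s2)$flags, "rim_unmeasurable")
})

test_that("MRW is the exact minimum BMO-to-ILM distance", {
  ilm <- curve2d(c(-800, 2300), c(-200, -200), "ILM")
  bm <- curve2d(c(-800, 0, 1500, 2300), rep(0, 4), "BM")
  alcs <- curve2d(c(-200, 750, 1700), c(300, 450, 300), "ALCS")
  s <- bscan_section("t", "central", 0L, ilm, bm, alcs,
                     point2d(0, 0), point2d(1500, 0), 30)
  expect_equal(compute_mrw(s, "temporal"), 200)

  # ILM through the BMO point -> zero rim
  ilm0 <- curve2d(c(-800, 0, 2300), c(-200, 0, -200), "ILM")
  s0 <- bscan_section("t", "central", 0L, ilm0, bm, alcs,
                      point2d(0, 0), point2d(1500, 0), 30)
  expect_equal(compute_mrw(s0, "temporal"), 0)

  # wavy ILM vs the dense-sampling oracle
  set.seed(5)
  cx <- seq(-700, 2200, by = 15)
  cz <- -220 + 60 * sin(cx / 150) + rnorm(length(cx), 0, 8)
  ilmw <- curve2d(cx, cz, "ILM")
  sw <- bscan_section("t", "central", 0L, ilmw, bm, alcs,
                      point2d(0, 0), point2d(1500, 0), 30)
  expect_equal(compute_mrw(sw, "temporal"),
               oracle_min_distance(c(0, 0), cx, cz), tolerance = 0.5)
})

test_that("LCCI follows the depth-over-width construction", {
  bm <- curve2d(c(-800, 0, 1500, 2300), rep(0, 4), "BM")
  ilm <- curve2d(c(-800, -300, 200, 750, 1300, 1800, 2300),
                 c(-150, 0, -250, -350, -250, 0, -150), "ILM")
  # flat ALCS: feet and all lamina points collinear
  flat <- curve2d(seq(-200, 1700, by = 50), rep(300, 39), "ALCS")
  s <- bscan_section("t", "central", 0L, ilm, bm, flat,
                     point2d(0, 0), point2d(1500, 0), 30)
  lc <- compute_lcci(s)
  expect_equal(lc$lccd, 0, tolerance = 1e-9)
  expect_equal(lc$lcci, 0, tolerance = 1e-9)

  # symmetric parabola, apex 150 um below the foot line, W = 1500
  x <- seq(-200, 1700, by = 10)
  depth <- 4 * 150 * (x / 1500) * (1 - x / 1500)
  para <- curve2d(x, 300 + depth, "ALCS")
  sp <- bscan_section("t", "central", 0L, ilm, bm, para,
                      point2d(0, 0), point2d(1500, 0), 30)
  expect_equal(compute_lcci(sp)$lcci, 10.0, tolerance = 1e-6)

  # tilted BMO line (200 um offset): against the dense point-to-line oracle
  st <- make_section(w = 1500, lcci = 8.5, tilt_deg = 7.6)
  ref <- bmo_reference_line(st)
  ft <- perpendicular_foot_on_curve(st$bmo_temporal, ref$line, st$alcs)
  fn <- perpendicular_foot_on_curve(st$bmo_nasal, ref$line, st$alcs)
  inside <- st$alcs$x >= min(ft[1], fn[1]) & st$alcs$x <= max(ft[1], fn[1])
  brute <- max(vapply(which(inside), function(i) {
    oracle_line_distance(c(st$alcs$x[i], st$alcs$z[i]), ft, fn)
  }, numeric(1)))
  lc <- compute_lcci(st)
  expect_equal(lc$lccd, brute, tolerance = 0.5)
  expect_equal(lc$lcci, 8.5, tolerance = 0.05)
})

test_that("LCCI is invariant to uniform scaling of the section", {
  base <- make_section(w = 1600, lcci = 11.2, tilt_deg = 3)
  lc0 <- compute_lcci(base)$lcci
  for (k in c(0.5, 2, 10)) {
    scaled <- base
    for (cv in c("ilm", "bm", "alcs")) {
      scaled[[cv]] <- curve2d(base[[cv]]$x * k, base[[cv]]$z * k,
                              role = base[[cv]]$role)
    }
    scaled$bmo_temporal <- base$bmo_temporal * k
    scaled$bmo_nasal <- base$bmo_nasal * k
    expect_equal(compute_lcci(scaled)$lcci, lc0, tolerance = 1e-9)
  }
})

test_that("indices are unchanged by rigid motion of a section", {
  s0 <- make_section(tilt_deg = 0)
  s1 <- make_section(tilt_deg = 4)  # same prescription, rotated frame
  m0 <- measure_section(s0)
  m1 <- measure_section(s1)
  for (v in c("hrw_temporal", "hrw_nasal", "mrw_temporal", "mrw_nasal", "lcci")) {
    expect_equal(m1[[v]], m0[[v]], tolerance = 1e-6)
  }
})

test_that("per-eye aggregation is the nested location/scan mean", {
  one <- measure_section(flat_section())
  nine <- do.call(rbind, rep(list(one), 9))
  nine$location <- rep(c("superior_mid", "central", "inferior_mid"), each = 3)
  agg <- aggregate_eye(nine, "e1")
  expect_equal(agg$mean_hrw, mean(c(300, 320)), tolerance = 1e-6)
  expect_equal(agg$n_usable_scans, 9)

  # location scan-means {9, 10, 11} -> eye mean 10
  nine$lcci <- rep(c(9, 10, 11), each = 3)
  expect_equal(aggregate_eye(nine, "e1")$mean_lcci, 10)

  # random per-scan values match a direct nested-mean recomputation
  set.seed(8)
  nine$lcci <- runif(9, 5, 15)
  nine$hrw_temporal <- runif(9, 100, 400)
  nine$hrw_nasal <- runif(9, 100, 400)
  agg <- aggregate_eye(nine, "e1")
  byloc <- tapply(nine$lcci, nine$location, mean)
  expect_equal(agg$mean_lcci, mean(byloc))
  hrw_sec <- (nine$hrw_temporal + nine$hrw_nasal) / 2
  expect_equal(agg$mean_hrw, mean(tapply(hrw_sec, nine$location, mean)))

  # HMR is ratio-then-average, not the ratio of the averages
  hmr_sec <- hrw_sec / ((nine$mrw_temporal + nine$mrw_nasal) / 2)
  expect_equal(agg$mean_hmr, mean(tapply(hmr_sec, nine$location, mean)))

  # a location with no usable scans flags the eye incomplete
  partial <- nine[nine$location != "central", ]
  expect_match(aggregate_eye(partial, "e1")$flags, "incomplete_eye")
})

test_that("flagged scans are dropped before averaging", {
  one <- measure_section(flat_section())
  nine <- do.call(rbind, rep(list(one), 9))
  nine$location <- rep(c("superior_mid", "central", "inferior_mid"), each = 3)
  nine$lcci <- 1:9
  shadowed <- nine
  shadowed$flags[5] <- "vessel_shadow"
  agg <- aggregate_eye(shadowed, "e1")
  expect_equal(agg$mean_lcci, mean(c(mean(1:3), mean(c(4, 6)), mean(7:9))))
  expect_equal(agg$n_usable_scans, 8)
})

test_that("ovality and torsion implement the strict exclusion thresholds", {
  expect_equal(disc_ovality(1800, 1800), 1)
  expect_equal(disc_ovality(1950, 1500), 1.3)
  expect_gt(disc_ovality(2000, 1500), 1.3)
  expect_error(disc_ovality(1500, 0), "positive")
  expect_error(disc_ovality(1400, 1500), ">=")
  expect_equal(torsion_angle(0), 0)
  expect_equal(torsion_angle(-20), 20)
  expect_equal(torsion_angle(15), 15)
  expect_error(torsion_angle(95), "degrees")
})
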