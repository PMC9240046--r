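# Independent brute-force oracles used to check the closed-form geometry.
# They share no code with the package internals: everything is dense
# sampling or direct per-segment arithmetic written from the definitions.

# unsigned distance from p to the infinite line through a--b, by minimising
# the Euclidean distance over densely sampled line points
oracle_line_distance <- function(p, a, b) {
  t <- seq(-20, 20, length.out = 400001)
  pts_x <- a[1] + t * (b[1] - a[1])
  pts_z <- a[2] + t * (b[2] - a[2])
  sqrt(min((pts_x - p[1])^2 + (pts_z - p[2])^2))
}

# per-segment line/segment solver written directly from the parametric form
oracle_intersections <- function(cx, cz, a, b) {
  dx <- b[1] - a[1]; dz <- b[2] - a[2]
  out <- NULL
  for (i in seq_len(length(cx) - 1)) {
    ex <- cx[i + 1] - cx[i]; ez <- cz[i + 1] - cz[i]
    det <- ex * (-dz) - (-dx) * ez
    if (abs(det) < 1e-14) next
    rhs <- c(a[1] - cx[i], a[2] - cz[i])
    t <- (rhs[1] * (-dz) - (-dx) * rhs[2]) / det
    if (t >= 0 && t <= 1) {
      out <- rbind(out, c(cx[i] + t * ex, cz[i] + t * ez))
    }
  }
  if (is.null(out)) return(matrix(numeric(0), ncol = 2))
  out <- out[order(out[, 1]), , drop = FALSE]
  keep <- c(TRUE, diff(out[, 1]) > 1e-9 | abs(diff(out[, 2])) > 1e-9)
  out[keep, , drop = FALSE]
}

# minimum distance from p to a polyline by dense resampling of every segment
oracle_min_distance <- function(p, cx, cz, pitch = 0.05) {
  best <- Inf
  for (i in seq_len(length(cx) - 1)) {
    len <- sqrt((cx[i + 1] - cx[i])^2 + (cz[i + 1] - cz[i])^2)
    t <- seq(0, 1, length.out = max(2, ceiling(len / pitch)))
    d2 <- (cx[i] + t * (cx[i + 1] - cx[i]) - p[1])^2 +
          (cz[i] + t * (cz[i + 1] - cz[i]) - p[2])^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

# first posterior intersection of the perpendicular ray from p with a curve,
# by marching along the ray at a fine step and bisecting the sign change of
# the vertical offset to the (x-monotone) curve
oracle_perpendicular_foot <- function(p, a, b, cx, cz, rmax = 2000, step = 0.05) {
  d <- c(b[1] - a[1], b[2] - a[2])
  d <- d / sqrt(sum(d^2))
  n <- c(-d[2], d[1])
  if (n[2] < 0) n <- -n
  r <- seq(0, rmax, by = step)
  qx <- p[1] + r * n[1]
  qz <- p[2] + r * n[2]
  ok <- qx >= min(cx) & qx <= max(cx)
  f <- rep(NA_real_, length(r))
  f[ok] <- qz[ok] - approx(cx, cz, xout = qx[ok])$y
  hit <- which(!is.na(f) & f >= 0)[1]
  if (is.na(hit)) stop("oracle: ray misses curve")
  c(qx[hit], qz[hit])
}

# random rigid motion (rotation small enough to keep curves x-monotone)
rigid_transform <- function(xy, theta, shift) {
  cbind(xy[, 1] * cos(theta) - xy[, 2] * sin(theta) + shift[1],
        xy[, 1] * sin(theta) + xy[, 2] * cos(theta) + shift[2])
}

# controlled synthetic section via the package constructor
make_section <- function(w = 1500, hrw_t = 300, hrw_n = 320, mrw_t = 200,
                         mrw_n = 210, lcci = 10, tilt_deg = 0, pitch = 10,
                         quality = 30, location = "central") {
  onhmorph:::build_section(
    section_id = "test", location = location, scan_offset = 0L, w = w,
    hrw_t = hrw_t, hrw_n = hrw_n, mrw_t = mrw_t, mrw_n = mrw_n,
    lcci = lcci, tilt_deg = tilt_deg, pitch = pitch, quality_score = quality)
}

# random valid section parameters under a fixed RNG stream
random_section <- function() {
  hrw_t <- runif(1, 40, 500)
  hrw_n <- runif(1, 40, 500)
  make_section(w = runif(1, 900, 2000),
               hrw_t = hrw_t, hrw_n = hrw_n,
               mrw_t = runif(1, 15, 0.97 * hrw_t),
               mrw_n = runif(1, 15, 0.97 * hrw_n),
               lcci = runif(1, 0.5, 16),
               tilt_deg = runif(1, -5, 5))
}

ntg_params <- function() {
  p <- default_group_params()
  p[p$group == "NTG", , drop = FALSE]
}
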