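#' Section-level 2D geometry for ONH B-scan morphometry
#'
#' All rim and lamina indices are built from a small set of exact polyline
#' primitives in a per-section coordinate frame: x is the lateral position in
#' micrometres, z the axial depth in micrometres with larger z meaning more
#' posterior (deeper). Curves are ordered polylines with strictly increasing x
#' and linear interpolation between samples, so every query below has a
#' closed-form per-segment solution.
#'
#' @name geometry
NULL

#' Construct a 2D point (lateral x, axial z, both in micrometres)
#'
#' @param x lateral position (um)
#' @param z axial depth (um), increasing posteriorly
#' @return named numeric vector with elements `x` and `z`
#' @export
point2d <- function(x, z) {
  if (!is.numeric(x) || !is.numeric(z) || length(x) != 1L || length(z) != 1L ||
      !is.finite(x) || !is.finite(z)) {
    stop("point2d() needs single finite numeric x and z coordinates")
  }
  c(x = as.numeric(x), z = as.numeric(z))
}

#' Construct a boundary polyline
#'
#' A `curve2d` is an ordered polyline with strictly increasing x, used for the
#' internal limiting membrane (ILM), Bruch's membrane (BM) and the anterior
#' lamina cribrosa surface (ALCS).
#'
#' @param x,z numeric vectors of vertex coordinates (um)
#' @param role one of `"ILM"`, `"BM"`, `"ALCS"`
#' @return an object of class `curve2d`
#' @export
curve2d <- function(x, z, role = c("ILM", "BM", "ALCS")) {
  role <- match.arg(role)
  x <- as.numeric(x)
  z <- as.numeric(z)
  if (length(x) < 2L || length(x) != length(z)) {
    stop("curve2d() needs >= 2 vertices with equal-length x and z")
  }
  if (anyNA(x) || anyNA(z) || !all(is.finite(x)) || !all(is.finite(z))) {
    stop("curve2d() coordinates must be finite and non-missing")
  }
  if (any(diff(x) <= 0)) {
    stop("curve2d() x coordinates must be strictly increasing")
  }
  structure(list(x = x, z = z, role = role), class = "curve2d")
}

#' @export
print.curve2d <- function(x, ...) {
  cat(sprintf("<curve2d %s: %d vertices, x in [%.1f, %.1f] um>\n",
              x$role, length(x$x), x$x[1L], x$x[length(x$x)]))
  invisible(x)
}

#' Construct a reference line through two distinct points
#'
#' @param p1,p2 `point2d` points (distinct)
#' @return an object of class `reference_line`
#' @export
reference_line <- function(p1, p2) {
  if (p1[1L] == p2[1L] && p1[2L] == p2[2L]) {
    stop("reference_line() endpoints coincide (degenerate line)")
  }
  structure(list(p1 = c(x = unname(p1[1L]), z = unname(p1[2L])),
                 p2 = c(x = unname(p2[1L]), z = unname(p2[2L]))),
            class = "reference_line")
}

#' @export
print.reference_line <- function(x, ...) {
  cat(sprintf("<reference_line (%.1f, %.1f) -- (%.1f, %.1f)>\n",
              x$p1["x"], x$p1["z"], x$p2["x"], x$p2["z"]))
  invisible(x)
}

# Unit tangent u and posterior-positive unit normal n of a line. Of the two
# perpendiculars the one with positive z component is posterior; for a
# perfectly vertical line (no z preference) the positive-x perpendicular is
# used as a deterministic fallback.
line_frame <- function(line) {
  d <- line$p2 - line$p1
  len <- sqrt(sum(d^2))
  if (len == 0) stop("degenerate line: endpoints coincide")
  u <- d / len
  n <- c(-u[2L], u[1L])
  if (n[2L] < 0) n <- -n
  if (n[2L] == 0) n <- c(abs(n[1L]), 0)
  list(u = unname(u), n = unname(n), origin = unname(line$p1), length = len)
}

#' Signed perpendicular distance from a point to an infinite line
#'
#' Positive on the posterior (larger-z) side of the line.
#'
#' @param p a `point2d`
#' @param line a `reference_line`
#' @return signed distance in micrometres
#' @export
signed_distance_to_line <- function(p, line) {
  fr <- line_frame(line)
  sum((unname(p) - fr$origin) * fr$n)
}

#' Intersections of a polyline with an infinite line
#'
#' Segment-line intersections are computed exactly for linear segments and
#' returned ordered by x. An exactly collinear segment overlap is an explicit
#' error (condition class `onh_collinear_error`), never a silent answer.
#'
#' @param curve a `curve2d`
#' @param line a `reference_line`
#' @return a matrix with columns `x`, `z` (zero rows when no intersection)
#' @export
curve_line_intersections <- function(curve, line) {
  fr <- line_frame(line)
  f <- (curve$x - fr$origin[1L]) * fr$n[1L] + (curve$z - fr$origin[2L]) * fr$n[2L]
  nseg <- length(f) - 1L
  fa <- f[-length(f)]
  fb <- f[-1L]
  if (any(fa == 0 & fb == 0)) {
    stop(structure(class = c("onh_collinear_error", "error", "condition"),
                   list(message = "curve segment is collinear with the line",
                        call = sys.call())))
  }
  xs <- numeric(0)
  zs <- numeric(0)
  cross <- which(fa * fb < 0)
  if (length(cross)) {
    t <- fa[cross] / (fa[cross] - fb[cross])
    xs <- curve$x[cross] + t * (curve$x[cross + 1L] - curve$x[cross])
    zs <- curve$z[cross] + t * (curve$z[cross + 1L] - curve$z[cross])
  }
  on <- which(f == 0)
  if (length(on)) {
    xs <- c(xs, curve$x[on])
    zs <- c(zs, curve$z[on])
  }
  o <- order(xs)
  xs <- xs[o]
  zs <- zs[o]
  if (length(xs) > 1L) {
    keep <- c(TRUE, abs(diff(xs)) > 1e-9 | abs(diff(zs)) > 1e-9)
    xs <- xs[keep]
    zs <- zs[keep]
  }
  cbind(x = xs, z = zs)
}

#' Exact minimum distance from a point to a polyline
#'
#' Uses the closed-form projection onto every segment (not vertex-only); ties
#' are broken toward the foot with smaller x.
#'
#' @param p a `point2d`
#' @param curve a `curve2d`
#' @return list with `distance` (um) and `foot` (`point2d` achieving it)
#' @export
min_distance_point_to_curve <- function(p, curve) {
  px <- unname(p[1L]); pz <- unname(p[2L])
  ax <- curve$x[-length(curve$x)]; az <- curve$z[-length(curve$z)]
  bx <- curve$x[-1L]; bz <- curve$z[-1L]
  dx <- bx - ax; dz <- bz - az
  tt <- ((px - ax) * dx + (pz - az) * dz) / (dx * dx + dz * dz)
  tt <- pmin(1, pmax(0, tt))
  fx <- ax + tt * dx
  fz <- az + tt * dz
  d2 <- (px - fx)^2 + (pz - fz)^2
  dmin <- min(d2)
  cand <- which(d2 <= dmin + 1e-12 * max(1, dmin))
  best <- cand[which.min(fx[cand])]
  list(distance = sqrt(d2[best]), foot = c(x = fx[best], z = fz[best]))
}

#' First posterior perpendicular intersection with a curve
#'
#' Drops a perpendicular from `p` to `line`, follows it toward the posterior
#' side, and returns the first intersection with `curve`. Used to project the
#' BMO termination points onto the anterior lamina cribrosa surface.
#'
#' @param p a `point2d` (typically a BMO termination point on the line)
#' @param line a `reference_line` (typically the BMO reference line)
#' @param curve a `curve2d` (typically the ALCS)
#' @return the intersection `point2d`
#' @export
perpendicular_foot_on_curve <- function(p, line, curve) {
  fr <- line_frame(line)
  px <- unname(p[1L]); pz <- unname(p[2L])
  nx <- fr$n[1L]; nz <- fr$n[2L]
  ax <- curve$x[-length(curve$x)]; az <- curve$z[-length(curve$z)]
  bx <- curve$x[-1L]; bz <- curve$z[-1L]
  dx <- bx - ax; dz <- bz - az
  # solve p + r*n = a + t*d for each segment
  det <- dx * nz - dz * nx
  ok <- abs(det) > 1e-15
  r <- rep(NA_real_, length(det))
  tt <- rep(NA_real_, length(det))
  r[ok] <- (dx[ok] * (az[ok] - pz) - dz[ok] * (ax[ok] - px)) / det[ok]
  tt[ok] <- (nx * (az[ok] - pz) - nz * (ax[ok] - px)) / det[ok]
  hit <- which(ok & r >= -1e-9 & tt >= -1e-9 & tt <= 1 + 1e-9)
  if (!length(hit)) {
    stop(structure(class = c("onh_no_alcs_error", "error", "condition"),
                   list(message = "ALCS not visible under BMO point (perpendicular misses curve)",
                        call = sys.call())))
  }
  i <- hit[which.min(r[hit])]
  rr <- max(r[i], 0)
  c(x = px + rr * nx, z = pz + rr * nz)
}
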