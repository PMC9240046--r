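#' Neuroretinal rim and lamina cribrosa indices
#'
#' Index definitions, all per horizontal B-scan section:
#' \itemize{
#'   \item W — Bruch's membrane opening (BMO) width: the Euclidean length of
#'     the line connecting the temporal and nasal BM termination points (the
#'     BMO reference line).
#'   \item HRW — horizontal rim width: the distance, measured along the BMO
#'     reference line, from a BMO point to the nearest ILM crossing of that
#'     line on the rim side of the point.
#'   \item MRW — minimum rim width: the minimum Euclidean distance from a BMO
#'     point to the ILM within the section.
#'   \item HMR — the ratio HRW/MRW, computed per section and then averaged.
#'   \item LCCI — lamina cribrosa curvature index: perpendiculars are dropped
#'     from both BMO points (posteriorly, perpendicular to the BMO reference
#'     line) to the anterior lamina cribrosa surface; the line through the two
#'     foot points is the depth reference; LCCD is the maximum perpendicular
#'     depth of the ALCS below that line between the feet, and
#'     LCCI = 100 * LCCD / W. Being a depth-to-width ratio it is independent
#'     of overall ONH size.
#' }
#' @name morphometry
NULL

#' Construct one B-scan section
#'
#' @param section_id identifier string
#' @param location one of `"superior_mid"`, `"central"`, `"inferior_mid"`
#' @param scan_offset integer scan index relative to the location's central
#'   scan (the averaging protocol uses -2, 0, +2)
#' @param ilm,bm,alcs `curve2d` boundary curves
#' @param bmo_temporal,bmo_nasal BM termination points (`point2d`); the
#'   temporal point has the smaller x (laterality is normalised at ingest)
#' @param quality_score device quality score; usable sections require > 15
#' @param flags character vector of quality flags (e.g. `"vessel_shadow"`)
#' @return an object of class `bscan_section`
#' @export
bscan_section <- function(section_id, location, scan_offset, ilm, bm, alcs,
                          bmo_temporal, bmo_nasal, quality_score,
                          flags = character(0)) {
  location <- match.arg(location, c("superior_mid", "central", "inferior_mid"))
  if (!inherits(ilm, "curve2d") || !inherits(bm, "curve2d") ||
      !inherits(alcs, "curve2d")) {
    stop("ilm, bm and alcs must be curve2d objects")
  }
  if (!(unname(bmo_temporal[1L]) < unname(bmo_nasal[1L]))) {
    stop("bmo_temporal must lie temporal to (smaller x than) bmo_nasal")
  }
  for (bp in list(bmo_temporal, bmo_nasal)) {
    d <- min_distance_point_to_curve(bp, bm)$distance
    if (d > 1.0) {
      stop(sprintf("BMO point (%.1f, %.1f) is %.2f um off the BM curve",
                   bp[1L], bp[2L], d))
    }
  }
  if (alcs$x[1L] > unname(bmo_temporal[1L]) + 1e-6 ||
      alcs$x[length(alcs$x)] < unname(bmo_nasal[1L]) - 1e-6) {
    stop("ALCS must span at least the BMO lateral extent")
  }
  structure(list(section_id = as.character(section_id), location = location,
                 scan_offset = as.integer(scan_offset), ilm = ilm, bm = bm,
                 alcs = alcs,
                 bmo_temporal = c(x = unname(bmo_temporal[1L]), z = unname(bmo_temporal[2L])),
                 bmo_nasal = c(x = unname(bmo_nasal[1L]), z = unname(bmo_nasal[2L])),
                 quality_score = as.numeric(quality_score),
                 flags = as.character(flags)),
            class = "bscan_section")
}

#' @export
print.bscan_section <- function(x, ...) {
  cat(sprintf("<bscan_section %s: %s scan %+d, W = %.1f um, quality %.1f>\n",
              x$section_id, x$location, x$scan_offset,
              bmo_reference_line(x)$w, x$quality_score))
  invisible(x)
}

#' BMO reference line and opening width of a section
#'
#' @param section a `bscan_section`
#' @return list with `line` (`reference_line` through the two BMO points) and
#'   `w` (BMO width, um)
#' @export
bmo_reference_line <- function(section) {
  p1 <- section$bmo_temporal
  p2 <- section$bmo_nasal
  w <- sqrt(sum((p2 - p1)^2))
  if (w == 0) stop("BMO termination points coincide")
  list(line = reference_line(p1, p2), w = w)
}

#' Horizontal rim width of one side of a section
#'
#' Distance along the BMO reference line from the BMO point to the nearest
#' ILM-line crossing on the rim side (temporal side: crossings with
#' x < bmo_temporal; nasal side: x > bmo_nasal). Returns `NA` when the ILM
#' never crosses the line on that side (rim absent/unmeasurable; the value is
#' excluded from aggregation).
#'
#' @param section a `bscan_section`
#' @param side `"temporal"` or `"nasal"`
#' @return rim width in um, or `NA_real_` when unmeasurable
#' @export
compute_hrw <- function(section, side = c("temporal", "nasal")) {
  side <- match.arg(side)
  ref <- bmo_reference_line(section)
  ints <- curve_line_intersections(section$ilm, ref$line)
  hrw_from_intersections(section, side, ints)
}

hrw_from_intersections <- function(section, side, ints) {
  if (nrow(ints) == 0L) return(NA_real_)
  bp <- if (side == "temporal") section$bmo_temporal else section$bmo_nasal
  if (side == "temporal") {
    sel <- ints[, 1L] < bp[[1L]] - 1e-9
    if (!any(sel)) return(NA_real_)
    i <- which(sel)[which.max(ints[sel, 1L])]
  } else {
    sel <- ints[, 1L] > bp[[1L]] + 1e-9
    if (!any(sel)) return(NA_real_)
    i <- which(sel)[which.min(ints[sel, 1L])]
  }
  unname(sqrt((ints[i, 1L] - bp[[1L]])^2 + (ints[i, 2L] - bp[[2L]])^2))
}

#' Minimum rim width of one side of a section
#'
#' Minimum Euclidean distance from the BMO point to the ILM polyline. This is
#' the per-horizontal-section minimum, not the radial-scan BMO-MRW.
#'
#' @inheritParams compute_hrw
#' @return minimum rim width in um
#' @export
compute_mrw <- function(section, side = c("temporal", "nasal")) {
  side <- match.arg(side)
  bp <- if (side == "temporal") section$bmo_temporal else section$bmo_nasal
  min_distance_point_to_curve(bp, section$ilm)$distance
}

#' Lamina cribrosa curvature of a section
#'
#' @param section a `bscan_section`
#' @return list with `w` (BMO width, um), `lccd` (maximum lamina depth below
#'   the foot-point line, um), `lcci` (= 100 * lccd / w) and `flags`
#'   (character; `"alcs_not_visible"` with `NA` indices when a perpendicular
#'   misses the ALCS)
#' @export
compute_lcci <- function(section) {
  lcci_core(section, bmo_reference_line(section))
}

lcci_core <- function(section, ref) {
  feet <- tryCatch(
    list(t = perpendicular_foot_on_curve(section$bmo_temporal, ref$line, section$alcs),
         n = perpendicular_foot_on_curve(section$bmo_nasal, ref$line, section$alcs)),
    onh_no_alcs_error = function(e) NULL)
  if (is.null(feet)) {
    return(list(w = ref$w, lccd = NA_real_, lcci = NA_real_,
                flags = "alcs_not_visible"))
  }
  depth_line <- reference_line(feet$t, feet$n)
  xlo <- min(feet$t["x"], feet$n["x"])
  xhi <- max(feet$t["x"], feet$n["x"])
  inside <- section$alcs$x >= xlo - 1e-9 & section$alcs$x <= xhi + 1e-9
  lccd <- 0
  if (any(inside)) {
    fr <- line_frame(depth_line)
    d <- (section$alcs$x[inside] - fr$origin[1L]) * fr$n[1L] +
         (section$alcs$z[inside] - fr$origin[2L]) * fr$n[2L]
    lccd <- max(0, d)
  }
  list(w = ref$w, lccd = lccd, lcci = 100 * lccd / ref$w, flags = character(0))
}

#' Measure all indices of one section
#'
#' @param section a `bscan_section`
#' @return one-row data.frame with section identifiers, per-side HRW and MRW,
#'   `w`, `lccd`, `lcci` and a semicolon-joined `flags` string
#' @export
measure_section <- function(section) {
  measure_sections(list(section))
}

# Shared fast path: one reference-line construction and one ILM/line
# intersection pass per section, rows assembled into a single data.frame.
measure_sections <- function(sections) {
  rows <- lapply(sections, function(section) {
    ref <- bmo_reference_line(section)
    ints <- curve_line_intersections(section$ilm, ref$line)
    hrw_t <- hrw_from_intersections(section, "temporal", ints)
    hrw_n <- hrw_from_intersections(section, "nasal", ints)
    mrw_t <- min_distance_point_to_curve(section$bmo_temporal, section$ilm)$distance
    mrw_n <- min_distance_point_to_curve(section$bmo_nasal, section$ilm)$distance
    lc <- lcci_core(section, ref)
    flags <- section$flags
    if (is.na(hrw_t) || is.na(hrw_n)) flags <- c(flags, "rim_unmeasurable")
    if (section$quality_score <= 15) flags <- c(flags, "poor_quality")
    flags <- unique(c(flags, lc$flags))
    list(section$section_id, section$location, section$scan_offset,
         hrw_t, hrw_n, mrw_t, mrw_n, lc$w, lc$lccd, lc$lcci,
         section$quality_score, paste(flags, collapse = ";"))
  })
  data.frame(
    section_id = vapply(rows, `[[`, "", 1L),
    location = vapply(rows, `[[`, "", 2L),
    scan_offset = vapply(rows, `[[`, 0L, 3L),
    hrw_temporal = vapply(rows, `[[`, 0, 4L),
    hrw_nasal = vapply(rows, `[[`, 0, 5L),
    mrw_temporal = vapply(rows, `[[`, 0, 6L),
    mrw_nasal = vapply(rows, `[[`, 0, 7L),
    w = vapply(rows, `[[`, 0, 8L),
    lccd = vapply(rows, `[[`, 0, 9L),
    lcci = vapply(rows, `[[`, 0, 10L),
    quality_score = vapply(rows, `[[`, 0, 11L),
    flags = vapply(rows, `[[`, "", 12L),
    stringsAsFactors = FALSE)
}

section_has_flag <- function(flags, what) {
  vapply(strsplit(flags, ";", fixed = TRUE),
         function(f) any(f == what), logical(1))
}

#' Aggregate section indices to per-eye values
#'
#' Follows the three-location/three-scan protocol: the value of a location is
#' the unweighted mean of its usable scans and the eye value is the unweighted
#' mean of the three location values. Per-section HRW and MRW average the
#' temporal and nasal sides; HMR is computed per section as HRW/MRW and then
#' averaged like any other index; `temporal_*` variants use the temporal side
#' only. Scans flagged `vessel_shadow` or `poor_quality` are dropped before
#' averaging; an eye with a location left without any usable scan is flagged
#' incomplete.
#'
#' @param indices data.frame of section indices as returned by
#'   [measure_section()] (one row per scan)
#' @param eye_id identifier carried into the result
#' @return one-row data.frame with `mean_hrw`, `mean_mrw`, `mean_hmr`,
#'   `mean_lcci`, `temporal_hrw`, `temporal_mrw`, `temporal_hmr`,
#'   `n_usable_scans` and `flags`; the per-location detail is attached as
#'   attribute `per_location`
#' @export
aggregate_eye <- function(indices, eye_id = "eye") {
  stopifnot(is.data.frame(indices))
  usable <- !(section_has_flag(indices$flags, "vessel_shadow") |
              section_has_flag(indices$flags, "poor_quality"))
  ind <- indices[usable, , drop = FALSE]
  ind$hrw <- rowMeans(cbind(ind$hrw_temporal, ind$hrw_nasal), na.rm = TRUE)
  ind$mrw <- rowMeans(cbind(ind$mrw_temporal, ind$mrw_nasal), na.rm = TRUE)
  ind$hmr <- ind$hrw / ind$mrw
  ind$hmr_temporal <- ind$hrw_temporal / ind$mrw_temporal
  locations <- c("superior_mid", "central", "inferior_mid")
  loc_mean <- function(var) {
    vapply(locations, function(l) {
      v <- ind[[var]][ind$location == l]
      v <- v[is.finite(v)]
      if (!length(v)) NA_real_ else mean(v)
    }, numeric(1))
  }
  per_location <- data.frame(
    location = locations,
    hrw = loc_mean("hrw"), mrw = loc_mean("mrw"), hmr = loc_mean("hmr"),
    lcci = loc_mean("lcci"),
    hrw_temporal = loc_mean("hrw_temporal"),
    mrw_temporal = loc_mean("mrw_temporal"),
    hmr_temporal = loc_mean("hmr_temporal"),
    n_scans = vapply(locations, function(l) sum(ind$location == l), numeric(1)),
    stringsAsFactors = FALSE)
  flags <- character(0)
  if (any(per_location$n_scans == 0)) flags <- c(flags, "incomplete_eye")
  eye_mean <- function(var) mean(per_location[[var]])
  out <- data.frame(
    eye_id = eye_id,
    mean_hrw = eye_mean("hrw"), mean_mrw = eye_mean("mrw"),
    mean_hmr = eye_mean("hmr"), mean_lcci = eye_mean("lcci"),
    temporal_hrw = eye_mean("hrw_temporal"),
    temporal_mrw = eye_mean("mrw_temporal"),
    temporal_hmr = eye_mean("hmr_temporal"),
    n_usable_scans = nrow(ind),
    flags = paste(flags, collapse = ";"),
    stringsAsFactors = FALSE)
  attr(out, "per_location") <- per_location
  out
}

#' Measure and aggregate all sections of one eye
#'
#' @param eye an `eye_record` with rendered sections
#' @return one-row per-eye data.frame (see [aggregate_eye()])
#' @export
measure_eye <- function(eye) {
  if (!length(eye$sections)) stop("eye has no sections to measure")
  aggregate_eye(measure_sections(eye$sections), eye_id = eye$eye_id)
}

#' Measure a whole cohort
#'
#' @param cohort an `onh_cohort` (see [generate_cohort()])
#' @return data.frame with one row per eye: group, covariates and the per-eye
#'   morphometry columns
#' @export
measure_cohort <- function(cohort) {
  res <- do.call(rbind, lapply(cohort$eyes, measure_eye))
  merge(cohort$cohort, res, by = "eye_id", sort = FALSE)
}

#' Disc ovality index
#'
#' Ratio of the longest to the shortest disc diameter; values > 1.3 define a
#' tilted disc (a screening exclusion).
#'
#' @param longest_diameter,shortest_diameter disc axes (same units)
#' @return the ovality ratio (>= 1)
#' @export
disc_ovality <- function(longest_diameter, shortest_diameter) {
  if (any(shortest_diameter <= 0)) stop("shortest diameter must be positive")
  if (any(longest_diameter < shortest_diameter)) {
    stop("longest diameter must be >= shortest diameter")
  }
  longest_diameter / shortest_diameter
}

#' Disc torsion angle
#'
#' Absolute deviation of the disc long axis from the vertical meridian;
#' values > 15 degrees define torsion (a screening exclusion).
#'
#' @param long_axis_azimuth_deg azimuth of the long axis, degrees from the
#'   vertical meridian, in (-90, 90]
#' @return torsion angle in degrees, in \[0, 90\]
#' @export
torsion_angle <- function(long_axis_azimuth_deg) {
  if (any(long_axis_azimuth_deg <= -90 | long_axis_azimuth_deg > 90)) {
    stop("azimuth must lie in (-90, 90] degrees")
  }
  abs(long_axis_azimuth_deg)
}
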