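#' Synthetic ONH cohort generator
#'
#' Generates per-eye clinical records and fully rendered B-scan section
#' geometry for three groups — normal-tension glaucoma (NTG), central retinal
#' artery occlusion (CRAO) and healthy fellow eyes of the CRAO subjects — so
#' that the whole measurement, screening and statistics pipeline can be
#' exercised without any real data. Latent per-eye indices (HRW*, MRW*,
#' LCCI*) and covariates are drawn from truncated normal distributions whose
#' moments are shipped in a packaged per-group parameter table; sections are
#' then constructed so that re-measuring them recovers the latent values
#' (construct-then-measure residual below 1 um before jitter).
#'
#' @name synthetic_cohort
NULL

#' Packaged per-group distribution parameters
#'
#' Reads the parameter table shipped with the package: per-group means and
#' SDs for the morphometric indices, disc geometry, age, IOP, refraction and
#' RNFL thicknesses, plus the temporal-to-overall rim fractions used to give
#' sections a mild temporal/nasal asymmetry.
#'
#' @param path optional path to an alternative parameter CSV with the same
#'   columns
#' @return data.frame with one row per group
#' @export
default_group_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "group_params.csv", package = "onhmorph",
                        mustWork = TRUE)
  }
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("group", "n", "hrw_mean", "hrw_sd", "mrw_mean", "mrw_sd",
              "lcci_mean", "lcci_sd")
  miss <- setdiff(needed, names(p))
  if (length(miss)) stop("parameter file lacks columns: ", paste(miss, collapse = ", "))
  if (any(p$n < 1)) stop("group n must be >= 1")
  sds <- p[, grep("_sd$", names(p)), drop = FALSE]
  if (any(unlist(sds) < 0)) stop("SD parameters must be >= 0")
  p
}

# Truncated normal draws by inverse-CDF (exact, no rejection). sd = 0
# degenerates to the mean (which must respect the bounds).
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) {
    if (mean < lower || mean > upper) stop("degenerate truncated normal outside bounds")
    return(rep(mean, n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (phi - plo < 1e-12) stop("truncated normal support has negligible mass")
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

# Seed-splitting rule: one root seed, per-eye child seeds derived from the
# root seed and a per-eye integer key, exact in double arithmetic and below
# 2^31 so cohorts are reproducible and order-independent.
child_seed <- function(seed, key) {
  ((seed %% 1000003) * 2017 + key * 7919) %% 2147483629 + 1
}

#' Sample one synthetic eye record
#'
#' Draws latent true indices and covariates from independent truncated normal
#' distributions: all widths are truncated below at 10 um, LCCI below at
#' 0.05. The rim-consistency constraint MRW* <= 0.98 HRW* is enforced by
#' resampling MRW* given the already-drawn HRW* (bounded retries), which
#' leaves HRW* and LCCI* exactly at their configured marginals.
#'
#' @param params one row of [default_group_params()]
#' @param seed integer seed (deterministic: same seed, same record)
#' @param eye_id,subject_id identifiers
#' @return an object of class `eye_record` (no sections yet; see
#'   [render_sections()])
#' @export
sample_eye <- function(params, seed, eye_id = "eye", subject_id = eye_id) {
  stopifnot(nrow(params) == 1L)
  set.seed(seed)
  # widths are truncated below at 10 um; HRW additionally needs room for the
  # MRW <= 0.98 HRW constraint, so its effective floor is 10/0.98
  hrw <- rnorm_trunc(1, params$hrw_mean, params$hrw_sd, lower = 10 / 0.98 + 0.01)
  # MRW given HRW: the exact conditional (doubly truncated) distribution,
  # equivalent to resampling the marginal until the constraint holds
  mrw <- tryCatch(
    rnorm_trunc(1, params$mrw_mean, params$mrw_sd, lower = 10,
                upper = 0.98 * hrw),
    error = function(e) {
      stop(sprintf("infeasible index parameters: MRW <= 0.98*HRW has negligible mass (HRW = %.1f)", hrw))
    })
  lcci <- rnorm_trunc(1, params$lcci_mean, params$lcci_sd, lower = 0.05)
  disc_area <- rnorm_trunc(1, params$disc_area_mean, params$disc_area_sd, lower = 0.8)
  ovality <- rnorm_trunc(1, params$ovality_mean, params$ovality_sd, lower = 1, upper = 1.3)
  torsion <- abs(rnorm_trunc(1, 0, 5, lower = -15, upper = 15))
  age <- rnorm_trunc(1, params$age_mean, params$age_sd, lower = 20, upper = 95)
  iop <- rnorm_trunc(1, params$iop_mean, params$iop_sd, lower = 5, upper = 21)
  se <- rnorm_trunc(1, params$se_mean, params$se_sd, lower = -8, upper = 3)
  rn <- vapply(c("rnfl_global", "rnfl_ts", "rnfl_t", "rnfl_ti",
                 "rnfl_ni", "rnfl_n", "rnfl_ns"),
               function(v) rnorm_trunc(1, params[[paste0(v, "_mean")]],
                                       params[[paste0(v, "_sd")]], lower = 5),
               numeric(1))
  sex <- if (stats::runif(1) < params$male_frac) "M" else "F"
  max_iop <- min(21, iop + abs(stats::rnorm(1, 2, 1.5)))
  tilt_deg <- rnorm_trunc(1, 0, 2, lower = -5, upper = 5)
  subtype <- if (params$group == "CRAO") {
    if (stats::runif(1) < 0.5) "subtotal" else "total"
  } else NA_character_
  structure(list(
    eye_id = eye_id, subject_id = subject_id, group = params$group,
    age = age, sex = sex, spherical_equivalent = se, iop_at_oct = iop,
    disc_area = disc_area, ovality = ovality, torsion_deg = torsion,
    rnfl_global = rn[["rnfl_global"]], rnfl_ts = rn[["rnfl_ts"]],
    rnfl_t = rn[["rnfl_t"]], rnfl_ti = rn[["rnfl_ti"]],
    rnfl_ni = rn[["rnfl_ni"]], rnfl_n = rn[["rnfl_n"]],
    rnfl_ns = rn[["rnfl_ns"]],
    crao_subtype = subtype, neovascular_glaucoma = FALSE,
    quality_fail_sections = 0L, max_iop = max_iop,
    vf_glaucomatous = identical(params$group, "NTG"),
    prior_surgery = FALSE, retinal_or_neuro_disease = FALSE,
    branch_rao = FALSE, glaucoma_history = FALSE,
    tilt_deg = tilt_deg,
    latent = list(hrw = hrw, mrw = mrw, lcci = lcci),
    hrw_temporal_frac = params$hrw_temporal_frac,
    mrw_temporal_frac = params$mrw_temporal_frac,
    sections = list()),
    class = "eye_record")
}

#' @export
print.eye_record <- function(x, ...) {
  cat(sprintf("<eye_record %s (%s): age %.0f, latent HRW %.0f / MRW %.0f um, LCCI %.1f, %d sections>\n",
              x$eye_id, x$group, x$age, x$latent$hrw, x$latent$mrw,
              x$latent$lcci, length(x$sections)))
  invisible(x)
}

# One constructed section in line coordinates (s along the BMO reference
# line from the temporal BMO point, h perpendicular with anterior positive),
# rotated into the section frame by the eye's tilt. The ILM is shaped so that
# (i) its only line crossing temporal of the temporal BMO point is at
# along-line distance hrw_t (and symmetrically nasally), and (ii) its closest
# approach to each BMO point is a flat rim run at exactly mrw on that side.
# The ALCS is a parabola through the two perpendicular feet (depth h0 below
# the BMO line) with apex depth lccd = lcci * w / 100.
build_section <- function(section_id, location, scan_offset, w,
                          hrw_t, hrw_n, mrw_t, mrw_n, lcci,
                          tilt_deg = 0, pitch = 10, quality_score = 25,
                          flags = character(0), h0 = 250, d_cup = 125,
                          tail_len = 300, tail_slope = 0.35) {
  th <- tilt_deg * pi / 180
  co <- cos(th); si <- sin(th)
  bt <- c(-(w / 2) * co, -(w / 2) * si)   # temporal BMO (x, z)
  to_xz <- function(s, h) {
    cbind(x = bt[1L] + s * co + h * si, z = bt[2L] + s * si - h * co)
  }
  grid <- function(a, b) {
    if (b - a < pitch) c(a, b) else unique(c(seq(a, b, by = pitch), b))
  }
  # ILM in (s, h)
  eps_t <- 0.9 * sqrt(max(hrw_t^2 - mrw_t^2, 1e-6))
  eps_n <- 0.9 * sqrt(max(hrw_n^2 - mrw_n^2, 1e-6))
  a_t <- min(max(1.3 * mrw_t, 0.08 * w), 0.35 * w)
  a_n <- min(max(1.3 * mrw_n, 0.08 * w), 0.35 * w)
  s_tail_t <- grid(-hrw_t - tail_len, -hrw_t)
  tail_t <- cbind(s_tail_t, -tail_slope * (-hrw_t - s_tail_t))
  s_flat_t <- grid(-hrw_t + eps_t, a_t)
  flat_t <- cbind(s_flat_t, mrw_t)
  mid <- (a_t + (w - a_n)) / 2
  s_cup1 <- grid(a_t, mid)
  cup1 <- cbind(s_cup1, -d_cup + (mrw_t + d_cup) *
                  (1 + cos(pi * (s_cup1 - a_t) / (mid - a_t))) / 2)
  s_cup2 <- grid(mid, w - a_n)
  cup2 <- cbind(s_cup2, -d_cup + (mrw_n + d_cup) *
                  (1 - cos(pi * (s_cup2 - mid) / (w - a_n - mid))) / 2)
  s_flat_n <- grid(w - a_n, w + hrw_n - eps_n)
  flat_n <- cbind(s_flat_n, mrw_n)
  s_tail_n <- grid(w + hrw_n, w + hrw_n + tail_len)
  tail_n <- cbind(s_tail_n, -tail_slope * (s_tail_n - w - hrw_n))
  ilm_sh <- rbind(tail_t, flat_t, cup1, cup2, flat_n,
                  c(w + hrw_n, 0), tail_n)
  keep <- c(TRUE, diff(ilm_sh[, 1L]) > 1e-9)
  ilm_sh <- ilm_sh[keep, , drop = FALSE]
  ilm_xz <- to_xz(ilm_sh[, 1L], ilm_sh[, 2L])
  # BM: straight along the reference line, through both BMO points exactly
  # (being straight it needs only its end vertices plus the BMO vertices)
  s_bm <- c(-hrw_t - tail_len - 100, 0, w, w + hrw_n + tail_len + 100)
  bm_xz <- to_xz(s_bm, rep(0, length(s_bm)))
  # ALCS: parabola through the perpendicular feet
  lccd <- lcci * w / 100
  ext <- 0.08 * w
  s_lc <- sort(unique(c(grid(-ext, w + ext), 0, w / 2, w)))
  depth <- 4 * lccd * (s_lc / w) * (1 - s_lc / w)
  alcs_xz <- to_xz(s_lc, -h0 - depth)
  bscan_section(
    section_id = section_id, location = location, scan_offset = scan_offset,
    ilm = curve2d(ilm_xz[, "x"], ilm_xz[, "z"], role = "ILM"),
    bm = curve2d(bm_xz[, "x"], bm_xz[, "z"], role = "BM"),
    alcs = curve2d(alcs_xz[, "x"], alcs_xz[, "z"], role = "ALCS"),
    bmo_temporal = point2d(bt[1L], bt[2L]),
    bmo_nasal = point2d(-bt[1L], -bt[2L]),
    quality_score = quality_score, flags = flags)
}

#' Render the nine B-scan sections of an eye
#'
#' Builds three scans (offsets -2, 0, +2) at each of the three measurement
#' locations (superior mid-periphery, centre, inferior mid-periphery placed
#' at fractions 0.25 / 0.5 / 0.75 of the vertical disc diameter). The BMO
#' width of each scan is the horizontal chord of the disc ellipse at the scan
#' height (scan lines 32 um apart vertically); per-scan multiplicative jitter
#' (default SD 2% of the value) models within-eye scan-to-scan variability.
#' Scans hit by a simulated vessel shadow are replaced by the adjacent scan
#' line, mirroring the reading-protocol rule of moving to a neighbouring
#' image.
#'
#' @param eye an `eye_record`
#' @param jitter_sd per-scan multiplicative jitter SD (fraction of the value)
#' @param pitch curve sampling pitch in um
#' @param vessel_shadow_prob per-scan probability of a vessel shadow
#' @param seed optional seed; by default the current RNG stream is used (the
#'   cohort generator seeds per eye)
#' @return the `eye_record` with its `sections` list filled (9 scans)
#' @export
render_sections <- function(eye, jitter_sd = 0.02, pitch = 10,
                            vessel_shadow_prob = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (eye$latent$mrw > 0.98 * eye$latent$hrw) {
    stop("geometrically unrealizable indices: MRW* > 0.98 * HRW*")
  }
  area_um2 <- eye$disc_area * 1e6
  a_h <- sqrt(area_um2 / (pi * eye$ovality))  # horizontal semi-axis, um
  a_v <- eye$ovality * a_h                    # vertical semi-axis, um
  locs <- c(superior_mid = 0.25, central = 0.5, inferior_mid = 0.75)
  sections <- list()
  for (li in seq_along(locs)) {
    loc <- names(locs)[li]
    for (off in c(-2L, 0L, 2L)) {
      shadow <- stats::runif(1) < vessel_shadow_prob
      use_off <- off
      if (shadow) use_off <- if (off < 2L) off + 1L else off - 1L
      y <- (2 * locs[[li]] - 1) * a_v + use_off * 32
      w <- 2 * a_h * sqrt(max(0.1, 1 - (y / a_v)^2))
      jf <- pmin(1.5, pmax(0.5, 1 + stats::rnorm(5, 0, jitter_sd)))
      hrw_t <- eye$latent$hrw * eye$hrw_temporal_frac * jf[1L]
      hrw_n <- eye$latent$hrw * (2 - eye$hrw_temporal_frac) * jf[2L]
      # per-side rim targets; if the temporal/nasal split would violate the
      # per-side MRW <= 0.98 HRW geometry on one side, move the excess to the
      # other side so the section mean is preserved
      t0 <- eye$latent$mrw * eye$mrw_temporal_frac * jf[3L]
      n0 <- eye$latent$mrw * (2 - eye$mrw_temporal_frac) * jf[4L]
      cap_t <- 0.98 * hrw_t; cap_n <- 0.98 * hrw_n
      mrw_t <- min(t0, cap_t); mrw_n <- min(n0, cap_n)
      r <- (t0 + n0) - (mrw_t + mrw_n)
      give_t <- min(r, cap_t - mrw_t); mrw_t <- mrw_t + give_t
      mrw_n <- mrw_n + min(r - give_t, cap_n - mrw_n)
      lcci <- eye$latent$lcci * jf[5L]
      q <- rnorm_trunc(1, 25, 4, lower = 15.5, upper = 45)
      sections[[length(sections) + 1L]] <- build_section(
        section_id = sprintf("%s_%s_%+d", eye$eye_id, loc, off),
        location = loc, scan_offset = use_off, w = w,
        hrw_t = hrw_t, hrw_n = hrw_n, mrw_t = mrw_t, mrw_n = mrw_n,
        lcci = lcci, tilt_deg = eye$tilt_deg, pitch = pitch,
        quality_score = q)
    }
  }
  eye$sections <- sections
  eye
}

#' Simulate two observers re-measuring section indices
#'
#' Applies independent multiplicative Gaussian noise per observer to each
#' section-level index, producing the paired measurement sets used to
#' exercise the interobserver ICC. Zero noise returns two identical copies.
#'
#' @param indices data.frame of section indices (rows from
#'   [measure_section()])
#' @param noise_sd_pct per-observer noise SD as a percentage of each value
#' @param seed optional integer seed
#' @return list with elements `obs1` and `obs2`
#' @export
simulate_observers <- function(indices, noise_sd_pct = 2, seed = NULL) {
  if (noise_sd_pct < 0) stop("noise_sd_pct must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  cols <- intersect(c("hrw_temporal", "hrw_nasal", "mrw_temporal",
                      "mrw_nasal", "lccd", "lcci"), names(indices))
  noisy <- function() {
    out <- indices
    for (cl in cols) {
      out[[cl]] <- indices[[cl]] * (1 + stats::rnorm(nrow(indices), 0, noise_sd_pct / 100))
    }
    out
  }
  list(obs1 = noisy(), obs2 = noisy())
}

#' Cohort generation configuration
#'
#' @param n_ntg,n_crao analysis-set group sizes (healthy fellow eyes mirror
#'   the CRAO count)
#' @param include_fellow generate the healthy fellow eye of each CRAO subject
#' @param pool generate a pre-screening candidate pool (with exclusion
#'   attributes at the study screening frequencies) instead of an analysis set
#' @param pool_n_ntg,pool_n_crao pool sizes in pool mode
#' @param jitter_sd per-scan jitter SD (fraction)
#' @param pitch curve sampling pitch (um)
#' @param vessel_shadow_prob per-scan vessel shadow probability
#' @param render render section geometry (pool mode skips rendering)
#' @param params per-group parameter table ([default_group_params()] if NULL)
#' @return validated config list of class `cohort_config`
#' @export
cohort_config <- function(n_ntg = 31, n_crao = 31, include_fellow = TRUE,
                          pool = FALSE, pool_n_ntg = 121, pool_n_crao = 90,
                          jitter_sd = 0.02, pitch = 10,
                          vessel_shadow_prob = 0, render = !pool,
                          params = NULL) {
  chk_count <- function(x, nm, min = 0) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
      stop(sprintf("invalid config field '%s': must be an integer >= %d", nm, min))
    }
  }
  chk_count(n_ntg, "n_ntg"); chk_count(n_crao, "n_crao")
  chk_count(pool_n_ntg, "pool_n_ntg", 1); chk_count(pool_n_crao, "pool_n_crao", 1)
  if (!is.numeric(jitter_sd) || jitter_sd < 0) stop("invalid config field 'jitter_sd': must be >= 0")
  if (!is.numeric(pitch) || pitch <= 0) stop("invalid config field 'pitch': must be > 0")
  if (!is.numeric(vessel_shadow_prob) || vessel_shadow_prob < 0 || vessel_shadow_prob > 1) {
    stop("invalid config field 'vessel_shadow_prob': must be in [0, 1]")
  }
  if (is.null(params)) params <- default_group_params()
  structure(list(n_ntg = as.integer(n_ntg), n_crao = as.integer(n_crao),
                 include_fellow = isTRUE(include_fellow), pool = isTRUE(pool),
                 pool_n_ntg = as.integer(pool_n_ntg),
                 pool_n_crao = as.integer(pool_n_crao),
                 jitter_sd = jitter_sd, pitch = pitch,
                 vessel_shadow_prob = vessel_shadow_prob,
                 render = isTRUE(render), params = params),
            class = "cohort_config")
}

eye_to_row <- function(eye) {
  data.frame(eye_id = eye$eye_id, subject_id = eye$subject_id,
             group = eye$group, age = eye$age, sex = eye$sex,
             spherical_equivalent = eye$spherical_equivalent,
             iop_at_oct = eye$iop_at_oct, disc_area = eye$disc_area,
             ovality = eye$ovality, torsion_deg = eye$torsion_deg,
             rnfl_global = eye$rnfl_global, rnfl_ts = eye$rnfl_ts,
             rnfl_t = eye$rnfl_t, rnfl_ti = eye$rnfl_ti,
             rnfl_ni = eye$rnfl_ni, rnfl_n = eye$rnfl_n,
             rnfl_ns = eye$rnfl_ns,
             crao_subtype = eye$crao_subtype,
             neovascular_glaucoma = eye$neovascular_glaucoma,
             quality_fail_sections = eye$quality_fail_sections,
             max_iop = eye$max_iop, vf_glaucomatous = eye$vf_glaucomatous,
             prior_surgery = eye$prior_surgery,
             retinal_or_neuro_disease = eye$retinal_or_neuro_disease,
             branch_rao = eye$branch_rao,
             glaucoma_history = eye$glaucoma_history,
             latent_hrw = eye$latent$hrw, latent_mrw = eye$latent$mrw,
             latent_lcci = eye$latent$lcci,
             stringsAsFactors = FALSE)
}

#' Generate a full synthetic cohort
#'
#' In analysis mode (default): `n_ntg` NTG eyes, `n_crao` CRAO eyes and the
#' healthy fellow eye of each CRAO subject (fellow eyes share subject-level
#' age and sex with their CRAO partner), all with rendered section geometry.
#' In pool mode: pre-screening candidate pools (default 121 NTG / 90 CRAO)
#' whose exclusion attributes are assigned deterministically at the study
#' screening frequencies, without rendered geometry.
#'
#' @param config a [cohort_config()]
#' @param seed integer root seed; per-eye child seeds are derived from it so
#'   output is deterministic and order-independent
#' @return an object of class `onh_cohort`: list with `cohort` (one row per
#'   eye) and `eyes` (list of `eye_record`)
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  p <- config$params
  prow <- function(g) p[p$group == g, , drop = FALSE]
  for (g in c("NTG", "CRAO", "healthy")) {
    if (nrow(prow(g)) != 1L) stop("parameter table must have exactly one row for group ", g)
  }
  eyes <- list()
  mk <- function(group, key, eye_id, subject_id) {
    e <- sample_eye(prow(group), seed = child_seed(seed, key),
                    eye_id = eye_id, subject_id = subject_id)
    e
  }
  if (!config$pool) {
    for (i in seq_len(config$n_crao)) {
      sid <- sprintf("subj_CRAO_%03d", i)
      ce <- mk("CRAO", 10000 + i, sprintf("CRAO_%03d", i), sid)
      if (config$render) {
        ce <- render_sections(ce, jitter_sd = config$jitter_sd,
                              pitch = config$pitch,
                              vessel_shadow_prob = config$vessel_shadow_prob)
      }
      eyes[[ce$eye_id]] <- ce
      if (config$include_fellow) {
        he <- mk("healthy", 20000 + i, sprintf("H_%03d", i), sid)
        he$age <- ce$age
        he$sex <- ce$sex
        if (config$render) {
          he <- render_sections(he, jitter_sd = config$jitter_sd,
                                pitch = config$pitch,
                                vessel_shadow_prob = config$vessel_shadow_prob)
        }
        eyes[[he$eye_id]] <- he
      }
    }
    for (i in seq_len(config$n_ntg)) {
      ne <- mk("NTG", i, sprintf("NTG_%03d", i), sprintf("subj_NTG_%03d", i))
      if (config$render) {
        ne <- render_sections(ne, jitter_sd = config$jitter_sd,
                              pitch = config$pitch,
                              vessel_shadow_prob = config$vessel_shadow_prob)
      }
      eyes[[ne$eye_id]] <- ne
    }
  } else {
    # Pre-screening pools with deterministic exclusion attributes: the first
    # k rows per reason, so screening counts are exact rather than expected.
    for (i in seq_len(config$pool_n_crao)) {
      e <- mk("CRAO", 30000 + i, sprintf("CRAOP_%03d", i), sprintf("subj_CRAOP_%03d", i))
      if (i <= 31) {
        e$crao_subtype <- "incomplete"
      } else if (i <= 36) {
        e$neovascular_glaucoma <- TRUE
      } else if (i <= 47) {
        e$ovality <- 1.40
      } else if (i <= 59) {
        e$quality_fail_sections <- 6L
      }
      eyes[[e$eye_id]] <- e
    }
    crao_clean <- eyes[sprintf("CRAOP_%03d", 60:90)]
    for (i in seq_len(config$pool_n_ntg)) {
      e <- mk("NTG", 40000 + i, sprintf("NTGP_%03d", i), sprintf("subj_NTGP_%03d", i))
      if (i <= 47) {
        e$ovality <- 1.40
      } else if (i <= 76) {
        e$quality_fail_sections <- 6L
      } else if (i <= 107) {
        # matchable candidates: covariates near a distinct clean CRAO eye
        partner <- crao_clean[[i - 76]]
        set.seed(child_seed(seed, 50000 + i))
        e$age <- partner$age + stats::runif(1, -1, 1)
        e$iop_at_oct <- partner$iop_at_oct + stats::runif(1, -0.5, 0.5)
        e$disc_area <- partner$disc_area + stats::runif(1, -0.05, 0.05)
        e$rnfl_global <- partner$rnfl_global + stats::runif(1, -2, 2)
      } else {
        # candidates with no acceptable partner: age beyond every caliper
        ages <- vapply(crao_clean, function(x) x$age, numeric(1))
        e$age <- max(ages) + 10 + (i - 107)
      }
      eyes[[e$eye_id]] <- e
    }
  }
  cohort <- do.call(rbind, lapply(eyes, eye_to_row))
  rownames(cohort) <- NULL
  structure(list(cohort = cohort, eyes = eyes, config = config, seed = seed),
            class = "onh_cohort")
}

#' @export
print.onh_cohort <- function(x, ...) {
  tab <- table(x$cohort$group)
  cat(sprintf("<onh_cohort: %d eyes (%s), seed %d%s>\n", nrow(x$cohort),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              x$seed, if (x$config$pool) ", pre-screening pool" else ""))
  invisible(x)
}
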