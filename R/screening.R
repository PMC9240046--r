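#' Eligibility screening and 1:1 matching
#'
#' Reproduces the study-flow from a candidate pool to the analysis set:
#' deterministic rule-based exclusions (CRAO completeness grade, neovascular
#' glaucoma, tilted/torted discs, OCT quality, refraction, surgery and
#' disease history, IOP history) followed by greedy 1:1 nearest-neighbour
#' matching of NTG to CRAO eyes on age, IOP at OCT, disc area and global
#' RNFL thickness within per-variable calipers.
#'
#' @name screening
NULL

exclusion_reasons <- c("incomplete_crao", "neovascular_glaucoma",
                       "tilted_or_torted_disc", "poor_oct_quality",
                       "refraction_out_of_range", "prior_surgery",
                       "retinal_or_neuro_disease", "high_iop",
                       "branch_rao", "glaucoma_history")

#' Apply the eligibility exclusion rules to a candidate pool
#'
#' Rules (an eye is excluded if any fires; reasons are reported in a fixed
#' order): incomplete-type CRAO (only subtotal/total grades are eligible);
#' neovascular glaucoma; tilted or torted disc (ovality index > 1.3 or
#' torsion angle > 15 degrees, both strict); poor OCT quality (more than five
#' sections failing the quality score); spherical equivalent < -8 D or
#' > +3 D; prior intraocular surgery; retinal or neurological disease;
#' maximum IOP > 21 mmHg; branch retinal artery occlusion; glaucoma
#' family/medication history.
#'
#' @param pool data.frame with one row per candidate eye (needs columns
#'   `eye_id`, `group`, `crao_subtype`, `neovascular_glaucoma`, `ovality`,
#'   `torsion_deg`, `quality_fail_sections`, `spherical_equivalent`,
#'   `prior_surgery`, `retinal_or_neuro_disease`, `max_iop`, `branch_rao`,
#'   `glaucoma_history`)
#' @return data.frame with `eye_id`, `excluded` and a semicolon-joined
#'   `reasons` column (empty when kept); row order follows the input
#' @export
apply_exclusions <- function(pool) {
  stopifnot(is.data.frame(pool))
  needed <- c("eye_id", "group", "crao_subtype", "neovascular_glaucoma",
              "ovality", "torsion_deg", "quality_fail_sections",
              "spherical_equivalent", "prior_surgery",
              "retinal_or_neuro_disease", "max_iop", "branch_rao",
              "glaucoma_history")
  miss <- setdiff(needed, names(pool))
  if (length(miss)) stop("pool lacks required columns: ", paste(miss, collapse = ", "))
  for (col in setdiff(needed, c("eye_id", "group", "crao_subtype"))) {
    bad <- which(is.na(pool[[col]]))
    if (length(bad)) {
      stop(sprintf("eye %s: missing attribute '%s'", pool$eye_id[bad[1L]], col))
    }
  }
  fired <- cbind(
    incomplete_crao = pool$group == "CRAO" & !is.na(pool$crao_subtype) &
      pool$crao_subtype == "incomplete",
    neovascular_glaucoma = pool$neovascular_glaucoma,
    tilted_or_torted_disc = pool$ovality > 1.3 | pool$torsion_deg > 15,
    poor_oct_quality = pool$quality_fail_sections > 5,
    refraction_out_of_range = pool$spherical_equivalent < -8 |
      pool$spherical_equivalent > 3,
    prior_surgery = pool$prior_surgery,
    retinal_or_neuro_disease = pool$retinal_or_neuro_disease,
    high_iop = pool$max_iop > 21,
    branch_rao = pool$branch_rao,
    glaucoma_history = pool$glaucoma_history)
  reasons <- apply(fired, 1L, function(f) paste(exclusion_reasons[f], collapse = ";"))
  data.frame(eye_id = pool$eye_id, excluded = rowSums(fired) > 0,
             reasons = reasons, stringsAsFactors = FALSE)
}

#' Greedy 1:1 nearest-neighbour matching with calipers
#'
#' NTG and CRAO eyes are matched 1:1 on the Euclidean distance of the
#' z-standardised matching variables (standardised over the pooled tables).
#' Pairs are accepted smallest distance first, and only when every raw
#' per-variable difference lies within its caliper. Ties are broken toward
#' the smaller NTG then CRAO `eye_id`, so the result is deterministic.
#'
#' @param ntg,crao data.frames of candidate eyes (post-exclusion), each with
#'   `eye_id` and the matching variables
#' @param variables matching variable names
#' @param calipers named (or positionally matched) per-variable maximum
#'   absolute differences; defaults: 5 years age, 3 mmHg IOP, 0.3 mm2 disc
#'   area, 10 um global RNFL
#' @return list with `pairs` (data.frame `ntg_eye_id`, `crao_eye_id`,
#'   `distance`), `caliper_used` and `unmatched` ids
#' @export
match_one_to_one <- function(ntg, crao,
                             variables = c("age", "iop_at_oct", "disc_area",
                                           "rnfl_global"),
                             calipers = c(age = 5, iop_at_oct = 3,
                                          disc_area = 0.3, rnfl_global = 10)) {
  if (length(calipers) != length(variables)) {
    stop("calipers must have one entry per matching variable")
  }
  if (is.null(names(calipers))) names(calipers) <- variables
  calipers <- calipers[variables]
  empty <- data.frame(ntg_eye_id = character(0), crao_eye_id = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  if (nrow(ntg) == 0L || nrow(crao) == 0L) {
    warning("empty candidate set: no pairs formed")
    return(list(pairs = empty, caliper_used = calipers,
                unmatched = c(ntg$eye_id, crao$eye_id)))
  }
  miss <- setdiff(variables, intersect(names(ntg), names(crao)))
  if (length(miss)) stop("matching variables absent: ", paste(miss, collapse = ", "))
  pooled <- rbind(ntg[, variables, drop = FALSE], crao[, variables, drop = FALSE])
  mu <- colMeans(pooled)
  sdv <- apply(pooled, 2L, stats::sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  zn <- scale(ntg[, variables, drop = FALSE], center = mu, scale = sdv)
  zc <- scale(crao[, variables, drop = FALSE], center = mu, scale = sdv)
  # admissibility and distances for every candidate pair
  cand <- expand.grid(i = seq_len(nrow(ntg)), j = seq_len(nrow(crao)))
  ok <- rep(TRUE, nrow(cand))
  for (v in variables) {
    dv <- abs(ntg[[v]][cand$i] - crao[[v]][cand$j])
    ok <- ok & dv <= calipers[[v]]
  }
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand)) {
    d <- sqrt(rowSums((zn[cand$i, , drop = FALSE] - zc[cand$j, , drop = FALSE])^2))
    o <- order(d, ntg$eye_id[cand$i], crao$eye_id[cand$j])
    cand <- cand[o, , drop = FALSE]
    d <- d[o]
  } else {
    d <- numeric(0)
  }
  used_n <- logical(nrow(ntg))
  used_c <- logical(nrow(crao))
  pairs <- empty
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (used_n[i] || used_c[j]) next
    used_n[i] <- TRUE
    used_c[j] <- TRUE
    pairs <- rbind(pairs, data.frame(ntg_eye_id = ntg$eye_id[i],
                                     crao_eye_id = crao$eye_id[j],
                                     distance = d[k],
                                     stringsAsFactors = FALSE))
  }
  list(pairs = pairs, caliper_used = calipers,
       unmatched = c(ntg$eye_id[!used_n], crao$eye_id[!used_c]))
}
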