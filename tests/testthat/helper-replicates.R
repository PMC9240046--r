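# Replicate-cohort simulation shared by the recovery and significance
# acceptance tests: full generate -> render -> measure -> compare pipeline on
# replicate cohorts (31 eyes per group), cached so the suite pays the
# simulation cost once.

.replicate_cache <- new.env(parent = emptyenv())

replicate_cohort_stats <- function(n_reps = 200) {
  key <- paste0("reps_", n_reps)
  if (!is.null(.replicate_cache[[key]])) return(.replicate_cache[[key]])
  cfg <- cohort_config()
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    co <- generate_cohort(cfg, seed = r)
    m <- measure_cohort(co)
    cmp <- compare_three_groups(m$mean_mrw, m$group)
    gm <- function(var, g) mean(m[[var]][m$group == g])
    rows[[r]] <- data.frame(
      rep = r,
      ntg_hrw = gm("mean_hrw", "NTG"),
      ntg_lcci = gm("mean_lcci", "NTG"),
      crao_lcci = gm("mean_lcci", "CRAO"),
      healthy_mrw = gm("mean_mrw", "healthy"),
      mrw_p = cmp$omnibus_p,
      mrw_pattern = cmp$pattern,
      hrw_lcci_slope = regress_hrw_on_lcci(m)$slope,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  .replicate_cache[[key]] <- out
  out
}
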