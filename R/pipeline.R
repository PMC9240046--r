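#' Pipeline orchestration and file round-tripping
#'
#' JSON is used for per-eye section geometry, CSV for cohort and morphometry
#' tables, and a JSON manifest records seed, inputs and output hashes. All
#' writes are atomic (temp file + rename) so an interrupted run never leaves
#' a half-written artifact.
#'
#' @name cli_reporting
NULL

atomic_write <- function(writer, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

curve_to_list <- function(curve) {
  unname(lapply(seq_along(curve$x),
                function(i) c(round(curve$x[i], 2), round(curve$z[i], 2))))
}

list_to_curve <- function(lst, role) {
  m <- do.call(rbind, lapply(lst, as.numeric))
  curve2d(m[, 1L], m[, 2L], role = role)
}

section_to_list <- function(s) {
  list(section_id = s$section_id, location = s$location,
       scan_offset = s$scan_offset, quality_score = round(s$quality_score, 2),
       flags = as.list(s$flags),
       curves = list(ilm = curve_to_list(s$ilm), bm = curve_to_list(s$bm),
                     alcs = curve_to_list(s$alcs)),
       bmo = list(temporal = round(unname(s$bmo_temporal), 2),
                  nasal = round(unname(s$bmo_nasal), 2)))
}

list_to_section <- function(l) {
  need <- c("section_id", "location", "scan_offset", "quality_score",
            "curves", "bmo")
  miss <- setdiff(need, names(l))
  if (length(miss)) {
    stop("section JSON lacks field(s): ", paste(miss, collapse = ", "))
  }
  bscan_section(section_id = l$section_id, location = l$location,
                scan_offset = l$scan_offset,
                ilm = list_to_curve(l$curves$ilm, "ILM"),
                bm = list_to_curve(l$curves$bm, "BM"),
                alcs = list_to_curve(l$curves$alcs, "ALCS"),
                bmo_temporal = point2d(as.numeric(l$bmo$temporal[[1L]]),
                                       as.numeric(l$bmo$temporal[[2L]])),
                bmo_nasal = point2d(as.numeric(l$bmo$nasal[[1L]]),
                                    as.numeric(l$bmo$nasal[[2L]])),
                quality_score = l$quality_score,
                flags = unlist(l$flags) %||% character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read per-eye section geometry JSON
#'
#' Coordinates are written in micrometres with 2-decimal precision; a parse,
#' serialise, parse cycle therefore reproduces the in-memory structures
#' exactly at that precision.
#'
#' @param sections list of `bscan_section`
#' @param path file path
#' @return `read_sections_json` returns a list of `bscan_section`
#' @export
write_sections_json <- function(sections, path) {
  payload <- list(sections = lapply(sections, section_to_list))
  atomic_write(function(tmp) {
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA)
  }, path)
}

#' @rdname write_sections_json
#' @export
read_sections_json <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(l$sections)) stop("not a section geometry file: missing 'sections'")
  lapply(l$sections, list_to_section)
}

#' Write / read a cohort (or morphometry) table as CSV
#'
#' @param df data.frame
#' @param path file path
#' @param required columns that must be present on read
#' @return `read_cohort_csv` returns the data.frame
#' @export
write_cohort_csv <- function(df, path) {
  atomic_write(function(tmp) utils::write.csv(df, tmp, row.names = FALSE), path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path, required = c("eye_id", "group")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("cohort CSV lacks required column(s): ", paste(miss, collapse = ", "))
  }
  df
}

#' Pipeline configuration
#'
#' @param seed integer root seed for all randomness
#' @param out output directory
#' @param n_ntg,n_crao analysis-set group sizes
#' @param jitter_sd per-scan jitter SD (fraction of the value)
#' @param observer_noise_pct interobserver simulation noise (percent)
#' @param alpha significance level
#' @param posthoc post-hoc method (`"auto"`, `"tukey"`, `"dunn"`)
#' @param pool also generate and screen a pre-screening pool
#' @param calipers matching calipers (see [match_one_to_one()])
#' @param write_sections write one section-geometry JSON per eye
#' @return validated list of class `pipeline_config`
#' @export
pipeline_config <- function(seed = 1, out = "onh_out", n_ntg = 31, n_crao = 31,
                            jitter_sd = 0.02, observer_noise_pct = 2,
                            alpha = 0.05, posthoc = "auto", pool = TRUE,
                            calipers = c(age = 5, iop_at_oct = 3,
                                         disc_area = 0.3, rnfl_global = 10),
                            write_sections = FALSE) {
  if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed)) {
    stop("invalid config field 'seed': must be an integer")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("invalid config field 'alpha': must lie in (0, 1)")
  }
  if (!is.numeric(observer_noise_pct) || observer_noise_pct < 0) {
    stop("invalid config field 'observer_noise_pct': must be >= 0")
  }
  posthoc <- match.arg(posthoc, c("auto", "tukey", "dunn"))
  structure(list(seed = as.integer(seed), out = out,
                 n_ntg = n_ntg, n_crao = n_crao, jitter_sd = jitter_sd,
                 observer_noise_pct = observer_noise_pct, alpha = alpha,
                 posthoc = posthoc, pool = isTRUE(pool), calipers = calipers,
                 write_sections = isTRUE(write_sections)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path config file; fields are passed to [pipeline_config()]
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, cfg)
}

#' Run the full simulate-measure-screen-analyse pipeline
#'
#' Stages: (1) simulate the analysis cohort (and optionally the
#' pre-screening pool), (2) render and measure every eye, (3) screen and
#' match the pool, (4) run the group comparisons, interobserver ICC and the
#' HRW-on-LCCI regression, (5) write tables and a manifest of output hashes.
#'
#' @param config a [pipeline_config()]
#' @return (invisibly) list with the measured cohort, screening results,
#'   report tables and the manifest
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate"
  res <- tryCatch({
    cohort <- generate_cohort(cohort_config(n_ntg = config$n_ntg,
                                            n_crao = config$n_crao,
                                            jitter_sd = config$jitter_sd),
                              seed = config$seed)
    stage <- "measure"
    measured <- measure_cohort(cohort)
    write_cohort_csv(measured, file.path(out, "morphometry.csv"))
    if (config$write_sections) {
      for (e in cohort$eyes) {
        write_sections_json(e$sections,
                            file.path(out, "sections", paste0(e$eye_id, ".json")))
      }
    }
    screening <- NULL
    if (config$pool) {
      stage <- "screen"
      pool <- generate_cohort(cohort_config(pool = TRUE), seed = config$seed)
      reports <- apply_exclusions(pool$cohort)
      kept <- pool$cohort[!reports$excluded, , drop = FALSE]
      match <- match_one_to_one(kept[kept$group == "NTG", , drop = FALSE],
                                kept[kept$group == "CRAO", , drop = FALSE],
                                calipers = config$calipers)
      write_cohort_csv(reports, file.path(out, "exclusions.csv"))
      write_cohort_csv(match$pairs, file.path(out, "matched_pairs.csv"))
      screening <- list(reports = reports, match = match)
    }
    stage <- "stats"
    tables <- build_tables(measured, alpha = config$alpha)
    section_ind <- measure_sections(do.call(c, lapply(cohort$eyes, `[[`, "sections")))
    obs <- simulate_observers(section_ind,
                              noise_sd_pct = config$observer_noise_pct,
                              seed = child_seed(config$seed, 99991))
    icc <- lapply(c(hrw = "hrw_temporal", mrw = "mrw_temporal", lcci = "lcci"),
                  function(cl) icc_two_observers(obs$obs1[[cl]], obs$obs2[[cl]]))
    reg <- regress_hrw_on_lcci(measured)
    stage <- "report"
    comp_df <- do.call(rbind, unclass(tables))
    write_cohort_csv(comp_df, file.path(out, "comparisons.csv"))
    atomic_write(function(tmp) {
      con <- file(tmp, "w")
      on.exit(close(con))
      sink(con)
      print(tables)
      cat(sprintf("Interobserver ICC(2,1): HRW %.3f [%.3f, %.3f], MRW %.3f [%.3f, %.3f], LCCI %.3f [%.3f, %.3f]\n",
                  icc$hrw$icc, icc$hrw$ci_low, icc$hrw$ci_high,
                  icc$mrw$icc, icc$mrw$ci_low, icc$mrw$ci_high,
                  icc$lcci$icc, icc$lcci$ci_low, icc$lcci$ci_high))
      cat(sprintf("HRW on LCCI (NTG + CRAO): slope %.2f, r^2 = %.4f, P = %.3g\n",
                  reg$slope, reg$r_squared, reg$p))
      sink()
    }, file.path(out, "tables.txt"))
    outputs <- list.files(out, recursive = TRUE, full.names = TRUE)
    outputs <- outputs[basename(outputs) != "manifest.json"]
    manifest <- list(seed = config$seed,
                     r_version = as.character(getRversion()),
                     package_version = as.character(utils::packageVersion("onhmorph")),
                     n_eyes = nrow(measured),
                     outputs = lapply(stats::setNames(outputs, sub(paste0("^", out, "/?"), "", outputs)),
                                      function(f) unname(tools::md5sum(f))))
    atomic_write(function(tmp) {
      jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA)
    }, file.path(out, "manifest.json"))
    list(measured = measured, screening = screening, tables = tables,
         icc = icc, regression = reg, manifest = manifest)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(res)
}
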