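#' Study-style group statistics
#'
#' The analysis plan mirrors common ophthalmic study practice: per-variable
#' normality is checked group-wise with Shapiro-Wilk at alpha = 0.05; if all
#' groups pass, the three-group omnibus test is one-way ANOVA with Tukey HSD
#' post-hoc, otherwise Kruskal-Wallis with Dunn's rank post-hoc (Bonferroni
#' corrected). Pairwise results are summarised as an ordering pattern string
#' such as `"A < B = C"` (groups sorted by mean; `"<"` where the pairwise
#' comparison is significant). Two-group comparisons are gated the same way
#' onto t / Mann-Whitney / paired-t / Wilcoxon tests. Interobserver agreement
#' uses the two-way random-effects, absolute-agreement, single-measures
#' ICC(2,1) with an F-based 95% confidence interval.
#'
#' @name stats_module
NULL

shapiro_ok <- function(x, alpha = 0.05) {
  # groups too small to test, or essentially constant, cannot support the
  # normality assumption: fall through to the nonparametric branch
  if (length(x) < 3L || stats::sd(x) == 0) return(FALSE)
  stats::shapiro.test(x)$p.value >= alpha
}

# Dunn's rank-based post-hoc after Kruskal-Wallis, with tie correction and
# Bonferroni adjustment over the three pairwise comparisons.
dunn_posthoc <- function(values, group, alpha = 0.05) {
  g <- factor(group)
  r <- rank(values)
  n <- length(values)
  ties <- table(r)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  rbar <- tapply(r, g, mean)
  ni <- tapply(r, g, length)
  lv <- levels(g)
  combs <- utils::combn(lv, 2L)
  out <- data.frame(a = combs[1L, ], b = combs[2L, ], p = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(ncol(combs))) {
    a <- combs[1L, k]; b <- combs[2L, k]
    se <- sqrt((n * (n + 1) / 12) * tie_corr * (1 / ni[[a]] + 1 / ni[[b]]))
    z <- (rbar[[a]] - rbar[[b]]) / se
    out$p[k] <- min(1, 2 * stats::pnorm(-abs(z)) * ncol(combs))
  }
  out
}

# "A < B = C" style summary: groups ordered by mean, adjacent connector "<"
# only when that pairwise comparison is significant AND the means differ in
# that direction (they do, once sorted).
pattern_string <- function(means, pairwise, alpha = 0.05) {
  ord <- names(sort(means))
  get_p <- function(a, b) {
    hit <- (pairwise$a == a & pairwise$b == b) | (pairwise$a == b & pairwise$b == a)
    pairwise$p[hit][1L]
  }
  sep <- vapply(seq_len(length(ord) - 1L), function(i) {
    p <- get_p(ord[i], ord[i + 1L])
    if (!is.na(p) && p < alpha) " < " else " = "
  }, character(1))
  paste0(ord[1L], paste0(sep, ord[-1L], collapse = ""))
}

#' Three-group omnibus comparison with post-hoc pattern
#'
#' @param values numeric vector of observations
#' @param group grouping factor/character (exactly three levels)
#' @param alpha significance level for the normality gate, the post-hoc
#'   pattern and the pairwise calls
#' @param posthoc `"auto"` (Tukey after ANOVA, Dunn after Kruskal-Wallis),
#'   `"tukey"` or `"dunn"` to force the pairwise method
#' @return list of class `group_comparison`: `test_used` (`"ANOVA"` or
#'   `"KruskalWallis"`), `statistic`, `omnibus_p`, `pairwise` (data.frame
#'   `a`, `b`, `p`), `pattern`, `means`
#' @export
compare_three_groups <- function(values, group, alpha = 0.05,
                                 posthoc = c("auto", "tukey", "dunn")) {
  posthoc <- match.arg(posthoc)
  g <- factor(group)
  if (nlevels(g) != 3L) stop("exactly three groups are required")
  ni <- tapply(values, g, length)
  if (any(ni < 2L)) stop("every group needs at least 2 observations")
  if (stats::sd(values) == 0) stop("all observations identical: no variance to test")
  normal <- all(vapply(split(values, g), shapiro_ok, logical(1), alpha = alpha))
  means <- tapply(values, g, mean)
  if (normal) {
    fit <- stats::aov(values ~ g)
    an <- summary(fit)[[1L]]
    omnibus_p <- an[["Pr(>F)"]][1L]
    statistic <- an[["F value"]][1L]
    test_used <- "ANOVA"
  } else {
    kw <- stats::kruskal.test(values, g)
    omnibus_p <- kw$p.value
    statistic <- unname(kw$statistic)
    test_used <- "KruskalWallis"
  }
  method <- if (posthoc == "auto") {
    if (test_used == "ANOVA") "tukey" else "dunn"
  } else posthoc
  if (method == "tukey") {
    tk <- stats::TukeyHSD(stats::aov(values ~ g))$g
    nm <- strsplit(rownames(tk), "-", fixed = TRUE)
    pairwise <- data.frame(a = vapply(nm, `[`, "", 2L),
                           b = vapply(nm, `[`, "", 1L),
                           p = unname(tk[, "p adj"]), stringsAsFactors = FALSE)
  } else {
    pairwise <- dunn_posthoc(values, g, alpha = alpha)
  }
  structure(list(test_used = test_used, statistic = statistic,
                 omnibus_p = omnibus_p, pairwise = pairwise,
                 pattern = pattern_string(means, pairwise, alpha = alpha),
                 means = means),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison: %s, P = %.3g, pattern %s>\n",
              x$test_used, x$omnibus_p, x$pattern))
  invisible(x)
}

#' Normality-gated two-group comparison
#'
#' Unpaired: t-test when both samples pass Shapiro-Wilk, Mann-Whitney U
#' otherwise. Paired: the gate is applied to the differences; paired t-test
#' or Wilcoxon signed-rank. All-zero paired differences are reported as
#' p = 1 (no evidence of a shift; the signed-rank zero rule leaves no ranks).
#'
#' @param x,y numeric samples
#' @param paired logical; requires equal lengths
#' @param alpha normality-gate level
#' @return list with `test`, `p`, `statistic`
#' @export
compare_two_groups <- function(x, y, paired = FALSE, alpha = 0.05) {
  if (length(x) < 2L || length(y) < 2L) stop("both samples need >= 2 values")
  if (paired && length(x) != length(y)) {
    stop("paired comparison requires equal-length samples")
  }
  if (paired) {
    d <- x - y
    if (all(d == 0)) return(list(test = "wilcoxon_signed_rank", p = 1,
                                 statistic = 0))
    if (shapiro_ok(d, alpha)) {
      tt <- stats::t.test(x, y, paired = TRUE)
      list(test = "paired_t", p = tt$p.value, statistic = unname(tt$statistic))
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE, exact = FALSE))
      list(test = "wilcoxon_signed_rank", p = wt$p.value,
           statistic = unname(wt$statistic))
    }
  } else {
    if (shapiro_ok(x, alpha) && shapiro_ok(y, alpha)) {
      tt <- stats::t.test(x, y)
      list(test = "t", p = tt$p.value, statistic = unname(tt$statistic))
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
      list(test = "mann_whitney", p = wt$p.value, statistic = unname(wt$statistic))
    }
  }
}

#' Interobserver ICC(2,1) with 95% confidence interval
#'
#' Two-way random-effects, absolute-agreement, single-measures intraclass
#' correlation from the two-way ANOVA mean squares, with the F-based
#' confidence bounds of McGraw & Wong.
#'
#' @param obs1,obs2 equal-length paired measurement vectors (n >= 3)
#' @param conf confidence level
#' @return list with `icc`, `ci_low`, `ci_high`, `n`
#' @export
icc_two_observers <- function(obs1, obs2, conf = 0.95) {
  if (length(obs1) != length(obs2)) stop("observer vectors must have equal length")
  n <- length(obs1)
  if (n < 3L) stop("ICC needs at least 3 paired measurements")
  y <- c(obs1, obs2)
  if (stats::var(y) == 0) stop("zero total variance: ICC undefined")
  k <- 2L
  subj <- rowMeans(cbind(obs1, obs2))
  rater <- c(mean(obs1), mean(obs2))
  grand <- mean(y)
  ssr <- k * sum((subj - grand)^2)            # between-subjects
  ssc <- n * sum((rater - grand)^2)           # between-raters
  sse <- sum((cbind(obs1, obs2) - outer(subj, c(1, 1)) -
                matrix(rater, n, k, byrow = TRUE) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  if (is.nan(lower)) lower <- icc
  if (is.nan(upper)) upper <- icc
  list(icc = icc, ci_low = min(lower, icc), ci_high = max(upper, icc), n = n)
}

#' Ordinary least squares of HRW on LCCI
#'
#' Pools the requested groups and regresses per-eye mean HRW on per-eye mean
#' LCCI; in glaucomatous remodelling a smaller rim is expected with a more
#' posteriorly bowed lamina, i.e. a negative slope.
#'
#' @param table measured cohort data.frame (needs `group`, `mean_hrw`,
#'   `mean_lcci`)
#' @param groups groups to pool (default NTG + CRAO)
#' @return list with `slope`, `intercept`, `r_squared`, `p`, `n`
#' @export
regress_hrw_on_lcci <- function(table, groups = c("NTG", "CRAO")) {
  d <- table[table$group %in% groups, , drop = FALSE]
  if (nrow(d) < 3L) stop("need at least 3 rows to fit the regression")
  if (stats::sd(d$mean_lcci) == 0) stop("constant predictor: LCCI has no variance")
  fit <- stats::lm(mean_hrw ~ mean_lcci, data = d)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared,
       p = sm$coefficients[2L, 4L],
       n = nrow(d))
}

fmt_mean_sd <- function(x, digits = 1) {
  sprintf(paste0("%.", digits, "f ± %.", digits, "f"), mean(x), stats::sd(x))
}

#' Build study-style summary tables
#'
#' Emits the three report tables: clinical characteristics (age, refraction,
#' IOP, RNFL thicknesses), ONH morphology (disc area, ovality, mean HRW /
#' MRW / HMR / LCCI) and temporal-rim variants, each with per-group
#' mean ± SD, the gated omnibus test and P, pairwise P values and the
#' ordering pattern.
#'
#' @param measured measured cohort data.frame as returned by
#'   [measure_cohort()]
#' @param alpha significance level
#' @return list of class `onh_report` with data.frames `characteristics`,
#'   `morphology`, `temporal`
#' @export
build_tables <- function(measured, alpha = 0.05) {
  need <- c("group", "age", "spherical_equivalent", "iop_at_oct",
            "rnfl_global", "rnfl_ts", "rnfl_t", "rnfl_ti", "rnfl_ni",
            "rnfl_n", "rnfl_ns", "disc_area", "ovality", "mean_hrw",
            "mean_mrw", "mean_hmr", "mean_lcci", "temporal_hrw",
            "temporal_mrw", "temporal_hmr")
  miss <- setdiff(need, names(measured))
  if (length(miss)) stop("measured cohort lacks columns: ", paste(miss, collapse = ", "))
  groups <- c("NTG", "CRAO", "healthy")
  row_for <- function(var, label, digits = 1) {
    v <- measured[[var]]
    cmp <- compare_three_groups(v, measured$group, alpha = alpha)
    cells <- vapply(groups, function(g) fmt_mean_sd(v[measured$group == g], digits),
                    character(1))
    pw <- function(a, b) {
      hit <- (cmp$pairwise$a == a & cmp$pairwise$b == b) |
             (cmp$pairwise$a == b & cmp$pairwise$b == a)
      cmp$pairwise$p[hit][1L]
    }
    data.frame(variable = label, NTG = cells[1L], CRAO = cells[2L],
               healthy = cells[3L], test = cmp$test_used,
               p_value = cmp$omnibus_p,
               p_ntg_crao = pw("NTG", "CRAO"),
               p_crao_healthy = pw("CRAO", "healthy"),
               p_healthy_ntg = pw("healthy", "NTG"),
               pattern = cmp$pattern, stringsAsFactors = FALSE)
  }
  characteristics <- rbind(
    row_for("age", "Age, years"),
    row_for("spherical_equivalent", "Spherical equivalent, D", 2),
    row_for("iop_at_oct", "IOP at OCT, mmHg"),
    row_for("rnfl_global", "RNFL global, um"),
    row_for("rnfl_ts", "RNFL temporal-superior, um"),
    row_for("rnfl_t", "RNFL temporal, um"),
    row_for("rnfl_ti", "RNFL temporal-inferior, um"),
    row_for("rnfl_ni", "RNFL nasal-inferior, um"),
    row_for("rnfl_n", "RNFL nasal, um"),
    row_for("rnfl_ns", "RNFL nasal-superior, um"))
  morphology <- rbind(
    row_for("disc_area", "Disc area, mm2", 2),
    row_for("ovality", "Disc ovality", 2),
    row_for("mean_hrw", "Mean HRW, um"),
    row_for("mean_mrw", "Mean MRW, um"),
    row_for("mean_hmr", "Mean HMR", 1),
    row_for("mean_lcci", "Mean LCCI", 1))
  temporal <- rbind(
    row_for("temporal_hrw", "Mean temporal HRW, um"),
    row_for("temporal_mrw", "Mean temporal MRW, um"),
    row_for("temporal_hmr", "Mean temporal HMR", 1))
  structure(list(characteristics = characteristics, morphology = morphology,
                 temporal = temporal),
            class = "onh_report")
}

#' @export
print.onh_report <- function(x, ...) {
  for (nm in names(x)) {
    cat("==", nm, "==\n")
    print(x[[nm]], row.names = FALSE, digits = 3)
    cat("\n")
  }
  invisible(x)
}
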