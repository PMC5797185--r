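# Cohort statistics: Welch's t-test, Cohen's d, analytic power for the
# two-sample t-test with unequal n, percent reductions, and the cohort
# report table.

#' Welch's two-sample t-test
#'
#' The unequal-variance t statistic
#' \deqn{t = \frac{\bar a - \bar b}{\sqrt{s_a^2/n_a + s_b^2/n_b}}}
#' with Welch–Satterthwaite degrees of freedom and a two-sided p-value.
#'
#' @param a,b Numeric vectors, one value per mouse (each of length >= 2).
#' @return A list of class `welch_t`: `t`, `df` (non-integer), `p`
#'   (two-sided), `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @export
welch_t <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2)
    stop("each group needs at least two observations", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0)
    stop("both groups have zero variance", call. = FALSE)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(t = t, df = df, p = p,
                 mean_a = mean(a), mean_b = mean(b), n_a = na, n_b = nb),
            class = "welch_t")
}

#' @export
print.welch_t <- function(x, ...) {
  cat(sprintf("Welch's t-test: t(%.1f) = %.2f, p = %.4g\n", x$df, x$t, x$p))
  invisible(x)
}

#' Cohen's d standardized effect size
#'
#' `d = (mean(a) - mean(b)) / s_pooled` with the pooled standard deviation
#' `s_pooled^2 = ((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2)`.
#' By default no small-sample correction is applied; `hedges = TRUE`
#' multiplies by the Hedges g correction factor `1 - 3/(4(n_a + n_b) - 9)`.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @param hedges Apply the small-sample bias correction (default `FALSE`).
#' @return Numeric scalar.
#' @export
cohens_d <- function(a, b, hedges = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2)
    stop("each group needs at least two observations", call. = FALSE)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0)
    stop("pooled variance is zero", call. = FALSE)
  d <- (mean(a) - mean(b)) / sqrt(sp2)
  if (hedges) d <- d * (1 - 3 / (4 * (na + nb) - 9))
  d
}

#' Analytic power of the two-sample t-test with unequal n
#'
#' Power of the two-sided pooled-variance two-sample t-test at standardized
#' effect size `d`, via the noncentral t distribution:
#' noncentrality `ncp = d * sqrt(n1 * n2 / (n1 + n2))`, `df = n1 + n2 - 2`,
#' `power = P(T' > t_crit) + P(T' < -t_crit)` with `t_crit` the upper
#' `alpha/2` quantile of the central t. This is the convention of standard
#' power calculators for the two-sample t-test with unequal group sizes.
#'
#' @param d Standardized effect size (Cohen's d).
#' @param n1,n2 Group sizes (each >= 2).
#' @param alpha Two-sided type-I error probability (default 0.05).
#' @return A list of class `power_t2n`: `d`, `n1`, `n2`, `alpha`, `power`.
#' @examples
#' power_t2n(1.8, 7, 12)$power   # ~0.946
#' power_t2n(1.6, 12, 12)$power  # ~0.963
#' @export
power_t2n <- function(d, n1, n2, alpha = 0.05) {
  if (!is.numeric(d) || length(d) != 1L || is.na(d))
    stop("`d` must be a single number", call. = FALSE)
  if (n1 < 2 || n2 < 2)
    stop("`n1` and `n2` must each be at least 2", call. = FALSE)
  if (alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tcrit <- stats::qt(1 - alpha / 2, df)
  power <- stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tcrit, df, ncp = ncp)
  structure(list(d = d, n1 = n1, n2 = n2, alpha = alpha, power = power),
            class = "power_t2n")
}

#' @export
print.power_t2n <- function(x, ...) {
  cat(sprintf("two-sample t power: d = %g, n = %d/%d, alpha = %g -> %.1f%%\n",
              x$d, x$n1, x$n2, x$alpha, 100 * x$power))
  invisible(x)
}

#' Percent reduction of a comparison mean relative to a reference mean
#'
#' `100 * (reference - comparison) / reference`; positive when the
#' comparison group is lower than the reference.
#'
#' @param reference_mean,comparison_mean Numeric scalars; `reference_mean`
#'   must be non-zero.
#' @return Numeric scalar, in percent.
#' @examples
#' percent_reduction(100, 63)  # 37
#' @export
percent_reduction <- function(reference_mean, comparison_mean) {
  if (reference_mean == 0)
    stop("`reference_mean` must be non-zero", call. = FALSE)
  100 * (reference_mean - comparison_mean) / reference_mean
}

#' Group-comparison report for a simulated cohort
#'
#' Computes, for each standard metric, the per-genotype means plus Welch's
#' t, Cohen's d and the percent reduction of the comparison genotype
#' relative to the reference genotype (the first profile of the cohort
#' spec). Metrics: FR1 days to criteria; mean active:inactive ratio and
#' mean total pokes per session in each phase; mean PR rewards per session;
#' and the stabilized breakpoint. Excluded mice are dropped; mice whose
#' breakpoint never stabilized are dropped from the breakpoint row.
#' Infinite discrimination ratios (no inactive pokes) are dropped from
#' per-mouse ratio averages. Rows with fewer than two mice in either group
#' carry `NA` comparison columns rather than failing.
#'
#' @param cohort An `operant_cohort` from [simulate_cohort()].
#' @return A data frame, one row per metric: `metric`, `n_ref`, `n_cmp`,
#'   `mean_ref`, `mean_cmp`, `t`, `df`, `p`, `d`, `pct_reduction`.
#' @export
cohort_report <- function(cohort) {
  stopifnot(inherits(cohort, "operant_cohort"))
  prog <- cohort$progress
  summ <- cohort$summaries
  labels <- vapply(cohort$spec$profiles, `[[`, character(1), "label")
  ref <- labels[1]
  cmp <- if (length(labels) > 1) labels[2] else NA_character_

  keep <- prog$mouse_id[!prog$excluded]
  summ <- summ[summ$mouse_id %in% keep, ]

  per_mouse <- function(metric) {
    switch(metric,
      fr1_days_to_criteria = prog[!prog$excluded,
                                  c("mouse_id", "genotype", "fr1_days_to_criteria")],
      breakpoint = prog[!prog$excluded & !is.na(prog$breakpoint),
                        c("mouse_id", "genotype", "breakpoint")],
      {
        parts <- strsplit(metric, "\\.")[[1]]
        ph <- toupper(parts[1]); col <- parts[2]
        s <- summ[summ$phase == ph, ]
        agg <- stats::aggregate(
          s[[col]], by = list(mouse_id = s$mouse_id, genotype = s$genotype),
          FUN = function(v) mean(v[is.finite(v)]))
        names(agg)[3] <- metric
        agg
      })
  }

  metrics <- c("fr1_days_to_criteria",
               "fr1.active_inactive_ratio", "fr1.total_pokes",
               "fr5.active_inactive_ratio", "fr5.total_pokes",
               "pr.active_inactive_ratio", "pr.total_pokes", "pr.rewards",
               "breakpoint")
  rows <- lapply(metrics, function(m) {
    pm <- per_mouse(m)
    v_ref <- pm[pm$genotype == ref, 3]
    v_cmp <- if (is.na(cmp)) numeric(0) else pm[pm$genotype == cmp, 3]
    v_ref <- v_ref[is.finite(v_ref)]
    v_cmp <- v_cmp[is.finite(v_cmp)]
    out <- data.frame(metric = m,
                      n_ref = length(v_ref), n_cmp = length(v_cmp),
                      mean_ref = if (length(v_ref)) mean(v_ref) else NA_real_,
                      mean_cmp = if (length(v_cmp)) mean(v_cmp) else NA_real_,
                      t = NA_real_, df = NA_real_, p = NA_real_, d = NA_real_,
                      pct_reduction = NA_real_,
                      stringsAsFactors = FALSE)
    if (length(v_ref) >= 2 && length(v_cmp) >= 2) {
      ok <- !(stats::var(v_ref) == 0 && stats::var(v_cmp) == 0)
      if (ok) {
        wt <- welch_t(v_ref, v_cmp)
        out$t <- wt$t; out$df <- wt$df; out$p <- wt$p
        out$d <- cohens_d(v_ref, v_cmp)
      }
      if (out$mean_ref != 0)
        out$pct_reduction <- percent_reduction(out$mean_ref, out$mean_cmp)
    }
    out
  })
  do.call(rbind, rows)
}
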