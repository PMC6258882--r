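#' Small-sample corrected coefficient of variation
#'
#' `100 * (sd / mean) * (1 + 1/(4n))`, with the n-1 sample SD. The factor
#' `1 + 1/(4n)` corrects the downward bias of the sample COV at small n;
#' at n = 2 it equals 1.125.
#'
#' @param values Numeric vector (n >= 2) with positive mean.
#' @return Corrected COV in percent.
#' @examples
#' corrected_cov(c(0.09, 0.11))   # 15.91
#' @export
corrected_cov <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) stop("COV needs at least two values", call. = FALSE)
  m <- mean(values)
  if (!is.finite(m) || m <= 0)
    stop("COV undefined for non-positive mean", call. = FALSE)
  100 * (stats::sd(values) / m) * (1 + 1 / (4 * n))
}

#' Pearson correlation with two-sided p-value
#'
#' The p-value comes from the t transform `t = r * sqrt(n-2) / sqrt(1-r^2)`
#' on n-2 degrees of freedom. [pearson_p_from_r()] applies the same
#' transform to a printed r and n, for verifying reported summaries.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), nonconstant.
#' @return List: `r`, `p`, `n`, `df`, `t`.
#' @export
pearson_r_p <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need n >= 3 for the correlation test", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  r <- stats::cor(x, y)
  c(list(r = r), pearson_p_from_r(r, n))
}

#' @rdname pearson_r_p
#' @param r Correlation coefficient in (-1, 1).
#' @param n Sample size (>= 3).
#' @export
pearson_p_from_r <- function(r, n) {
  stopifnot(n >= 3, abs(r) <= 1)
  df <- n - 2
  t <- r * sqrt(df) / sqrt(1 - r^2)
  list(p = 2 * stats::pt(-abs(t), df), n = n, df = df, t = t)
}

#' Paired t-test on two-site values
#'
#' Tests `site1 - site2` (the package-wide difference convention) against
#' zero. The 95 percent confidence half-width is the smallest difference
#' the design could have detected.
#'
#' @param site1,site2 Paired numeric vectors of equal length (n >= 2).
#' @param conf_level Confidence level for the CI (default 0.95).
#' @return List: `mean_diff`, `se`, `t`, `df`, `p`, `ci` (length 2),
#'   `n`.
#' @export
paired_t <- function(site1, site2, conf_level = 0.95) {
  stopifnot(length(site1) == length(site2))
  n <- length(site1)
  if (n < 2) stop("paired t needs n >= 2", call. = FALSE)
  d <- site1 - site2
  md <- mean(d)
  se <- stats::sd(d) / sqrt(n)
  df <- n - 1
  if (se == 0) {
    t <- if (md == 0) 0 else sign(md) * Inf
  } else t <- md / se
  p <- 2 * stats::pt(-abs(t), df)
  tc <- stats::qt(1 - (1 - conf_level) / 2, df)
  list(mean_diff = md, se = se, t = t, df = df, p = p,
       ci = c(md - tc * se, md + tc * se), n = n)
}

#' Two-sided p-value from a printed t statistic
#' @param t t statistic.
#' @param df Degrees of freedom.
#' @return Two-sided p-value.
#' @export
p_from_t <- function(t, df) 2 * stats::pt(-abs(t), df)

#' Two one-sided tests (TOST) of equivalence
#'
#' Declares two paired means statistically equivalent when the mean
#' difference is significantly greater than `-delta` AND significantly
#' less than `+delta`. The overall p is the larger of the two one-sided
#' p-values, and the (1 - 2 alpha) CI — 90 percent at alpha 0.05 — must
#' fall inside the bounds for equivalence at level alpha.
#'
#' Accepts either raw paired data (`site1`, `site2`) or printed summary
#' statistics (`mean_diff`, `se`, `df`), so reported results can be
#' verified without raw data.
#'
#' @param site1,site2 Paired numeric vectors (raw-data interface).
#' @param mean_diff,se,df Summary-statistic interface.
#' @param delta Equivalence bound (> 0); bounds are `c(-delta, delta)`.
#' @param alpha Significance level (default 0.05).
#' @return List: `mean_diff`, `se`, `df`, `bounds`, `p_lower`, `p_upper`,
#'   `p` (max of the two), `ci` (the 1 - 2 alpha CI), `equivalent`.
#' @export
tost <- function(site1 = NULL, site2 = NULL, mean_diff = NULL, se = NULL,
                 df = NULL, delta = 0.005, alpha = 0.05) {
  if (!is.null(site1)) {
    pt_ <- paired_t(site1, site2)
    mean_diff <- pt_$mean_diff; se <- pt_$se; df <- pt_$df
  }
  if (is.null(mean_diff) || is.null(se) || is.null(df))
    stop("supply raw paired data or (mean_diff, se, df)", call. = FALSE)
  if (!(delta > 0) || !(se > 0) || df < 1)
    stop("tost requires delta > 0, se > 0, df >= 1", call. = FALSE)
  t_lower <- (mean_diff + delta) / se     # H0: diff <= -delta
  t_upper <- (mean_diff - delta) / se     # H0: diff >= +delta
  p_lower <- stats::pt(t_lower, df, lower.tail = FALSE)
  p_upper <- stats::pt(t_upper, df)
  p <- max(p_lower, p_upper)
  tc <- stats::qt(1 - alpha, df)
  list(mean_diff = mean_diff, se = se, df = df,
       bounds = c(-delta, delta), p_lower = p_lower, p_upper = p_upper,
       p = p, ci = c(mean_diff - tc * se, mean_diff + tc * se),
       equivalent = p < alpha)
}

#' Bland-Altman agreement analysis
#'
#' Bias is the mean of the paired differences (`site1 - site2`); limits of
#' agreement are `bias +/- 1.96 * SD(differences)`. Proportional bias is
#' assessed by the OLS slope of the differences on the pair means, with a
#' two-sided t test on the slope (df = n - 2).
#'
#' @param site1,site2 Paired numeric vectors.
#' @return List: `bias`, `sd_diff`, `loa` (lower, upper), `slope`,
#'   `slope_p` (`NA` when all pair means are equal), `n`.
#' @export
bland_altman <- function(site1, site2) {
  stopifnot(length(site1) == length(site2))
  n <- length(site1)
  if (n < 2) stop("Bland-Altman needs n >= 2", call. = FALSE)
  d <- site1 - site2
  m <- (site1 + site2) / 2
  bias <- mean(d)
  sdd <- stats::sd(d)
  loa <- c(bias - 1.96 * sdd, bias + 1.96 * sdd)
  slope <- NA_real_; slope_p <- NA_real_
  if (n >= 3 && stats::sd(m) > 0) {
    # OLS of differences on pair means, two-sided t on the slope (df n-2)
    sxx <- sum((m - mean(m))^2)
    slope <- sum((m - mean(m)) * (d - mean(d))) / sxx
    rss <- sum((d - mean(d) - slope * (m - mean(m)))^2)
    if (rss > 1e-20 * max(sum(d^2), .Machine$double.xmin)) {
      se_slope <- sqrt(rss / (n - 2) / sxx)
      slope_p <- 2 * stats::pt(-abs(slope / se_slope), n - 2)
    } else slope_p <- if (abs(slope) < 1e-12) 1 else 0
  }
  list(bias = bias, sd_diff = sdd, loa = loa, slope = slope,
       slope_p = slope_p, n = n)
}

#' Required sample size for a paired t-test
#'
#' Smallest n >= 2 such that a two-sided paired t-test at level `alpha`
#' reaches `power` against effect size `d` (Cohen's d of the differences).
#' Power is computed exactly from the noncentral t distribution with
#' noncentrality `d * sqrt(n)` and `n - 1` degrees of freedom.
#'
#' @param d Effect size (> 0).
#' @param power Target power in (0, 1).
#' @param alpha Two-sided significance level in (0, 1).
#' @param n_max Search cap (error if exceeded).
#' @return Integer sample size.
#' @examples
#' required_sample_size(0.49, 0.90)   # 46
#' required_sample_size(0.49, 0.80)   # 35
#' @export
required_sample_size <- function(d, power, alpha = 0.05, n_max = 1e5) {
  if (!(d > 0)) stop("effect size d must be positive", call. = FALSE)
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1)
  for (n in 2:n_max) {
    if (paired_t_power(n, d, alpha) >= power) return(as.integer(n))
  }
  stop("required sample size exceeds n_max: effect too small", call. = FALSE)
}

#' @rdname required_sample_size
#' @param n Sample size.
#' @return For `paired_t_power`, the power of the two-sided test.
#' @export
paired_t_power <- function(n, d, alpha = 0.05) {
  df <- n - 1
  tc <- stats::qt(1 - alpha / 2, df)
  ncp <- d * sqrt(n)
  stats::pt(-tc, df, ncp) + stats::pt(tc, df, ncp, lower.tail = FALSE)
}

#' Smallest detectable difference of a paired design
#'
#' The half-width of the (default 95 percent) confidence interval of the
#' mean paired difference, `t_{1-(1-conf)/2, df} * SE`: differences
#' smaller than this could not have been distinguished from zero.
#'
#' @param se Standard error of the mean difference.
#' @param df Degrees of freedom.
#' @param conf_level Confidence level (default 0.95).
#' @return The detectable-difference threshold, in the units of `se`.
#' @export
smallest_detectable_difference <- function(se, df, conf_level = 0.95) {
  stopifnot(se > 0, df >= 1)
  stats::qt(1 - (1 - conf_level) / 2, df) * se
}

#' Full intersite reproducibility report
#'
#' Assembles, per ROI, the per-participant corrected COVs across sites and
#' their mean, plus Pearson correlation, paired t, TOST, and Bland-Altman
#' statistics of the per-participant site means. Input is the long-format
#' ROI summary table written by the fitting/ROI stages.
#'
#' @param roi_table Data frame with columns `participant`, `site`, `roi`,
#'   `mean_mwf` (and optionally `n_voxels`, `sd_mwf`). Exactly two sites;
#'   every (participant, roi) pair must be present at both.
#' @param delta TOST equivalence bound (default 0.005).
#' @param alpha Significance level (default 0.05).
#' @return Object of class `repro_report`: list with `cov` (data frame of
#'   per-participant per-ROI corrected COVs), `cov_summary` (per-ROI mean
#'   COV), and `agreement` (per-ROI list of `pearson`, `paired_t`, `tost`,
#'   `bland_altman`).
#' @export
cohort_report <- function(roi_table, delta = 0.005, alpha = 0.05) {
  need <- c("participant", "site", "roi", "mean_mwf")
  if (!all(need %in% names(roi_table)))
    stop("roi_table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  sites <- sort(unique(roi_table$site))
  if (length(sites) != 2)
    stop("expected exactly two sites, found ", length(sites), call. = FALSE)
  wide <- merge(
    roi_table[roi_table$site == sites[1], c("participant", "roi", "mean_mwf")],
    roi_table[roi_table$site == sites[2], c("participant", "roi", "mean_mwf")],
    by = c("participant", "roi"), suffixes = c("_1", "_2"), all = TRUE)
  miss <- wide[is.na(wide$mean_mwf_1) | is.na(wide$mean_mwf_2), ]
  if (nrow(miss) > 0)
    stop("unmatched (participant, roi) pairs: ",
         paste(sprintf("%s/%s", miss$participant, miss$roi), collapse = ", "),
         call. = FALSE)
  wide <- wide[order(wide$roi, wide$participant), ]
  wide$cov <- vapply(seq_len(nrow(wide)), function(i)
    corrected_cov(c(wide$mean_mwf_1[i], wide$mean_mwf_2[i])), numeric(1))
  cov_summary <- stats::aggregate(cov ~ roi, wide, mean)
  names(cov_summary)[2] <- "mean_cov"
  agreement <- lapply(split(wide, wide$roi), function(w) {
    x <- w$mean_mwf_1; y <- w$mean_mwf_2
    if (nrow(w) < 2) {
      # single participant: only the raw bias is defined
      return(list(pearson = NULL, paired_t = NULL, tost = NULL,
                  bland_altman = list(bias = mean(x - y), sd_diff = NA_real_,
                                      loa = c(NA_real_, NA_real_),
                                      slope = NA_real_, slope_p = NA_real_,
                                      n = nrow(w))))
    }
    list(
      pearson = if (nrow(w) >= 3 && stats::sd(x) > 0 && stats::sd(y) > 0)
        pearson_r_p(x, y) else NULL,
      paired_t = paired_t(x, y),
      tost = if (stats::sd(x - y) > 0)
        tost(x, y, delta = delta, alpha = alpha) else NULL,
      bland_altman = bland_altman(x, y))
  })
  structure(list(cov = wide[, c("participant", "roi", "mean_mwf_1",
                                "mean_mwf_2", "cov")],
                 cov_summary = cov_summary, agreement = agreement,
                 sites = sites, delta = delta, alpha = alpha),
            class = "repro_report")
}

#' @export
print.repro_report <- function(x, ...) {
  cat("Intersite reproducibility report\n")
  cat(sprintf("  sites: %s vs %s; TOST bounds +/-%g, alpha %g\n",
              x$sites[1], x$sites[2], x$delta, x$alpha))
  cat("  mean corrected COV (%) by ROI:\n")
  for (i in seq_len(nrow(x$cov_summary)))
    cat(sprintf("    %-24s %6.2f\n", x$cov_summary$roi[i],
                x$cov_summary$mean_cov[i]))
  for (roi in names(x$agreement)) {
    a <- x$agreement[[roi]]
    cat(sprintf("  [%s] bias %.4g, LoA (%.4g, %.4g)",
                roi, a$bland_altman$bias, a$bland_altman$loa[1],
                a$bland_altman$loa[2]))
    if (!is.null(a$pearson))
      cat(sprintf(", r %.3f (p %.3g)", a$pearson$r, a$pearson$p))
    if (!is.null(a$paired_t))
      cat(sprintf(", paired t p %.3g", a$paired_t$p))
    if (!is.null(a$tost)) cat(sprintf(", TOST p %.3g", a$tost$p))
    cat("\n")
  }
  invisible(x)
}
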