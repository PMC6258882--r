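test_that("corrected COV applies the small-sample factor to the n-1 SD", {
  expect_equal(corrected_cov(c(0.10, 0.10)), 0)
  # two-point SD = |a-b|/sqrt(2); factor at n=2 is 1.125
  expect_equal(corrected_cov(c(0.09, 0.11)),
               100 * (0.02 / sqrt(2)) / 0.10 * 1.125, tolerance = 1e-12)
  expect_equal(corrected_cov(c(0.09, 0.11)), 15.90990, tolerance = 1e-5)
  # scale invariance
  set.seed(8)
  for (rep in 1:10) {
    v <- runif(5, 0.5, 1.5)
    expect_equal(corrected_cov(3.7 * v), corrected_cov(v),
                 tolerance = 1e-12)
  }
  expect_error(corrected_cov(c(-1, 1)), "non-positive mean")
  expect_error(corrected_cov(0.1), "two values")
})

test_that("Pearson r and its t-transform p-value behave as printed", {
  x <- 1:10
  expect_equal(pearson_r_p(x, 2 * x + 1)$r, 1)
  expect_equal(round(pearson_p_from_r(0.14, 10)$p, 2), 0.70)
  expect_lt(pearson_p_from_r(0.91, 10)$p, 0.001)
  expect_equal(pearson_p_from_r(0.91, 10)$p, 2.5e-4, tolerance = 0.03)
  # p decreases monotonically in |r| at fixed n
  ps <- vapply(seq(0.05, 0.95, by = 0.05),
               function(r) pearson_p_from_r(r, 10)$p, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(pearson_r_p(rep(1, 5), 1:5), "zero variance")
  # agrees with cor.test as an independent path
  set.seed(9)
  a <- rnorm(12); b <- a + rnorm(12)
  ct <- cor.test(a, b)
  pr <- pearson_r_p(a, b)
  expect_equal(pr$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pr$p, ct$p.value, tolerance = 1e-12)
})

test_that("paired t reproduces hand computations and printed summaries", {
  expect_equal(paired_t(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(paired_t(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(round(p_from_t(-1.480, 9), 3), 0.173)
  h <- paired_t(c(2, 4, 6), c(1, 2, 3))       # diffs 1, 2, 3
  expect_equal(h$mean_diff, 2)
  expect_equal(h$se, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(h$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(h$df, 2)
  expect_equal(h$p, 0.0742, tolerance = 1e-3)
  expect_true(h$ci[1] < h$mean_diff && h$mean_diff < h$ci[2])
  # independent path: stats::t.test
  set.seed(10)
  a <- rnorm(9); b <- rnorm(9)
  tt <- t.test(a, b, paired = TRUE)
  p <- paired_t(a, b)
  expect_equal(p$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(p$p, tt$p.value, tolerance = 1e-12)
  expect_equal(p$ci, unname(as.numeric(tt$conf.int)), tolerance = 1e-12)
})

test_that("TOST combines two one-sided tests and matches the printed case", {
  # reconstruction from printed summaries: d = -0.002, SE = 0.002/1.480
  r <- tost(mean_diff = -0.002, se = 0.002 / 1.480, df = 9, delta = 0.005)
  expect_equal(round(r$p, 2), 0.03)
  expect_true(r$equivalent)
  # symmetric at zero difference
  r0 <- tost(mean_diff = 0, se = 0.001, df = 9, delta = 0.005)
  expect_equal(r0$p_lower, r0$p_upper)
  # decomposition oracle: overall p = max of the one-sided p's computed
  # directly from the t distribution
  set.seed(11)
  for (rep in 1:10) {
    d <- rnorm(1, 0, 0.003); se <- runif(1, 5e-4, 3e-3); df <- sample(4:20, 1)
    r <- tost(mean_diff = d, se = se, df = df, delta = 0.005)
    p1 <- pt((d + 0.005) / se, df, lower.tail = FALSE)
    p2 <- pt((d - 0.005) / se, df)
    expect_equal(r$p, max(p1, p2), tolerance = 1e-12)
    expect_true(r$ci[1] <= d && d <= r$ci[2])
  }
  # raw-data interface agrees with paired_t on shared quantities
  set.seed(12)
  a <- 0.1 + rnorm(8, 0, 0.004); b <- 0.1 + rnorm(8, 0, 0.004)
  rt <- tost(a, b); pt_ <- paired_t(a, b)
  expect_equal(rt$mean_diff, pt_$mean_diff)
  expect_equal(rt$se, pt_$se)
  expect_equal(rt$df, pt_$df)
  expect_error(tost(mean_diff = 0, se = 0, df = 9), "se > 0")
})

test_that("Bland-Altman bias, limits, and slope match the formulas", {
  ide <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ide$bias, 0); expect_equal(ide$loa, c(0, 0))
  co <- bland_altman(c(1.0, 2.0, 3.0), c(1.1, 2.1, 3.1))
  expect_equal(co$bias, -0.1)
  expect_equal(co$loa, c(-0.1, -0.1))
  expect_equal(co$slope, 0)
  # formula oracle on seeded pairs
  set.seed(13)
  x <- rnorm(10, 10, 1); y <- x + rnorm(10, 0.2, 0.3)
  ba <- bland_altman(x, y)
  d <- x - y; m <- (x + y) / 2
  expect_equal(ba$bias, sum(d) / 10, tolerance = 1e-12)
  sdd <- sqrt(sum((d - mean(d))^2) / 9)
  expect_equal(ba$loa, c(mean(d) - 1.96 * sdd, mean(d) + 1.96 * sdd),
               tolerance = 1e-12)
  sl <- sum((m - mean(m)) * (d - mean(d))) / sum((m - mean(m))^2)
  expect_equal(ba$slope, sl, tolerance = 1e-12)
  # bias identical to the paired-t mean difference
  expect_equal(ba$bias, paired_t(x, y)$mean_diff)
  # degenerate pair means
  dg <- bland_altman(c(1, 1, 1), c(1, 1, 1))
  expect_true(is.na(dg$slope_p) || dg$slope_p == 1)
})

test_that("required sample size follows the noncentral-t power curve", {
  expect_identical(required_sample_size(0.49, 0.90, 0.05), 46L)
  expect_identical(required_sample_size(0.49, 0.80, 0.05), 35L)
  # returned n reaches the power, n-1 does not
  for (case in list(c(0.49, 0.90), c(0.49, 0.80), c(0.8, 0.9))) {
    n <- required_sample_size(case[1], case[2])
    expect_gte(paired_t_power(n, case[1]), case[2])
    expect_lt(paired_t_power(n - 1, case[1]), case[2])
  }
  # monotone: non-increasing in d, non-decreasing in power
  ds <- c(0.2, 0.35, 0.5, 0.8, 1.2)
  ns <- vapply(ds, required_sample_size, integer(1), power = 0.9)
  expect_true(all(diff(ns) <= 0))
  for (d in ds)
    expect_lte(required_sample_size(d, 0.80), required_sample_size(d, 0.90))
  expect_error(required_sample_size(1e-4, 0.9, n_max = 300), "n_max")
  expect_error(required_sample_size(-1, 0.9), "positive")
})

test_that("cohort_report assembles COVs and agreement per ROI", {
  # two ROIs, 5 participants, constructed so global roi has known COVs
  set.seed(17)
  tab <- expand.grid(participant = 1:5, site = c("site1", "site2"),
                     roi = c("global_wm", "genu"), stringsAsFactors = FALSE)
  tab$mean_mwf <- 0.10 + 0.01 * (tab$participant - 3) +
    ifelse(tab$site == "site2", 0.002, 0) + rnorm(20, 0, 1e-4)
  rep_ <- cohort_report(tab)
  expect_setequal(rep_$cov_summary$roi, c("global_wm", "genu"))
  # per-row COV equals corrected_cov of the two site values
  r1 <- rep_$cov[1, ]
  expect_equal(r1$cov, corrected_cov(c(r1$mean_mwf_1, r1$mean_mwf_2)))
  # mean per ROI equals mean of per-participant COVs
  gw <- rep_$cov[rep_$cov$roi == "global_wm", ]
  expect_equal(rep_$cov_summary$mean_cov[rep_$cov_summary$roi == "global_wm"],
               mean(gw$cov))
  a <- rep_$agreement$global_wm
  expect_equal(a$bland_altman$bias, a$paired_t$mean_diff)
  # single participant, identical sites
  one <- data.frame(participant = 1, site = rep(c("site1", "site2")),
                    roi = "global_wm", mean_mwf = c(0.1, 0.1))
  rep1 <- cohort_report(one)
  expect_equal(rep1$cov$cov, 0)
  expect_equal(rep1$agreement$global_wm$bland_altman$bias, 0)
  # unmatched participants are reported by id
  bad <- tab[-1, ]
  expect_error(cohort_report(bad), "unmatched.*1/global_wm")
})

test_that("smallest detectable difference is the CI half-width", {
  sdd <- smallest_detectable_difference(0.002 / 1.480, 9)
  expect_equal(sdd, qt(0.975, 9) * 0.002 / 1.480, tolerance = 1e-12)
  expect_equal(round(sdd, 3), 0.003)
})
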