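test_that("t2 grid is geometric with inclusive endpoints", {
  g <- make_t2_grid(0.015, 2.0, 40)
  expect_equal(g[1], 0.015)
  expect_equal(g[40], 2.0)
  expect_equal(g[2], 0.015 * (2 / 0.015)^(1 / 39), tolerance = 1e-12)
  # constant ratio to machine precision
  r <- g[-1] / g[-40]
  expect_lt(diff(range(r)), 1e-12)
  # geometric mean in the middle of a 3-point grid
  g3 <- make_t2_grid(0.02, 0.02 * 1.5^2, 3)
  expect_equal(g3[2], 0.02 * 1.5, tolerance = 1e-14)
  expect_error(make_t2_grid(0.1, 0.1), "t2_min")
  expect_error(make_t2_grid(0.015, 2, 1), "n >= 2")
})

test_that("decay basis columns are the EPG curves of the grid", {
  B <- decay_basis(fx_grid, 143.7, fx_train)
  expect_equal(dim(B), c(32L, 40L))
  expect_true(all(B >= 0 & B <= 1))
  for (j in c(1, 17, 40))
    expect_equal(B[, j],
                 suppressWarnings(
                   epg_echo_amplitudes(fx_grid[j], 1, 143.7, fx_train)),
                 tolerance = 1e-12)
})

test_that("flip-angle estimation inverts forward-simulated curves", {
  # exact candidate with zero residual (boundary)
  est <- estimate_flip_angle(fx_wm_curve(0.2, 180), fx_grid, fx_train,
                             fx_cfg, fx_bases)
  expect_equal(as.numeric(est), 180)
  # interior candidate angle (7th of 8): 161.4286
  a7 <- fx_cfg$candidate_angles[7]
  est7 <- estimate_flip_angle(fx_wm_curve(0.2, a7), fx_grid, fx_train,
                              fx_cfg, fx_bases)
  expect_lt(abs(as.numeric(est7) - a7), 0.5)
  # between candidates
  est130 <- estimate_flip_angle(fx_wm_curve(0.2, 130), fx_grid, fx_train,
                                fx_cfg, fx_bases)
  expect_lt(abs(as.numeric(est130) - 130), 2)
  expect_true(is.na(estimate_flip_angle(numeric(32), fx_grid, fx_train,
                                        fx_cfg, fx_bases)))
})

test_that("noiseless curves take the unregularized path and reproduce pools", {
  curve <- fx_wm_curve(0.3, 180)
  B <- decay_basis(fx_grid, 180, fx_train)
  reg <- regularized_nnls(curve, B, fx_cfg)
  expect_identical(reg$mu, 0)
  expect_equal(reg$distribution, as.numeric(nnls_solve(B, curve)),
               tolerance = 1e-12)
  x <- reg$distribution / sum(reg$distribution)
  expect_equal(x[4], 0.3, tolerance = 1e-6)
  expect_equal(x[13], 0.7, tolerance = 1e-6)
})

test_that("regularization hits the chi-square inflation band on noisy data", {
  set.seed(21)
  for (rep in 1:5) {
    curve <- fx_wm_curve(0.15, 160)
    curve <- curve + rnorm(32, 0, curve[1] / 100)   # SNR 100
    B <- decay_basis(fx_grid, 160, fx_train)
    reg <- regularized_nnls(curve, B, fx_cfg)
    ratio <- reg$chi2_reg / reg$chi2_min
    expect_gte(ratio, fx_cfg$reg_lo)
    expect_lte(ratio, fx_cfg$reg_hi)
    expect_gte(reg$chi2_reg, reg$chi2_min)
  }
})

test_that("misfit chi-square is non-decreasing in the penalty weight", {
  set.seed(22)
  curve <- fx_wm_curve(0.15, 150)
  curve <- curve + rnorm(32, 0, curve[1] / 200)
  B <- decay_basis(fx_grid, 150, fx_train)
  b_aug <- c(curve, numeric(40))
  chi2 <- vapply(10^seq(-8, 0, by = 1), function(mu) {
    x <- nnls_solve(rbind(B, sqrt(mu) * diag(40)), b_aug)
    sum((curve - B %*% x)^2)
  }, numeric(1))
  expect_true(all(diff(chi2) >= -1e-12))
})

test_that("compute_mwf is the inclusive windowed fraction", {
  d <- numeric(40)
  d[which.min(abs(fx_grid - 0.020))] <- 5      # fully inside window
  expect_equal(compute_mwf(d, fx_grid), 1.0)
  d2 <- numeric(40); d2[4] <- 0.3; d2[13] <- 0.7
  expect_equal(compute_mwf(d2, fx_grid), 0.3)
  # window endpoints inclusive: grid[1] = 0.015 is in by definition
  d3 <- numeric(40); d3[1] <- 1
  expect_equal(compute_mwf(d3, fx_grid), 1.0)
  expect_true(is.na(compute_mwf(numeric(40), fx_grid)))
  expect_error(compute_mwf(d, fx_grid, c(0.001, 0.04)), "window")
  # windowed + complementary fractions sum to one exactly
  set.seed(3)
  for (rep in 1:20) {
    d <- runif(40)
    inw <- compute_mwf(d, fx_grid, c(0.015, 0.040))
    out <- sum(d[fx_grid > 0.040]) / sum(d)
    expect_equal(inw + out, 1.0)
  }
})

test_that("fit_voxel recovers noiseless two-pool voxels", {
  f <- fit_voxel(fx_wm_curve(0.2, 180), fx_grid, fx_train, fx_cfg, fx_bases)
  expect_lt(abs(f$mwf - 0.2), 0.005)
  f140 <- fit_voxel(fx_wm_curve(0.2, 140), fx_grid, fx_train, fx_cfg,
                    fx_bases)
  expect_lt(abs(f140$mwf - 0.2), 0.01)
  expect_lt(abs(f140$angle - 140), 2)
  expect_gte(f140$chi2_reg, f140$chi2_min)
  # pure CSF voxel: all amplitude at long T2
  csf <- suppressWarnings(epg_echo_amplitudes(2.0, 1.0, 180, fx_train))
  fcsf <- fit_voxel(csf, fx_grid, fx_train, fx_cfg, fx_bases)
  expect_equal(fcsf$mwf, 0, tolerance = 1e-6)
  # all-zero curve is flagged undefined
  f0 <- fit_voxel(numeric(32), fx_grid, fx_train, fx_cfg, fx_bases)
  expect_true(is.na(f0$mwf) && is.na(f0$angle))
})

test_that("MWF and estimated angle are scale invariant", {
  set.seed(31)
  curve <- fx_wm_curve(0.12, 155)
  curve <- curve + rnorm(32, 0, curve[1] / 150)
  f1 <- fit_voxel(curve, fx_grid, fx_train, fx_cfg, fx_bases)
  for (c_scale in c(0.25, 7)) {
    f2 <- fit_voxel(c_scale * curve, fx_grid, fx_train, fx_cfg, fx_bases)
    expect_equal(f2$mwf, f1$mwf, tolerance = 1e-6)
    expect_equal(f2$angle, f1$angle, tolerance = 1e-9)
    expect_equal(sum(f2$distribution), c_scale * sum(f1$distribution),
                 tolerance = 1e-4)
  }
})

test_that("fit_volume reduces to fit_voxel and is order independent", {
  set.seed(41)
  vol <- array(0, c(2, 2, 1, 32))
  for (i in 1:2) for (j in 1:2) {
    cv <- fx_wm_curve(0.05 * (i + j), 100 + 20 * i + 5 * j)
    vol[i, j, 1, ] <- cv + rnorm(32, 0, cv[1] / 300)
  }
  mask1 <- array(0, c(2, 2, 1)); mask1[2, 1, 1] <- 1
  maps1 <- fit_volume(vol, mask1, fx_grid, fx_train, fx_cfg)
  fv <- fit_voxel(vol[2, 1, 1, ], fx_grid, fx_train, fx_cfg)
  expect_equal(maps1$mwf[2, 1, 1], fv$mwf, tolerance = 1e-12)
  expect_equal(maps1$angle[2, 1, 1], fv$angle, tolerance = 1e-12)
  expect_true(all(is.na(maps1$mwf[mask1 == 0])))
  # full mask: every voxel equals its independent single-voxel fit
  maps <- fit_volume(vol, array(1, c(2, 2, 1)), fx_grid, fx_train, fx_cfg)
  for (i in 1:2) for (j in 1:2)
    expect_equal(maps$mwf[i, j, 1],
                 fit_voxel(vol[i, j, 1, ], fx_grid, fx_train, fx_cfg)$mwf,
                 tolerance = 1e-12)
  expect_error(fit_volume(vol, array(1, c(3, 2, 1))), "mask")
  expect_error(fit_volume(vol[, , , 1:10], array(1, c(2, 2, 1))), "4D")
})
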