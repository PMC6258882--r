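test_that("single-compartment phantom reduces to the forward model", {
  spec <- phantom_spec(shape = c(2, 2, 1), wm_mwf = 0, ie_t2 = 0.1,
                       b1_center = 180, b1_amplitude = 0, snr = Inf)
  ph <- generate_phantom(spec)
  expect_equal(ph$volume[1, 1, 1, ],
               exp(-echo_times(echo_train()) / 0.1), tolerance = 1e-10)
  expect_true(all(ph$truth$mwf == 0))
})

test_that("phantom generation is deterministic and truth matches the window", {
  spec <- phantom_spec(shape = c(4, 3, 2), wm_mwf = 0.12, csf_frac = 0.25)
  ph1 <- generate_phantom(spec)
  ph2 <- generate_phantom(spec)
  expect_identical(ph1$volume, ph2$volume)
  # ground truth equals the fraction of compartments inside the window
  expect_true(all(ph1$truth$mwf[ph1$truth$regions == 1L] == 0.12))
  expect_true(all(ph1$truth$mwf[ph1$truth$regions == 2L] == 0))
  expect_equal(sum(ph1$truth$regions == 2L), 1 * 3 * 2)  # CSF slab
  # flip-angle field is within physical bounds and smooth
  expect_true(all(ph1$truth$angle > 0 & ph1$truth$angle <= 180))
})

test_that("noise injection is calibrated, seeded, and vanishes at high SNR", {
  vol <- array(1, c(25, 20, 10, 20))            # 1e5 voxels x 20 echoes
  noisy <- add_noise(vol, snr = 100, seed = 5)
  expect_equal(sd(noisy - vol), 1 / 100, tolerance = 0.02)
  expect_lt(abs(mean(noisy - vol)), 1e-3)
  expect_identical(noisy, add_noise(vol, snr = 100, seed = 5))
  expect_false(identical(noisy, add_noise(vol, snr = 100, seed = 6)))
  # snr -> Inf limits
  expect_lt(max(abs(add_noise(vol, snr = 1e12, seed = 1) - vol)), 1e-6)
  expect_identical(add_noise(vol, snr = Inf, seed = 1), vol)
  # rician magnitude noise matches gaussian at high SNR
  ric <- add_noise(vol, snr = 200, seed = 7, type = "rician")
  expect_equal(sd(ric - vol), 1 / 200, tolerance = 0.05)
})

test_that("noiseless white-matter voxel round-trips through the fit", {
  spec <- phantom_spec(shape = c(1, 1, 1), wm_mwf = 0.10, b1_center = 180,
                       b1_amplitude = 0, snr = Inf)
  ph <- generate_phantom(spec)
  f <- fit_voxel(ph$volume[1, 1, 1, ], fx_grid, fx_train, fx_cfg, fx_bases)
  expect_lt(abs(f$mwf - 0.10), 0.01)
})

test_that("two-site study is reproducible and respects its seed rule", {
  s1 <- generate_two_site_study(2, shape = c(2, 2, 1), seed = 9)
  s2 <- generate_two_site_study(2, shape = c(2, 2, 1), seed = 9)
  expect_identical(s1$records[[3]]$volume, s2$records[[3]]$volume)
  s3 <- generate_two_site_study(2, shape = c(2, 2, 1), seed = 10)
  expect_false(identical(s1$records[[1]]$volume, s3$records[[1]]$volume))
  # same participant truth at both sites; different noise
  expect_identical(s1$records[[1]]$truth$mwf, s1$records[[2]]$truth$mwf)
  expect_false(identical(s1$records[[1]]$volume, s1$records[[2]]$volume))
  # compartment fractions normalized: first-echo noiseless signal <= 1
  spec <- phantom_spec(shape = c(2, 2, 1), snr = Inf)
  expect_true(all(generate_phantom(spec)$volume <= 1))
})

test_that("swapping site labels flips the Bland-Altman bias sign", {
  set.seed(12)
  x <- 0.1 + rnorm(8, 0, 0.005); y <- 0.1 + rnorm(8, 0, 0.005)
  ba <- bland_altman(x, y); ba_sw <- bland_altman(y, x)
  expect_equal(ba_sw$bias, -ba$bias)
  expect_equal(abs(ba_sw$loa), rev(abs(ba$loa)))
})
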