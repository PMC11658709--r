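test_that("autocorrelograms of pure harmonics match their closed forms", {
  ## traveling: A(dPhi, dt) = cos(dPhi - omega dt)
  k <- harmonic_kymo("traveling", period = 100, n_t = 400, m = 60)
  ac <- autocorrelogram(k)
  expect_equal(ac$A[which(ac$lags_t == 0), 1], 1, tolerance = 1e-12)
  om <- 2 * pi / 100
  sel <- abs(ac$lags_t) <= 50
  pred <- outer(ac$lags_t[sel], ac$dphi, function(dt, dp) cos(dp - om * dt))
  expect_lt(max(abs(ac$A[sel, ] - pred)), 1e-10)
  ## standing: A = cos(dPhi) cos(omega dt); A(0, T/2) = -1
  ks <- harmonic_kymo("standing", period = 100, n_t = 400, m = 60)
  acs <- autocorrelogram(ks)
  sel <- abs(acs$lags_t) <= 50
  preds <- outer(acs$lags_t[sel], acs$dphi,
                 function(dt, dp) cos(dp) * cos(om * dt))
  expect_lt(max(abs(acs$A[sel, ] - preds)), 0.05)
  expect_lt(acs$A[which(acs$lags_t == 50), 1], -0.9)
  ## invariance under affine intensity changes
  k2 <- kymograph(3 * k$I + 17, times = k$times, phi = k$phi)
  ac2 <- autocorrelogram(k2)
  expect_equal(ac2$A, ac$A, tolerance = 1e-10)
  expect_error(autocorrelogram(kymograph(matrix(5, 10, 10))), "degenerate")
})

test_that("matrix Pearson correlation behaves as corr2", {
  k <- harmonic_kymo("traveling", n_t = 200, m = 60)
  neg <- kymograph(-k$I, times = k$times, phi = k$phi)
  expect_equal(pearson_full(k, k), 1)
  expect_equal(pearson_full(k, neg), -1)
  expect_equal(pearson_full(k, neg), pearson_full(neg, k))
  ## sampling null: independent white-noise pairs decorrelate
  set.seed(8)
  a <- kymograph(matrix(rnorm(12000), 120, 100))
  b <- kymograph(matrix(rnorm(12000), 120, 100))
  expect_lt(abs(pearson_full(a, b, window = 120)), 0.03)
  expect_error(pearson_full(a, kymograph(matrix(1, 120, 100))),
               "zero-variance")
  expect_error(pearson_full(a, kymograph(matrix(rnorm(200), 20, 10))),
               "co-registered")
})

test_that("sliding correlation tracks a constructed phase flip", {
  k1 <- harmonic_kymo("traveling", period = 60, n_t = 300, m = 40)
  anti <- kymograph(200 - k1$I, times = k1$times, phi = k1$phi)
  ## identical channels: r = 1 throughout; anti-phase: r = -1 throughout
  expect_true(all(sliding_pearson(k1, k1, window = 10)$r > 0.999))
  expect_true(all(sliding_pearson(k1, anti, window = 10)$r < -0.999))
  ## channel 2 flips from in-phase to anti-phase at frame 150
  I2 <- rbind(k1$I[1:150, ], 200 - k1$I[151:300, ])
  k2 <- kymograph(I2, times = k1$times, phi = k1$phi)
  r <- sliding_pearson(k1, k2, window = 10)
  sign_flip <- r$t[which(r$r < 0)[1]]
  expect_lt(abs(sign_flip - 150), 11)
  expect_error(sliding_pearson(k1, k2, window = 1e5), "window longer")
})

test_that("PCA alignment recovers period and phases of a clean wave pair", {
  sp <- synthetic_spec("traveling", period = 190, snr_db = Inf,
                       n_t = 400, m = 100)
  pr <- generate_pair(sp)
  al <- pca_align(pr$ch1, pr$ch2)
  expect_equal(al$T, 190, tolerance = 0.02)
  ## the first two components dominate a clean traveling pair
  expect_gt(sum(al$var_frac[1:2]), 0.5)
  ## phases cover the circle nearly uniformly for a mode-1 traveling wave
  expect_gt(diff(range(al$phase)), 5)
  ## aligned columns re-projected on the axes concentrate at one angle
  z <- mean(exp(1i * al$phase_aligned))
  spread <- sqrt(-2 * log(Mod(z)))   # circular standard deviation
  expect_lt(spread, 0.1)
  ## period agrees with the autocorrelogram recurrence within 5%
  expect_equal(al$T, estimate_period(pr$ch1), tolerance = 0.05)
})

test_that("phase portraits orient by the signed trajectory area", {
  t <- seq(0, 2 * pi, length.out = 201)[-201]
  expect_equal(phase_portrait(cos(t), sin(t))$orientation,
               "counterclockwise")
  expect_equal(phase_portrait(sin(t), cos(t))$orientation, "clockwise")
  expect_warning(phase_portrait(cos(t[1:120]), sin(t[1:120])),
                 "does not close")
})

test_that("spatial PSD has the white-noise and stop-band signatures", {
  set.seed(2)
  k <- kymograph(matrix(abs(rnorm(200 * 100, 100, 10)), 200, 100))
  ps <- psd_noise(k)
  ## flat above twice the cutoff
  band <- ps$freq > 0.3
  expect_lt(max(ps$psd[band]) / min(ps$psd[band]), 3)
  ## harmonic far below the cutoff is suppressed below 1% in power
  I2 <- 100 + 40 * outer(rep(1, 50), cos(2 * pi * (0:99) / 100))
  ps2 <- psd_noise(kymograph(I2))
  inpow <- mean(apply(sqrt(I2), 1, var))
  outpow <- sum(ps2$psd) * (ps2$freq[2] - ps2$freq[1])
  expect_lt(outpow / inpow, 0.01)
  ## Parseval: integrated PSD equals the filtered signal's mean power
  got <- sum(ps$psd) * (ps$freq[2] - ps$freq[1])
  want <- mean(apply(ps$filtered, 1, function(r) mean(r^2)))
  expect_equal(got, want, tolerance = 0.01)
  ## both frequency scales are reported
  expect_equal(ps$freq_um, ps$freq * 100 / (2 * pi))
  expect_error(psd_noise(kymograph(matrix(-1, 10, 10))), "non-negative")
  expect_error(psd_noise(kymograph(matrix(1, 10, 4))), "8 spatial")
})
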