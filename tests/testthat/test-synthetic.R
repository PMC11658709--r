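test_that("generation is deterministic and respects its contracts", {
  sp <- synthetic_spec("standing", period = 140, snr_db = 20, seed = 7,
                       jitter = 0.3)
  a <- generate_pair(sp)
  b <- generate_pair(sp)
  expect_identical(a$ch1$I, b$ch1$I)
  expect_identical(a$ch2$I, b$ch2$I)
  ## Nyquist guard and positivity guard
  expect_error(synthetic_spec("traveling", period = 1.5,
                              frame_interval = 1), "Nyquist")
  expect_error(synthetic_spec(baseline = 10, amplitude = 20),
               "baseline > amplitude")
})

test_that("anti-phase construction yields perfect anti-correlation", {
  sp <- synthetic_spec("traveling", period = 190, phase_offset = pi,
                       snr_db = Inf)
  pr <- generate_pair(sp)
  expect_equal(pearson_full(pr$ch1, pr$ch2, window = Inf), -1,
               tolerance = 1e-10)
  cl <- classify_pattern(pr$ch1)
  expect_equal(cl$class, "traveling")
  expect_equal(cl$mode_order, 1L)
})

test_that("noisy standing-wave pairs still yield the period by PCA", {
  sp <- synthetic_spec("standing", period = 140, snr_db = 20, seed = 7)
  pr <- generate_pair(sp)
  al <- pca_align(pr$ch1, pr$ch2)
  expect_equal(al$T, 140, tolerance = 0.05)
})

test_that("realized SNR matches the specification", {
  for (noise in c("gaussian", "poisson_like")) {
    sp <- synthetic_spec("traveling", snr_db = 20, noise = noise, seed = 3)
    pr <- generate_pair(sp)
    expect_equal(pr$truth$snr_db_realized, 20,
                 tolerance = 0.8)  # 20% in linear variance ~ 0.8 dB
  }
})

test_that("the analysis pipeline recovers seeded random specifications", {
  patterns <- c("traveling", "standing", "stationary", "homogeneous")
  ok <- 0
  total <- 0
  set.seed(99)
  for (i in 1:20) {
    pat <- patterns[(i %% 4) + 1]
    n <- sample(1:2, 1)
    Tper <- sample(c(120, 190, 240), 1)
    sp <- synthetic_spec(pat, mode_order = n, period = Tper,
                         snr_db = 25, n_t = 500, seed = 1000 + i)
    pr <- generate_pair(sp)
    cl <- classify_pattern(pr$ch1)
    good <- cl$class == pat &&
      (pat == "homogeneous" || cl$mode_order == n)
    if (good && pat %in% c("traveling", "standing")) {
      al <- pca_align(pr$ch1, pr$ch2)
      good <- abs(al$T - Tper) / Tper < 0.05
    }
    ok <- ok + good
    total <- total + 1
  }
  expect_gte(ok, 19)
})

test_that("simulation-derived channels behave like their source fields", {
  st <- make_initial_state(baseline, snr_db = 30, seed = 2)
  sim <- simulate1d(baseline, st, t_end = 2600, dt = 2)
  ch <- from_simulation(sim, snr_db = Inf)
  ## noise-free mapping preserves the simulation's own classification
  cl_sim <- classify_pattern(sim_kymograph(sim, "rho_R"),
                             discard_transient = 1500)
  cl_map <- classify_pattern(ch$ch1, discard_transient = 1500)
  expect_equal(cl_map$class, cl_sim$class)
  ## 20 dB noise leaves the correlation sign unchanged
  chn <- from_simulation(sim, snr_db = 20, seed = 5)
  r0 <- pearson_full(ch$ch1, ch$ch2, window = Inf)
  rn <- pearson_full(chn$ch1, chn$ch2, window = Inf)
  expect_equal(sign(rn), sign(r0))
  expect_error(from_simulation(sim, channel1 = "rho_x"), "not present")
})
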