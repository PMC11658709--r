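test_that("the ring Laplacian is the circulant second-difference operator", {
  L <- 40
  n <- 50
  M <- build_laplacian(L, n)
  h <- L / n
  ## constant in the kernel; symmetric; negative semi-definite
  expect_lt(max(abs(M %*% rep(3, n))), 1e-12)
  expect_equal(M, t(M))
  ev <- eigen(M, only.values = TRUE)$values
  expect_lt(max(ev), 1e-10)
  ## cos(2 pi x / L) is an eigenvector with the discrete eigenvalue
  x <- (seq_len(n) - 1) * h
  v <- cos(2 * pi * x / L)
  lam <- -(2 / h^2) * (1 - cos(2 * pi * h / L))
  expect_equal(as.vector(M %*% v), lam * v, tolerance = 1e-10)
  expect_error(build_laplacian(40, 2), "at least 3")
})

test_that("initial-state generation is exact, reproducible and calibrated", {
  ## no noise reproduces the steady state exactly
  st0 <- make_initial_state(baseline, snr_db = Inf, n_points = 50)
  s <- solve_homogeneous_steady_state(baseline)
  expect_equal(unique(st0$rho_R), s$rho_R)
  ## fixed seed gives bitwise identical draws
  a <- make_initial_state(baseline, snr_db = 30, seed = 11)
  b <- make_initial_state(baseline, snr_db = 30, seed = 11)
  expect_identical(a, b)
  ## totals are conserved exactly after clipping and renormalization
  expect_equal(unname(species_totals(a)),
               c(baseline$N_Rac1, baseline$N_GAP, baseline$N_DGAP1))
  ## 30 dB: per-field variance ~ 1e-3 * mean^2 (within sampling error)
  st <- make_initial_state(baseline, snr_db = 30, seed = 3)
  v <- var(st$rho_r) / mean(st$rho_r)^2
  expect_equal(v, 1e-3, tolerance = 0.2)
  expect_error(make_initial_state(baseline, snr_db = -Inf), "SNR")
})

test_that("a steady-state initial condition stays put", {
  st <- make_initial_state(baseline, snr_db = Inf)
  sim <- simulate1d(baseline, st, t_end = 50, dt = 5)
  rel <- abs(sim$fields$rho_R / sim$fields$rho_R[1, 1] - 1)
  expect_lt(max(rel), 1e-6)
})

test_that("simulated trajectories conserve every species total", {
  st <- make_initial_state(baseline, snr_db = 30, seed = 1)
  sim <- simulate1d(baseline, st, t_end = 400, dt = 4)
  expect_lt(max(conservation_drift(sim)), 1e-6)
  ## totals at any snapshot match the copy numbers
  tot <- species_totals(sim_state(sim))
  expect_equal(unname(tot),
               c(baseline$N_Rac1, baseline$N_GAP, baseline$N_DGAP1),
               tolerance = 1e-6)
})

test_that("synthetic kymographs are classified by their construction", {
  expect_equal(classify_pattern(harmonic_kymo("traveling"))$class,
               "traveling")
  expect_equal(classify_pattern(harmonic_kymo("traveling"))$mode_order, 1L)
  expect_equal(classify_pattern(harmonic_kymo("standing"))$class,
               "standing")
  const <- kymograph(matrix(7, 50, 40))
  cl <- classify_pattern(const)
  expect_equal(cl$class, "homogeneous")
  expect_equal(cl$mode_order, 0L)
  expect_error(classify_pattern(harmonic_kymo("traveling"),
                                discard_transient = 1e6),
               "too short")
})

test_that("windowed classification tracks a constructed direction reversal", {
  k1 <- harmonic_kymo("traveling", period = 80, n_t = 240, dir = 1)
  k2 <- harmonic_kymo("traveling", period = 80, n_t = 240, dir = -1)
  ## splice at frame 240: ridge slope flips sign
  I <- rbind(k1$I, k2$I)
  k <- kymograph(I)
  tr <- transition_run(k, window = 120, stride = 60)
  ## windows spanning the splice may mix directions; the rest travel
  expect_gt(mean(tr$windows$class == "traveling"), 0.7)
  expect_true("reversal" %in% tr$events$type)
  flip <- tr$events$time[tr$events$type == "reversal"][1]
  expect_lt(abs(flip - 240), 61)
  ## a clean traveling record has a single class and no events
  tr0 <- transition_run(k1, window = 120, stride = 60)
  expect_equal(unique(tr0$windows$class), "traveling")
  expect_equal(nrow(tr0$events), 0)
})

test_that("trajectories from different random inits reach the same limit cycle", {
  ## attractor probe at baseline: compare late-time orbits in the
  ## (rho_R, rho_RG) plane at one grid point for two seeds
  orbit <- function(seed) {
    st <- make_initial_state(baseline, snr_db = 25, seed = seed)
    sim <- simulate1d(baseline, st, t_end = 3000, dt = 2)
    i <- sim$times >= 2400
    cbind(sim$fields$rho_R[i, 1], sim$fields$rho_RG[i, 1])
  }
  o1 <- orbit(101)
  o2 <- orbit(202)
  ## one-sided Hausdorff distances, relative to the cycle diameter
  dmat <- function(a, b)
    max(apply(a, 1, function(p) min(sqrt((b[, 1] - p[1])^2 +
                                           (b[, 2] - p[2])^2))))
  diam <- sqrt(diff(range(o1[, 1]))^2 + diff(range(o1[, 2]))^2)
  expect_lt(max(dmat(o1, o2), dmat(o2, o1)) / diam, 0.05)
})

test_that("grid refinement leaves the oscillation period unchanged", {
  period_at <- function(n_points) {
    st <- make_initial_state(baseline, snr_db = 30, seed = 5,
                             n_points = n_points)
    sim <- simulate1d(baseline, st, t_end = 2600, dt = 2)
    estimate_period(sim_kymograph(sim, "rho_R"), discard_transient = 1500)
  }
  T100 <- period_at(100)
  T200 <- period_at(200)
  expect_lt(abs(T200 - T100) / T100, 0.02)
})
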