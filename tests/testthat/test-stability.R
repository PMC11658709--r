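test_that("the analytic Jacobian matches numerical differentiation", {
  skip_if_not_installed("pracma")
  s <- solve_homogeneous_steady_state(baseline)
  J <- rac_jacobian(baseline, s)
  x0 <- unlist(s[c("rho_r", "rho_R", "rho_g", "rho_RG",
                   "rho_d", "rho_D", "rho_RD")], use.names = FALSE)
  Jnum <- pracma::jacobian(function(x) racdyn:::point_rhs(x, baseline), x0)
  expect_lt(max(abs(J - Jnum)) / max(abs(J)), 1e-6)
})

test_that("conservation null vectors annihilate the Jacobian", {
  s <- solve_homogeneous_steady_state(baseline)
  J <- rac_jacobian(baseline, s)
  for (v in conservation_vectors())
    expect_lt(max(abs(v %*% J)), 1e-8)
})

test_that("the Jacobian vanishes when all rates vanish", {
  p <- rac_params(k1 = 0, k11 = 0, k12 = 0, k2 = 0, k3a = 0, k4 = 0,
                  k41 = 0, k42 = 0, k5 = 0, k6a = 0, k6b = 0)
  J <- rac_jacobian(p, list(rho_r = 10, rho_R = 5, rho_g = 3, rho_RG = 2,
                            rho_d = 4, rho_D = 1, rho_RD = 2))
  expect_true(all(J == 0))
})

test_that("three conservation eigenvalues vanish at zero wavenumber", {
  s <- solve_homogeneous_steady_state(baseline)
  J <- rac_jacobian(baseline, s)
  ev <- eigen(J, only.values = TRUE)$values
  expect_equal(sum(Mod(ev) < 1e-8), 3)
})

test_that("the baseline dispersion relation has a mode-1 oscillatory band", {
  d <- dispersion_relation(baseline, n_max = 10)
  expect_equal(d$classification, "hopf")
  m1 <- d$modes[d$modes$n == 1, ]
  expect_gt(m1$re_sigma, 0)
  expect_gt(abs(m1$im_sigma), 0)
  ## growth rates decay for strongly diffusive high-q modes
  expect_lt(d$modes$re_sigma[11], d$modes$re_sigma[2])
  ## the unstable band ends near q_m ~ 2 pi / 20 um
  qm <- marginal_wavenumber(baseline)
  expect_equal(qm, 2 * pi / 20, tolerance = 0.15)
})

test_that("diffusion is stabilizing: doubling D cannot increase q_m", {
  qm0 <- marginal_wavenumber(baseline)
  p2 <- vary_param(vary_param(vary_param(baseline, "Dr", 2), "Dg", 2),
                   "Dd", 2)
  expect_lte(marginal_wavenumber(p2), qm0 * (1 + 1e-8))
})

test_that("single-species accumulation has no unstable band", {
  p <- baseline_params()
  p$N_GAP <- 0
  p$N_DGAP1 <- 0
  expect_error(marginal_wavenumber(p), "no unstable band")
})

test_that("mode thresholds scale linearly in the mode order", {
  L1 <- min_length_for_mode(baseline, 1)
  L3 <- min_length_for_mode(baseline, 3)
  expect_equal(L3, 3 * L1)
})

test_that("wave speed is a finite positive magnitude at baseline", {
  ws <- wave_speed(baseline)
  expect_gt(ws$v, 0)
  expect_equal(ws$type, "oscillatory")
  expect_lt(abs(Re(ws$sigma)), 1e-7)
  ## v is |Im sigma| / q_m by definition
  expect_equal(ws$v, abs(Im(ws$sigma)) / ws$q_m)
})

test_that("sensitivity coefficients are step-consistent", {
  for (nm in c("k3a", "rho_Rmax", "Dg", "rho_Dtotal")) {
    s1 <- sensitivity(baseline, nm, rel_step = 0.01)$S
    s2 <- sensitivity(baseline, nm, rel_step = 0.005)$S
    expect_lt(abs(s1 - s2), 0.05)
  }
})

test_that("a coarse regime scan records failures as missing, not fatal", {
  p <- baseline_params()
  rg <- regime_diagram(p,
                       axis1 = list(name = "N_GAP", values = c(0, 1200)),
                       axis2 = list(name = "N_DGAP1", values = c(0, 1600)),
                       n_max = 5)
  expect_true(all(dim(rg$class) == c(2, 2)))
  expect_true(all(rg$class[!is.na(rg$class)] %in%
                  c("stable", "turing", "hopf", "turing-hopf")))
  f <- tempfile(fileext = ".tsv")
  write_regimes(rg, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), 4)
  unlink(f)
})
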