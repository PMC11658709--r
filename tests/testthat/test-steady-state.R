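test_that("conservation forces the trivial partitions", {
  ## no Rac1: all Rac1 pools empty, GAP and DGAP1 fully cytoplasmic
  p <- baseline_params()
  p$N_Rac1 <- 0
  s <- solve_homogeneous_steady_state(p)
  expect_equal(s$rho_R, 0)
  expect_equal(s$rho_r, 0)
  expect_equal(s$rho_RG, 0)
  expect_equal(s$rho_RD, 0)
  expect_equal(s$rho_g, p$N_GAP / p$L)
  ## DGAP1 keeps binding the membrane without Rac1 to release it, so it
  ## fills the membrane up to saturation; the remainder stays cytoplasmic
  expect_equal(s$rho_D, min(p$N_DGAP1 / p$L, p$rho_Dmax), tolerance = 1e-6)
  expect_equal(s$rho_d + s$rho_D, p$N_DGAP1 / p$L, tolerance = 1e-9)

  ## no return pathway: all Rac1 accumulates on the membrane
  p2 <- baseline_params()
  p2$N_GAP <- 0
  p2$N_DGAP1 <- 0
  s2 <- solve_homogeneous_steady_state(p2)
  expect_equal(s2$rho_R, 130, tolerance = 1e-8)
  expect_lt(s2$rho_r, 1e-8)
})

test_that("the baseline root satisfies all seven equations", {
  s <- solve_homogeneous_steady_state(baseline)
  expect_lt(s$residual, 1e-10)
  expect_true(all(unlist(s[c("rho_r", "rho_R", "rho_g", "rho_RG",
                             "rho_d", "rho_D", "rho_RD")]) >= 0))
  expect_lt(s$rho_R, baseline$rho_Rmax)
  expect_lt(s$rho_D, baseline$rho_Dmax)
})

test_that("a multi-start least-squares oracle finds the same unique root", {
  skip_if_not_installed("pracma")
  p <- baseline
  Rt <- p$N_Rac1 / p$L
  G <- p$N_GAP / p$L
  Dt <- p$N_DGAP1 / p$L
  fn <- function(x) {
    ## four balances + three conservation equations
    x <- abs(x)
    b <- racdyn:::point_rhs(x, p)
    c(b[1], b[3], b[5], b[7],
      sum(x[c(1, 2, 4, 7)]) - Rt, x[3] + x[4] - G, sum(x[5:7]) - Dt)
  }
  s <- solve_homogeneous_steady_state(p)
  ref <- unlist(s[c("rho_r", "rho_R", "rho_g", "rho_RG",
                    "rho_d", "rho_D", "rho_RD")], use.names = FALSE)
  set.seed(42)
  roots <- list()
  for (i in 1:50) {
    x0 <- runif(7, 0, c(Rt, Rt, G, G, Dt, min(Dt, p$rho_Dmax), Dt))
    sol <- tryCatch(
      suppressWarnings(pracma::fsolve(fn, x0, maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(sol) && max(abs(fn(sol$x))) < 1e-8)
      roots[[length(roots) + 1]] <- abs(sol$x)
  }
  expect_gt(length(roots), 10)
  for (r in roots)
    expect_lt(max(abs(r - ref)), 1e-6)
})

test_that("high-DGAP1 parameter sets still have a steady state", {
  ## total DGAP1 density above the membrane saturation value
  p <- baseline_params()
  p$N_Rac1 <- 5200
  p$N_GAP <- 960
  p$N_DGAP1 <- 2800
  s <- solve_homogeneous_steady_state(p)
  expect_lt(s$residual, 1e-10)
  expect_lt(s$rho_D, p$rho_Dmax)
})

test_that("the extensive steady state solves the eight-species system", {
  pE <- equivalence_params()
  sE <- solve_homogeneous_steady_state(pE, model = "extensive")
  expect_lt(sE$residual, 1e-10)
  expect_gt(sE$rho_m, 0)
  ## degenerate extensive constants reproduce the condensed root
  pE0 <- baseline_params(extensive = TRUE)
  pE0$k_minus1 <- 1e-12; pE0$k_act <- 1e6
  pE0$k_minus4 <- 0; pE0$k3b <- 0; pE0$k6c <- 0; pE0$k6d <- 0
  sFast <- solve_homogeneous_steady_state(pE0, model = "extensive")
  sC <- solve_homogeneous_steady_state(baseline_params())
  expect_equal(sFast$rho_R, sC$rho_R, tolerance = 1e-3)
})
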