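test_that("an empty system has zero reaction flux", {
  z <- rep(0, 10)
  st <- field_state(z, z, z, z, z, z, z, L = 40)
  d <- condensed_rhs(st, baseline)
  expect_true(all(vapply(d, function(v) all(v == 0), logical(1))))
  stE <- field_state(z, z, z, z, z, z, z, L = 40, rho_m = z)
  dE <- extensive_rhs(stE, baseline_params(extensive = TRUE))
  expect_true(all(vapply(dE, function(v) all(v == 0), logical(1))))
})

test_that("the GAP-binding term evaluates to its direct mass-action value", {
  ## only rho_R = 10 and rho_g = 30 nonzero: d rho_RG/dt = k2 * 10 * 30
  z <- rep(0, 5)
  st <- field_state(z, rep(10, 5), rep(30, 5), z, z, z, z, L = 40)
  d <- condensed_rhs(st, baseline)
  expect_equal(d$rho_RG, rep(0.22 * 10 * 30, 5))
  expect_equal(d$rho_g, rep(-66, 5))
})

test_that("the steady state annihilates the reaction terms", {
  s <- solve_homogeneous_steady_state(baseline)
  st <- uniform_state(steady_vec(s), baseline$L, 12)
  d <- condensed_rhs(st, baseline)
  expect_lt(max(abs(unlist(d))), 1e-9)
})

test_that("membrane activation/release terms match direct evaluation", {
  ## only rho_m = 5 nonzero with k_act = 1, k_minus1 = 0.85
  pE <- baseline_params(extensive = TRUE)
  z <- rep(0, 4)
  st <- field_state(z, z, z, z, z, z, z, L = 40, rho_m = rep(5, 4))
  d <- extensive_rhs(st, pE)
  expect_equal(d$rho_R, rep(5, 4))
  expect_equal(d$rho_r, rep(4.25, 4))
  expect_equal(d$rho_m, rep(-9.25, 4))
})

test_that("the extensive model degenerates to the condensed model", {
  ## with the extra pathways off and rho_m empty, every shared field except
  ## the lumped binding/activation step coincides, and the total membrane
  ## Rac1 production (rho_R + rho_m) matches the condensed rho_R term:
  ## the condensed model lumps binding and activation into one step
  pE <- baseline_params(extensive = TRUE)
  pE$k_minus1 <- 0; pE$k_act <- 0; pE$k_minus4 <- 0
  pE$k3b <- 0; pE$k6c <- 0; pE$k6d <- 0
  st <- random_state(n = 16, seed = 4)
  stE <- random_state(n = 16, seed = 4, extensive = TRUE)
  stE$rho_m <- rep(0, 16)
  dC <- condensed_rhs(st, baseline)
  dE <- extensive_rhs(stE, pE)
  for (nm in c("rho_r", "rho_g", "rho_RG", "rho_d", "rho_D", "rho_RD"))
    expect_equal(dE[[nm]], dC[[nm]], tolerance = 1e-14)
  expect_equal(dE$rho_R + dE$rho_m, dC$rho_R, tolerance = 1e-14)
  ## in the fast-activation limit the intermediate pool passes straight
  ## through and the models share their fixed point (checked in the
  ## steady-state tests)
})

test_that("reaction fluxes cancel within each conservation group", {
  vecs <- conservation_vectors()
  for (seed in 1:5) {
    st <- random_state(seed = seed)
    d <- condensed_rhs(st, baseline)
    dm <- do.call(cbind, d)
    for (v in vecs)
      expect_lt(max(abs(dm %*% v)), 1e-10)
  }
  ## extensive: rho_m joins the Rac1 group
  pE <- baseline_params(extensive = TRUE)
  stE <- random_state(seed = 9, extensive = TRUE)
  dE <- do.call(cbind, extensive_rhs(stE, pE))
  expect_lt(max(abs(dE %*% c(1, 1, 0, 1, 0, 0, 1, 1))), 1e-10)
  expect_lt(max(abs(dE %*% c(0, 0, 1, 1, 0, 0, 0, 0))), 1e-10)
  expect_lt(max(abs(dE %*% c(0, 0, 0, 0, 1, 1, 1, 0))), 1e-10)
})

test_that("no field turns negative under small explicit Euler steps", {
  for (seed in 1:8) {
    st <- random_state(n = 12, seed = seed)
    d <- condensed_rhs(st, baseline)
    dt <- 1e-4
    for (nm in names(d)) {
      new <- st[[nm]] + dt * d[[nm]]
      expect_true(all(new >= -1e-12),
                  info = sprintf("field %s, seed %d", nm, seed))
    }
  }
})

test_that("species totals count every pool of each protein", {
  n <- 20
  L <- 40
  ## homogeneous cytoplasmic Rac1 only
  st <- uniform_state(list(rho_r = 5200 / L, rho_R = 0, rho_g = 0,
                           rho_RG = 0, rho_d = 0, rho_D = 0, rho_RD = 0),
                      L, n)
  expect_equal(unname(species_totals(st)), c(5200, 0, 0))
  z <- rep(0, n)
  expect_equal(unname(species_totals(field_state(z, z, z, z, z, z, z, L))),
               c(0, 0, 0))
  ## complexes contribute to two groups at once
  st2 <- uniform_state(list(rho_r = 1, rho_R = 2, rho_g = 3, rho_RG = 4,
                            rho_d = 5, rho_D = 6, rho_RD = 7), L, n)
  expect_equal(unname(species_totals(st2)),
               c((1 + 2 + 4 + 7) * L, (3 + 4) * L, (5 + 6 + 7) * L))
})

test_that("shape and domain errors are reported", {
  expect_error(field_state(rep(1, 5), rep(1, 4), rep(1, 5), rep(1, 5),
                           rep(1, 5), rep(1, 5), rep(1, 5), L = 40),
               "same length")
  expect_error(field_state(rep(-1, 5), rep(1, 5), rep(1, 5), rep(1, 5),
                           rep(1, 5), rep(1, 5), rep(1, 5), L = 40),
               "non-negative")
  st <- random_state()
  expect_error(extensive_rhs(st, baseline), "extensive")
  stE <- random_state(extensive = TRUE)
  expect_error(condensed_rhs(stE, baseline), "7-field")
})
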