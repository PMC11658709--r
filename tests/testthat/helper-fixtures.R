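## shared fixtures: small states and kymographs built in code

baseline <- baseline_params()

## arbitrary strictly positive 7-field state on a small grid
random_state <- function(n = 16, L = 40, seed = 1, extensive = FALSE) {
  set.seed(seed)
  f <- function(lo, hi) runif(n, lo, hi)
  field_state(rho_r = f(0, 100), rho_R = f(0, 150), rho_g = f(0, 30),
              rho_RG = f(0, 25), rho_d = f(0, 30), rho_D = f(0, 30),
              rho_RD = f(0, 15), L = L,
              rho_m = if (extensive) f(0, 20))
}

## pure harmonic kymographs with unit angular grid
harmonic_kymo <- function(type = c("traveling", "standing"), n = 1,
                          period = 100, n_t = 300, m = 60,
                          baseline_I = 100, amp = 40, dir = 1) {
  type <- match.arg(type)
  tt <- seq_len(n_t) - 1
  phi <- 2 * pi * (seq_len(m) - 1) / m
  om <- 2 * pi / period
  I <- switch(type,
    traveling = baseline_I + amp *
      cos(n * outer(rep(1, n_t), phi) - dir * om * tt),
    standing = baseline_I + amp *
      outer(cos(om * tt), cos(n * phi)))
  kymograph(I, times = tt, phi = phi)
}

## per-group indicator vectors in the (r, R, g, RG, d, D, RD) ordering
conservation_vectors <- function() {
  list(Rac1 = c(1, 1, 0, 1, 0, 0, 1),
       GAP = c(0, 0, 1, 1, 0, 0, 0),
       DGAP1 = c(0, 0, 0, 0, 1, 1, 1))
}
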