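#' Polar grid for the disk model
#'
#' Segments a disk of radius R into n concentric rings of width h = R/n,
#' each split into m angular segments of width dphi = 2 pi / m. Radial
#' centers sit at r_i = (2i - 1) h / 2; segment areas are A_i = r_i h dphi;
#' ring boundaries carry lengths dl = r_{i +/- 1/2} dphi. The membrane is
#' the circle at radius R = n h.
#'
#' @param R disk radius (um).
#' @param n number of rings.
#' @param m number of angular segments.
#' @return An object of class `disk_grid`.
#' @export
disk_grid <- function(R = 6, n = 30, m = 100) {
  stopifnot(R > 0, n >= 2, m >= 4)
  h <- R / n
  dphi <- 2 * pi / m
  r <- (2 * seq_len(n) - 1) * h / 2
  structure(list(R = R, n = n, m = m, h = h, dphi = dphi,
                 r = r, r_in = r - h / 2, r_out = r + h / 2,
                 area = r * h * dphi,
                 phi = (2 * seq_len(m) - 1) * dphi / 2),
            class = "disk_grid")
}

#' @export
print.disk_grid <- function(x, ...) {
  cat(sprintf("disk grid: R = %g um, %d rings x %d angular segments (h = %.3g um)\n",
              x$R, x$n, x$m, x$h))
  invisible(x)
}

#' Discrete polar Laplacian in conservative flux form
#'
#' Applies D times the flux-form polar Laplacian to a field on the disk
#' grid: radial term (dl_in J_in - dl_out J_out)/A_i with
#' J = -D (rho_out - rho_in)/h, plus the angular second difference divided
#' by r_i^2 dphi^2. The inner boundary has zero flux through r = 0 by
#' construction; the outer flux is zero here (membrane exchange is added by
#' the integrator). Total mass sum(A_i rho_ij) is conserved exactly.
#'
#' @param field n x m matrix on the disk grid.
#' @param D diffusion coefficient (um^2/s).
#' @param grid a `disk_grid`.
#' @return n x m matrix of time-derivative contributions.
#' @export
polar_laplacian <- function(field, D, grid) {
  g <- grid
  n <- g$n
  m <- g$m
  up <- rbind(field[1, ], field[-n, , drop = FALSE])     # i - 1 (clamped)
  dn <- rbind(field[-1, , drop = FALSE], field[n, ])     # i + 1 (clamped)
  rad <- (matrix(g$r_out, n, m) * (dn - field) -
            matrix(g$r_in, n, m) * (field - up)) / (matrix(g$r, n, m) * g$h^2)
  ## boundary rows: no flux through r = 0 and through r = R
  rad[1, ] <- g$r_out[1] * (field[2, ] - field[1, ]) / (g$r[1] * g$h^2)
  rad[n, ] <- -g$r_in[n] * (field[n, ] - field[n - 1, ]) / (g$r[n] * g$h^2)
  jp <- c(2:m, 1)
  jm <- c(m, 1:(m - 1))
  ang <- (field[, jp, drop = FALSE] - 2 * field +
            field[, jm, drop = FALSE]) / matrix(g$r^2 * g$dphi^2, n, m)
  D * (rad + ang)
}

#' Convert a ring-model rate constant to its disk-model counterpart
#'
#' The membrane fluxes of the disk model use cytoplasmic densities per area
#' instead of per length, so the binding constants are rescaled by the
#' ratio of the reference densities: k' = k rho_1d / rho_2d, both evaluated
#' at the homogeneous reference state.
#'
#' @param k ring-model constant.
#' @param rho_1d reference cytoplasmic linear density (1/um).
#' @param rho_2d reference cytoplasmic boundary density (1/um^2).
#' @return The primed constant.
#' @export
convert_rates <- function(k, rho_1d, rho_2d) {
  if (rho_1d <= 0 || rho_2d <= 0)
    stop("reference densities must be positive", call. = FALSE)
  k * rho_1d / rho_2d
}

#' Parameters of the disk (cycle-i) model
#'
#' The two-dimensional model carries only the Rac1-GAP cycle: cytoplasmic
#' Rac1 and GAP diffuse on the disk; membrane-bound Rac1-GTP and the
#' Rac1-GAP complex live on the bounding circle. Membrane binding uses the
#' primed rate constants (see [convert_rates()]).
#'
#' `rac1_accounting` selects what the quoted N_Rac1 counts when solving the
#' reference uniform state: `"free"` counts cytoplasmic Rac1 plus
#' uncomplexed membrane Rac1-GTP (Rac1 sequestered in membrane Rac1-GAP
#' complexes comes on top), `"total"` counts every Rac1-containing pool.
#' Only the free-Rac1 reading reproduces the published traveling/standing
#' sequence at the published copy numbers; see the methods vignette.
#'
#' @param k1p,k11p,k12p primed Rac1 binding constants (um/s, um^2/s, um^2/s).
#' @param k2p primed GAP binding constant (um^2/s).
#' @param k3a complex dissociation rate (1/s).
#' @param rho_Rmax membrane saturation density (1/um).
#' @param Dr,Dg cytoplasmic diffusion coefficients (um^2/s).
#' @param R disk radius (um).
#' @param N_Rac1,N_GAP copy numbers.
#' @param rac1_accounting `"free"` or `"total"` (see above).
#' @return An object of class `rac_params2d`.
#' @export
rac_params2d <- function(k1p = 1.6e-2, k11p = 3.2e-3, k12p = 4.8e-3,
                         k2p = 2.5, k3a = 0.3, rho_Rmax = 200,
                         Dr = 30, Dg = 8, R = 6,
                         N_Rac1 = 7600, N_GAP = 2000,
                         rac1_accounting = c("free", "total")) {
  rac1_accounting <- match.arg(rac1_accounting)
  vals <- c(k1p = k1p, k11p = k11p, k12p = k12p, k2p = k2p, k3a = k3a,
            rho_Rmax = rho_Rmax, Dr = Dr, Dg = Dg, R = R,
            N_Rac1 = N_Rac1, N_GAP = N_GAP)
  if (any(vals < 0) || R <= 0)
    stop("2D parameters must be non-negative (R positive)", call. = FALSE)
  structure(c(as.list(vals), list(rac1_accounting = rac1_accounting)),
            class = "rac_params2d")
}

#' Homogeneous reference state of the disk model
#'
#' Uniform cytoplasmic densities (1/um^2) and membrane densities (1/um)
#' with zero net membrane flux per species, consistent with the copy
#' numbers under the selected Rac1 accounting.
#'
#' @param p2 a `rac_params2d`.
#' @return Named vector (rho_r, rho_g, rho_R, rho_RG) plus attribute
#'   `N_Rac1_total`, the all-pool Rac1 count.
#' @export
steady_state_2d <- function(p2) {
  A <- pi * p2$R^2
  P <- 2 * pi * p2$R
  part <- function(rR) {
    ## GAP: binding k2p rg rR balances release k3a rRG, with
    ## rg A + rRG P = N_GAP
    rRG <- p2$k2p * rR * p2$N_GAP / (p2$k3a * A + p2$k2p * rR * P)
    rg <- (p2$N_GAP - rRG * P) / A
    SR <- 1 - rR / p2$rho_Rmax
    rr <- p2$k3a * rRG /
      max(SR * (p2$k1p + p2$k11p * rR + p2$k12p * rRG), 1e-300)
    c(rr = rr, rg = rg, rR = rR, rRG = rRG)
  }
  resid <- function(rR) {
    s <- part(rR)
    tot <- s[["rr"]] * A + s[["rR"]] * P
    if (p2$rac1_accounting == "total") tot <- tot + s[["rRG"]] * P
    tot - p2$N_Rac1
  }
  rR <- stats::uniroot(resid, c(1e-9, p2$rho_Rmax * (1 - 1e-9)),
                       tol = 1e-13)$root
  s <- part(rR)
  attr(s, "N_Rac1_total") <- s[["rr"]] * A + (s[["rR"]] + s[["rRG"]]) * P
  s
}

#' Integrate the disk (cycle-i) model
#'
#' Stiff sparse-BDF integration of the coupled cytoplasm/membrane system:
#' n x m cytoplasmic Rac1 and GAP fields plus m membrane Rac1-GTP and
#' Rac1-GAP densities. The membrane exchange enters the outermost ring as
#' the radial flux J_{n+1/2} (binding minus k3a release for Rac1; complex
#' formation minus release for GAP), and the membrane ODEs are the same
#' fluxes split between the two membrane species, so every species total
#' (disk integral plus membrane line integral) is conserved exactly.
#'
#' @param p2 a `rac_params2d`.
#' @param grid a `disk_grid`.
#' @param init optional initial condition list with matrices `rho_r`,
#'   `rho_g` (n x m, 1/um^2) and vectors `rho_R`, `rho_RG` (m, 1/um);
#'   defaults to the uniform reference state.
#' @param t_end final time (s).
#' @param dt output cadence (s).
#' @param seed_amplitude when nonzero, a mode-1 perturbation of this
#'   relative amplitude is superposed on the membrane fields (phase-lagged
#'   on the complex, breaking mirror symmetry); when zero with
#'   `snr_db` finite, white noise is used instead.
#' @param snr_db noise level for the noise init (dB, Inf for none).
#' @param seed RNG seed for the noise init.
#' @param rtol,atol solver tolerances.
#' @return An object of class `rac_sim2d`: membrane kymographs (`rho_R`,
#'   `rho_RG` as `kymo` objects), final cytoplasm snapshots, times, grid,
#'   parameters and conservation diagnostics.
#' @export
simulate2d <- function(p2, grid = disk_grid(R = p2$R), init = NULL,
                       t_end = 12000, dt = 4, seed_amplitude = 0.4,
                       snr_db = 30, seed = NULL, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(p2, "rac_params2d"), inherits(grid, "disk_grid"))
  g <- grid
  n <- g$n
  m <- g$m
  ss <- NULL
  if (is.null(init)) {
    ss <- steady_state_2d(p2)
    rho_r <- matrix(ss[["rr"]], n, m)
    rho_g <- matrix(ss[["rg"]], n, m)
    rho_R <- rep(ss[["rR"]], m)
    rho_RG <- rep(ss[["rRG"]], m)
    if (seed_amplitude > 0) {
      rho_R <- pmax(rho_R + seed_amplitude * ss[["rR"]] * cos(g$phi), 1e-9)
      rho_RG <- pmax(rho_RG + 0.5 * seed_amplitude * ss[["rRG"]] *
                       cos(g$phi - pi / 3), 1e-9)
    } else if (is.finite(snr_db)) {
      if (!is.null(seed)) set.seed(seed)
      sdrel <- 1 / sqrt(10^(snr_db / 10))
      rho_r <- rho_r * (1 + matrix(stats::rnorm(n * m, 0, sdrel), n, m))
      rho_R <- pmax(rho_R * (1 + stats::rnorm(m, 0, sdrel)), 0)
      rho_RG <- pmax(rho_RG * (1 + stats::rnorm(m, 0, sdrel)), 0)
      rho_r <- pmax(rho_r, 0)
    }
    init <- list(rho_r = rho_r, rho_g = rho_g,
                 rho_R = rho_R, rho_RG = rho_RG)
  }
  nm <- n * m
  y0 <- c(as.vector(init$rho_r), as.vector(init$rho_g),
          init$rho_R, init$rho_RG)
  fac <- g$r_out[n] / (g$r[n] * g$h)
  rhs <- function(t, y, parms) {
    rr <- matrix(y[seq_len(nm)], n, m)
    rg <- matrix(y[nm + seq_len(nm)], n, m)
    rR <- y[2 * nm + seq_len(m)]
    rRG <- y[2 * nm + m + seq_len(m)]
    SR <- pmax(1 - rR / p2$rho_Rmax, 0)
    bind <- rr[n, ] * SR * (p2$k1p + p2$k11p * rR + p2$k12p * rRG)
    form <- p2$k2p * rg[n, ] * rR
    Jr <- bind - p2$k3a * rRG
    Jg <- form - p2$k3a * rRG
    drr <- polar_laplacian(rr, p2$Dr, g)
    drg <- polar_laplacian(rg, p2$Dg, g)
    drr[n, ] <- drr[n, ] - fac * Jr
    drg[n, ] <- drg[n, ] - fac * Jg
    list(c(as.vector(drr), as.vector(drg), bind - form,
           form - p2$k3a * rRG))
  }
  times <- seq(0, t_end, by = dt)
  out <- deSolve::ode(y0, times, rhs, NULL, method = "lsodes",
                      rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("2D integration failed at t = ", max(out[, 1]), call. = FALSE)
  dl <- g$r_out[n] * g$dphi       # membrane segment length
  totals <- function(row) {
    rr <- matrix(row[1 + seq_len(nm)], n, m)
    rg <- matrix(row[1 + nm + seq_len(nm)], n, m)
    rR <- row[1 + 2 * nm + seq_len(m)]
    rRG <- row[1 + 2 * nm + m + seq_len(m)]
    c(Rac1 = sum(rr * matrix(g$area, n, m)) + sum(rR + rRG) * dl,
      GAP = sum(rg * matrix(g$area, n, m)) + sum(rRG) * dl)
  }
  t0 <- totals(out[1, ])
  tN <- totals(out[nrow(out), ])
  drift <- abs(tN - t0) / t0
  if (max(drift) > 1e-4)
    stop("2D species totals drifted by more than 1e-4 relative",
         call. = FALSE)
  kR <- kymograph(out[, 1 + 2 * nm + seq_len(m), drop = FALSE],
                  times = out[, 1], phi = g$phi, channel = "rho_R")
  kRG <- kymograph(out[, 1 + 2 * nm + m + seq_len(m), drop = FALSE],
                   times = out[, 1], phi = g$phi, channel = "rho_RG")
  structure(list(membrane = list(rho_R = kR, rho_RG = kRG),
                 cytoplasm_final = list(
                   rho_r = matrix(out[nrow(out), 1 + seq_len(nm)], n, m),
                   rho_g = matrix(out[nrow(out), 1 + nm + seq_len(nm)], n, m)),
                 times = out[, 1], grid = g, params = p2,
                 conservation_drift = drift,
                 steady = ss),
            class = "rac_sim2d")
}

#' @export
print.rac_sim2d <- function(x, ...) {
  cat(sprintf("rac_sim2d: %d rings x %d segments, t = [%g, %g] s\n",
              x$grid$n, x$grid$m, min(x$times), max(x$times)))
  cat(sprintf("  conservation drift: Rac1 %.2g, GAP %.2g\n",
              x$conservation_drift[["Rac1"]],
              x$conservation_drift[["GAP"]]))
  invisible(x)
}
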