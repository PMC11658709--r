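#' Periodic second-difference operator on the ring
#'
#' Three-point circulant stencil for the 1D Laplacian on `n_points` uniform
#' grid points over a ring of perimeter `L` (spacing h = L/n_points), with
#' periodic wrap at both ends. The operator is symmetric, negative
#' semi-definite, and has zero row sums.
#'
#' @param L perimeter (um).
#' @param n_points grid size (>= 3).
#' @return An `n_points` x `n_points` matrix.
#' @export
build_laplacian <- function(L, n_points = 100) {
  if (n_points < 3) stop("n_points must be at least 3", call. = FALSE)
  h <- L / n_points
  M <- matrix(0, n_points, n_points)
  idx <- seq_len(n_points)
  M[cbind(idx, idx)] <- -2
  M[cbind(idx, c(2:n_points, 1))] <- 1
  M[cbind(idx, c(n_points, 1:(n_points - 1)))] <- 1
  M / h^2
}

## index-shift Laplacian application used inside the integrators
lap_apply <- function(u, ip, im, h2) (u[ip] - 2 * u + u[im]) / h2

#' Initial conditions for the ring simulations
#'
#' `"perturbed_steady"` adds white Gaussian noise to every field of the
#' homogeneous steady state at the given signal-to-noise ratio (the standard
#' deviation per field is mean/sqrt(10^(snr_db/10))); negative draws are
#' clipped to zero and each conservation group is rescaled so the copy
#' numbers are conserved exactly. `"seeded_pattern"` superposes a single
#' Fourier mode of relative amplitude `amplitude` on the membrane Rac1-GTP
#' field (mass drawn from the cytoplasmic pool) plus a phase-lagged
#' component of half that amplitude on the Rac1-GAP complex; the lag breaks
#' the mirror symmetry of the ring so rotating solutions are reachable.
#'
#' @param params a `rac_params` object.
#' @param mode `"perturbed_steady"` or `"seeded_pattern"`.
#' @param snr_db signal-to-noise ratio in dB (`Inf` returns the exact
#'   steady state).
#' @param seed RNG seed for reproducibility (`NULL` leaves the RNG alone).
#' @param n_points grid size.
#' @param model condensed or extensive.
#' @param mode_order Fourier mode for `"seeded_pattern"`.
#' @param amplitude relative seed amplitude for `"seeded_pattern"`.
#' @param phase_lag lag (rad) of the complex-field seed.
#' @return A `field_state`.
#' @export
make_initial_state <- function(params,
                               mode = c("perturbed_steady", "seeded_pattern"),
                               snr_db = 30, seed = NULL, n_points = 100,
                               model = c("condensed", "extensive"),
                               mode_order = 1, amplitude = 0.4,
                               phase_lag = pi / 3) {
  mode <- match.arg(mode)
  model <- match.arg(model)
  extensive <- model == "extensive"
  steady <- solve_homogeneous_steady_state(params, model = model)
  st <- uniform_state(steady_vec(steady), params$L, n_points)
  if (mode == "perturbed_steady") {
    if (identical(snr_db, Inf)) return(st)
    snr_lin <- 10^(snr_db / 10)
    if (!is.finite(snr_lin) || snr_lin <= 0)
      stop("unphysical SNR", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    for (nm in field_names(st)) {
      f <- st[[nm]]
      st[[nm]] <- pmax(f * (1 + stats::rnorm(n_points, 0, 1 / sqrt(snr_lin))),
                       0)
    }
    st <- renormalize_totals(st, params)
  } else {
    x <- st$x
    pert <- amplitude * steady$rho_R *
      cos(2 * pi * mode_order * x / params$L)
    st$rho_R <- pmax(st$rho_R + pert, 0)
    st$rho_r <- pmax(st$rho_r - pert, 0)
    pert2 <- 0.5 * amplitude * steady$rho_RG *
      cos(2 * pi * mode_order * x / params$L - phase_lag)
    st$rho_RG <- pmax(st$rho_RG + pert2, 0)
    st$rho_g <- pmax(st$rho_g - pert2, 0)
    st <- renormalize_totals(st, params)
  }
  st
}

## rescale each conservation group so species totals match the copy numbers
renormalize_totals <- function(st, params) {
  tot <- species_totals(st)
  targets <- c(params$N_Rac1, params$N_GAP, params$N_DGAP1)
  ## the complexes straddle two conservation groups; keep them fixed and
  ## rescale the single-group fields to absorb each group's mismatch
  fix_rac <- sum(st$rho_RG + st$rho_RD) * st$h
  free_rac <- tot[1] - fix_rac
  if (free_rac > 0) {
    f <- (targets[1] - fix_rac) / free_rac
    for (nm in c("rho_r", "rho_R", if (!is.null(st$rho_m)) "rho_m"))
      st[[nm]] <- st[[nm]] * f
  }
  fix_gap <- sum(st$rho_RG) * st$h
  free_gap <- tot[2] - fix_gap
  if (free_gap > 0) {
    st$rho_g <- st$rho_g * (targets[2] - fix_gap) / free_gap
  }
  fix_d <- sum(st$rho_RD) * st$h
  free_d <- tot[3] - fix_d
  if (free_d > 0) {
    f <- (targets[3] - fix_d) / free_d
    for (nm in c("rho_d", "rho_D")) st[[nm]] <- st[[nm]] * f
  }
  st
}

#' Integrate the reaction-diffusion system on the periodic ring
#'
#' Semi-discrete integration of the condensed (700 ODEs at the default
#' 100-point grid) or extensive (800 ODEs) model with the stiff sparse-BDF
#' solver (`deSolve::ode`, method `"lsodes"`), relative tolerance 1e-8 and
#' absolute tolerance 1e-10 by default. Output is sampled on a uniform time
#' grid. Species totals are checked against the initial totals; drift beyond
#' 1e-4 relative aborts. Small negative undershoots (above -1e-12) are
#' floored to zero in the returned kymographs; larger negatives abort.
#'
#' @param params a `rac_params` object.
#' @param init a `field_state` (see [make_initial_state()]).
#' @param t_end final time (s).
#' @param model condensed or extensive.
#' @param dt output cadence (s), default 1 s.
#' @param rtol,atol solver tolerances.
#' @return An object of class `rac_sim`: `times`, a named list `fields` of
#'   (time x space) kymograph matrices, `params`, `model`, grid metadata and
#'   solver diagnostics.
#' @export
simulate1d <- function(params, init, t_end, model = c("condensed", "extensive"),
                       dt = 1, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "rac_params"), inherits(init, "field_state"))
  model <- match.arg(model)
  extensive <- model == "extensive"
  if (extensive && is.null(init$rho_m))
    stop("extensive model needs an 8-field initial state", call. = FALSE)
  if (!extensive && !is.null(init$rho_m))
    stop("condensed model needs a 7-field initial state", call. = FALSE)
  n <- length(init$rho_r)
  h2 <- (params$L / n)^2
  ip <- c(2:n, 1)
  im <- c(n, 1:(n - 1))
  p <- params
  nf <- if (extensive) 8L else 7L
  rhs <- if (!extensive) {
    function(t, y, parms) {
      m <- matrix(y, nrow = n)
      rr <- m[, 1]; rR <- m[, 2]; rg <- m[, 3]; rRG <- m[, 4]
      rd <- m[, 5]; rD <- m[, 6]; rRD <- m[, 7]
      SR <- pmax(1 - rR / p$rho_Rmax, 0)
      SD <- pmax(1 - rD / p$rho_Dmax, 0)
      K1 <- p$k1 + p$k11 * rR + p$k12 * rRG
      K4 <- p$k4 + p$k41 * rR + p$k42 * rRG
      bR <- rr * SR * K1
      bD <- rd * SD * K4
      fRG <- p$k2 * rR * rg
      fRD <- p$k5 * rR * rD
      list(c(p$Dr * lap_apply(rr, ip, im, h2) + p$k3a * rRG - bR + p$k6b * rRD,
             p$k6a * rRD - fRG - fRD + bR,
             p$Dg * lap_apply(rg, ip, im, h2) + p$k3a * rRG - fRG,
             fRG - p$k3a * rRG,
             p$Dd * lap_apply(rd, ip, im, h2) - bD + (p$k6a + p$k6b) * rRD,
             bD - fRD,
             fRD - (p$k6a + p$k6b) * rRD))
    }
  } else {
    k6s <- p$k6a + p$k6b + p$k6c + p$k6d
    function(t, y, parms) {
      m <- matrix(y, nrow = n)
      rr <- m[, 1]; rR <- m[, 2]; rg <- m[, 3]; rRG <- m[, 4]
      rd <- m[, 5]; rD <- m[, 6]; rRD <- m[, 7]; rm <- m[, 8]
      SR <- pmax(1 - rR / p$rho_Rmax, 0)
      SD <- pmax(1 - rD / p$rho_Dmax, 0)
      K1 <- p$k1 + p$k11 * rR + p$k12 * rRG
      K4 <- p$k4 + p$k41 * rR + p$k42 * rRG
      bR <- rr * SR * K1
      bD <- rd * SD * K4
      fRG <- p$k2 * rR * rg
      fRD <- p$k5 * rR * rD
      list(c(p$Dr * lap_apply(rr, ip, im, h2) + p$k3a * rRG - bR +
               (p$k6b + p$k6d) * rRD + p$k_minus1 * rm,
             (p$k6a + p$k6c) * rRD + p$k_act * rm - fRG - fRD,
             p$Dg * lap_apply(rg, ip, im, h2) + (p$k3a + p$k3b) * rRG - fRG,
             fRG - (p$k3a + p$k3b) * rRG,
             p$Dd * lap_apply(rd, ip, im, h2) - bD + (p$k6a + p$k6b) * rRD +
               p$k_minus4 * rD,
             bD + (p$k6c + p$k6d) * rRD - fRD - p$k_minus4 * rD,
             fRD - k6s * rRD,
             bR + p$k3b * rRG - (p$k_act + p$k_minus1) * rm))
    }
  }
  y0 <- state_to_vec(init)
  times <- seq(0, t_end, by = dt)
  out <- deSolve::ode(y0, times, rhs, NULL, method = "lsodes",
                      rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("stiff integration failed at t = ", max(out[, 1]), call. = FALSE)
  y <- out[, -1, drop = FALSE]
  if (min(y) < -1e-12)
    stop("integration produced significantly negative densities (min ",
         format(min(y)), ")", call. = FALSE)
  y[y < 0] <- 0
  nm <- c("rho_r", "rho_R", "rho_g", "rho_RG", "rho_d", "rho_D", "rho_RD",
          if (extensive) "rho_m")
  fields <- lapply(seq_len(nf), function(k) {
    m <- y[, (k - 1) * n + seq_len(n), drop = FALSE]
    dimnames(m) <- NULL
    m
  })
  names(fields) <- nm
  sim <- structure(list(times = out[, 1], fields = fields, params = params,
                        model = model, n_points = n, L = params$L,
                        diagnostics = list(steps = attr(out, "istate")[3],
                                           rtol = rtol, atol = atol)),
                   class = "rac_sim")
  drift <- conservation_drift(sim)
  if (max(drift) > 1e-4)
    stop("species totals drifted by more than 1e-4 relative (max ",
         format(max(drift)), ")", call. = FALSE)
  sim
}

#' Relative conservation drift of a simulation
#'
#' Maximum over time of |N(t) - N(0)| / N(0) for each conservation group.
#'
#' @param sim a `rac_sim`.
#' @return Named numeric vector (Rac1, GAP, DGAP1).
#' @export
conservation_drift <- function(sim) {
  h <- sim$L / sim$n_points
  f <- sim$fields
  rac <- rowSums(f$rho_r + f$rho_R + f$rho_RG + f$rho_RD) * h
  if (!is.null(f$rho_m)) rac <- rac + rowSums(f$rho_m) * h
  gap <- rowSums(f$rho_g + f$rho_RG) * h
  dg <- rowSums(f$rho_d + f$rho_D + f$rho_RD) * h
  rel <- function(x) if (x[1] == 0) max(abs(x - x[1])) else
    max(abs(x - x[1]) / x[1])
  c(Rac1 = rel(rac), GAP = rel(gap), DGAP1 = rel(dg))
}

#' @export
print.rac_sim <- function(x, ...) {
  cat(sprintf("rac_sim (%s): %d fields, %d x %d (time x space), t = [%g, %g] s\n",
              x$model, length(x$fields), length(x$times), x$n_points,
              min(x$times), max(x$times)))
  cat(sprintf("  conservation drift: %.2g (max over species)\n",
              max(conservation_drift(x))))
  invisible(x)
}

#' Extract a field of a simulation as a kymograph object
#'
#' @param sim a `rac_sim` (or the membrane output of [simulate2d()]).
#' @param field field name (e.g. `"rho_R"`), or a list of fields to sum
#'   (e.g. `c("rho_D", "rho_RD")` for total membrane DGAP1).
#' @return A [kymograph()].
#' @export
sim_kymograph <- function(sim, field = "rho_R") {
  m <- Reduce(`+`, sim$fields[field])
  kymograph(m, times = sim$times,
            phi = 2 * pi * (seq_len(sim$n_points) - 1) / sim$n_points,
            channel = paste(field, collapse = "+"))
}

#' Final snapshot of a simulation as a field state
#'
#' @param sim a `rac_sim`.
#' @param i time index (default last).
#' @return A `field_state`.
#' @export
sim_state <- function(sim, i = length(sim$times)) {
  f <- lapply(sim$fields, function(m) m[i, ])
  field_state(rho_r = f$rho_r, rho_R = f$rho_R, rho_g = f$rho_g,
              rho_RG = f$rho_RG, rho_d = f$rho_d, rho_D = f$rho_D,
              rho_RD = f$rho_RD, L = sim$L, rho_m = f$rho_m)
}
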