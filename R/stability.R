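#' Jacobian of the condensed reaction terms at a steady state
#'
#' Analytic partial derivatives of the seven reaction terms with respect to
#' the seven densities, evaluated at a homogeneous state. Mass conservation
#' makes the left null space three-dimensional: the indicator vectors of the
#' Rac1, GAP and DGAP1 conservation groups annihilate the matrix from the
#' left.
#'
#' @param params a `rac_params` object.
#' @param steady a `rac_steady` from [solve_homogeneous_steady_state()] (or
#'   any named density list at which to linearize).
#' @return A 7x7 numeric matrix, rows/columns ordered
#'   (rho_r, rho_R, rho_g, rho_RG, rho_d, rho_D, rho_RD).
#' @export
rac_jacobian <- function(params, steady) {
  p <- params
  s <- as.list(steady)
  rr <- s$rho_r; rR <- s$rho_R; rg <- s$rho_g; rRG <- s$rho_RG
  rd <- s$rho_d; rD <- s$rho_D
  SR <- 1 - rR / p$rho_Rmax
  SD <- 1 - rD / p$rho_Dmax
  K1 <- p$k1 + p$k11 * rR + p$k12 * rRG
  K4 <- p$k4 + p$k41 * rR + p$k42 * rRG
  ## binding-term partials: B = rho_r * SR * K1, W = rho_d * SD * K4
  dB_dr <- SR * K1
  dB_dR <- rr * (-K1 / p$rho_Rmax + SR * p$k11)
  dB_dRG <- rr * SR * p$k12
  dW_dd <- SD * K4
  dW_dD <- -rd * K4 / p$rho_Dmax
  dW_dR <- rd * SD * p$k41
  dW_dRG <- rd * SD * p$k42
  nm <- c("rho_r", "rho_R", "rho_g", "rho_RG", "rho_d", "rho_D", "rho_RD")
  J <- matrix(0, 7, 7, dimnames = list(nm, nm))
  J[1, ] <- c(-dB_dr, -dB_dR, 0, p$k3a - dB_dRG, 0, 0, p$k6b)
  J[2, ] <- c(dB_dr, dB_dR - p$k2 * rg - p$k5 * rD, -p$k2 * rR, dB_dRG,
              0, -p$k5 * rR, p$k6a)
  J[3, ] <- c(0, -p$k2 * rg, -p$k2 * rR, p$k3a, 0, 0, 0)
  J[4, ] <- c(0, p$k2 * rg, p$k2 * rR, -p$k3a, 0, 0, 0)
  J[5, ] <- c(0, -dW_dR, 0, -dW_dRG, -dW_dd, -dW_dD, p$k6a + p$k6b)
  J[6, ] <- c(0, dW_dR - p$k5 * rD, 0, dW_dRG, dW_dd,
              dW_dD - p$k5 * rR, 0)
  J[7, ] <- c(0, p$k5 * rD, 0, 0, 0, p$k5 * rR, -(p$k6a + p$k6b))
  J
}

diffusion_matrix <- function(params, extensive = FALSE) {
  d <- c(params$Dr, 0, params$Dg, 0, params$Dd, 0, 0)
  if (extensive) d <- c(d, 0)
  diag(d)
}

## leading eigenvalue of J - q^2 D: maximum real part, ties by larger |Im|
leading_eigenvalue <- function(J, Dm, q, tol = 1e-9) {
  ev <- eigen(J - q^2 * Dm, only.values = TRUE)$values
  re <- Re(ev)
  top <- which(re > max(re) - tol)
  ev[top[which.max(abs(Im(ev[top])))]]
}

#' Dispersion relation over the discrete Fourier modes of the ring
#'
#' Computes the eigenvalue spectrum of M_q = J - q^2 D at each wavenumber
#' q = 2 pi n / L, n = 0 .. n_max, where D carries the cytoplasmic diffusion
#' coefficients (membrane species do not diffuse). A mode is unstable when
#' the leading real part exceeds the zero threshold; an unstable mode with
#' nonzero imaginary part is oscillatory (Hopf), otherwise stationary
#' (Turing). The three conservation-induced neutral eigenvalues at q = 0 are
#' not counted as instabilities. The overall label is `"turing-hopf"` when
#' both kinds occur across modes.
#'
#' @param params a `rac_params` object.
#' @param n_max highest Fourier mode (default 10).
#' @param steady optional precomputed steady state.
#' @param zero_tol threshold below which a real part or imaginary part is
#'   treated as zero (default 1e-9).
#' @return An object of class `rac_dispersion`: data frame of per-mode
#'   results (`n`, `q`, `re_sigma`, `im_sigma`, `class`), the full
#'   eigenvalue list, and the overall `classification` among
#'   `"stable"`, `"turing"`, `"hopf"`, `"turing-hopf"`.
#' @export
dispersion_relation <- function(params, n_max = 10, steady = NULL,
                                zero_tol = 1e-9) {
  stopifnot(inherits(params, "rac_params"))
  if (is.null(steady))
    steady <- solve_homogeneous_steady_state(params)
  J <- rac_jacobian(params, steady)
  Dm <- diffusion_matrix(params)
  modes <- 0:n_max
  qs <- 2 * pi * modes / params$L
  eig <- lapply(qs, function(q) eigen(J - q^2 * Dm, only.values = TRUE)$values)
  lead <- lapply(seq_along(qs), function(i) {
    ev <- eig[[i]]
    if (modes[i] == 0) {
      ## drop the three conservation zero modes before picking the leader
      ord <- order(Mod(ev))
      ev <- ev[-ord[1:3]]
    }
    re <- Re(ev)
    top <- which(re > max(re) - zero_tol)
    ev[top[which.max(abs(Im(ev[top])))]]
  })
  lead <- unlist(lead)
  cls <- ifelse(Re(lead) > zero_tol,
                ifelse(abs(Im(lead)) > zero_tol, "hopf", "turing"),
                "stable")
  overall <- if (any(cls == "turing") && any(cls == "hopf")) {
    "turing-hopf"
  } else if (any(cls == "turing")) {
    "turing"
  } else if (any(cls == "hopf")) {
    "hopf"
  } else {
    "stable"
  }
  structure(list(modes = data.frame(n = modes, q = qs,
                                    re_sigma = Re(lead),
                                    im_sigma = Im(lead),
                                    class = cls,
                                    stringsAsFactors = FALSE),
                 eigenvalues = eig,
                 classification = overall,
                 steady = steady,
                 params = params),
            class = "rac_dispersion")
}

#' @export
print.rac_dispersion <- function(x, ...) {
  cat("Dispersion relation:", x$classification, "\n")
  un <- x$modes[x$modes$class != "stable", ]
  if (nrow(un)) {
    cat("  unstable modes:\n")
    print(un, row.names = FALSE)
  } else {
    cat("  all modes stable\n")
  }
  invisible(x)
}

## leading growth rate on the continuum dispersion relation
continuum_growth <- function(J, Dm, q) Re(leading_eigenvalue(J, Dm, q))

#' Marginal wavenumber of the continuum dispersion relation
#'
#' Finds q_m where the leading growth rate Re sigma(q) crosses zero, with q
#' treated as a continuous variable. The unstable band of the model extends
#' over (0, q_m), so q_m is located by scanning for the sign change of the
#' leading real part and bisecting to relative precision 1e-8.
#'
#' @param params a `rac_params` object.
#' @param q_max upper end of the scan range (1/um).
#' @param steady optional precomputed steady state.
#' @return `q_m` (1/um).
#' @export
marginal_wavenumber <- function(params, q_max = 2, steady = NULL) {
  stopifnot(inherits(params, "rac_params"))
  if (is.null(steady))
    steady <- solve_homogeneous_steady_state(params)
  J <- rac_jacobian(params, steady)
  Dm <- diffusion_matrix(params)
  qs <- seq(q_max / 400, q_max, length.out = 400)
  re <- vapply(qs, function(q) continuum_growth(J, Dm, q), numeric(1))
  i <- which(re[-length(re)] > 0 & re[-1] < 0)
  if (!length(i))
    stop("no unstable band: Re sigma(q) does not change sign on (0, ",
         q_max, "]", call. = FALSE)
  i <- i[1]
  stats::uniroot(function(q) continuum_growth(J, Dm, q),
                 c(qs[i], qs[i + 1]), tol = 1e-8 * qs[i])$root
}

#' Traveling-wave speed from the marginally stable mode
#'
#' The growth ansatz matched to a traveling-wave ansatz gives
#' v = Im sigma(q_m) / q_m at the marginal wavenumber where
#' Re sigma(q_m) = 0. The eigenvalue branch is the one that crosses the zero
#' line: at q_m it is the leading eigenvalue; a nearest-neighbour continuity
#' check against a slightly smaller q guards against branch switching. The
#' spectrum at -q is the complex conjugate, so speeds come in +/- pairs and
#' the magnitude is reported.
#'
#' @param params a `rac_params` object.
#' @param q_max scan range for the marginal wavenumber.
#' @param steady optional precomputed steady state.
#' @return List with `v` (um/s), `q_m` (1/um) and `sigma` (the marginal
#'   eigenvalue). `v` = 0 with a `"stationary"` flag when the marginal mode
#'   is purely real.
#' @export
wave_speed <- function(params, q_max = 2, steady = NULL) {
  if (is.null(steady))
    steady <- solve_homogeneous_steady_state(params)
  qm <- marginal_wavenumber(params, q_max = q_max, steady = steady)
  J <- rac_jacobian(params, steady)
  Dm <- diffusion_matrix(params)
  sig <- leading_eigenvalue(J, Dm, qm)
  ## branch continuity: the crossing branch must connect to the leading
  ## eigenvalue just inside the unstable band
  sig_in <- leading_eigenvalue(J, Dm, qm * 0.999)
  ev <- eigen(J - qm^2 * Dm, only.values = TRUE)$values
  near <- ev[which.min(Mod(ev - sig_in))]
  if (Mod(near - sig) > 1e-6 * max(1, Mod(sig))) sig <- near
  if (abs(Im(sig)) < 1e-9) {
    list(v = 0, q_m = qm, sigma = sig, type = "stationary")
  } else {
    list(v = abs(Im(sig)) / qm, q_m = qm, sigma = sig, type = "oscillatory")
  }
}

#' Normalized sensitivity of the wave speed to one parameter
#'
#' One-sided finite-difference estimate of
#' S = (delta v / v0) / (delta p / p0), the relative change of the
#' marginal-mode traveling-wave speed per relative change in the parameter.
#' Saturation densities are varied with the intrinsic-constant rescaling of
#' [vary_param()]; totals are varied as linear densities (N with L fixed).
#'
#' @param params baseline `rac_params`.
#' @param name parameter name as accepted by [vary_param()].
#' @param rel_step relative perturbation (default +0.01).
#' @param q_max scan range for the marginal wavenumber.
#' @return An object of class `rac_sensitivity`: `S`, the baseline speed
#'   `v0`, the perturbed speed `v1`, `name` and `rel_step`.
#' @export
sensitivity <- function(params, name, rel_step = 0.01, q_max = 2) {
  v0 <- wave_speed(params, q_max = q_max)$v
  if (v0 == 0)
    stop("wave speed undefined at baseline (stationary marginal mode)",
         call. = FALSE)
  p1 <- vary_param(params, name, 1 + rel_step)
  v1 <- tryCatch(wave_speed(p1, q_max = q_max)$v,
                 error = function(e)
                   stop("wave speed undefined after perturbing '", name,
                        "'; try a smaller rel_step", call. = FALSE))
  structure(list(name = name, rel_step = rel_step, v0 = v0, v1 = v1,
                 S = (v1 - v0) / (v0 * rel_step)),
            class = "rac_sensitivity")
}

#' @export
print.rac_sensitivity <- function(x, ...) {
  cat(sprintf("S(%s) = %.3f  (v0 = %.5g um/s, step %+g%%)\n",
              x$name, x$S, x$v0, 100 * x$rel_step))
  invisible(x)
}

#' Wave-speed sensitivities for a set of parameters
#'
#' @param params baseline `rac_params`.
#' @param names parameters to scan (default: the full published set).
#' @param rel_step relative perturbation.
#' @return Data frame with one row per parameter, ordered as given.
#' @export
sensitivity_table <- function(params = baseline_params(),
                              names = c("k3a", "rho_Rmax", "rho_Gtotal",
                                        "Dg", "k4", "rho_Dtotal", "rho_Dmax",
                                        "k2", "k6b", "k1", "k6a", "k12",
                                        "k42", "rho_Rtotal", "k5", "k11",
                                        "Dr", "k41", "Dd"),
                              rel_step = 0.01) {
  rows <- lapply(names, function(nm) {
    s <- sensitivity(params, nm, rel_step = rel_step)
    data.frame(parameter = nm, S = s$S, v0 = s$v0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Minimum perimeter for instability of the n-th Fourier mode
#'
#' The discrete wavenumbers scale as q = 2 n pi / L, so with the linear
#' total densities held fixed the n-th mode first becomes unstable at
#' L_n_min = 2 n pi / q_m.
#'
#' @param params a `rac_params` object.
#' @param n Fourier mode order (positive integer).
#' @param q_max scan range for the marginal wavenumber.
#' @return L_n_min (um).
#' @export
min_length_for_mode <- function(params, n, q_max = 2) {
  stopifnot(n >= 1)
  2 * n * pi / marginal_wavenumber(params, q_max = q_max)
}

#' Instability regime diagram over two parameter axes
#'
#' Classifies the homogeneous steady state at every grid point of a
#' two-parameter scan using the discrete-mode dispersion relation. Axis
#' names follow [vary_param()] conventions except that values are absolute,
#' not factors. Points where the steady state cannot be computed are
#' recorded as `NA` rather than failing the scan. The result distinguishes
#' whether only the first mode or several modes are unstable.
#'
#' @param params baseline `rac_params`.
#' @param axis1,axis2 lists `list(name =, values =)`.
#' @param n_max highest Fourier mode examined.
#' @return An object of class `rac_regimes`: the two axes plus a character
#'   matrix `class` (`length(values1)` x `length(values2)`) with entries in
#'   stable/turing/hopf/turing-hopf, and an integer matrix `n_unstable`.
#' @export
regime_diagram <- function(params, axis1, axis2, n_max = 10) {
  set_abs <- function(p, name, value) {
    cur <- switch(name,
                  rho_Rtotal = p$N_Rac1 / p$L,
                  rho_Gtotal = p$N_GAP / p$L,
                  rho_Dtotal = p$N_DGAP1 / p$L,
                  N_Rac1 = p$N_Rac1, N_GAP = p$N_GAP, N_DGAP1 = p$N_DGAP1,
                  p[[name]])
    if (is.null(cur)) stop("unknown axis parameter '", name, "'")
    if (cur == 0) {
      ## cannot scale from zero: set directly (totals and plain rates only)
      if (name %in% c("N_Rac1", "N_GAP", "N_DGAP1") ||
          (name %in% names(p) && is.numeric(p[[name]]))) {
        p[[name]] <- value
        return(validate_rac_params(p))
      }
      stop("cannot vary '", name, "' away from a zero baseline")
    }
    vary_param(p, name, value / cur)
  }
  cls <- matrix(NA_character_, length(axis1$values), length(axis2$values),
                dimnames = list(axis1$values, axis2$values))
  nun <- matrix(NA_integer_, length(axis1$values), length(axis2$values))
  for (i in seq_along(axis1$values)) {
    for (j in seq_along(axis2$values)) {
      res <- tryCatch({
        p <- set_abs(params, axis1$name, axis1$values[i])
        p <- set_abs(p, axis2$name, axis2$values[j])
        d <- dispersion_relation(p, n_max = n_max)
        list(cl = d$classification,
             nu = sum(d$modes$class != "stable"))
      }, error = function(e) NULL)
      if (!is.null(res)) {
        cls[i, j] <- res$cl
        nun[i, j] <- res$nu
      }
    }
  }
  structure(list(axis1 = axis1, axis2 = axis2, class = cls,
                 n_unstable = nun),
            class = "rac_regimes")
}

#' @export
print.rac_regimes <- function(x, ...) {
  cat(sprintf("Regime diagram: %s x %s (%d x %d points)\n",
              x$axis1$name, x$axis2$name, nrow(x$class), ncol(x$class)))
  print(table(x$class, useNA = "ifany"))
  invisible(x)
}

#' Write a regime diagram as a delimited text grid
#'
#' Axis values plus integer class codes (0 stable, 1 turing, 2 hopf,
#' 3 turing-hopf, NA missing), tab-separated.
#'
#' @param x a `rac_regimes` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_regimes <- function(x, path) {
  codes <- matrix(match(x$class, c("stable", "turing", "hopf", "turing-hopf")) - 1L,
                  nrow(x$class), ncol(x$class))
  df <- data.frame(axis1 = rep(x$axis1$values, times = ncol(codes)),
                   axis2 = rep(x$axis2$values, each = nrow(codes)),
                   class_code = as.vector(codes))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
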