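#' Homogeneous steady state of the cycling model
#'
#' Solves the four independent reaction-balance equations together with the
#' three conservation equations for the spatially uniform fixed point. The
#' system is reduced semi-analytically: given the membrane Rac1-GTP density,
#' GAP partitioning is linear, the DGAP1 balance reduces to a monotone
#' scalar equation (solved by bisection), and the remaining Rac1
#' conservation residual is a bracketed scalar root in rho_R. The same
#' reduction applies to the extensive model with `rho_m` eliminated through
#' its own balance.
#'
#' For parameter sets where the total DGAP1 density exceeds `rho_Dmax`, very
#' small rho_R leaves the membrane DGAP1 balance without a root below
#' saturation; such trial values are treated as lying below the Rac1
#' conservation root so the outer bisection still brackets.
#'
#' @param params a `rac_params` object.
#' @param model `"condensed"` (default) or `"extensive"`.
#' @param tol residual tolerance on the root (default 1e-12 on rho_R).
#' @return An object of class `rac_steady`: the per-species densities
#'   (1/um), the `model` tag, and `residual`, the max-norm of the reaction
#'   terms at the solution.
#' @export
solve_homogeneous_steady_state <- function(params,
                                           model = c("condensed", "extensive"),
                                           tol = 1e-12) {
  stopifnot(inherits(params, "rac_params"))
  model <- match.arg(model)
  extensive <- model == "extensive"
  if (extensive && !has_extensive(params))
    stop("extensive steady state requested but extensive constants unset",
         call. = FALSE)
  p <- params
  G <- p$N_GAP / p$L
  Rt <- p$N_Rac1 / p$L
  Dt <- p$N_DGAP1 / p$L
  k3s <- if (extensive) p$k3a + p$k3b else p$k3a
  k6s <- if (extensive) p$k6a + p$k6b + p$k6c + p$k6d else p$k6a + p$k6b

  ## DGAP1 partitioning at given membrane Rac1 and Rac1-GAP densities:
  ## monotone in rho_D on [0, rho_Dmax); NA when pinned at saturation
  solve_D <- function(rR, rRG) {
    if (Dt == 0) return(0)
    K4 <- p$k4 + p$k41 * rR + p$k42 * rRG
    ## cytoplasmic return flux per unit rho_D
    cret <- if (extensive) {
      p$k5 * rR * (1 - (p$k6c + p$k6d) / k6s) + p$k_minus4
    } else {
      p$k5 * rR
    }
    g <- function(rD) {
      rD * cret / (max(1 - rD / p$rho_Dmax, 1e-300) * K4) +
        rD + p$k5 * rR * rD / k6s - Dt
    }
    if (K4 <= 0 || cret <= 0) {
      ## no binding or no return pathway: all free DGAP1 on one side
      if (K4 <= 0) return(0)
      return(min(Dt, p$rho_Dmax * (1 - 1e-12)))
    }
    hi <- p$rho_Dmax * (1 - 1e-12)
    if (g(hi) < 0) return(NA_real_)
    stats::uniroot(g, c(0, hi), tol = 1e-14)$root
  }

  assemble <- function(rR) {
    rg <- if (rR > 0 || G == 0) G / (1 + p$k2 * rR / k3s) else G
    rRG <- G - rg
    rD <- solve_D(rR, rRG)
    if (is.na(rD)) return(NULL)
    rRD <- p$k5 * rR * rD / k6s
    SR <- 1 - rR / p$rho_Rmax
    K1 <- p$k1 + p$k11 * rR + p$k12 * rRG
    if (extensive) {
      rm <- (p$k2 * rR * rg + p$k5 * rR * rD -
               (p$k6a + p$k6c) * rRD) / p$k_act
      bind <- (p$k_act + p$k_minus1) * rm - p$k3b * rRG
      rr <- if (SR * K1 > 0) bind / (SR * K1) else 0
    } else {
      rm <- NULL
      rr <- if (SR * K1 > 0) (p$k3a * rRG + p$k6b * rRD) / (SR * K1) else 0
    }
    rd <- Dt - rD - rRD
    list(rho_r = rr, rho_R = rR, rho_g = rg, rho_RG = rRG,
         rho_d = rd, rho_D = rD, rho_RD = rRD, rho_m = rm)
  }

  resid <- function(rR) {
    s <- assemble(rR)
    if (is.null(s)) return(-Rt)  # DGAP1 pinned at saturation: need larger rho_R
    tot <- s$rho_r + s$rho_R + s$rho_RG + s$rho_RD
    if (extensive) tot <- tot + s$rho_m
    tot - Rt
  }

  if (Rt == 0) {
    s <- assemble(0)
  } else {
    lo <- 1e-12
    hi <- p$rho_Rmax * (1 - 1e-9)
    flo <- resid(lo)
    fhi <- resid(hi)
    if (flo * fhi > 0)
      stop("no non-negative steady state found: residual does not change ",
           "sign over (0, rho_Rmax); best residual ",
           format(min(abs(flo), abs(fhi))), call. = FALSE)
    rR <- stats::uniroot(resid, c(lo, hi), tol = tol)$root
    s <- assemble(rR)
  }
  x <- unlist(s[c("rho_r", "rho_R", "rho_g", "rho_RG",
                  "rho_d", "rho_D", "rho_RD",
                  if (extensive) "rho_m")], use.names = FALSE)
  res <- max(abs(point_rhs(x, p, extensive = extensive)))
  structure(c(s[!vapply(s, is.null, logical(1))],
              list(model = model, residual = res)),
            class = "rac_steady")
}

#' @export
print.rac_steady <- function(x, ...) {
  cat("Homogeneous steady state (", x$model, " model)\n", sep = "")
  nm <- c("rho_r", "rho_R", "rho_g", "rho_RG", "rho_d", "rho_D", "rho_RD",
          if (x$model == "extensive") "rho_m")
  cat("  ", paste(sprintf("%s=%.4g", nm, unlist(x[nm])), collapse = " "),
      "\n")
  cat(sprintf("  residual (max-norm) = %.3g\n", x$residual))
  invisible(x)
}

steady_vec <- function(steady) {
  nm <- c("rho_r", "rho_R", "rho_g", "rho_RG", "rho_d", "rho_D", "rho_RD",
          if (steady$model == "extensive") "rho_m")
  stats::setNames(unlist(steady[nm]), nm)
}
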