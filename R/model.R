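#' Reaction right-hand sides of the condensed and extensive models
#'
#' `condensed_rhs()` evaluates the mass-action reaction terms of the
#' seven-species model at every grid point (no diffusion, no spatial
#' coupling). Membrane binding of Rac1 is limited by the saturation factor
#' (1 - rho_R/rho_Rmax) and DGAP1 binding by (1 - rho_D/rho_Dmax).
#' `extensive_rhs()` evaluates the eight-species system that separates Rac1
#' membrane binding from activation (via `rho_m`) and includes the reverse
#' and alternative dissociation pathways.
#'
#' Saturation factors are clamped at zero when a numerical transient pushes
#' a membrane density above its saturation value; an overshoot beyond 1% of
#' the saturation density raises a warning.
#'
#' @param state a `field_state` (7 fields for condensed, 8 for extensive).
#' @param params a `rac_params` object (extensive constants required by
#'   `extensive_rhs`).
#' @return A named list of time derivatives (1/(um s)), one vector per field.
#' @export
condensed_rhs <- function(state, params) {
  stopifnot(inherits(state, "field_state"), inherits(params, "rac_params"))
  if (!is.null(state$rho_m))
    stop("condensed_rhs expects a 7-field state (no rho_m)", call. = FALSE)
  with_fields(state, params, function(f, p) {
    SR <- clamp_saturation(1 - f$rho_R / p$rho_Rmax, "rho_R")
    SD <- clamp_saturation(1 - f$rho_D / p$rho_Dmax, "rho_D")
    K1 <- p$k1 + p$k11 * f$rho_R + p$k12 * f$rho_RG
    K4 <- p$k4 + p$k41 * f$rho_R + p$k42 * f$rho_RG
    bind_R <- f$rho_r * SR * K1
    bind_D <- f$rho_d * SD * K4
    form_RG <- p$k2 * f$rho_R * f$rho_g
    form_RD <- p$k5 * f$rho_R * f$rho_D
    list(
      rho_r  = p$k3a * f$rho_RG - bind_R + p$k6b * f$rho_RD,
      rho_R  = p$k6a * f$rho_RD - form_RG - form_RD + bind_R,
      rho_g  = p$k3a * f$rho_RG - form_RG,
      rho_RG = form_RG - p$k3a * f$rho_RG,
      rho_d  = -bind_D + (p$k6a + p$k6b) * f$rho_RD,
      rho_D  = bind_D - form_RD,
      rho_RD = form_RD - (p$k6a + p$k6b) * f$rho_RD)
  })
}

#' @rdname condensed_rhs
#' @export
extensive_rhs <- function(state, params) {
  stopifnot(inherits(state, "field_state"), inherits(params, "rac_params"))
  if (!has_extensive(params))
    stop("extensive rate constants are not set in 'params'", call. = FALSE)
  if (is.null(state$rho_m))
    stop("extensive_rhs expects an 8-field state including rho_m",
         call. = FALSE)
  with_fields(state, params, function(f, p) {
    SR <- clamp_saturation(1 - f$rho_R / p$rho_Rmax, "rho_R")
    SD <- clamp_saturation(1 - f$rho_D / p$rho_Dmax, "rho_D")
    K1 <- p$k1 + p$k11 * f$rho_R + p$k12 * f$rho_RG
    K4 <- p$k4 + p$k41 * f$rho_R + p$k42 * f$rho_RG
    bind_R <- f$rho_r * SR * K1
    bind_D <- f$rho_d * SD * K4
    form_RG <- p$k2 * f$rho_R * f$rho_g
    form_RD <- p$k5 * f$rho_R * f$rho_D
    k6s <- p$k6a + p$k6b + p$k6c + p$k6d
    list(
      rho_r  = p$k3a * f$rho_RG - bind_R + (p$k6b + p$k6d) * f$rho_RD +
               p$k_minus1 * f$rho_m,
      rho_R  = (p$k6a + p$k6c) * f$rho_RD + p$k_act * f$rho_m -
               form_RG - form_RD,
      rho_g  = (p$k3a + p$k3b) * f$rho_RG - form_RG,
      rho_RG = form_RG - (p$k3a + p$k3b) * f$rho_RG,
      rho_d  = -bind_D + (p$k6a + p$k6b) * f$rho_RD +
               p$k_minus4 * f$rho_D,
      rho_D  = bind_D + (p$k6c + p$k6d) * f$rho_RD - form_RD -
               p$k_minus4 * f$rho_D,
      rho_RD = form_RD - k6s * f$rho_RD,
      rho_m  = bind_R + p$k3b * f$rho_RG - (p$k_act + p$k_minus1) * f$rho_m)
  })
}

with_fields <- function(state, params, fn) {
  f <- state[field_names(state)]
  fn(f, params)
}

clamp_saturation <- function(s, which) {
  if (any(s < -0.01))
    warning("membrane density ", which,
            " exceeds its saturation value by more than 1%", call. = FALSE)
  pmax(s, 0)
}

## rhs on the raw per-point density vector (steady-state / Jacobian helpers);
## x is c(rho_r, rho_R, rho_g, rho_RG, rho_d, rho_D, rho_RD)[, + rho_m]
point_rhs <- function(x, p, extensive = FALSE) {
  SR <- max(1 - x[2] / p$rho_Rmax, 0)
  SD <- max(1 - x[6] / p$rho_Dmax, 0)
  K1 <- p$k1 + p$k11 * x[2] + p$k12 * x[4]
  K4 <- p$k4 + p$k41 * x[2] + p$k42 * x[4]
  bR <- x[1] * SR * K1
  bD <- x[5] * SD * K4
  fRG <- p$k2 * x[2] * x[3]
  fRD <- p$k5 * x[2] * x[6]
  if (!extensive) {
    c(p$k3a * x[4] - bR + p$k6b * x[7],
      p$k6a * x[7] - fRG - fRD + bR,
      p$k3a * x[4] - fRG,
      fRG - p$k3a * x[4],
      -bD + (p$k6a + p$k6b) * x[7],
      bD - fRD,
      fRD - (p$k6a + p$k6b) * x[7])
  } else {
    k6s <- p$k6a + p$k6b + p$k6c + p$k6d
    c(p$k3a * x[4] - bR + (p$k6b + p$k6d) * x[7] + p$k_minus1 * x[8],
      (p$k6a + p$k6c) * x[7] + p$k_act * x[8] - fRG - fRD,
      (p$k3a + p$k3b) * x[4] - fRG,
      fRG - (p$k3a + p$k3b) * x[4],
      -bD + (p$k6a + p$k6b) * x[7] + p$k_minus4 * x[6],
      bD + (p$k6c + p$k6d) * x[7] - fRD - p$k_minus4 * x[6],
      fRD - k6s * x[7],
      bR + p$k3b * x[4] - (p$k_act + p$k_minus1) * x[8])
  }
}
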