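#' Model parameters for the Rac1/GAP/DGAP1 cycling model
#'
#' Constructs and validates the full parameter set of the mass-conserving
#' reaction-diffusion model of Rac1 membrane-cytoplasm cycling. Rates are
#' first-order (1/s) or density-weighted second-order (um/s) constants;
#' diffusion coefficients are cytoplasmic (um^2/s); membrane diffusion is
#' neglected. Copy numbers enter the dynamics only through the linear total
#' densities N/L.
#'
#' The condensed model uses seven species: cytoplasmic inactive Rac1 (rho_r),
#' membrane-bound active Rac1 (rho_R), cytoplasmic GAP (rho_g), membrane
#' Rac1-GAP complex (rho_RG), cytoplasmic DGAP1 (rho_d), membrane DGAP1
#' (rho_D) and the membrane Rac1-DGAP1 complex (rho_RD). The extensive model
#' adds membrane-bound inactive Rac1 (rho_m) together with the explicit
#' activation (`k_act`), membrane release (`k_minus1`, `k_minus4`),
#' alternative Rac1-GAP dissociation (`k3b`) and the two membrane-retaining
#' Rac1-DGAP1 dissociation pathways (`k6c`, `k6d`).
#'
#' @param k1,k11,k12 membrane binding + activation of Rac1: basal (1/s),
#'   stimulated by membrane Rac1-GTP (um/s) and by the Rac1-GAP complex
#'   (um/s). These constants scale with `rho_Rmax` (see [vary_param()]).
#' @param k2 GAP binding to membrane Rac1-GTP (um/s).
#' @param k3a dissociation of the Rac1-GAP complex with release of both
#'   proteins to the cytoplasm (1/s).
#' @param k4,k41,k42 DGAP1 membrane binding: basal (1/s), stimulated by
#'   Rac1-GTP (um/s) and by the Rac1-GAP complex (um/s). Scale with
#'   `rho_Dmax`.
#' @param k5 Rac1-DGAP1 complex formation on the membrane (um/s).
#' @param k6a,k6b Rac1-DGAP1 dissociation releasing DGAP1 only (`k6a`) or
#'   both proteins (`k6b`) to the cytoplasm (1/s).
#' @param Dr,Dg,Dd cytoplasmic diffusion coefficients of Rac1, GAP and DGAP1
#'   (um^2/s).
#' @param rho_Rmax,rho_Dmax membrane saturation densities for Rac1-GTP and
#'   DGAP1 (1/um).
#' @param L cell perimeter (um).
#' @param N_Rac1,N_GAP,N_DGAP1 total copy numbers (dimensionless).
#' @param k_minus1,k_act,k_minus4,k3b,k6c,k6d extensive-model rate constants
#'   (1/s); `NULL` for a condensed-only parameter set.
#' @return An object of class `rac_params` (a validated named list).
#' @seealso [baseline_params()] for the published defaults,
#'   [solve_homogeneous_steady_state()], [simulate1d()].
#' @export
rac_params <- function(k1 = 2e-2, k11 = 4e-3, k12 = 6e-3,
                       k2 = 0.22, k3a = 0.45,
                       k4 = 0.24, k41 = 0.8e-3, k42 = 3.6e-3,
                       k5 = 0.095, k6a = 0.6, k6b = 0.43,
                       Dr = 30, Dg = 8, Dd = 12,
                       rho_Rmax = 200, rho_Dmax = 40,
                       L = 40, N_Rac1 = 5200, N_GAP = 1200, N_DGAP1 = 1600,
                       k_minus1 = NULL, k_act = NULL, k_minus4 = NULL,
                       k3b = NULL, k6c = NULL, k6d = NULL) {
  p <- list(k1 = k1, k11 = k11, k12 = k12, k2 = k2, k3a = k3a,
            k4 = k4, k41 = k41, k42 = k42, k5 = k5, k6a = k6a, k6b = k6b,
            Dr = Dr, Dg = Dg, Dd = Dd,
            rho_Rmax = rho_Rmax, rho_Dmax = rho_Dmax,
            L = L, N_Rac1 = N_Rac1, N_GAP = N_GAP, N_DGAP1 = N_DGAP1,
            k_minus1 = k_minus1, k_act = k_act, k_minus4 = k_minus4,
            k3b = k3b, k6c = k6c, k6d = k6d)
  validate_rac_params(structure(p, class = "rac_params"))
}

validate_rac_params <- function(p) {
  rates <- c("k1", "k11", "k12", "k2", "k3a", "k4", "k41", "k42",
             "k5", "k6a", "k6b", "Dr", "Dg", "Dd",
             "rho_Rmax", "rho_Dmax", "N_Rac1", "N_GAP", "N_DGAP1")
  for (nm in rates) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("parameter '", nm, "' must be a single non-negative number",
           call. = FALSE)
  }
  if (!is.numeric(p$L) || length(p$L) != 1L || is.na(p$L) || p$L <= 0)
    stop("perimeter L must be a single positive number", call. = FALSE)
  ext <- c("k_minus1", "k_act", "k_minus4", "k3b", "k6c", "k6d")
  has <- !vapply(p[ext], is.null, logical(1))
  if (any(has) && !all(has))
    stop("extensive rate constants must be supplied together (",
         paste(ext[!has], collapse = ", "), " missing)", call. = FALSE)
  if (all(has)) {
    for (nm in ext) {
      v <- p[[nm]]
      if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
        stop("parameter '", nm, "' must be a single non-negative number",
             call. = FALSE)
    }
  }
  p
}

#' Does a parameter set carry the extensive-model constants?
#' @param p a `rac_params` object.
#' @return `TRUE` if all six extensive rate constants are set.
#' @export
has_extensive <- function(p) {
  !is.null(p$k_act)
}

#' Published baseline parameter set
#'
#' The published initial estimates of all rate constants, diffusion
#' coefficients, saturation densities and copy numbers, optionally with one
#' of the published per-pattern presets applied on top (each preset is
#' named for the dynamic regime it was tuned to produce), and optionally
#' including the extensive-model constants (k_minus1 = 0.85, k_act = 1,
#' k_minus4 = 0.05, k3b = 0.25, k6c = k6d = 0.3).
#'
#' @param preset a published per-pattern parameter preset, or "none".
#' @param extensive include the extensive-model constants.
#' @return A `rac_params` object.
#' @export
baseline_params <- function(preset = c("none", "traveling_wave",
                                       "standing_wave", "rotating_monopole",
                                       "oscillating_monopole",
                                       "stationary_monopole",
                                       "oscillating_dipole",
                                       "rotating_dipole",
                                       "stationary_dipole",
                                       "transition_osc_rot",
                                       "transition_reversal",
                                       "phase_portrait_waves"),
                            extensive = FALSE) {
  preset <- match.arg(preset)
  p <- rac_params()
  ov <- switch(preset,
    none = list(),
    traveling_wave = list(N_Rac1 = 4500, N_DGAP1 = 800),
    standing_wave = list(N_Rac1 = 5000, N_DGAP1 = 800),
    rotating_monopole = list(k3a = 0.77, N_Rac1 = 7000, N_GAP = 1000,
                             N_DGAP1 = 900),
    oscillating_monopole = list(k3a = 0.65, N_Rac1 = 6000, N_DGAP1 = 900),
    stationary_monopole = list(N_Rac1 = 6200, N_DGAP1 = 3400),
    oscillating_dipole = list(k3a = 0.42, L = 60, N_Rac1 = 8580,
                              N_GAP = 2040, N_DGAP1 = 1320),
    rotating_dipole = list(k1 = 4.8e-2, k2 = 0.33, k3a = 0.57, k11 = 6e-3,
                           L = 60, N_Rac1 = 8100, N_GAP = 1380,
                           N_DGAP1 = 1440),
    stationary_dipole = list(N_Rac1 = 6000, N_GAP = 1100, N_DGAP1 = 4400),
    transition_osc_rot = list(k1 = 3e-2, k2 = 0.25, k3a = 0.7, k11 = 4.6e-3,
                              k12 = 5.6e-3, N_Rac1 = 7300, N_GAP = 1600,
                              N_DGAP1 = 1100),
    transition_reversal = list(rho_Dmax = 70, Dr = 70, Dg = 40, Dd = 30,
                               k1 = 1.57e-2, k2 = 0.72, k3a = 0.71,
                               k11 = 6.6e-3, k12 = 7.9e-3, k5 = 0.126,
                               k6a = 0.393, k6b = 0.157, k4 = 0.11,
                               k41 = 0.22, k42 = 1e-3, N_Rac1 = 6340,
                               N_GAP = 1360, N_DGAP1 = 1530),
    phase_portrait_waves = list(k3a = 0.39, k11 = 3e-3, k12 = 5e-3,
                                k41 = 0.4e-3, k42 = 2e-3, N_Rac1 = 5400,
                                N_GAP = 1440, N_DGAP1 = 1460))
  p[names(ov)] <- ov
  if (extensive)
    p[c("k_minus1", "k_act", "k_minus4", "k3b", "k6c", "k6d")] <-
      list(0.85, 1, 0.05, 0.25, 0.3, 0.3)
  validate_rac_params(p)
}

#' Parameter set for the condensed/extensive equivalence run
#'
#' Copy numbers and the k11 value at which the eight-species extensive model
#' is stated to match the seven-species condensed model at its baseline
#' parameters. The retention pathways k6c/k6d can be kept at their listed
#' values or zeroed (they were dropped from the condensed model).
#'
#' @param k6cd value used for both k6c and k6d (default the listed 0.3/s).
#' @return A `rac_params` object with extensive constants set.
#' @export
equivalence_params <- function(k6cd = 0.3) {
  p <- baseline_params(extensive = TRUE)
  p$N_Rac1 <- 9200
  p$N_GAP <- 880
  p$N_DGAP1 <- 1500
  p$k11 <- 5e-3
  p$k6c <- k6cd
  p$k6d <- k6cd
  validate_rac_params(p)
}

#' Perturb one model parameter, honouring the saturation-density scaling
#'
#' Multiplies one parameter by `factor`. The membrane-binding constants are
#' stored already scaled with the saturation densities, so varying
#' `rho_Rmax` rescales k1, k11, k12 proportionally (the intrinsic constants
#' k/rho_Rmax are held fixed), and varying `rho_Dmax` rescales k4, k41, k42.
#' The linear totals can be addressed as "rho_Rtotal", "rho_Gtotal" and
#' "rho_Dtotal" (the copy number is varied with L fixed).
#'
#' @param p a `rac_params` object.
#' @param name parameter name (a `rac_params` field, or one of the
#'   `rho_*total` aliases).
#' @param factor multiplicative factor (> 0).
#' @return The perturbed `rac_params` object.
#' @export
vary_param <- function(p, name, factor) {
  stopifnot(inherits(p, "rac_params"), is.numeric(factor), factor > 0)
  if (name == "rho_Rmax") {
    p$rho_Rmax <- p$rho_Rmax * factor
    p$k1 <- p$k1 * factor
    p$k11 <- p$k11 * factor
    p$k12 <- p$k12 * factor
  } else if (name == "rho_Dmax") {
    p$rho_Dmax <- p$rho_Dmax * factor
    p$k4 <- p$k4 * factor
    p$k41 <- p$k41 * factor
    p$k42 <- p$k42 * factor
  } else if (name == "rho_Rtotal") {
    p$N_Rac1 <- p$N_Rac1 * factor
  } else if (name == "rho_Gtotal") {
    p$N_GAP <- p$N_GAP * factor
  } else if (name == "rho_Dtotal") {
    p$N_DGAP1 <- p$N_DGAP1 * factor
  } else if (name %in% names(p) && is.numeric(p[[name]])) {
    p[[name]] <- p[[name]] * factor
  } else {
    stop("unknown parameter '", name, "'", call. = FALSE)
  }
  validate_rac_params(p)
}

#' Read or write a parameter set as a flat YAML or JSON file
#'
#' @param p a `rac_params` object.
#' @param path file path; the extension selects the dialect (`.yaml`/`.yml`
#'   or `.json`).
#' @return `write_params()` returns `path` invisibly; `read_params()` a
#'   `rac_params` object.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "rac_params"))
  x <- p[!vapply(p, is.null, logical(1))]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(rac_params, x)
}

#' @export
print.rac_params <- function(x, ...) {
  cat("Rac1/GAP/DGAP1 model parameters",
      if (has_extensive(x)) "(extensive)" else "(condensed)", "\n")
  cat(sprintf("  L = %g um, N_Rac1 = %g, N_GAP = %g, N_DGAP1 = %g\n",
              x$L, x$N_Rac1, x$N_GAP, x$N_DGAP1))
  cat(sprintf("  rho_Rmax = %g, rho_Dmax = %g (1/um); Dr/Dg/Dd = %g/%g/%g um^2/s\n",
              x$rho_Rmax, x$rho_Dmax, x$Dr, x$Dg, x$Dd))
  ks <- c("k1", "k11", "k12", "k2", "k3a", "k4", "k41", "k42", "k5",
          "k6a", "k6b")
  cat("  ", paste(sprintf("%s=%g", ks, unlist(x[ks])), collapse = " "), "\n")
  if (has_extensive(x)) {
    ke <- c("k_minus1", "k_act", "k_minus4", "k3b", "k6c", "k6d")
    cat("  ", paste(sprintf("%s=%g", ke, unlist(x[ke])), collapse = " "), "\n")
  }
  invisible(x)
}
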