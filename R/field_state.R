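#' Spatial state of the reaction-diffusion fields
#'
#' Bundles the linear-density fields on a shared uniform periodic grid over
#' the cell perimeter. The condensed model carries seven fields; the
#' extensive model adds `rho_m`, the membrane-bound inactive Rac1.
#'
#' @param rho_r,rho_R,rho_g,rho_RG,rho_d,rho_D,rho_RD numeric vectors of
#'   equal length: linear densities (1/um) at the grid points.
#' @param L perimeter (um); the grid is x_i = (i-1) L/n.
#' @param rho_m optional eighth field (extensive model only).
#' @return An object of class `field_state`: a list of fields plus grid
#'   metadata (`x`, `h`, `L`).
#' @export
field_state <- function(rho_r, rho_R, rho_g, rho_RG, rho_d, rho_D, rho_RD,
                        L, rho_m = NULL) {
  f <- list(rho_r = rho_r, rho_R = rho_R, rho_g = rho_g, rho_RG = rho_RG,
            rho_d = rho_d, rho_D = rho_D, rho_RD = rho_RD)
  if (!is.null(rho_m)) f$rho_m <- rho_m
  n <- length(rho_r)
  lens <- vapply(f, length, integer(1))
  if (any(lens != n))
    stop("all fields must have the same length", call. = FALSE)
  vals <- unlist(f, use.names = FALSE)
  if (any(!is.finite(vals)))
    stop("fields must be finite", call. = FALSE)
  if (any(vals < 0))
    stop("densities must be non-negative", call. = FALSE)
  if (!is.numeric(L) || L <= 0)
    stop("L must be positive", call. = FALSE)
  structure(c(f, list(L = L, h = L / n, x = (seq_len(n) - 1) * L / n)),
            class = "field_state")
}

field_names <- function(state) {
  nm <- c("rho_r", "rho_R", "rho_g", "rho_RG", "rho_d", "rho_D", "rho_RD")
  if (!is.null(state$rho_m)) nm <- c(nm, "rho_m")
  nm
}

#' Homogeneous field state from per-species densities
#'
#' @param dens named numeric vector or list with entries `rho_r` ... `rho_RD`
#'   (and optionally `rho_m`), each a single density (1/um).
#' @param L perimeter (um).
#' @param n_points grid size.
#' @return A `field_state` with every field spatially constant.
#' @export
uniform_state <- function(dens, L, n_points = 100) {
  dens <- as.list(dens)
  field_state(rho_r = rep(dens$rho_r, n_points),
              rho_R = rep(dens$rho_R, n_points),
              rho_g = rep(dens$rho_g, n_points),
              rho_RG = rep(dens$rho_RG, n_points),
              rho_d = rep(dens$rho_d, n_points),
              rho_D = rep(dens$rho_D, n_points),
              rho_RD = rep(dens$rho_RD, n_points),
              L = L,
              rho_m = if (!is.null(dens$rho_m)) rep(dens$rho_m, n_points))
}

#' Grid-summed copy numbers per conservation group
#'
#' On the uniform periodic grid the spatial integral of a density is
#' `sum(field) * h`. Rac1 counts the cytoplasmic and membrane pools plus
#' both complexes (plus `rho_m` in the extensive model); GAP counts the free
#' cytoplasmic pool plus the Rac1-GAP complex; DGAP1 the free pools plus the
#' Rac1-DGAP1 complex.
#'
#' @param state a `field_state`.
#' @return Named numeric vector `c(Rac1, GAP, DGAP1)` in molecule counts.
#' @export
species_totals <- function(state) {
  stopifnot(inherits(state, "field_state"))
  h <- state$h
  rac <- sum(state$rho_r + state$rho_R + state$rho_RG + state$rho_RD) * h
  if (!is.null(state$rho_m)) rac <- rac + sum(state$rho_m) * h
  c(Rac1 = rac,
    GAP = sum(state$rho_g + state$rho_RG) * h,
    DGAP1 = sum(state$rho_d + state$rho_D + state$rho_RD) * h)
}

#' @export
print.field_state <- function(x, ...) {
  nm <- field_names(x)
  cat(sprintf("field_state: %d fields on %d grid points, L = %g um\n",
              length(nm), length(x$rho_r), x$L))
  tot <- species_totals(x)
  cat(sprintf("  totals: Rac1 = %.4g, GAP = %.4g, DGAP1 = %.4g\n",
              tot[1], tot[2], tot[3]))
  invisible(x)
}

## flatten to / from the solver layout (field-major: all rho_r, then rho_R, ...)
state_to_vec <- function(state) {
  unlist(lapply(field_names(state), function(nm) state[[nm]]),
         use.names = FALSE)
}

vec_to_state <- function(y, L, extensive = FALSE) {
  nf <- if (extensive) 8L else 7L
  n <- length(y) %/% nf
  m <- matrix(y, nrow = n)
  field_state(rho_r = m[, 1], rho_R = m[, 2], rho_g = m[, 3], rho_RG = m[, 4],
              rho_d = m[, 5], rho_D = m[, 6], rho_RD = m[, 7], L = L,
              rho_m = if (extensive) m[, 8])
}
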