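#' Specification of a synthetic two-channel kymograph pair
#'
#' Describes QuimP-style cortical intensity data: a wave pattern on a
#' closed contour observed in two fluorescence channels with a prescribed
#' phase relation, intensity-dependent noise and (optionally) irregular
#' angular sampling followed by interpolation onto a regular grid.
#'
#' @param pattern one of `"traveling"`, `"standing"`, `"stationary"`,
#'   `"homogeneous"`, `"random"`.
#' @param mode_order spatial Fourier mode (>= 1).
#' @param period oscillation period (s); ignored for stationary and
#'   homogeneous patterns.
#' @param amplitude,baseline signal amplitude and offset (a.u.);
#'   `baseline > amplitude` keeps intensities positive.
#' @param phase_offset channel-2 phase offset in radians (pi gives
#'   anti-correlated channels).
#' @param noise `"gaussian"` (constant variance) or `"poisson_like"`
#'   (variance proportional to the mean, as for photon-limited detection).
#' @param snr_db signal-to-noise ratio (dB); `Inf` for noise-free.
#' @param m angular samples per frame.
#' @param n_t number of frames.
#' @param frame_interval time between frames (s).
#' @param jitter irregular-sampling jitter as a fraction of the angular
#'   grid step (0 = regular sampling).
#' @param domain_width half-width (rad) of the raised-cosine enriched
#'   domain used for the stationary pattern.
#' @param seed RNG seed.
#' @return An object of class `synth_spec`.
#' @export
synthetic_spec <- function(pattern = c("traveling", "standing", "stationary",
                                       "homogeneous", "random"),
                           mode_order = 1, period = 190,
                           amplitude = 40, baseline = 100,
                           phase_offset = pi,
                           noise = c("gaussian", "poisson_like"),
                           snr_db = Inf, m = 100, n_t = 400,
                           frame_interval = 1, jitter = 0,
                           domain_width = pi / 2, seed = 1) {
  pattern <- match.arg(pattern)
  noise <- match.arg(noise)
  if (baseline <= amplitude || amplitude < 0)
    stop("need baseline > amplitude >= 0", call. = FALSE)
  if (pattern %in% c("traveling", "standing") &&
      period <= 2 * frame_interval)
    stop("period must exceed twice the frame interval (Nyquist)",
         call. = FALSE)
  stopifnot(mode_order >= 1, m >= 8, n_t >= 8)
  structure(list(pattern = pattern, mode_order = mode_order, period = period,
                 amplitude = amplitude, baseline = baseline,
                 phase_offset = phase_offset, noise = noise,
                 snr_db = snr_db, m = m, n_t = n_t,
                 frame_interval = frame_interval, jitter = jitter,
                 domain_width = domain_width, seed = seed),
            class = "synth_spec")
}

#' Generate a two-channel synthetic kymograph pair
#'
#' Builds the noise-free signal for both channels (channel 2 shifted by the
#' spec's phase offset), adds intensity-dependent or constant-variance
#' noise calibrated to the requested SNR, optionally samples each frame at
#' jittered angular positions and interpolates back onto the regular grid.
#' Fully deterministic under the spec's seed.
#'
#' @param spec a `synth_spec`.
#' @return List with `ch1`, `ch2` (`kymo` objects) and `truth`: the ground
#'   truth (pattern, mode order, period, phase offset, orientation of the
#'   traveling wave, realized SNR).
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  tt <- (seq_len(spec$n_t) - 1) * spec$frame_interval
  phi <- 2 * pi * (seq_len(spec$m) - 1) / spec$m
  omega <- 2 * pi / spec$period
  n <- spec$mode_order
  signal_at <- function(ph, t, offset = 0) {
    arg <- n * outer(rep(1, length(t)), ph) - offset
    switch(spec$pattern,
      traveling = spec$baseline +
        spec$amplitude * cos(arg - omega * t),
      standing = spec$baseline +
        spec$amplitude * cos(arg) * cos(omega * t),
      stationary = {
        ## n raised-cosine domains, phase-wrapped in the mode coordinate
        d <- atan2(sin(arg - pi), cos(arg - pi))
        prof <- ifelse(abs(d) < spec$domain_width * pi / 2,
                       0.5 * (1 + cos(2 * d / spec$domain_width)), 0)
        spec$baseline + spec$amplitude * (prof - 0.5)
      },
      homogeneous = matrix(spec$baseline, length(t), length(ph)),
      random = spec$baseline +
        spec$amplitude * matrix(stats::runif(length(t) * length(ph), -1, 1),
                                length(t), length(ph)))
  }
  make_channel <- function(offset) {
    if (spec$jitter > 0) {
      step <- 2 * pi / spec$m
      frames <- lapply(seq_along(tt), function(i) {
        ph <- (phi + stats::runif(spec$m, -spec$jitter, spec$jitter) * step) %%
          (2 * pi)
        list(phi = ph, I = as.vector(signal_at(ph, tt[i], offset)))
      })
      clean <- interpolate_to_grid(frames, m = spec$m, times = tt)$I
    } else {
      clean <- signal_at(phi, tt, offset)
    }
    noisy <- add_noise(clean, spec)
    list(clean = clean, noisy = noisy)
  }
  ch1 <- make_channel(0)
  ch2 <- make_channel(spec$phase_offset)
  snr_real <- if (is.finite(spec$snr_db)) {
    sig_var <- stats::var(as.vector(ch1$clean))
    noi_var <- stats::var(as.vector(ch1$noisy - ch1$clean))
    if (noi_var > 0) 10 * log10(sig_var / noi_var) else Inf
  } else Inf
  truth <- list(pattern = spec$pattern, mode_order = spec$mode_order,
                period = if (spec$pattern %in% c("traveling", "standing"))
                  spec$period else NA_real_,
                phase_offset = spec$phase_offset,
                orientation = if (spec$pattern == "traveling")
                  "counterclockwise" else NA_character_,
                snr_db_realized = snr_real)
  list(ch1 = kymograph(ch1$noisy, times = tt, phi = phi, channel = "ch1"),
       ch2 = kymograph(ch2$noisy, times = tt, phi = phi, channel = "ch2"),
       truth = truth)
}

## noise calibrated so that var(noise) = var(signal) / 10^(snr/10);
## poisson_like spreads that variance proportionally to the local mean
add_noise <- function(clean, spec) {
  if (!is.finite(spec$snr_db)) return(clean)
  target_var <- stats::var(as.vector(clean)) / 10^(spec$snr_db / 10)
  if (target_var == 0) return(clean)
  eps <- if (spec$noise == "gaussian") {
    stats::rnorm(length(clean), 0, sqrt(target_var))
  } else {
    w <- clean / mean(clean)
    stats::rnorm(length(clean), 0, sqrt(target_var * w))
  }
  pmax(clean + matrix(eps, nrow(clean), ncol(clean)), 0)
}

#' Two-channel kymograph pair from a ring simulation
#'
#' Maps simulated density fields to fluorescence-like channels: channel 1
#' is membrane Rac1-GTP and channel 2 total membrane DGAP1 (free plus
#' complexed) by default, rescaled to intensity units, with optional noise.
#'
#' @param sim a `rac_sim`.
#' @param channel1,channel2 field names (summed when several).
#' @param snr_db noise level (dB, Inf for none).
#' @param noise noise model as in [synthetic_spec()].
#' @param intensity_scale multiplies the densities into arbitrary units.
#' @param seed RNG seed.
#' @return List with `ch1` and `ch2` `kymo` objects.
#' @export
from_simulation <- function(sim, channel1 = "rho_R",
                            channel2 = c("rho_D", "rho_RD"),
                            snr_db = Inf, noise = "gaussian",
                            intensity_scale = 1, seed = 1) {
  stopifnot(inherits(sim, "rac_sim"))
  missing_f <- setdiff(c(channel1, channel2), names(sim$fields))
  if (length(missing_f))
    stop("fields not present in the simulation: ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  set.seed(seed)
  spec <- list(snr_db = snr_db, noise = noise)
  mk <- function(fields, label) {
    I <- Reduce(`+`, sim$fields[fields]) * intensity_scale
    I <- add_noise(I, structure(spec, class = "synth_spec"))
    kymograph(I, times = sim$times,
              phi = 2 * pi * (seq_len(sim$n_points) - 1) / sim$n_points,
              channel = label)
  }
  list(ch1 = mk(channel1, paste(channel1, collapse = "+")),
       ch2 = mk(channel2, paste(channel2, collapse = "+")))
}
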