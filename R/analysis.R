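#' Spatio-temporal autocorrelogram of a kymograph
#'
#' Computes A(dPhi, dt) = <dI(phi+dPhi, t+dt) dI(phi, t)> / <dI^2> where the
#' fluctuation dI removes the angular mean at each time point. The spatial
#' lag wraps periodically around the ring; the temporal lag truncates (no
#' wrap in time). A(0, 0) = 1 by construction.
#'
#' @param kymo a `kymo`.
#' @param max_lag_t maximum temporal lag in frames (default half the record).
#' @return An object of class `rac_acf`: matrix `A` ((2 max_lag_t + 1) x m,
#'   temporal lags in rows), plus the lag grids `dphi` (rad) and `dt` (s).
#' @export
autocorrelogram <- function(kymo, max_lag_t = NULL) {
  stopifnot(inherits(kymo, "kymo"))
  dI <- kymo$I - rowMeans(kymo$I)
  denom <- mean(dI^2)
  if (denom == 0)
    stop("degenerate signal: no angular fluctuations", call. = FALSE)
  nt <- nrow(dI)
  m <- ncol(dI)
  if (is.null(max_lag_t)) max_lag_t <- nt %/% 2
  lags_t <- -max_lag_t:max_lag_t
  ## spatial correlation via FFT along the periodic angular axis
  A <- matrix(0, length(lags_t), m)
  F <- t(apply(dI, 1, stats::fft))            # nt x m, per-row spectra
  for (k in seq_along(lags_t)) {
    lt <- lags_t[k]
    i1 <- max(1, 1 - lt):min(nt, nt - lt)     # t indices
    i2 <- i1 + lt                             # t + dt indices
    cross <- F[i2, , drop = FALSE] * Conj(F[i1, , drop = FALSE])
    corr <- Re(stats::fft(colSums(cross), inverse = TRUE)) / m
    A[k, ] <- corr / (length(i1) * m) / denom
  }
  structure(list(A = A, dt = lags_t * mean(diff(kymo$times)),
                 dphi = kymo$phi, lags_t = lags_t),
            class = "rac_acf")
}

#' @export
print.rac_acf <- function(x, ...) {
  cat(sprintf("autocorrelogram: %d temporal x %d angular lags, A(0,0) = %.3f\n",
              nrow(x$A), ncol(x$A), x$A[which(x$lags_t == 0), 1]))
  invisible(x)
}

#' Pearson correlation between two kymographs
#'
#' `pearson_full()` correlates all matrix elements inside a time window from
#' the start of the record (the whole record by default behaviour of a
#' window longer than the record is an error only when shorter than one
#' frame). `sliding_pearson()` evaluates the same element-wise correlation
#' over sliding windows.
#'
#' @param k1,k2 co-registered `kymo` objects.
#' @param window window length (s) from the start of the record.
#' @return `pearson_full()`: a single correlation. `sliding_pearson()`: data
#'   frame with window mid-times and correlations.
#' @export
pearson_full <- function(k1, k2, window = 120) {
  check_coregistered(k1, k2)
  sel <- k1$times <= k1$times[1] + window
  a <- as.vector(k1$I[sel, , drop = FALSE])
  b <- as.vector(k2$I[sel, , drop = FALSE])
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: zero-variance channel", call. = FALSE)
  stats::cor(a, b)
}

#' @rdname pearson_full
#' @param stride window stride in frames (default 1).
#' @export
sliding_pearson <- function(k1, k2, window = 10, stride = 1) {
  check_coregistered(k1, k2)
  dt <- mean(diff(k1$times))
  wlen <- max(2L, round(window / dt))
  nt <- nrow(k1$I)
  if (wlen > nt)
    stop("window longer than the record", call. = FALSE)
  starts <- seq(1L, nt - wlen + 1L, by = stride)
  r <- vapply(starts, function(s) {
    i <- s:(s + wlen - 1L)
    stats::cor(as.vector(k1$I[i, ]), as.vector(k2$I[i, ]))
  }, numeric(1))
  data.frame(t = k1$times[starts] + (wlen - 1) * dt / 2, r = r)
}

check_coregistered <- function(k1, k2) {
  stopifnot(inherits(k1, "kymo"), inherits(k2, "kymo"))
  if (!identical(dim(k1$I), dim(k2$I)) ||
      max(abs(k1$times - k2$times)) > 1e-9 ||
      max(abs(k1$phi - k2$phi)) > 1e-9)
    stop("kymographs are not co-registered", call. = FALSE)
  invisible(TRUE)
}

#' PCA phase alignment of a two-channel kymograph pair
#'
#' Stacks the two intensity matrices vertically into a 2 n_t x m matrix,
#' standardizes each row (mean 0, sd 1), and treats the m angular positions
#' as data points in the 2 n_t-dimensional space. The first two principal
#' axes capture the oscillation; the projections (c_1j, c_2j) give each
#' position's phase angle phi_j = atan2(c_2j, c_1j). The period T is
#' estimated from the oscillation of the first principal axis read as a
#' time series (mean spacing of zero crossings of its channel-1 half, with
#' a spectral-peak fallback below 4 crossings). Each column is then shifted
#' in time by -T phi_j / (2 pi) (circular, linearly interpolated) and the
#' aligned columns averaged per channel.
#'
#' @param k1,k2 co-registered `kymo` objects (channel 1 and 2).
#' @return An object of class `rac_pca`: projections `c1`, `c2`, phase
#'   angles `phase` (in [0, 2 pi)), period `T` (s), variance fractions
#'   `var_frac`, component time series `v1`, `v2` (length n_t each), time
#'   shifts `shifts`, and the aligned-and-averaged channel profiles
#'   `mean1`, `mean2` on the common time grid.
#' @export
pca_align <- function(k1, k2) {
  check_coregistered(k1, k2)
  nt <- nrow(k1$I)
  m <- ncol(k1$I)
  X <- rbind(k1$I, k2$I)
  mu <- rowMeans(X)
  sdv <- apply(X, 1, stats::sd)
  if (any(sdv == 0))
    stop("constant row in the stacked intensity matrix", call. = FALSE)
  Z <- (X - mu) / sdv
  ## the principal axes of the column cloud; the projections dot the raw
  ## standardized columns with the axes (no re-centering), so aligned data
  ## project onto a common direction
  pc <- stats::prcomp(t(Z), center = FALSE, scale. = FALSE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  if (sum(var_frac[1:2]) < 0.2)
    warning("first two components carry under 20% of the variance; ",
            "phase alignment may be unreliable", call. = FALSE)
  c1 <- pc$x[, 1]
  c2 <- pc$x[, 2]
  phase <- atan2(c2, c1) %% (2 * pi)
  ## period from the first principal axis, channel-1 half, as a time series
  v1 <- pc$rotation[seq_len(nt), 1]
  v2 <- pc$rotation[nt + seq_len(nt), 1]
  dt <- mean(diff(k1$times))
  Tper <- estimate_period_series(v1, dt)
  shifts <- -Tper * phase / (2 * pi)
  al1 <- align_columns(k1$I, shifts, dt)
  al2 <- align_columns(k2$I, shifts, dt)
  ## phases of the aligned columns, re-projected on the original axes:
  ## concentrated at one angle when the alignment succeeded
  Zal <- rbind(align_columns(Z[seq_len(nt), , drop = FALSE], shifts, dt),
               align_columns(Z[nt + seq_len(nt), , drop = FALSE], shifts, dt))
  c1a <- as.vector(t(Zal) %*% pc$rotation[, 1])
  c2a <- as.vector(t(Zal) %*% pc$rotation[, 2])
  structure(list(c1 = c1, c2 = c2, phase = phase, T = Tper,
                 var_frac = var_frac, v1 = v1, v2 = v2, shifts = shifts,
                 phase_aligned = atan2(c2a, c1a) %% (2 * pi),
                 mean1 = rowMeans(al1), mean2 = rowMeans(al2),
                 aligned1 = al1, aligned2 = al2, times = k1$times),
            class = "rac_pca")
}

#' @export
print.rac_pca <- function(x, ...) {
  cat(sprintf("PCA phase alignment: T = %.4g s, first two components %.0f%% of variance\n",
              x$T, 100 * sum(x$var_frac[1:2])))
  invisible(x)
}

## zero-crossing period estimator with spectral fallback
estimate_period_series <- function(v, dt) {
  v <- v - mean(v)
  s <- sign(v)
  cross <- which(s[-1] * s[-length(s)] < 0)
  if (length(cross) >= 4) {
    2 * mean(diff(cross)) * dt
  } else {
    sp <- Mod(stats::fft(v))[2:(length(v) %/% 2)]
    (length(v) * dt) / which.max(sp)
  }
}

## displace each column in time by its shift (circular, interpolated):
## the shifted series S satisfies S(t) = I(t - shift)
align_columns <- function(I, shifts, dt) {
  nt <- nrow(I)
  tt <- seq_len(nt)
  out <- I
  for (j in seq_len(ncol(I))) {
    src <- ((tt - 1 - shifts[j] / dt) %% nt) + 1
    lo <- floor(src)
    hi <- lo + 1
    w <- src - lo
    lo <- ((lo - 1) %% nt) + 1
    hi <- ((hi - 1) %% nt) + 1
    out[, j] <- (1 - w) * I[lo, j] + w * I[hi, j]
  }
  out
}

#' Orientation of a closed two-variable phase trajectory
#'
#' Computes the signed (shoelace) area swept by the trajectory
#' (x(t), y(t)); positive area means counterclockwise rotation in the
#' (x, y) plane. Warns when the trajectory does not close (endpoint gap
#' above 10% of the trajectory diameter).
#'
#' @param x,y co-sampled periodic series, or an `rac_pca` object in `x`
#'   (using its averaged channel profiles).
#' @return List with `area` and `orientation`
#'   (`"counterclockwise"`/`"clockwise"`).
#' @export
phase_portrait <- function(x, y = NULL) {
  if (inherits(x, "rac_pca")) {
    y <- x$mean2
    x <- x$mean1
  }
  stopifnot(length(x) == length(y), length(x) >= 3)
  gap <- sqrt((x[1] - x[length(x)])^2 + (y[1] - y[length(y)])^2)
  diam <- sqrt(diff(range(x))^2 + diff(range(y))^2)
  if (diam > 0 && gap > 0.1 * diam)
    warning("trajectory does not close (gap ", format(gap, digits = 3),
            " vs diameter ", format(diam, digits = 3), ")", call. = FALSE)
  area <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
  list(area = area,
       orientation = if (area >= 0) "counterclockwise" else "clockwise")
}

#' Spatial power spectral density of the noise in a raw kymograph
#'
#' Mirrors the measurement-side noise analysis: a variance-stabilizing
#' square root of the raw intensities, a 4th-order high-pass Butterworth
#' filter at cutoff 0.15 cycles per angular grid step applied spatially with
#' zero-phase forward-backward filtering, then a per-time-point spatial FFT
#' whose single-sided power spectral density (2/N |FFT|^2) is averaged over
#' time. Frequencies are reported both per grid step and per micrometre
#' (using the perimeter implied by `L`).
#'
#' @param kymo a `kymo` with non-negative intensities on a regular grid
#'   (interpolate first if sampling is irregular), at least 8 angular
#'   positions.
#' @param fc cutoff frequency in cycles per grid step.
#' @param order filter order.
#' @param L perimeter (um) used to express frequencies per micrometre
#'   (default 2 pi, i.e. unit radius).
#' @return An object of class `rac_psd`: `freq` (cycles per grid step),
#'   `freq_um` (cycles per um), `psd` (averaged single-sided PSD), and the
#'   filtered matrix.
#' @export
psd_noise <- function(kymo, fc = 0.15, order = 4, L = 2 * pi) {
  stopifnot(inherits(kymo, "kymo"))
  if (any(kymo$I < 0))
    stop("raw intensities must be non-negative", call. = FALSE)
  m <- ncol(kymo$I)
  if (m < 8) stop("need at least 8 spatial points", call. = FALSE)
  Isq <- sqrt(kymo$I)
  bf <- signal::butter(order, fc / 0.5, type = "high")
  ## the angular axis is periodic: filter a triple-wrapped copy and keep the
  ## central section, so the zero-phase filter sees no artificial edges
  filt <- t(apply(Isq, 1, function(row) {
    w <- signal::filtfilt(bf, c(row, row, row))
    w[m + seq_len(m)]
  }))
  ## single-sided PSD per time point, averaged
  nfreq <- m %/% 2 + 1
  psd_t <- t(apply(filt, 1, function(row) {
    sp <- (2 / m) * Mod(stats::fft(row))^2
    s <- sp[seq_len(nfreq)]
    s[1] <- s[1] / 2
    if (m %% 2 == 0) s[nfreq] <- s[nfreq] / 2
    s
  }))
  freq <- (seq_len(nfreq) - 1) / m      # cycles per grid step
  structure(list(freq = freq, freq_um = freq * m / L,
                 psd = colMeans(psd_t), filtered = filt,
                 fc = fc, order = order),
            class = "rac_psd")
}

#' @export
print.rac_psd <- function(x, ...) {
  cat(sprintf("spatial PSD: %d frequencies, cutoff %.2f cycles/step (order %d)\n",
              length(x$freq), x$fc, x$order))
  invisible(x)
}
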