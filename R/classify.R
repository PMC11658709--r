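#' Classify the wave type of a kymograph
#'
#' Operationalizes the visual taxonomy of membrane patterns. After
#' discarding the transient, the dominant spatial Fourier mode n is taken
#' from the time-averaged spatial power spectrum. The complex mode
#' amplitude c_n(t) then separates the classes: a traveling wave rotates
#' its phase at a steady rate (nonzero autocorrelogram ridge slope); a
#' standing wave keeps a fixed phase axis while its amplitude periodically
#' collapses through zero (temporal autocorrelation at a fixed point
#' reaches A(0, T/2) < 0); a stationary pattern keeps both phase and
#' amplitude (no temporal decorrelation, persistent spatial contrast); a
#' kymograph without spatial contrast is homogeneous.
#'
#' @param kymo a `kymo`.
#' @param discard_transient time (s) dropped from the start.
#' @param contrast_tol spatial contrast (sd/mean) below which the record is
#'   homogeneous.
#' @param rotation_tol minimum total phase rotation (rad) counted as
#'   traveling.
#' @param collapse_tol amplitude min/max ratio below which the mode
#'   amplitude is considered to collapse (standing candidate).
#' @return An object of class `rac_pattern`: `class` in
#'   homogeneous/stationary/traveling/standing, `mode_order`, `period` (s,
#'   NA for stationary/homogeneous), `speed` (um-free phase speed d phi/dt
#'   in rad/s) and the diagnostics used.
#' @export
classify_pattern <- function(kymo, discard_transient = 0,
                             contrast_tol = 0.02, rotation_tol = pi,
                             collapse_tol = 0.3) {
  stopifnot(inherits(kymo, "kymo"))
  keep <- kymo$times >= kymo$times[1] + discard_transient
  if (sum(keep) < 8)
    stop("record too short after transient discard", call. = FALSE)
  I <- kymo$I[keep, , drop = FALSE]
  tt <- kymo$times[keep]
  m <- ncol(I)
  mu <- rowMeans(I)
  contrast <- mean(apply(I, 1, stats::sd)) /
    max(mean(abs(mu)), .Machine$double.eps)
  if (contrast < contrast_tol)
    return(pattern_result("homogeneous", 0L, NA_real_, 0, contrast))
  dI <- I - mu
  spec <- t(apply(dI, 1, function(r) Mod(stats::fft(r))[2:(m %/% 2)]))
  n_dom <- which.max(colMeans(spec))
  cn <- apply(dI, 1, function(r) stats::fft(r)[n_dom + 1])
  amp <- Mod(cn)
  th <- Arg(cn)
  for (i in 2:length(th))
    th[i] <- th[i - 1] + Arg(exp(1i * (th[i] - th[i - 1])))
  slope <- unname(stats::coef(stats::lm(th ~ tt))[2])   # rad/s of mode phase
  rotation <- abs(slope) * (max(tt) - min(tt))
  collapse <- min(amp) / max(amp)
  ## temporal autocorrelation at fixed points (averaged over positions)
  tac <- temporal_acf(dI)
  if (rotation >= rotation_tol && collapse >= collapse_tol) {
    period <- 2 * pi / abs(slope)
    return(pattern_result("traveling", n_dom, period, slope, contrast))
  }
  if (collapse < collapse_tol && min(tac) < -0.3) {
    period <- 2 * first_trough(tac, -0.3) * mean(diff(tt))
    return(pattern_result("standing", n_dom, period, slope, contrast))
  }
  if (min(tac[seq_len(min(length(tac), 50))]) > 0.5 || max(amp) > 0 &&
      stats::sd(amp) / mean(amp) < 0.1 && rotation < rotation_tol) {
    return(pattern_result("stationary", n_dom, NA_real_, slope, contrast))
  }
  ## fallbacks: oscillatory but irregular records side with the closer class
  if (rotation >= rotation_tol)
    return(pattern_result("traveling", n_dom, 2 * pi / abs(slope), slope,
                          contrast))
  if (min(tac) < 0) {
    return(pattern_result("standing", n_dom,
                          2 * first_trough(tac, 0) * mean(diff(tt)),
                          slope, contrast))
  }
  pattern_result("stationary", n_dom, NA_real_, slope, contrast)
}

pattern_result <- function(class, n, period, slope, contrast) {
  structure(list(class = class, mode_order = as.integer(n), period = period,
                 phase_slope = slope, contrast = contrast),
            class = "rac_pattern")
}

#' @export
print.rac_pattern <- function(x, ...) {
  cat(sprintf("pattern: %s (mode %d)%s\n", x$class, x$mode_order,
              if (is.finite(x$period))
                sprintf(", period %.4g s", x$period) else ""))
  invisible(x)
}

## lag (in frames) of the first local minimum of the autocorrelation
## falling below `thresh`; falls back to the global minimum
first_trough <- function(tac, thresh) {
  tr <- which(diff(sign(diff(tac))) == 2) + 1
  tr <- tr[tac[tr] < thresh]
  if (length(tr)) tr[1] - 1 else which.min(tac) - 1
}

## mean temporal autocorrelation over angular positions
temporal_acf <- function(dI) {
  nt <- nrow(dI)
  lagmax <- nt - 1
  ac <- rep(0, lagmax + 1)
  denom <- sum(dI^2)
  for (lag in 0:lagmax) {
    i <- seq_len(nt - lag)
    ac[lag + 1] <- sum(dI[i, , drop = FALSE] * dI[i + lag, , drop = FALSE]) /
      denom * nt / (nt - lag)
  }
  ac
}

#' Estimate the oscillation period of a kymograph
#'
#' First positive-lag recurrence (local maximum above 0.2) of the mean
#' temporal autocorrelation of the angular fluctuations; falls back to
#' twice the lag of the deepest minimum for standing-type records.
#'
#' @param kymo a `kymo`.
#' @param discard_transient time (s) dropped from the start.
#' @return Period (s), or NA when no recurrence is found.
#' @export
estimate_period <- function(kymo, discard_transient = 0) {
  keep <- kymo$times >= kymo$times[1] + discard_transient
  I <- kymo$I[keep, , drop = FALSE]
  dI <- I - rowMeans(I)
  if (sum(dI^2) == 0) return(NA_real_)
  ac <- temporal_acf(dI)
  dt <- mean(diff(kymo$times[keep]))
  pk <- which(diff(sign(diff(ac))) == -2) + 1
  pk <- pk[ac[pk] > 0.2]
  if (length(pk)) return((pk[1] - 1) * dt)
  tr <- which.min(ac)
  if (ac[tr] < -0.2) return(2 * (tr - 1) * dt)
  NA_real_
}

#' Sliding-window classification and transition detection
#'
#' Classifies overlapping windows of a kymograph and reports the sequence
#' of classes together with detected transitions: a change of class
#' (e.g. standing to traveling) or a sign reversal of the traveling-phase
#' slope (direction reversal) between consecutive windows.
#'
#' @param kymo a `kymo`.
#' @param window window length (s).
#' @param stride window stride (s).
#' @param ... passed to [classify_pattern()].
#' @return An object of class `rac_transitions`: data frame `windows`
#'   (start, mid, class, phase_slope, period) and data frame `events`
#'   (time, type).
#' @export
transition_run <- function(kymo, window, stride = window / 2, ...) {
  stopifnot(inherits(kymo, "kymo"))
  t0 <- kymo$times[1]
  tmax <- max(kymo$times)
  starts <- seq(t0, tmax - window, by = stride)
  if (!length(starts)) stop("record shorter than one window", call. = FALSE)
  rows <- lapply(starts, function(s) {
    sel <- kymo$times >= s & kymo$times <= s + window
    sub <- kymograph(kymo$I[sel, , drop = FALSE], times = kymo$times[sel],
                     phi = kymo$phi, channel = kymo$channel)
    cl <- classify_pattern(sub, ...)
    data.frame(start = s, mid = s + window / 2, class = cl$class,
               phase_slope = cl$phase_slope, period = cl$period,
               stringsAsFactors = FALSE)
  })
  w <- do.call(rbind, rows)
  events <- list()
  last_travel_slope <- NA_real_
  for (i in seq_len(nrow(w))) {
    if (i > 1 && w$class[i] != w$class[i - 1])
      events[[length(events) + 1]] <-
        data.frame(time = w$start[i],
                   type = paste0(w$class[i - 1], "->", w$class[i]))
    if (w$class[i] == "traveling") {
      ## direction reversals are tracked across any intervening windows
      if (!is.na(last_travel_slope) &&
          sign(w$phase_slope[i]) != sign(last_travel_slope))
        events[[length(events) + 1]] <-
          data.frame(time = w$start[i], type = "reversal")
      last_travel_slope <- w$phase_slope[i]
    }
  }
  structure(list(windows = w,
                 events = if (length(events)) do.call(rbind, events)
                          else data.frame(time = numeric(0),
                                          type = character(0))),
            class = "rac_transitions")
}

#' @export
print.rac_transitions <- function(x, ...) {
  cat("windowed classification:\n")
  print(x$windows[, c("mid", "class", "phase_slope")], row.names = FALSE)
  if (nrow(x$events)) {
    cat("events:\n")
    print(x$events, row.names = FALSE)
  }
  invisible(x)
}
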