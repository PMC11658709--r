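#' Kymograph container
#'
#' An intensity (or linear density) matrix over angular position on the cell
#' perimeter and time: rows are time points, columns are uniformly spaced,
#' periodic angular positions.
#'
#' @param I numeric matrix, n_t x m (time x angle).
#' @param times strictly increasing time stamps (s), length n_t.
#' @param phi angular positions in [0, 2 pi), length m, uniform.
#' @param channel optional channel label.
#' @return An object of class `kymo`.
#' @export
kymograph <- function(I, times = seq_len(nrow(I)) - 1,
                      phi = 2 * pi * (seq_len(ncol(I)) - 1) / ncol(I),
                      channel = "") {
  I <- as.matrix(I)
  if (!is.numeric(I) || any(!is.finite(I)))
    stop("kymograph intensities must be finite numbers", call. = FALSE)
  if (length(times) != nrow(I) || length(phi) != ncol(I))
    stop("grid metadata does not match the matrix dimensions", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("time stamps must be strictly increasing", call. = FALSE)
  dphi <- diff(phi)
  if (length(dphi) && max(abs(dphi - dphi[1])) > 1e-8 * abs(dphi[1]))
    stop("angular grid must be uniform", call. = FALSE)
  structure(list(I = unname(I), times = as.numeric(times),
                 phi = as.numeric(phi), channel = channel),
            class = "kymo")
}

#' @export
print.kymo <- function(x, ...) {
  cat(sprintf("kymograph%s: %d time points x %d angular positions, t = [%g, %g] s\n",
              if (nzchar(x$channel)) paste0(" [", x$channel, "]") else "",
              nrow(x$I), ncol(x$I), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
dim.kymo <- function(x) dim(x$I)

#' Write / read a kymograph as delimited text
#'
#' Tab-separated matrix (rows = time) preceded by comment-prefixed header
#' lines carrying the time stamps, angular grid and channel label.
#'
#' @param kymo a `kymo` object.
#' @param path file path.
#' @return `write_kymograph()` returns `path` invisibly; `read_kymograph()`
#'   the reconstructed `kymo`.
#' @export
write_kymograph <- function(kymo, path) {
  stopifnot(inherits(kymo, "kymo"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# channel: ", kymo$channel),
               paste0("# times: ",
                      paste(format(kymo$times, digits = 15, trim = TRUE),
                            collapse = " ")),
               paste0("# phi: ",
                      paste(format(kymo$phi, digits = 15, trim = TRUE),
                            collapse = " "))), con)
  utils::write.table(kymo$I, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(path) {
  hdr <- readLines(path, n = 3)
  channel <- sub("^# channel: ?", "", hdr[1])
  num_fields <- function(line, tag) {
    parts <- strsplit(trimws(sub(tag, "", line)), " +")[[1]]
    as.numeric(parts[nzchar(parts)])
  }
  times <- num_fields(hdr[2], "^# times: ?")
  phi <- num_fields(hdr[3], "^# phi: ?")
  I <- as.matrix(utils::read.table(path, sep = "\t", skip = 3))
  kymograph(I, times = times, phi = phi, channel = channel)
}

#' Interpolate irregular angular samples onto a uniform grid
#'
#' Periodic linear interpolation of per-frame samples taken at irregular
#' angular positions (as produced by contour-tracking tools) onto `m`
#' uniform positions. Samples straddling phi = 0 are handled by wrapping.
#'
#' @param samples list with one entry per frame, each a list/data.frame with
#'   `phi` (radians, any order, no duplicates) and `I` (intensities); or a
#'   matrix of intensities plus a shared `phi` vector.
#' @param m number of uniform angular positions.
#' @param times time stamps (s).
#' @param phi shared angular positions when `samples` is a matrix.
#' @param channel label.
#' @return A `kymo` on the uniform grid.
#' @export
interpolate_to_grid <- function(samples, m = 100, times = NULL, phi = NULL,
                                channel = "") {
  if (is.matrix(samples)) {
    stopifnot(!is.null(phi))
    samples <- lapply(seq_len(nrow(samples)), function(i)
      list(phi = phi, I = samples[i, ]))
  }
  if (is.null(times)) times <- seq_along(samples) - 1
  grid <- 2 * pi * (seq_len(m) - 1) / m
  rows <- lapply(samples, function(s) {
    ph <- s$phi %% (2 * pi)
    if (length(ph) < 4) stop("need at least 4 samples per frame", call. = FALSE)
    if (anyDuplicated(ph)) stop("duplicate angular positions", call. = FALSE)
    o <- order(ph)
    ph <- ph[o]
    v <- s$I[o]
    ## periodic padding on both sides
    php <- c(ph[length(ph)] - 2 * pi, ph, ph[1] + 2 * pi)
    vp <- c(v[length(v)], v, v[1])
    stats::approx(php, vp, xout = grid)$y
  })
  kymograph(do.call(rbind, rows), times = times, phi = grid,
            channel = channel)
}

#' Smooth a kymograph with cubic smoothing splines
#'
#' Fits a cubic smoothing spline along each axis in turn: first along time
#' for every angular position, then along angle for every time point with
#' periodic padding (the spatial axis is wrapped by one period on each side
#' and the central section retained). `spar = 0` reproduces the input
#' (interpolation extreme); larger values smooth more.
#'
#' @param kymo a `kymo`.
#' @param spar smoothing parameter passed to [stats::smooth.spline()]
#'   (0..1 scale).
#' @return The smoothed `kymo`.
#' @export
smooth_kymograph <- function(kymo, spar = 0.5) {
  stopifnot(inherits(kymo, "kymo"))
  I <- kymo$I
  if (stats::sd(I) == 0 || spar == 0) return(kymo)
  nt <- nrow(I)
  m <- ncol(I)
  if (nt >= 4) {
    for (j in seq_len(m)) {
      if (stats::sd(I[, j]) > 0)
        I[, j] <- stats::smooth.spline(kymo$times, I[, j], spar = spar)$y
    }
  }
  if (m >= 4) {
    idx <- c(seq_len(m), seq_len(m), seq_len(m))
    xx <- c(kymo$phi - 2 * pi, kymo$phi, kymo$phi + 2 * pi)
    for (i in seq_len(nt)) {
      v <- I[i, idx]
      if (stats::sd(v) > 0)
        I[i, ] <- stats::smooth.spline(xx, v, spar = spar)$y[m + seq_len(m)]
    }
  }
  kymograph(I, times = kymo$times, phi = kymo$phi, channel = kymo$channel)
}
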