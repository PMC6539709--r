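#' Peak amplitude of a pyroelectric transient
#'
#' The pyroelectric response metric used for active-area mapping: the
#' maximum absolute sample of a (DC-corrected) transient. `"peak_to_peak"`
#' uses max - min instead.
#'
#' @param trace an [oa_trace], baseline-corrected for DC offset.
#' @param metric `"peak_abs"` (default) or `"peak_to_peak"`.
#' @return amplitude in the trace's units.
#' @export
pyro_amplitude <- function(trace, metric = c("peak_abs", "peak_to_peak")) {
  stopifnot(inherits(trace, "oa_trace"))
  metric <- match.arg(metric)
  if (metric == "peak_abs") max(abs(trace$samples))
  else diff(range(trace$samples))
}

#' Assemble an energy-normalized pyroelectric scan map
#'
#' Builds the active-area map of the detector from repeated transients
#' recorded on a lateral position grid: each pixel is the mean over its
#' repeats of pyroelectric amplitude divided by the pulse energy of that
#' shot, and the finished map is normalized to its maximum (so values lie
#' in [0, 1] and the map is invariant under a common scaling of all
#' traces).
#'
#' @param traces a list-matrix (`dim = c(n1, n2)`) whose `[i, j]` element
#'   is a list of [oa_trace] repeats at position `(x1[i], x2[j])`; a single
#'   `oa_trace` per pixel is also accepted.
#' @param pulse_energies pulse energy in J per shot: a single number, a
#'   matrix matching `traces`, or a list-matrix of per-repeat vectors. If
#'   `NULL`, each trace's own `pulse_energy` annotation is used.
#' @param x1_positions,x2_positions numeric position grids in m.
#' @param metric amplitude metric, see [pyro_amplitude()].
#' @return An object of class `oa_scanmap`: list with `x1`, `x2` and the
#'   normalized `amplitude` matrix.
#' @export
assemble_scan_map <- function(traces, pulse_energies = NULL,
                              x1_positions = NULL, x2_positions = NULL,
                              metric = "peak_abs") {
  if (!is.list(traces) || is.null(dim(traces))) {
    stop("traces must be a list-matrix with dim = c(n1, n2)", call. = FALSE)
  }
  d <- dim(traces)
  if (any(d < 1L)) stop("empty scan grid", call. = FALSE)
  if (is.null(x1_positions)) x1_positions <- seq_len(d[1])
  if (is.null(x2_positions)) x2_positions <- seq_len(d[2])
  if (length(x1_positions) != d[1] || length(x2_positions) != d[2]) {
    stop("position grids do not match the trace grid", call. = FALSE)
  }
  amp <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      reps <- traces[[i, j]]
      if (inherits(reps, "oa_trace")) reps <- list(reps)
      if (!length(reps)) stop("pixel with no repeats", call. = FALSE)
      en <- pixel_energies(pulse_energies, reps, i, j)
      if (any(!is.finite(en)) || any(en <= 0)) {
        stop("pulse energies must be positive", call. = FALSE)
      }
      a <- vapply(reps, pyro_amplitude, numeric(1), metric = metric)
      amp[i, j] <- mean(a / en)
    }
  }
  m <- max(amp)
  if (m > 0) amp <- amp / m
  structure(list(x1 = as.numeric(x1_positions),
                 x2 = as.numeric(x2_positions), amplitude = amp),
            class = "oa_scanmap")
}

# Resolve the pulse energies for one pixel's repeats.
pixel_energies <- function(pulse_energies, reps, i, j) {
  if (is.null(pulse_energies)) {
    en <- vapply(reps, function(tr) {
      if (is.null(tr$pulse_energy)) NA_real_ else tr$pulse_energy
    }, numeric(1))
    if (any(is.na(en))) {
      stop("no pulse_energies given and traces lack pulse_energy annotations",
           call. = FALSE)
    }
    en
  } else if (is.numeric(pulse_energies) && length(pulse_energies) == 1L) {
    rep(pulse_energies, length(reps))
  } else if (is.matrix(pulse_energies) && !is.list(pulse_energies)) {
    rep(pulse_energies[i, j], length(reps))
  } else if (is.list(pulse_energies) && !is.null(dim(pulse_energies))) {
    rep_len(as.numeric(pulse_energies[[i, j]]), length(reps))
  } else {
    stop("unsupported pulse_energies layout", call. = FALSE)
  }
}

#' @export
print.oa_scanmap <- function(x, ...) {
  cat(sprintf("<oa_scanmap> %d x %d pixels, x1 span %.4g mm, x2 span %.4g mm\n",
              nrow(x$amplitude), ncol(x$amplitude),
              diff(range(x$x1)) * 1e3, diff(range(x$x2)) * 1e3))
  cat(sprintf("  normalized amplitude range [%.3g, %.3g]\n",
              min(x$amplitude), max(x$amplitude)))
  invisible(x)
}

#' @export
plot.oa_scanmap <- function(x, ...,
                            xlab = "x1 [mm]", ylab = "x2 [mm]") {
  graphics::image(x$x1 * 1e3, x$x2 * 1e3, x$amplitude,
                  xlab = xlab, ylab = ylab, useRaster = TRUE, ...)
  invisible(x)
}

#' Full width at half maximum of a scan-map profile
#'
#' Linear-interpolated FWHM of a 1D cut through the map, used to compare a
#' recovered active-area extent with its design size.
#'
#' @param positions numeric positions in m.
#' @param values profile values (need not be normalized).
#' @return FWHM in m (`NA` if the profile never drops below half maximum
#'   on both sides).
#' @export
profile_fwhm <- function(positions, values) {
  stopifnot(length(positions) == length(values), length(values) >= 3L)
  half <- max(values) / 2
  imax <- which.max(values)
  left <- NA_real_
  for (i in seq(imax, 2L)) {
    if (values[i - 1L] < half) {
      left <- positions[i - 1L] + (positions[i] - positions[i - 1L]) *
        (half - values[i - 1L]) / (values[i] - values[i - 1L])
      break
    }
  }
  right <- NA_real_
  for (i in seq(imax, length(values) - 1L)) {
    if (values[i + 1L] < half) {
      right <- positions[i] + (positions[i + 1L] - positions[i]) *
        (values[i] - half) / (values[i] - values[i + 1L])
      break
    }
  }
  right - left
}

#' Calibrate photodiode readings against a pyroelectric energy reference
#'
#' Least-squares proportional fit through the origin, E = gain * V: zero
#' light gives zero diode voltage, so the map has no intercept.
#'
#' @param diode_readings photodiode voltages (V).
#' @param reference_energies reference pulse energies (J), same length.
#' @return An object of class `oa_energy_cal`: list with `gain` (J/V),
#'   `residuals`, `rse` (residual standard error) and `n`.
#' @export
calibrate_energy <- function(diode_readings, reference_energies) {
  v <- as.numeric(diode_readings)
  e <- as.numeric(reference_energies)
  if (length(v) != length(e)) {
    stop("readings and energies must pair up", call. = FALSE)
  }
  if (length(v) < 2L) {
    stop("need at least 2 paired readings for calibration", call. = FALSE)
  }
  if (all(v == 0)) stop("degenerate calibration: all readings zero",
                        call. = FALSE)
  gain <- sum(v * e) / sum(v * v)
  res <- e - gain * v
  rse <- sqrt(sum(res^2) / (length(v) - 1L))
  structure(list(gain = gain, residuals = res, rse = rse, n = length(v)),
            class = "oa_energy_cal")
}

#' @export
print.oa_energy_cal <- function(x, ...) {
  cat(sprintf("<oa_energy_cal> gain = %.6g J/V (n = %d, RSE = %.3g J)\n",
              x$gain, x$n, x$rse))
  invisible(x)
}

#' @export
predict.oa_energy_cal <- function(object, diode_readings, ...) {
  object$gain * as.numeric(diode_readings)
}
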