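#' Uniformly sampled detector trace
#'
#' `oa_trace` is the package's time-series container: a vector of amplitudes
#' sampled at a fixed interval `dt`, starting at time `t0`. All times are in
#' seconds on the acquisition (DAQ trigger) axis: the trigger defines t = 0
#' and the laser fires at `trigger_delay` seconds, so an acoustic arrival
#' appears at `trigger_delay` plus its time of flight. Amplitudes are volts
#' for raw traces and arbitrary pressure units after deconvolution.
#'
#' @param samples numeric vector of amplitudes (length >= 2, finite).
#' @param dt sampling interval in seconds (> 0).
#' @param t0 time of the first sample in seconds. Default 0.
#' @param trigger_delay laser emission time on the trace axis, seconds
#'   (optional annotation).
#' @param pulse_energy laser pulse energy in joules (optional annotation).
#' @param units amplitude unit label, e.g. `"V"` or `"a.u."`.
#' @return An object of class `oa_trace`.
#' @examples
#' tr <- oa_trace(sin(2 * pi * 1e6 * seq(0, 1e-5, by = 4e-9)), dt = 4e-9)
#' tr
#' @export
oa_trace <- function(samples, dt, t0 = 0, trigger_delay = NULL,
                     pulse_energy = NULL, units = "V") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) {
    stop("an oa_trace needs at least two samples", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("trace samples must be finite", call. = FALSE)
  }
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("dt must be a single positive number (seconds)", call. = FALSE)
  }
  structure(
    list(samples = samples, dt = as.numeric(dt), t0 = as.numeric(t0),
         trigger_delay = if (is.null(trigger_delay)) NULL else as.numeric(trigger_delay),
         pulse_energy = if (is.null(pulse_energy)) NULL else as.numeric(pulse_energy),
         units = units),
    class = "oa_trace")
}

#' Sample times of a trace
#'
#' @param trace an [oa_trace].
#' @return numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "oa_trace"))
  trace$t0 + (seq_along(trace$samples) - 1) * trace$dt
}

#' @export
length.oa_trace <- function(x) length(x$samples)

#' @export
print.oa_trace <- function(x, ...) {
  n <- length(x$samples)
  span <- (n - 1) * x$dt
  cat(sprintf("<oa_trace> %d samples @ %.4g ns, t0 = %.4g us, span = %.4g us [%s]\n",
              n, x$dt * 1e9, x$t0 * 1e6, span * 1e6, x$units))
  if (!is.null(x$trigger_delay)) {
    cat(sprintf("  trigger_delay = %.4g us", x$trigger_delay * 1e6))
    if (!is.null(x$pulse_energy)) {
      cat(sprintf(", pulse_energy = %.4g mJ", x$pulse_energy * 1e3))
    }
    cat("\n")
  }
  cat(sprintf("  amplitude range [%.4g, %.4g]\n",
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
as.data.frame.oa_trace <- function(x, ...) {
  data.frame(time = trace_times(x), amplitude = x$samples)
}

#' @export
plot.oa_trace <- function(x, ..., xlab = "time [µs]", ylab = NULL,
                          type = "l") {
  if (is.null(ylab)) ylab <- sprintf("amplitude [%s]", x$units)
  graphics::plot(trace_times(x) * 1e6, x$samples, type = type,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

# Internal: check two traces share a sampling interval (relative tolerance).
same_dt <- function(a, b, tol = 1e-9) {
  abs(a$dt - b$dt) <= tol * max(a$dt, b$dt)
}
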