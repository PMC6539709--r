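#' Signal mask: intervals containing optoacoustic signal
#'
#' A set of half-open time intervals `[start, end)` flagged as containing
#' acoustic signal. The pyroelectric baseline fit excludes these intervals;
#' everything outside them is treated as baseline-only. Overlapping or
#' touching intervals are merged on construction.
#'
#' @param starts,ends numeric vectors of equal length, interval edges in s.
#' @return An object of class `signal_mask` (data frame with `start`,
#'   `end`).
#' @seealso [propose_signal_mask()] to derive a mask from predicted echo
#'   arrival times.
#' @export
signal_mask <- function(starts = numeric(0), ends = numeric(0)) {
  starts <- as.numeric(starts)
  ends <- as.numeric(ends)
  if (length(starts) != length(ends)) {
    stop("starts and ends must have equal length", call. = FALSE)
  }
  if (any(ends < starts)) stop("interval end before start", call. = FALSE)
  if (length(starts)) {
    o <- order(starts)
    starts <- starts[o]
    ends <- ends[o]
    ks <- starts[1]
    ke <- ends[1]
    ms <- numeric(0)
    me <- numeric(0)
    if (length(starts) > 1L) {
      for (i in 2:length(starts)) {
        if (starts[i] <= ke) {
          ke <- max(ke, ends[i])
        } else {
          ms <- c(ms, ks); me <- c(me, ke)
          ks <- starts[i]; ke <- ends[i]
        }
      }
    }
    starts <- c(ms, ks)
    ends <- c(me, ke)
  }
  structure(data.frame(start = starts, end = ends),
            class = c("signal_mask", "data.frame"))
}

#' @export
print.signal_mask <- function(x, ...) {
  cat(sprintf("<signal_mask> %d interval(s)\n", nrow(x)))
  if (nrow(x)) {
    cat(paste(sprintf("  [%.4g, %.4g) us", x$start * 1e6, x$end * 1e6),
              collapse = "\n"), "\n")
  }
  invisible(x)
}

# Internal: logical vector, TRUE where a trace sample falls inside the mask.
mask_membership <- function(trace, mask) {
  tt <- trace_times(trace)
  inside <- rep(FALSE, length(tt))
  if (!is.null(mask) && nrow(mask)) {
    for (i in seq_len(nrow(mask))) {
      inside <- inside | (tt >= mask$start[i] & tt < mask$end[i])
    }
  }
  inside
}

#' Remove the pyroelectric baseline from a raw trace
#'
#' Direct light absorption in the piezoelectric film produces a slow
#' pyroelectric voltage valley that overlays the acoustic signal. Its
#' precise shape depends on uncontrolled factors (e.g. sample capacitance),
#' so it is treated as an unknown smooth background: a polynomial of the
#' given order is least-squares fitted to the samples *outside* the signal
#' mask and subtracted from the whole trace. The fit uses times rescaled to
#' [-1, 1] for conditioning (an identical projection). The operation is a
#' projection: applying it twice with the same mask and order equals
#' applying it once.
#'
#' @param trace an [oa_trace].
#' @param mask a [signal_mask()] of intervals excluded from the fit
#'   (may be empty).
#' @param order polynomial order (default 10).
#' @return the baseline-subtracted [oa_trace].
#' @export
remove_pyroelectric_baseline <- function(trace, mask = signal_mask(),
                                         order = 10L) {
  stopifnot(inherits(trace, "oa_trace"))
  if (order < 0) stop("order must be >= 0", call. = FALSE)
  order <- as.integer(order)
  inside <- mask_membership(trace, mask)
  keep <- !inside
  if (sum(keep) < order + 1L) {
    stop(sprintf("baseline fit needs at least %d unmasked samples, have %d",
                 order + 1L, sum(keep)), call. = FALSE)
  }
  tt <- trace_times(trace)
  mid <- (tt[1] + tt[length(tt)]) / 2
  halfspan <- (tt[length(tt)] - tt[1]) / 2
  x <- (tt - mid) / halfspan
  y <- trace$samples
  if (order == 0L) {
    baseline <- rep(mean(y[keep]), length(y))
  } else {
    pb <- stats::poly(x[keep], degree = order)
    fit <- stats::lm.fit(cbind(1, unclass(pb)), y[keep])
    Xall <- cbind(1, unclass(stats::predict(pb, x)))
    baseline <- drop(Xall %*% fit$coefficients)
  }
  out <- trace
  out$samples <- y - baseline
  out
}

#' Butterworth time-domain window
#'
#' Multiplies a trace by the maximally flat window
#' W(t) = 1 / sqrt(1 + ((t - center)/half_width)^(2*order)):
#' unit gain at the center, 1/sqrt(2) at `center +/- half_width`, and a
#' smooth monotone roll-off that avoids the spectral artifacts a sharp
#' rectangular cut would create.
#'
#' @param trace an [oa_trace].
#' @param center window center in s.
#' @param half_width half-width (the -3 dB half-extent) in s, > 0.
#' @param order window order (>= 1, default 4).
#' @return the windowed [oa_trace].
#' @export
butterworth_time_window <- function(trace, center, half_width, order = 4L) {
  stopifnot(inherits(trace, "oa_trace"))
  if (half_width <= 0) stop("half_width must be > 0", call. = FALSE)
  if (order < 1) stop("order must be >= 1", call. = FALSE)
  tt <- trace_times(trace)
  if (center + half_width < tt[1] || center - half_width > tt[length(tt)]) {
    stop("window does not overlap the trace", call. = FALSE)
  }
  w <- butterworth_gain((tt - center), half_width, order)
  out <- trace
  out$samples <- trace$samples * w
  out
}

# |H| of a Butterworth magnitude response: 1/sqrt(1 + (u/u_c)^(2n)).
butterworth_gain <- function(u, u_c, order) {
  1 / sqrt(1 + abs(u / u_c)^(2 * order))
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies the Butterworth magnitude response
#' |H(f)| = 1 / sqrt(1 + (f/cutoff)^(2*order)) as a real, zero-phase mask
#' on the two-sided FFT spectrum of the trace, so peak timing is preserved
#' exactly. DC gain is 1 and the gain at the cutoff is 1/sqrt(2).
#'
#' @param trace an [oa_trace].
#' @param cutoff -3 dB cutoff frequency in Hz (default 20 MHz); must be
#'   below the Nyquist frequency `1/(2 dt)`.
#' @param order filter order (>= 1, default 4).
#' @return the filtered [oa_trace].
#' @export
butterworth_lowpass <- function(trace, cutoff = 20e6, order = 4L) {
  stopifnot(inherits(trace, "oa_trace"))
  if (cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  nyq <- 1 / (2 * trace$dt)
  if (cutoff >= nyq) {
    stop(sprintf("cutoff (%.3g Hz) must be below Nyquist (%.3g Hz)",
                 cutoff, nyq), call. = FALSE)
  }
  if (order < 1) stop("order must be >= 1", call. = FALSE)
  out <- trace
  out$samples <- lowpass_samples(trace$samples, trace$dt, cutoff, order)
  out
}

# Internal: zero-phase Butterworth magnitude mask on a sample vector.
lowpass_samples <- function(y, dt, cutoff, order) {
  n <- length(y)
  f <- fft_frequencies(n, dt)
  H <- butterworth_gain(f, cutoff, order)
  Re(stats::fft(stats::fft(y) * H, inverse = TRUE)) / n
}

# Two-sided FFT frequency grid (Hz) matching stats::fft ordering.
fft_frequencies <- function(n, dt) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k / (n * dt)
}

#' Extract the instrument response function from a delta-source trace
#'
#' Runs the IRF signal chain on the raw trace of a quasi-delta optoacoustic
#' source (a strongly absorbing thick sample): (1) pyroelectric baseline
#' removal by masked polynomial fit, (2) Butterworth time-domain window
#' around the primary pulse, which suppresses the sample's boundary
#' reflections, leaving the trace zero-padded to its original length
#' outside the window. The result is the system's recorded response to a
#' delta-like pressure input, used by [deconvolve()].
#'
#' @param trace raw [oa_trace] of the delta-source measurement.
#' @param mask [signal_mask()] of acoustic-signal regions excluded from the
#'   baseline fit.
#' @param center,half_width,order time-window parameters as in
#'   [butterworth_time_window()]; if `center` is `NULL` the strongest peak
#'   inside the mask's first interval (or the whole trace) is used.
#' @param baseline_order pyroelectric polynomial order (default 10).
#' @param snr_min minimum peak-to-noise ratio for a pulse to count as
#'   detected (default 5); noise is the robust SD of the baseline-removed
#'   samples outside the window.
#' @return An object of class `oa_irf`: list with the windowed `kernel`
#'   ([oa_trace]), `reference_arrival` (peak time, s), and the processing
#'   provenance (`window`, `mask`, `baseline_order`).
#' @export
extract_irf <- function(trace, mask, center = NULL, half_width,
                        order = 4L, baseline_order = 10L, snr_min = 5) {
  stopifnot(inherits(trace, "oa_trace"))
  cleaned <- remove_pyroelectric_baseline(trace, mask, order = baseline_order)
  tt <- trace_times(cleaned)
  if (is.null(center)) {
    search <- if (!is.null(mask) && nrow(mask)) {
      tt >= mask$start[1] & tt < mask$end[1]
    } else rep(TRUE, length(tt))
    center <- tt[search][which.max(abs(cleaned$samples[search]))]
  }
  in_window <- abs(tt - center) <= half_width
  noise_sd <- robust_sd(cleaned$samples[!in_window])
  peak <- max(abs(cleaned$samples[in_window]))
  if (peak <= 0 || (noise_sd > 0 && peak < snr_min * noise_sd)) {
    stop("no detectable pulse in the IRF window (peak below noise floor)",
         call. = FALSE)
  }
  kernel <- butterworth_time_window(cleaned, center, half_width, order)
  pk <- max(abs(kernel$samples))
  ends <- abs(kernel$samples[c(1L, length(kernel$samples))])
  if (any(ends > 0.01 * pk)) {
    stop(paste("window too wide: kernel endpoints exceed 1% of the peak;",
               "reduce half_width or increase order"), call. = FALSE)
  }
  ref <- tt[which.max(abs(kernel$samples))]
  structure(list(kernel = kernel, reference_arrival = ref,
                 window = list(center = center, half_width = half_width,
                               order = as.integer(order)),
                 mask = mask, baseline_order = as.integer(baseline_order)),
            class = "oa_irf")
}

robust_sd <- function(x) {
  if (!length(x)) return(0)
  stats::mad(x, center = stats::median(x))
}

#' @export
print.oa_irf <- function(x, ...) {
  cat(sprintf("<oa_irf> kernel of %d samples @ %.4g ns\n",
              length(x$kernel$samples), x$kernel$dt * 1e9))
  cat(sprintf("  reference arrival %.4g us; window center %.4g us, half-width %.4g us (order %d)\n",
              x$reference_arrival * 1e6, x$window$center * 1e6,
              x$window$half_width * 1e6, x$window$order))
  invisible(x)
}

#' Deconvolve a trace with the instrument response function
#'
#' Recovers the pressure profile that produced a measured trace by spectral
#' division: the FFT of the (baseline-removed) signal is divided by the FFT
#' of the IRF kernel, a zero-phase Butterworth low-pass suppresses the
#' bands where the division would amplify noise, and the result is
#' back-transformed. Denominator magnitudes below
#' `epsilon * max|FFT(irf)|` are clamped to that floor (phase preserved) to
#' stabilize the division.
#'
#' Time alignment of the output (`align`):
#' \describe{
#'   \item{`"irf"`}{(default) lag 0 of the division is placed at the IRF's
#'     `reference_arrival`, so a signal recorded with the same system
#'     reads in absolute trace time.}
#'   \item{`"first_peak"`}{the strongest output peak is shifted to t = 0,
#'     the convention used when comparing a deconvolved measurement with a
#'     simulation.}
#'   \item{`"none"`}{raw circular-division time base starting at the
#'     signal's `t0`.}
#' }
#'
#' @param signal baseline-removed [oa_trace] to deconvolve.
#' @param irf an [extract_irf()] result (or an `oa_irf`-like list with a
#'   `kernel` trace).
#' @param cutoff,order frequency-domain Butterworth low-pass parameters
#'   (defaults 20 MHz, order 4).
#' @param epsilon spectral-division floor relative to the IRF spectrum
#'   maximum (default 1e-3).
#' @param align output time-axis convention, see Details.
#' @return the deconvolved [oa_trace] (arbitrary pressure units).
#' @export
deconvolve <- function(signal, irf, cutoff = 20e6, order = 4L,
                       epsilon = 1e-3, align = c("irf", "first_peak", "none")) {
  stopifnot(inherits(signal, "oa_trace"), inherits(irf, "oa_irf"))
  align <- match.arg(align)
  kernel <- irf$kernel
  if (!same_dt(signal, kernel)) {
    stop("signal and IRF sampling intervals differ", call. = FALSE)
  }
  if (!any(kernel$samples != 0)) stop("all-zero IRF kernel", call. = FALSE)
  n <- length(signal$samples)
  k <- kernel$samples
  if (length(k) < n) {
    k <- c(k, numeric(n - length(k)))
  } else if (length(k) > n) {
    stop("IRF kernel longer than the signal; re-extract on a matching span",
         call. = FALSE)
  }
  S <- stats::fft(signal$samples)
  K <- stats::fft(k)
  magK <- Mod(K)
  floor_mag <- epsilon * max(magK)
  scale <- pmax(magK, floor_mag)
  Kc <- ifelse(magK > 0, K * (scale / magK), floor_mag)
  H <- butterworth_gain(fft_frequencies(n, signal$dt), cutoff, order)
  D <- H * S / Kc
  y <- Re(stats::fft(D, inverse = TRUE)) / n
  # The division removes the kernel's position within its own trace, so lag
  # zero corresponds to events at (kernel position). Relate lags to signal
  # time through the IRF reference arrival.
  lag0_time <- irf$reference_arrival - kernel$t0 + signal$t0
  out <- oa_trace(y, dt = signal$dt, t0 = signal$t0, units = "a.u.",
                  trigger_delay = signal$trigger_delay)
  if (align == "irf") {
    out$t0 <- lag0_time
  } else if (align == "first_peak") {
    ip <- which.max(abs(y))
    # interpret late indices as negative (circular) lags
    lag <- if (ip - 1L > n / 2) ip - 1L - n else ip - 1L
    out$t0 <- -lag * signal$dt
  }
  out
}

#' Axial resolution and absorption-coefficient limits
#'
#' Closed-form resolution bookkeeping for a band-limited optoacoustic
#' system: a low-pass cutoff `f_c` admits signal features no shorter than
#' `1/f_c` in time, i.e. `c/f_c` in depth; a source shallower than that
#' cannot be resolved, which translates into a minimum resolvable optical
#' absorption coefficient `f_c/c`. Independently, a detector film of finite
#' thickness cannot resolve signals shorter than its own transit, bounding
#' the absorption coefficient at `1/thickness`.
#'
#' @param cutoff low-pass cutoff frequency in Hz.
#' @param sound_velocity sound velocity of the absorber in m/s.
#' @param detector_thickness detector film thickness in m.
#' @return list with `min_duration` (s), `min_depth` (m),
#'   `min_mu_a_cutoff` (1/m), `min_mu_a_detector` (1/m).
#' @examples
#' lim <- resolution_limits(20e6, 2150, 10e-6)
#' lim$min_duration * 1e9   # 50 ns
#' lim$min_depth * 1e3      # 0.1075 mm
#' @export
resolution_limits <- function(cutoff, sound_velocity, detector_thickness) {
  vals <- c(cutoff, sound_velocity, detector_thickness)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all inputs must be positive and finite", call. = FALSE)
  }
  min_duration <- 1 / cutoff
  min_depth <- min_duration * sound_velocity
  list(min_duration = min_duration,
       min_depth = min_depth,
       min_mu_a_cutoff = 1 / min_depth,
       min_mu_a_detector = 1 / detector_thickness)
}
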