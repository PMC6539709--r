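#' Specification for a synthetic raw trace
#'
#' Collects everything needed to generate a seeded synthetic detector
#' trace that mimics a real acquisition: the simulated optoacoustic
#' pressure at the detector, blurred by a band-limited detector kernel,
#' overlaid with a slow pyroelectric valley and additive Gaussian noise.
#' Because every component is constructed, the generator returns the exact
#' ground truth alongside the trace, giving every pipeline stage an
#' oracle.
#'
#' Defaults describe a realistic acquisition for this probe class:
#' 250 MS/s sampling (Nyquist 125 MHz, far above the 20 MHz processing
#' band), a 20 MHz detector bandwidth, a 1.12 us laser-to-trigger delay,
#' a broad pyroelectric valley starting at the laser shot (4 us decay
#' scale) of 0.2 V depth, 2 mV RMS noise, 50 J/m^2 fluence and a
#' 1e-7 V/Pa detector gain (the absolute scale is arbitrary).
#'
#' @param stack an [layer_stack()]; layers with `mu_a > 0` act as sources.
#' @param seed integer seed; a fixed seed makes the output byte-identical.
#' @param sample_rate acquisition rate in samples/s.
#' @param duration trace length in s (trigger axis).
#' @param kernel_bandwidth detector -3 dB bandwidth in Hz.
#' @param kernel_shape `"lowpassed-delta"` (default) or
#'   `"gaussian-derivative"`.
#' @param pyro_depth pyroelectric valley depth in V (0 disables it).
#' @param pyro_onset valley onset in s; defaults to `trigger_delay` (the
#'   film heats at the laser shot).
#' @param pyro_timescale valley decay time scale in s.
#' @param noise_sd additive Gaussian noise SD in V.
#' @param trigger_delay laser emission time on the trace axis, s.
#' @param fluence surface fluence in J/m^2.
#' @param gain detector sensitivity in V/Pa.
#' @return An object of class `oa_synth_spec`.
#' @export
synth_spec <- function(stack, seed = 1L, sample_rate = 250e6,
                       duration = 6e-6, kernel_bandwidth = 20e6,
                       kernel_shape = c("lowpassed-delta",
                                        "gaussian-derivative"),
                       pyro_depth = 0.2, pyro_onset = NULL,
                       pyro_timescale = 4e-6, noise_sd = 2e-3,
                       trigger_delay = 1.12e-6, fluence = 50,
                       gain = 1e-7) {
  stopifnot(inherits(stack, "oa_stack"))
  kernel_shape <- match.arg(kernel_shape)
  if (is.null(pyro_onset)) pyro_onset <- trigger_delay
  for (nm in c("sample_rate", "duration", "kernel_bandwidth",
               "pyro_timescale", "trigger_delay", "gain")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("%s must be a single positive number", nm), call. = FALSE)
    }
  }
  if (pyro_depth < 0 || noise_sd < 0 || fluence < 0) {
    stop("pyro_depth, noise_sd and fluence must be >= 0", call. = FALSE)
  }
  if (kernel_bandwidth >= sample_rate / 2) {
    stop("kernel_bandwidth must be below the Nyquist frequency",
         call. = FALSE)
  }
  structure(list(stack = stack, seed = as.integer(seed),
                 sample_rate = sample_rate, duration = duration,
                 kernel_bandwidth = kernel_bandwidth,
                 kernel_shape = kernel_shape, pyro_depth = pyro_depth,
                 pyro_onset = pyro_onset, pyro_timescale = pyro_timescale,
                 noise_sd = noise_sd, trigger_delay = trigger_delay,
                 fluence = fluence, gain = gain),
            class = "oa_synth_spec")
}

#' Synthetic detector kernel (instrument response)
#'
#' Deterministically builds a unit-peak kernel whose spectral magnitude
#' falls to 1/sqrt(2) at the requested bandwidth, standing in for the
#' measured delta-source response. `"lowpassed-delta"` low-passes a single-
#' sample impulse with a zero-phase Butterworth mask (order 4), so its
#' -3 dB point equals the requested bandwidth by construction;
#' `"gaussian-derivative"` is the bipolar N-shaped pulse typical of
#' thin-layer optoacoustic sources, with its width calibrated to the same
#' -3 dB definition.
#'
#' @param spec an [synth_spec()].
#' @return the kernel as an [oa_trace] (time axis centred near 0, peak
#'   magnitude 1).
#' @export
make_synthetic_irf <- function(spec) {
  stopifnot(inherits(spec, "oa_synth_spec"))
  dt <- 1 / spec$sample_rate
  bw <- spec$kernel_bandwidth
  if (bw >= 1 / (2 * dt)) stop("bandwidth at or above Nyquist", call. = FALSE)
  if (spec$kernel_shape == "lowpassed-delta") {
    half <- max(8L, ceiling(5 / bw / dt))
    nbig <- 8L * half           # generous support so truncation is negligible
    y <- numeric(nbig)
    y[nbig / 2L] <- 1
    y <- lowpass_samples(y, dt, bw, order = 4L)
    idx <- (nbig / 2L - half):(nbig / 2L + half)
    y <- y[idx]
  } else {
    # u exp(-u^2/2) with u = 2*pi*sigma*f peaks at u = 1; the upper -3 dB
    # point u3 solves u exp(-u^2/2) = exp(-1/2)/sqrt(2)
    u3 <- stats::uniroot(function(u) u * exp(-u^2 / 2) - exp(-0.5) / sqrt(2),
                         c(1, 4), tol = 1e-12)$root
    sigma <- u3 / (2 * pi * bw)
    half <- max(8L, ceiling(6 * sigma / dt))
    tt <- (-half:half) * dt
    y <- -tt / sigma * exp(-tt^2 / (2 * sigma^2))
  }
  y <- y / max(abs(y))
  oa_trace(y, dt = dt, t0 = -(length(y) - 1) / 2 * dt, units = "V")
}

# Measured -3 dB bandwidth of a kernel trace (zero-padded FFT magnitude).
kernel_bandwidth_measured <- function(kernel, pad = 16L) {
  y <- kernel$samples
  n <- length(y) * pad
  mag <- Mod(stats::fft(c(y, numeric(n - length(y)))))
  f <- fft_frequencies(n, kernel$dt)
  pos <- f >= 0
  mag <- mag[pos]
  f <- f[pos]
  o <- order(f)
  mag <- mag[o]
  f <- f[o]
  ipk <- which.max(mag)
  target <- mag[ipk] / sqrt(2)
  above <- which(mag[ipk:length(mag)] < target)[1]
  if (is.na(above)) return(NA_real_)
  i2 <- ipk + above - 1L
  i1 <- i2 - 1L
  f[i1] + (f[i2] - f[i1]) * (mag[i1] - target) / (mag[i1] - mag[i2])
}

#' Generate a synthetic raw trace with ground truth
#'
#' Builds `trace = (simulated pressure delayed by the trigger delay)
#' convolved with the synthetic kernel + pyroelectric valley + Gaussian
#' noise`, returning every component so downstream processing can be
#' checked against exact ground truth. The pyroelectric valley is a smooth
#' difference of exponentials starting at `pyro_onset` — any low-order
#' smooth shape a 10th-order polynomial can absorb is a faithful stand-in
#' for the unmodelled physical drift.
#'
#' @param spec an [synth_spec()].
#' @param grid optional [simulation_grid()] for the forward simulation
#'   (built from the stack by default); pass one to reuse between calls.
#' @return list with `trace` (the noisy raw [oa_trace]) and `truth`, a
#'   list holding `pressure` (delayed, resampled, gain-scaled noise-free
#'   pressure), `kernel`, `oa` (pressure convolved with kernel), `drift`,
#'   `noiseless` (`oa + drift`) and `first_arrival` (s, trigger axis).
#' @export
synth_raw_trace <- function(spec, grid = NULL) {
  stopifnot(inherits(spec, "oa_synth_spec"))
  dt <- 1 / spec$sample_rate
  n <- as.integer(floor(spec$duration / dt)) + 1L
  t_acq <- (seq_len(n) - 1) * dt

  mu <- stack_mu_a(spec$stack)
  has_source <- any(mu > 0)
  pressure <- numeric(n)
  first_arrival <- NA_real_
  if (has_source) {
    if (is.null(grid)) grid <- simulation_grid(spec$stack)
    p0 <- initial_pressure_profile(spec$stack, grid, fluence = spec$fluence)
    sim_dur <- spec$duration - spec$trigger_delay
    if (sim_dur <= 0) stop("duration must exceed the trigger delay",
                           call. = FALSE)
    sim <- fd_simulate(spec$stack, p0, grid, duration = sim_dur)
    pressure <- stats::approx(trace_times(sim) + spec$trigger_delay,
                              sim$samples, xout = t_acq,
                              yleft = 0, yright = 0)$y * spec$gain
    # direct transit from the nearest source cell to the detector cell
    src <- which(p0$p0 > 0)
    det <- grid$detector_cell
    nearest <- src[which.min(abs(src - det))]
    cells <- if (nearest >= det) det:nearest else nearest:det
    cells <- setdiff(cells, nearest)  # source cell itself emits at t = 0
    first_arrival <- spec$trigger_delay + sum(grid$dx / grid$c[cells])
  }

  kernel <- make_synthetic_irf(spec)
  oa <- convolve_aligned(pressure, kernel$samples)

  drift <- numeric(n)
  if (spec$pyro_depth > 0) {
    tau_d <- spec$pyro_timescale
    tau_r <- spec$pyro_timescale / 2
    u <- t_acq - spec$pyro_onset
    g <- ifelse(u > 0, exp(-u / tau_d) - exp(-u / tau_r), 0)
    drift <- -spec$pyro_depth * g / max(g)
  }

  noise <- numeric(n)
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed, stats::rnorm(n, sd = spec$noise_sd))
  }

  mk <- function(y, units = "V") {
    oa_trace(y, dt = dt, t0 = 0, trigger_delay = spec$trigger_delay,
             units = units)
  }
  list(trace = mk(oa + drift + noise),
       truth = list(pressure = mk(pressure), kernel = kernel,
                    oa = mk(oa), drift = mk(drift),
                    noiseless = mk(oa + drift),
                    first_arrival = first_arrival))
}

# Linear convolution of a signal with a kernel, output aligned so the
# kernel's peak acts at lag zero (an impulse in x stays at its index).
convolve_aligned <- function(x, k) {
  n <- length(x)
  m <- which.max(abs(k))
  full <- stats::convolve(x, rev(k), type = "open")  # length n + length(k) - 1
  full[m:(m + n - 1L)]
}

# Evaluate an expression under a fixed RNG seed, restoring global state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
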