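make_poly_trace <- function(n = 800, dt = 4e-9, coefs = c(0.2, -1, 3, -2, 1,
                                                          0.5, -0.3, 0.2,
                                                          -0.1, 0.05, 0.01)) {
  tt <- (0:(n - 1)) * dt
  x <- (tt - mean(range(tt))) / (diff(range(tt)) / 2)
  y <- drop(outer(x, 0:(length(coefs) - 1), "^") %*% coefs)
  oa_trace(y, dt = dt)
}

test_that("baseline removal annihilates polynomials up to order 10", {
  tr <- make_poly_trace()
  out <- remove_pyroelectric_baseline(tr, signal_mask(), order = 10)
  expect_lt(max(abs(out$samples)), 1e-8 * max(abs(tr$samples)))
})

test_that("baseline removal is a projection (idempotent) and linear", {
  set.seed(4)
  n <- 600
  tr <- oa_trace(rnorm(n), dt = 4e-9)
  mask <- signal_mask(0.4e-6, 0.9e-6)
  once <- remove_pyroelectric_baseline(tr, mask)
  twice <- remove_pyroelectric_baseline(once, mask)
  expect_equal(twice$samples, once$samples, tolerance = 1e-9)
  # commutes with scalar multiplication
  tr3 <- tr
  tr3$samples <- 3.7 * tr$samples
  out3 <- remove_pyroelectric_baseline(tr3, mask)
  expect_equal(out3$samples, 3.7 * once$samples, tolerance = 1e-9)
})

test_that("a masked pulse riding on a polynomial is recovered undistorted", {
  tr <- make_poly_trace(n = 1000)
  tt <- trace_times(tr)
  pulse <- exp(-((tt - 2e-6) / 4e-8)^2)
  with_pulse <- tr
  with_pulse$samples <- tr$samples + pulse
  mask <- signal_mask(1.8e-6, 2.2e-6)
  out <- remove_pyroelectric_baseline(with_pulse, mask)
  sel <- tt >= 1.8e-6 & tt < 2.2e-6
  expect_lt(max(abs(out$samples[sel] - pulse[sel])), 0.01 * max(pulse))
})

test_that("baseline fit demands enough unmasked samples", {
  tr <- oa_trace(rnorm(30), dt = 4e-9)
  full <- signal_mask(0, 1)    # masks everything
  expect_error(remove_pyroelectric_baseline(tr, full), "unmasked")
  expect_error(remove_pyroelectric_baseline(tr, signal_mask(), order = -1),
               "order")
})

test_that("the Butterworth time window has unit center gain and -3 dB edges", {
  n <- 1001
  dt <- 4e-9
  tr <- oa_trace(rep(1, n), dt = dt)
  center <- 2e-6
  hw <- 0.5e-6
  out <- butterworth_time_window(tr, center, hw, order = 4)
  tt <- trace_times(tr)
  expect_equal(out$samples[which.min(abs(tt - center))], 1, tolerance = 1e-9)
  for (edge in c(center - hw, center + hw)) {
    expect_equal(out$samples[which.min(abs(tt - edge))], 1 / sqrt(2),
                 tolerance = 1e-3)
  }
  # monotone suppression away from the center
  right <- out$samples[tt >= center]
  expect_true(all(diff(right) <= 1e-12))
  expect_error(butterworth_time_window(tr, center, -1e-7), "half_width")
  expect_error(butterworth_time_window(tr, 1, 1e-7), "overlap")
})

test_that("windowed constant integrates to the analytic window area", {
  # integral of W(t) dt over the trace vs adaptive quadrature of the same
  n <- 4001
  dt <- 2e-9
  tr <- oa_trace(rep(1, n), dt = dt)
  center <- (n - 1) / 2 * dt
  hw <- 0.4e-6
  out <- butterworth_time_window(tr, center, hw, order = 4)
  got <- sum(out$samples) * dt
  W <- function(t) 1 / sqrt(1 + ((t - center) / hw)^8)
  want <- stats::integrate(W, 0, (n - 1) * dt, rel.tol = 1e-10)$value
  # trapezoid-vs-exact edge effects only; interior is exact sampling
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("frequency-domain Butterworth: DC gain 1, cutoff -3 dB, monotone", {
  n <- 2000
  dt <- 4e-9
  fc <- 20e6
  tt <- (0:(n - 1)) * dt
  # DC unchanged
  dc <- butterworth_lowpass(oa_trace(rep(2.5, n), dt = dt), fc, order = 4)
  expect_equal(dc$samples, rep(2.5, n), tolerance = 1e-9)
  # sinusoid exactly at an FFT bin equal to the cutoff
  k <- round(fc * n * dt)
  f_bin <- k / (n * dt)
  s <- sin(2 * pi * f_bin * tt)
  out <- butterworth_lowpass(oa_trace(s, dt = dt), cutoff = f_bin, order = 4)
  ratio <- max(abs(out$samples)) / max(abs(s))
  expect_equal(ratio, 1 / sqrt(2), tolerance = 0.01)
  # gain is non-increasing in frequency for random orders and cutoffs
  set.seed(9)
  f <- seq(0, 1 / (2 * dt), length.out = 500)
  for (i in 1:20) {
    ord <- sample(1:8, 1)
    fc_i <- runif(1, 1e6, 1e8)
    g <- 1 / sqrt(1 + (f / fc_i)^(2 * ord))
    expect_true(all(diff(g) <= 0))
  }
  expect_error(butterworth_lowpass(oa_trace(s, dt = dt), cutoff = 1 / dt),
               "Nyquist")
})

test_that("white noise filtered at order 4 leaks < 1% power above 2x cutoff", {
  set.seed(21)
  n <- 8192
  dt <- 4e-9
  fc <- 20e6
  tr <- oa_trace(rnorm(n), dt = dt)
  out <- butterworth_lowpass(tr, fc, order = 4)
  spec_out <- Mod(stats::fft(out$samples))^2
  f <- abs(oadepth:::fft_frequencies(n, dt))
  frac <- sum(spec_out[f > 2 * fc]) / sum(spec_out)
  # analytic expectation: integral of |H|^2 above 2 fc ~ 0.2% of total
  expect_lt(frac, 0.01)
})

test_that("IRF extraction recovers a known kernel and validates its window", {
  st <- black_plastic_stack()
  spec <- synth_spec(st, seed = 7)
  syn <- synth_raw_trace(spec)
  mask <- propose_signal_mask(st, source_boundary = 5,
                              trigger_delay = spec$trigger_delay,
                              half_width = 0.12e-6, max_reflections = 2,
                              amplitude_floor = 5e-3)
  irf <- extract_irf(syn$trace, mask, half_width = 0.25e-6)
  # endpoints suppressed below 1% of the kernel peak
  k <- irf$kernel$samples
  expect_lt(max(abs(k[c(1, length(k))])), 0.01 * max(abs(k)))
  # the extracted kernel matches the true kernel shape inside the window:
  # compare against truth OA component (kernel convolved with the nearly
  # delta-like pressure), normalized RMS inside the window
  tt <- trace_times(syn$trace)
  win <- abs(tt - irf$window$center) <= irf$window$half_width
  truth <- syn$truth$oa$samples
  scale <- max(abs(truth[win]))
  expect_lt(sqrt(mean((k[win] - truth[win])^2)) / scale, 0.05)
  # reference arrival sits at the primary-pulse peak
  expect_lt(abs(irf$reference_arrival - syn$truth$first_arrival),
            2 * syn$trace$dt)
})

test_that("IRF extraction refuses a signal-free trace", {
  set.seed(3)
  tr <- oa_trace(rnorm(2000, sd = 1e-3), dt = 4e-9)
  expect_error(extract_irf(tr, signal_mask(3e-6, 4e-6), center = 3.5e-6,
                           half_width = 0.3e-6),
               "no detectable pulse")
})

test_that("self-deconvolution gives a single compact peak at the reference", {
  st <- black_plastic_stack()
  spec <- synth_spec(st, seed = 3)
  k <- make_synthetic_irf(spec)
  irf <- manual_irf(k, n = 1500, at = 301)
  self <- deconvolve(irf$kernel, irf, align = "irf")
  n <- length(self$samples)
  ipk <- which.max(abs(self$samples))
  expect_equal(trace_times(self)[ipk], irf$reference_arrival,
               tolerance = 1e-12)
  # side lobes beyond the main-lobe width (~1/cutoff) stay below 5%
  lag <- ((seq_len(n) - ipk + n %/% 2) %% n) - n %/% 2
  side <- max(abs(self$samples[abs(lag) * self$dt > 50e-9]))
  expect_lt(side, 0.05 * max(abs(self$samples)))
})

test_that("conv-then-deconv reproduces the low-passed input (noiseless)", {
  st <- black_plastic_stack()
  spec <- synth_spec(st, seed = 3)
  k <- make_synthetic_irf(spec)
  n <- 1500
  dt <- k$dt
  irf <- manual_irf(k, n = n, at = 301)
  p <- numeric(n)
  p[c(400, 700, 1100)] <- c(1, -0.4, 0.6)
  s <- oadepth:::convolve_aligned(p, irf$kernel$samples)
  dec <- deconvolve(oa_trace(s, dt = dt), irf, align = "irf")
  ref <- oadepth:::lowpass_samples(p, dt, 20e6, 4)
  # map the deconvolved samples onto the input's time grid (circular)
  shift <- round(dec$t0 / dt)
  got <- dec$samples[(((seq_len(n) - 1) - shift) %% n) + 1]
  nrmse <- sqrt(mean((got - ref)^2)) / (max(ref) - min(ref))
  expect_lt(nrmse, 0.02)
  # peak positions and amplitudes survive the round trip
  for (idx in c(400, 700, 1100)) {
    w <- (idx - 20):(idx + 20)
    expect_equal(which.max(abs(got[w])), which.max(abs(ref[w])))
    expect_lt(abs(max(abs(got[w])) - max(abs(ref[w]))) / max(abs(ref[w])),
              0.10)
  }
})

test_that("deconvolution is linear and validates its inputs", {
  st <- black_plastic_stack()
  spec <- synth_spec(st, seed = 3)
  k <- make_synthetic_irf(spec)
  irf <- manual_irf(k, n = 800, at = 201)
  p <- numeric(800)
  p[300] <- 1
  s <- oadepth:::convolve_aligned(p, irf$kernel$samples)
  d1 <- deconvolve(oa_trace(s, dt = k$dt), irf)
  d2 <- deconvolve(oa_trace(5 * s, dt = k$dt), irf)
  expect_equal(d2$samples, 5 * d1$samples, tolerance = 1e-9)
  expect_error(deconvolve(oa_trace(s, dt = 2 * k$dt), irf),
               "sampling intervals")
  zero_irf <- irf
  zero_irf$kernel$samples <- numeric(800)
  expect_error(deconvolve(oa_trace(s, dt = k$dt), zero_irf), "all-zero")
})

test_that("resolution limits reproduce the closed-form bookkeeping", {
  lim <- resolution_limits(20e6, 2150, 10e-6)
  expect_equal(lim$min_duration, 50e-9)
  expect_equal(lim$min_depth, 50e-9 * 2150)
  expect_equal(round(lim$min_depth * 1e3, 2), 0.11)
  expect_equal(lim$min_mu_a_detector, 1e5)  # 100 per mm
  expect_equal(lim$min_mu_a_cutoff, 1 / (50e-9 * 2150))
  expect_error(resolution_limits(0, 2150, 1e-5), "positive")
})
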