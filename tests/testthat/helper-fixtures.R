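# Shared fixtures: stacks, compact sources and an independent echo oracle.

probe_stack <- function(sample_layers = list(), detector = 3L,
                        boundaries = c("air", "air")) {
  base <- list(
    layer("PMMA", 2777, 5.00e-3),      # backing
    layer("Adhesive", 2000, 0.02e-3),
    layer("PVDF", 2250, 0.01e-3),
    layer("Adhesive", 2000, 0.02e-3),
    layer("PMMA", 2777, 0.5e-3))       # fronting
  layer_stack(c(base, sample_layers), detector_index = detector,
              boundaries = boundaries)
}

ink_on_glass_stack <- function() {
  probe_stack(list(layer("Ink", 1500, 0.04e-3, mu_a = 100e3),
                   layer("Glass", 5640, 4.00e-3)))
}

black_plastic_stack <- function() {
  probe_stack(list(layer("BlackPlastic", 2150, 1.65e-3, mu_a = 100e3)))
}

# Gaussian initial pressure with hard compact support (no underflow tails),
# so causality windows are well defined.
compact_gauss <- function(x, x0, w) {
  p <- exp(-((x - x0) / w)^2)
  p[abs(x - x0) > 4 * w] <- 0
  p
}

# Independent echo-path oracle: breadth-first queue over (boundary,
# direction) states instead of the package's depth-first recursion.
# Returns arrivals at `receiver` sorted by time.
echo_oracle <- function(stack, source, receiver, max_reflections,
                        amplitude_floor = 0) {
  thk <- vapply(stack$layers, `[[`, numeric(1), "thickness")
  vel <- vapply(stack$layers, `[[`, numeric(1), "sound_velocity")
  Z <- vapply(stack$layers, `[[`, numeric(1), "density") * vel
  seg <- thk / vel
  n <- length(thk)
  res_t <- numeric(0)
  res_a <- numeric(0)
  res_r <- integer(0)
  queue <- list(list(b = source, d = +1L, t = 0, a = 1, r = 0L),
                list(b = source, d = -1L, t = 0, a = 1, r = 0L))
  if (source == receiver) {
    res_t <- 0; res_a <- 1; res_r <- 0L
  }
  while (length(queue)) {
    st <- queue[[1]]
    queue <- queue[-1]
    if (abs(st$a) < amplitude_floor) next
    bn <- st$b + st$d
    if (bn < 0 || bn > n) next
    lay <- if (st$d > 0) bn else bn + 1L
    tn <- st$t + seg[lay]
    if (bn == receiver) {
      res_t <- c(res_t, tn); res_a <- c(res_a, st$a)
      res_r <- c(res_r, st$r)
    }
    if (bn == 0L || bn == n) {
      bc <- stack$boundaries[if (bn == 0L) 1L else 2L]
      if (bc != "absorbing" && st$r < max_reflections) {
        rr <- if (bc == "air") -1 else 1
        queue <- c(queue, list(list(b = bn, d = -st$d, t = tn,
                                    a = st$a * rr, r = st$r + 1L)))
      }
    } else {
      from <- if (st$d > 0) bn else bn + 1L
      to <- if (st$d > 0) bn + 1L else bn
      Tc <- 2 * Z[to] / (Z[from] + Z[to])
      Rc <- (Z[to] - Z[from]) / (Z[to] + Z[from])
      queue <- c(queue, list(list(b = bn, d = st$d, t = tn,
                                  a = st$a * Tc, r = st$r)))
      if (st$r < max_reflections && Rc != 0) {
        queue <- c(queue, list(list(b = bn, d = -st$d, t = tn,
                                    a = st$a * Rc, r = st$r + 1L)))
      }
    }
  }
  o <- order(res_t, res_r)
  data.frame(arrival_time = res_t[o], amplitude = res_a[o],
             n_reflections = res_r[o])
}

# Place a kernel inside a zero trace and wrap it as an oa_irf, bypassing
# extraction (for deconvolution unit tests).
manual_irf <- function(kernel, n, at, dt = kernel$dt) {
  stopifnot(at + length(kernel$samples) - 1L <= n)
  samples <- numeric(n)
  samples[at:(at + length(kernel$samples) - 1L)] <- kernel$samples
  ktr <- oa_trace(samples, dt = dt)
  ref <- trace_times(ktr)[which.max(abs(ktr$samples))]
  structure(list(kernel = ktr, reference_arrival = ref,
                 window = list(center = ref, half_width = 3e-7, order = 4L),
                 mask = NULL, baseline_order = 10L),
            class = "oa_irf")
}
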