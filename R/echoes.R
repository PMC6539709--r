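#' Enumerate echo paths through a layer stack
#'
#' Traces every 1D ray that starts at `source_boundary` and arrives at
#' `receiver_boundary` with at most `max_reflections` reflections and an
#' accumulated pressure amplitude factor of at least `amplitude_floor` in
#' magnitude. The source radiates in both directions with unit relative
#' amplitude; at each interior boundary a ray splits into a transmitted
#' branch (factor T = 2 Z2/(Z1+Z2)) and a reflected branch (factor
#' R = (Z2-Z1)/(Z2+Z1)); at the outer faces it reflects with R = -1 (air),
#' R = +1 (rigid) or leaves the stack (absorbing). Every visit to the
#' receiver boundary is recorded as an arrival; a ray keeps propagating
#' after passing the receiver, so later echoes of the same ray family are
#' enumerated too.
#'
#' The direct (reflection-free) path is always present. Note that pressure
#' transmission factors exceed unity into stiffer media, so an individual
#' `amplitude` can be > 1; round trips always attenuate
#' (T12 * T21 = 4 Z1 Z2/(Z1+Z2)^2 <= 1).
#'
#' @param stack an [layer_stack()].
#' @param source_boundary boundary index (0..N) where the pressure source
#'   sits, e.g. the illuminated absorber surface.
#' @param max_reflections maximum number of reflections per path (>= 0).
#' @param amplitude_floor prune rays whose |amplitude factor| falls below
#'   this value (default 1e-3, keeps echo lists finite).
#' @param receiver_boundary boundary index where arrivals are recorded;
#'   defaults to the sample-side face of the detector layer.
#' @return A data frame of class `echo_paths`, sorted by arrival time, with
#'   columns `arrival_time` (s, relative to emission at the source),
#'   `amplitude` (dimensionless factor), `n_reflections` and `itinerary`
#'   (boundary indices visited, as a `">"`-separated string).
#' @examples
#' st <- layer_stack(list(layer("PMMA", 2777, 0.5e-3)), detector_index = 1)
#' enumerate_echoes(st, source_boundary = 1, max_reflections = 1)
#' @export
enumerate_echoes <- function(stack, source_boundary, max_reflections = 4L,
                             amplitude_floor = 1e-3,
                             receiver_boundary = NULL) {
  stopifnot(inherits(stack, "oa_stack"))
  n <- length(stack$layers)
  if (!is.numeric(source_boundary) || length(source_boundary) != 1L ||
      source_boundary != round(source_boundary) ||
      source_boundary < 0 || source_boundary > n) {
    stop(sprintf("source_boundary must be an integer in 0..%d", n),
         call. = FALSE)
  }
  if (is.null(receiver_boundary)) {
    receiver_boundary <- detector_boundary(stack, "sample")
  }
  if (receiver_boundary < 0 || receiver_boundary > n ||
      receiver_boundary != round(receiver_boundary)) {
    stop("invalid receiver_boundary", call. = FALSE)
  }
  if (max_reflections < 0) stop("max_reflections must be >= 0", call. = FALSE)
  if (amplitude_floor < 0) stop("amplitude_floor must be >= 0", call. = FALSE)

  thk <- stack_thicknesses(stack)
  vel <- stack_velocities(stack)
  Z <- stack_densities(stack) * vel
  seg_time <- thk / vel  # transit time of each layer

  acc <- new.env(parent = emptyenv())
  acc$time <- numeric(0)
  acc$amp <- numeric(0)
  acc$nref <- integer(0)
  acc$itin <- character(0)

  emit <- function(time, amp, nref, itin) {
    acc$time <- c(acc$time, time)
    acc$amp <- c(acc$amp, amp)
    acc$nref <- c(acc$nref, nref)
    acc$itin <- c(acc$itin, paste(itin, collapse = ">"))
  }

  # Walk a ray sitting at boundary b, about to move in direction d (+1
  # toward the sample, -1 toward the backing).
  walk <- function(b, d, time, amp, nref, itin) {
    if (abs(amp) < amplitude_floor) return(invisible())
    bn <- b + d
    if (bn < 0 || bn > n) return(invisible())       # cannot leave the index range
    lay <- if (d > 0) bn else bn + 1L               # layer traversed
    time <- time + seg_time[lay]
    itin <- c(itin, bn)
    if (bn == receiver_boundary) emit(time, amp, nref, itin)
    if (bn == 0L || bn == n) {
      side <- if (bn == 0L) 1L else 2L
      bc <- stack$boundaries[side]
      if (bc == "absorbing") return(invisible())
      r <- if (bc == "air") -1 else 1
      if (nref < max_reflections) {
        walk(bn, -d, time, amp * r, nref + 1L, itin)
      }
    } else {
      from <- if (d > 0) bn else bn + 1L
      to <- if (d > 0) bn + 1L else bn
      Tc <- transmission_coefficient(Z[from], Z[to])
      Rc <- reflection_coefficient(Z[from], Z[to])
      walk(bn, d, time, amp * Tc, nref, itin)
      if (nref < max_reflections && Rc != 0) {
        walk(bn, -d, time, amp * Rc, nref + 1L, itin)
      }
    }
    invisible()
  }

  if (source_boundary == receiver_boundary) {
    emit(0, 1, 0L, source_boundary)
  }
  walk(source_boundary, +1L, 0, 1, 0L, source_boundary)
  walk(source_boundary, -1L, 0, 1, 0L, source_boundary)

  ord <- order(acc$time, acc$nref)
  out <- data.frame(arrival_time = acc$time[ord], amplitude = acc$amp[ord],
                    n_reflections = acc$nref[ord], itinerary = acc$itin[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("echo_paths", "data.frame")
  out
}

#' @export
print.echo_paths <- function(x, ...) {
  cat(sprintf("<echo_paths> %d arrivals\n", nrow(x)))
  y <- data.frame(arrival_us = x$arrival_time * 1e6,
                  amplitude = signif(x$amplitude, 4),
                  n_refl = x$n_reflections, itinerary = x$itinerary)
  print.data.frame(utils::head(y, 20L), row.names = FALSE)
  if (nrow(x) > 20L) cat(sprintf("  ... %d more\n", nrow(x) - 20L))
  invisible(x)
}

#' Propose a signal mask from predicted echo arrivals
#'
#' Builds a [signal_mask()] flagging an interval of `half_width` seconds
#' around every predicted optoacoustic arrival (trigger delay plus echo
#' arrival times from [enumerate_echoes()]). Useful as the exclusion mask
#' for the pyroelectric baseline fit, mirroring the practice of fitting the
#' baseline only where no acoustic signal can be present.
#'
#' @inheritParams enumerate_echoes
#' @param trigger_delay laser emission time on the trace axis, s.
#' @param half_width half-width of each flagged interval, s.
#' @return a [signal_mask()].
#' @export
propose_signal_mask <- function(stack, source_boundary, trigger_delay,
                                half_width, max_reflections = 3L,
                                amplitude_floor = 1e-2,
                                receiver_boundary = NULL) {
  ech <- enumerate_echoes(stack, source_boundary,
                          max_reflections = max_reflections,
                          amplitude_floor = amplitude_floor,
                          receiver_boundary = receiver_boundary)
  centers <- trigger_delay + ech$arrival_time
  signal_mask(centers - half_width, centers + half_width)
}
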