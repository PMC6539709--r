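#' Material layer
#'
#' One homogeneous slab of the probe/sample stack, described by its sound
#' velocity, thickness, density and optical absorption coefficient. All
#' quantities are SI: m/s, m, kg/m^3, 1/m.
#'
#' @param material material name (e.g. "PMMA", "PVDF").
#' @param sound_velocity longitudinal sound velocity in m/s (> 0).
#' @param thickness layer thickness in m (>= 0; a zero-thickness layer is
#'   allowed and contributes no time of flight).
#' @param density mass density in kg/m^3 (> 0).
#' @param mu_a optical absorption coefficient in 1/m (>= 0).
#' @return An object of class `oa_layer`.
#' @examples
#' layer("PMMA", sound_velocity = 2777, thickness = 0.5e-3, density = 1000)
#' @export
layer <- function(material, sound_velocity, thickness, density = 1000,
                  mu_a = 0) {
  if (!is.character(material) || length(material) != 1L) {
    stop("material must be a single name", call. = FALSE)
  }
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop(sprintf("%s must be a single finite number", nm), call. = FALSE)
    }
    as.numeric(x)
  }
  sound_velocity <- num1(sound_velocity, "sound_velocity")
  thickness <- num1(thickness, "thickness")
  density <- num1(density, "density")
  mu_a <- num1(mu_a, "mu_a")
  if (sound_velocity <= 0) stop("sound_velocity must be > 0", call. = FALSE)
  if (density <= 0) stop("density must be > 0", call. = FALSE)
  if (thickness < 0) stop("thickness must be >= 0", call. = FALSE)
  if (mu_a < 0) stop("mu_a must be >= 0", call. = FALSE)
  structure(list(material = material, sound_velocity = sound_velocity,
                 thickness = thickness, density = density, mu_a = mu_a),
            class = "oa_layer")
}

#' Ordered stack of material layers
#'
#' Layers are ordered from the detector-side outermost slab (the backing,
#' index 1) toward the sample. Boundaries are indexed 0..N around the N
#' layers: boundary `i` separates layer `i` from layer `i + 1`; boundary 0
#' is the outer face of the backing, boundary N the outer face of the last
#' layer. The two outer faces carry a boundary condition: `"air"`
#' (pressure release, R = -1), `"rigid"` (R = +1) or `"absorbing"`.
#'
#' @param layers list of [layer] objects (at least one).
#' @param detector_index index of the piezoelectric (PVDF) layer.
#' @param boundaries character vector of length 2, outer boundary conditions
#'   (backing side, sample side); each of "air", "rigid", "absorbing".
#' @return An object of class `oa_stack`.
#' @seealso [read_stack()] to load a stack from a config file,
#'   [time_of_flight()], [enumerate_echoes()].
#' @export
layer_stack <- function(layers, detector_index = NA_integer_,
                        boundaries = c("air", "air")) {
  if (inherits(layers, "oa_layer")) layers <- list(layers)
  if (!is.list(layers) || length(layers) < 1L ||
      !all(vapply(layers, inherits, logical(1), "oa_layer"))) {
    stop("layers must be a non-empty list of oa_layer objects", call. = FALSE)
  }
  if (!is.na(detector_index)) {
    detector_index <- as.integer(detector_index)
    if (detector_index < 1L || detector_index > length(layers)) {
      stop("detector_index out of range", call. = FALSE)
    }
  }
  boundaries <- match.arg(boundaries, c("air", "rigid", "absorbing"),
                          several.ok = TRUE)
  if (length(boundaries) == 1L) boundaries <- rep(boundaries, 2L)
  if (length(boundaries) != 2L) {
    stop("boundaries must name the two outer faces", call. = FALSE)
  }
  structure(list(layers = layers, detector_index = detector_index,
                 boundaries = boundaries),
            class = "oa_stack")
}

#' @export
print.oa_stack <- function(x, ...) {
  n <- length(x$layers)
  cat(sprintf("<oa_stack> %d layers, boundaries: %s | %s\n", n,
              x$boundaries[1], x$boundaries[2]))
  for (i in seq_len(n)) {
    l <- x$layers[[i]]
    tag <- if (!is.na(x$detector_index) && i == x$detector_index) " <- detector" else ""
    cat(sprintf("  %d: %-10s c = %6.0f m/s, d = %8.4g mm, rho = %6.0f kg/m3, mu_a = %.3g /mm%s\n",
                i, l$material, l$sound_velocity, l$thickness * 1e3,
                l$density, l$mu_a * 1e-3, tag))
  }
  invisible(x)
}

#' @export
length.oa_stack <- function(x) length(x$layers)

# Internal numeric accessors over a stack.
stack_velocities <- function(stack) vapply(stack$layers, `[[`, numeric(1), "sound_velocity")
stack_thicknesses <- function(stack) vapply(stack$layers, `[[`, numeric(1), "thickness")
stack_densities <- function(stack) vapply(stack$layers, `[[`, numeric(1), "density")
stack_mu_a <- function(stack) vapply(stack$layers, `[[`, numeric(1), "mu_a")

#' Total thickness of a stack
#' @param stack an [layer_stack()].
#' @return total thickness in m.
#' @export
stack_thickness <- function(stack) {
  stopifnot(inherits(stack, "oa_stack"))
  sum(stack_thicknesses(stack))
}

#' Acoustic impedance of a layer
#'
#' Specific acoustic impedance Z = rho * c, the quantity whose jumps across
#' layer boundaries set the partial reflections of a normally incident
#' plane wave.
#'
#' @param layer an [layer] object.
#' @return impedance in kg m^-2 s^-1 (rayl).
#' @examples
#' acoustic_impedance(layer("glass", 5640, 4e-3, density = 1000))  # 5.64e6
#' @export
acoustic_impedance <- function(layer) {
  stopifnot(inherits(layer, "oa_layer"))
  layer$density * layer$sound_velocity
}

#' Pressure reflection and transmission coefficients
#'
#' For a wave travelling from a medium of impedance `Z1` into `Z2` at normal
#' incidence, in the pressure convention (the detector measures pressure):
#' R = (Z2 - Z1) / (Z2 + Z1) and T = 2 Z2 / (Z1 + Z2), so 1 + R = T.
#' `Z2 = 0` is the pressure-release (air) limit with R = -1; `Z2 = Inf` the
#' rigid limit with R = +1.
#'
#' @param Z1,Z2 acoustic impedances in kg m^-2 s^-1. `Z1 > 0`; `Z2 >= 0`
#'   and may be `Inf` (boundary sentinels).
#' @return dimensionless coefficient.
#' @examples
#' reflection_coefficient(2.777e6, 5.64e6)  # PMMA -> glass, 0.3401
#' reflection_coefficient(1e6, 0)           # air boundary, -1
#' @export
reflection_coefficient <- function(Z1, Z2) {
  check_impedance_pair(Z1, Z2)
  if (is.infinite(Z2)) return(1)
  (Z2 - Z1) / (Z2 + Z1)
}

#' @rdname reflection_coefficient
#' @export
transmission_coefficient <- function(Z1, Z2) {
  check_impedance_pair(Z1, Z2)
  if (is.infinite(Z2)) return(2)
  2 * Z2 / (Z1 + Z2)
}

check_impedance_pair <- function(Z1, Z2) {
  if (!is.numeric(Z1) || !is.numeric(Z2) || length(Z1) != 1L || length(Z2) != 1L) {
    stop("impedances must be single numbers", call. = FALSE)
  }
  if (is.na(Z1) || is.na(Z2)) stop("impedances must not be NA", call. = FALSE)
  if (Z1 <= 0 || !is.finite(Z1)) {
    stop("Z1 must be positive and finite (sentinels apply to Z2)", call. = FALSE)
  }
  if (Z2 < 0) stop("Z2 must be >= 0", call. = FALSE)
  if (Z1 == 0 && Z2 == 0) stop("both impedances zero: undefined", call. = FALSE)
  invisible(TRUE)
}

#' Acoustic time of flight between two boundaries
#'
#' Sum of thickness / sound_velocity over the layers between two boundary
#' indices (0..N convention, see [layer_stack()]). Symmetric in its
#' arguments.
#'
#' @param stack an [layer_stack()].
#' @param from_boundary,to_boundary boundary indices in 0..N.
#' @return one-way time of flight in seconds.
#' @examples
#' st <- layer_stack(list(layer("PMMA", 2777, 0.5e-3)))
#' time_of_flight(st, 0, 1) * 1e6  # 0.18005 us
#' @export
time_of_flight <- function(stack, from_boundary, to_boundary) {
  stopifnot(inherits(stack, "oa_stack"))
  n <- length(stack$layers)
  for (b in c(from_boundary, to_boundary)) {
    if (!is.numeric(b) || length(b) != 1L || b != round(b) || b < 0 || b > n) {
      stop(sprintf("boundary index must be an integer in 0..%d", n),
           call. = FALSE)
    }
  }
  lo <- min(from_boundary, to_boundary)
  hi <- max(from_boundary, to_boundary)
  if (lo == hi) return(0)
  idx <- (lo + 1L):hi
  sum(stack_thicknesses(stack)[idx] / stack_velocities(stack)[idx])
}

# Internal: boundary index of the detector layer's face.
# side = "sample" gives the sample-side face, "backing" the backing-side one.
detector_boundary <- function(stack, side = c("sample", "backing")) {
  side <- match.arg(side)
  if (is.na(stack$detector_index)) {
    stop("stack has no detector_index set", call. = FALSE)
  }
  if (side == "sample") stack$detector_index else stack$detector_index - 1L
}
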