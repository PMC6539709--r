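#' Read and write trace files
#'
#' Traces are stored as plain two-column delimited text (time and
#' amplitude, full precision) preceded by `#`-prefixed header lines
#' carrying the sampling metadata (`dt`, `t0`, and optionally
#' `trigger_delay`, `pulse_energy`, `units`). A write followed by a read
#' reproduces the samples exactly and preserves every header key.
#' Gzip-compressed files (`.gz`) are handled transparently.
#'
#' @param path file path.
#' @param trace an [oa_trace] to write.
#' @return `read_trace` returns an [oa_trace]; `write_trace` returns
#'   `path` invisibly.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  is_header <- grepl("^\\s*#", lines)
  header <- lines[is_header]
  body_idx <- which(!is_header & nzchar(trimws(lines)))
  hdr <- list()
  for (h in header) {
    m <- regmatches(h, regexec("^\\s*#\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*[:=]\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) hdr[[m[2]]] <- trimws(m[3])
  }
  if (is.null(hdr$dt)) stop("missing dt header", call. = FALSE)
  dt <- as.numeric(hdr$dt)
  if (!is.finite(dt) || dt <= 0) stop("invalid dt header", call. = FALSE)
  if (length(body_idx) < 2L) stop("trace has fewer than 2 data rows",
                                  call. = FALSE)
  tvals <- numeric(length(body_idx))
  avals <- numeric(length(body_idx))
  for (i in seq_along(body_idx)) {
    ln <- body_idx[i]
    fields <- strsplit(trimws(lines[ln]), "[,;[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2L || any(is.na(vals[1:2]))) {
      stop(sprintf("malformed numeric row at line %d: '%s'", ln, lines[ln]),
           call. = FALSE)
    }
    tvals[i] <- vals[1]
    avals[i] <- vals[2]
  }
  dts <- diff(tvals)
  if (any(abs(dts - dt) > 1e-6 * dt)) {
    bad <- body_idx[which.max(abs(dts - dt)) + 1L]
    stop(sprintf("non-uniform time column (line %d deviates from dt)", bad),
         call. = FALSE)
  }
  num_or_null <- function(x) if (is.null(x)) NULL else as.numeric(x)
  tr <- oa_trace(avals, dt = dt,
                 t0 = if (is.null(hdr$t0)) tvals[1] else as.numeric(hdr$t0),
                 trigger_delay = num_or_null(hdr$trigger_delay),
                 pulse_energy = num_or_null(hdr$pulse_energy),
                 units = if (is.null(hdr$units)) "V" else hdr$units)
  attr(tr, "headers") <- hdr
  tr
}

#' @rdname read_trace
#' @param extra named character/numeric vector of additional header keys to
#'   write.
#' @export
write_trace <- function(trace, path, extra = NULL) {
  stopifnot(inherits(trace, "oa_trace"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  fmt <- function(x) sprintf("%.17g", x)
  extra_lines <- if (length(extra)) {
    vapply(names(extra), function(k) {
      v <- extra[[k]]
      paste0("# ", k, ": ", if (is.numeric(v)) fmt(v) else as.character(v))
    }, character(1))
  }
  writeLines(c("# oadepth trace v1",
               paste0("# dt: ", fmt(trace$dt)),
               paste0("# t0: ", fmt(trace$t0)),
               if (!is.null(trace$trigger_delay))
                 paste0("# trigger_delay: ", fmt(trace$trigger_delay)),
               if (!is.null(trace$pulse_energy))
                 paste0("# pulse_energy: ", fmt(trace$pulse_energy)),
               paste0("# units: ", trace$units),
               extra_lines), con)
  tt <- trace_times(trace)
  writeLines(paste(fmt(tt), fmt(trace$samples), sep = "\t"), con)
  invisible(path)
}

#' Read and write instrument response functions
#'
#' An IRF file is a trace file (see [read_trace()]) whose header carries
#' the extraction provenance (`reference_arrival`, window parameters,
#' baseline order), so extracted IRFs survive a round trip to disk.
#'
#' @param irf an `oa_irf` from [extract_irf()].
#' @param path file path.
#' @return `read_irf` returns an `oa_irf`; `write_irf` returns `path`
#'   invisibly.
#' @export
write_irf <- function(irf, path) {
  stopifnot(inherits(irf, "oa_irf"))
  write_trace(irf$kernel, path, extra = c(
    kind = "irf",
    reference_arrival = irf$reference_arrival,
    window_center = irf$window$center,
    window_half_width = irf$window$half_width,
    window_order = irf$window$order,
    baseline_order = irf$baseline_order))
  invisible(path)
}

#' @rdname write_irf
#' @export
read_irf <- function(path) {
  kernel <- read_trace(path)
  hdr <- attr(kernel, "headers")
  attr(kernel, "headers") <- NULL
  num <- function(k, default = NA_real_) {
    if (is.null(hdr[[k]])) default else as.numeric(hdr[[k]])
  }
  ref <- num("reference_arrival")
  if (is.na(ref)) {
    ref <- trace_times(kernel)[which.max(abs(kernel$samples))]
  }
  structure(list(kernel = kernel, reference_arrival = ref,
                 window = list(center = num("window_center"),
                               half_width = num("window_half_width"),
                               order = as.integer(num("window_order", 4))),
                 mask = NULL,
                 baseline_order = as.integer(num("baseline_order", 10))),
            class = "oa_irf")
}

#' Read and write layer-stack configuration files
#'
#' Stacks are described in YAML: a `layers` sequence (ordered from the
#' detector-side backing toward the sample) whose entries carry the keys
#' `material`, `sound_velocity_m_s`, `thickness_mm`, `density_kg_m3` and
#' `mu_a_per_mm`, plus optional top-level `detector` (material name or
#' 1-based index of the piezoelectric layer) and `boundaries` (two of
#' "air"/"rigid"/"absorbing"). The packaged fixture
#' `system.file("extdata", "table1_ink_on_glass.yaml", package = "oadepth")`
#' describes the full probe + ink-on-glass test sample, and
#' `black_plastic.yaml` the probe on a thick strong absorber.
#'
#' @param path config file path.
#' @param stack an [layer_stack()] to write.
#' @return `read_stack` returns an [layer_stack()]; `write_stack` returns
#'   `path` invisibly.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$layers) || !length(cfg$layers)) {
    stop("stack config must define at least one layer", call. = FALSE)
  }
  layers <- lapply(cfg$layers, function(l) {
    for (k in c("material", "sound_velocity_m_s", "thickness_mm")) {
      if (is.null(l[[k]])) {
        stop(sprintf("layer entry missing key '%s'", k), call. = FALSE)
      }
    }
    layer(material = as.character(l$material),
          sound_velocity = as.numeric(l$sound_velocity_m_s),
          thickness = as.numeric(l$thickness_mm) * 1e-3,
          density = if (is.null(l$density_kg_m3)) 1000 else as.numeric(l$density_kg_m3),
          mu_a = if (is.null(l$mu_a_per_mm)) 0 else as.numeric(l$mu_a_per_mm) * 1e3)
  })
  det <- NA_integer_
  if (!is.null(cfg$detector)) {
    det <- if (is.character(cfg$detector)) {
      mats <- vapply(layers, `[[`, character(1), "material")
      idx <- which(mats == cfg$detector)
      if (!length(idx)) {
        stop(sprintf("detector material '%s' not found in layers",
                     cfg$detector), call. = FALSE)
      }
      idx[1]
    } else as.integer(cfg$detector)
  }
  bnd <- if (is.null(cfg$boundaries)) c("air", "air") else as.character(cfg$boundaries)
  layer_stack(layers, detector_index = det, boundaries = bnd)
}

#' @rdname read_stack
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "oa_stack"))
  cfg <- list(
    layers = lapply(stack$layers, function(l) {
      list(material = l$material,
           sound_velocity_m_s = l$sound_velocity,
           thickness_mm = l$thickness * 1e3,
           density_kg_m3 = l$density,
           mu_a_per_mm = l$mu_a * 1e-3)
    }),
    boundaries = as.list(stack$boundaries))
  if (!is.na(stack$detector_index)) cfg$detector <- stack$detector_index
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write a scan map as a delimited matrix with a position header
#'
#' @param map an `oa_scanmap`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_scan_map <- function(map, path) {
  stopifnot(inherits(map, "oa_scanmap"))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("# oadepth scanmap v1",
               paste0("# x1_m: ", paste(sprintf("%.10g", map$x1), collapse = " ")),
               paste0("# x2_m: ", paste(sprintf("%.10g", map$x2), collapse = " "))),
             con)
  utils::write.table(map$amplitude, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
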