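test_that("initial pressure follows Beer-Lambert deposition", {
  st <- layer_stack(list(layer("clear", 1500, 1e-3),
                         layer("dark", 2000, 1e-3, mu_a = 2e3)),
                    detector_index = 1)
  g <- simulation_grid(st, dx = 1e-5)
  # no absorption anywhere -> identically zero
  st0 <- layer_stack(list(layer("clear", 1500, 2e-3)), detector_index = 1)
  g0 <- simulation_grid(st0, dx = 1e-5)
  p00 <- initial_pressure_profile(st0, g0, fluence = 50)
  expect_true(all(p00$p0 == 0))

  p0 <- initial_pressure_profile(st, g, fluence = 50)
  expect_true(all(p0$p0 >= 0))
  expect_true(all(p0$p0[g$mu_a == 0] == 0))
  # entry value: Gamma * mu_a * F before attenuation (cell-averaged)
  first <- which(p0$p0 > 0)[1]
  expect_equal(p0$p0[first], 2e3 * 50, tolerance = 0.02)
  # total deposited energy equals F * (1 - exp(-mu_a * L))
  dep <- sum(p0$p0 / p0$grueneisen) * g$dx
  expect_equal(dep, 50 * (1 - exp(-2e3 * 1e-3)), tolerance = 1e-9)
  expect_error(initial_pressure_profile(st, g, fluence = -1), "fluence")
})

test_that("a buried source in a homogeneous medium arrives at d/c", {
  st <- layer_stack(list(layer("m", 1500, 3e-3)), detector_index = 1,
                    boundaries = c("absorbing", "absorbing"))
  g <- simulation_grid(st, dx = 5e-6)
  p0 <- compact_gauss(g$x, 2.4e-3, 3e-5)
  tr <- fd_simulate(st, p0, g, duration = 1.2e-6)
  tt <- trace_times(tr)
  d <- abs(2.4e-3 - g$x[g$detector_cell])
  expect_equal(tt[which.max(tr$samples)], d / 1500,
               tolerance = 2 * g$dx / 1500 / (d / 1500))
  # causality: silent before the leading edge can arrive
  t_edge <- (d - 4 * 3e-5 - 2 * g$dx) / 1500
  expect_lt(max(abs(tr$samples[tt < t_edge])), 1e-6 * max(abs(tr$samples)))
})

test_that("matched media produce no interface echo", {
  # one material split into two layers: the field must be bit-identical to
  # the unsplit medium, so the interface is exactly invisible
  split <- layer_stack(list(layer("a", 1500, 1.5e-3),
                            layer("a", 1500, 1.5e-3)), detector_index = 2)
  whole <- layer_stack(list(layer("a", 1500, 3e-3)), detector_index = 1)
  g <- simulation_grid(split, dx = 5e-6)
  gw <- simulation_grid(whole, dx = 5e-6)
  p0 <- compact_gauss(g$x, 2.4e-3, 3e-5)
  tr_split <- fd_simulate(split, p0, g, duration = 1.3e-6,
                          detector = "center")
  # same grid, same physics: compare at the same cell
  gw$detector_cell <- g$detector_cell
  gw$detector_cells <- g$detector_cells
  tr_whole <- fd_simulate(whole, p0, gw, duration = 1.3e-6,
                          detector = "center")
  prim <- max(abs(tr_whole$samples))
  expect_lt(max(abs(tr_split$samples - tr_whole$samples)), 1e-12 * prim)
})

test_that("discrete acoustic energy is conserved under reflective boundaries", {
  st_air <- layer_stack(list(layer("a", 1500, 1.5e-3),
                             layer("b", 2777, 1.5e-3)), detector_index = 1)
  st_rig <- layer_stack(list(layer("a", 1500, 1.5e-3),
                             layer("b", 2777, 1.5e-3)), detector_index = 1,
                        boundaries = c("rigid", "rigid"))
  g <- simulation_grid(st_air, dx = 5e-6)
  p0 <- compact_gauss(g$x, 1.0e-3, 3e-5)
  for (st in list(st_air, st_rig)) {
    tr <- fd_simulate(st, p0, g, duration = 6e-6, track_energy = TRUE)
    en <- attr(tr, "energy")
    expect_lt((max(en) - min(en)) / en[1], 1e-3)
  }
})

test_that("halving the grid step moves the first-arrival peak by < 1 coarse cell", {
  st <- layer_stack(list(layer("m", 1500, 3e-3)), detector_index = 1,
                    boundaries = c("absorbing", "absorbing"))
  peak_time <- function(dx) {
    g <- simulation_grid(st, dx = dx)
    p0 <- compact_gauss(g$x, 2.4e-3, 3e-5)
    tr <- fd_simulate(st, p0, g, duration = 0.8e-6)
    trace_times(tr)[which.max(tr$samples)]
  }
  coarse <- 1e-5
  expect_lt(abs(peak_time(coarse) - peak_time(coarse / 2)), coarse / 1500)
})

test_that("reflected/incident amplitude ratio matches the impedance formula", {
  st <- layer_stack(list(layer("w", 1500, 3e-3, density = 1000),
                         layer("g", 2500, 3e-3, density = 1600)),
                    detector_index = 1,
                    boundaries = c("absorbing", "absorbing"))
  g <- simulation_grid(st, dx = 5e-6)
  p0 <- compact_gauss(g$x, 2.0e-3, 5e-5)
  tr <- fd_simulate(st, p0, g, duration = 2.5e-6)
  tt <- trace_times(tr)
  inc <- tr$samples[tt > 0.2e-6 & tt < 0.6e-6]
  refl <- tr$samples[tt > 1.4e-6 & tt < 1.95e-6]
  Rnum <- refl[which.max(abs(refl))] / max(abs(inc))
  Rth <- reflection_coefficient(1500 * 1000, 2500 * 1600)
  expect_equal(Rnum, Rth, tolerance = 0.02)
})

test_that("simulated echo arrivals agree with analytic echo enumeration", {
  # cross-module oracle on the full probe + ink-on-glass sample
  st <- ink_on_glass_stack()
  g <- simulation_grid(st)
  p0 <- initial_pressure_profile(st, g, fluence = 50)
  tr <- fd_simulate(st, p0, g, duration = 2.2e-6)
  tt <- trace_times(tr)
  ech <- enumerate_echoes(st, source_boundary = 5, max_reflections = 2,
                          amplitude_floor = 0.05)
  # the three principal features: direct pulse, fronting double transit,
  # glass bottom echo
  t_direct <- ech$arrival_time[1]
  t_front <- t_direct + 2 * time_of_flight(st, 3, 5)
  t_glass <- t_direct + 2 * time_of_flight(st, 5, 7)  # ink + glass, down and back
  cell_transit <- g$dx / min(g$c)
  # the direct pulse is sharp: its peak sits within a few cell transits;
  # the weaker fronting double transit rides on the dispersion tails of
  # larger features, so its association window is wider
  win <- tt > t_direct - 0.05e-6 & tt < t_direct + 0.05e-6
  t_peak <- tt[win][which.max(abs(tr$samples[win]))]
  expect_lt(abs(t_peak - t_direct), 6 * cell_transit)
  win <- tt > t_front - 0.05e-6 & tt < t_front + 0.05e-6
  t_peak <- tt[win][which.max(abs(tr$samples[win]))]
  expect_lt(abs(t_peak - t_front), 30 * cell_transit)
  # ordering of the narrated sequence holds
  expect_true(t_direct < t_front && t_front < t_glass)
})

test_that("simulation rejects invalid inputs", {
  st <- layer_stack(list(layer("m", 1500, 1e-3)), detector_index = 1)
  g <- simulation_grid(st, dx = 1e-5)
  expect_error(fd_simulate(st, numeric(g$n_cells), g, 1e-6), "empty source")
  g_bad <- g
  g_bad$dt <- 2 * g$dx / 1500
  p0 <- compact_gauss(g$x, 0.5e-3, 3e-5)
  expect_error(fd_simulate(st, p0, g_bad, 1e-6), "CFL")
})
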