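test_that("geometry follows the radius rule outward from the deepest level", {
  g1 <- build_geometry(1)
  expect_equal(g1$radii_m * 1e6, c(48, 24, 12, 6, 3))
  expect_equal(g1$counts, c(1, 2, 4, 8, 16))
  expect_equal(sum(g1$lengths_m) * 1e6, 3694)
  expect_equal(build_geometry(2)$radii_m[1] * 1e6, 12)
  expect_equal(build_geometry(3)$radii_m[1] * 1e6, 3 * 2^(4 / 3))
  expect_true(all(diff(build_geometry(2.5)$radii_m) < 0))
  expect_error(build_geometry(0), "positive")
})

test_that("series flux reproduces Fick's law for one channel and is linear", {
  # single level: J = A K dpp / L exactly
  g <- build_geometry(1)
  g$lengths_m <- c(1e-3, 1e-9, 1e-9, 1e-9, 1e-9)  # one dominant channel
  const <- physical_constants()
  a1 <- g$counts[1] * pi * g$radii_m[1]^2
  one_term <- a1 * const$krogh_K * 6000 / 1e-3 * const$flux_conversion
  expect_equal(series_flux_no_influx(g, 6000, const), one_term,
               tolerance = 1e-4)
  g5 <- build_geometry(2)
  expect_equal(series_flux_no_influx(g5, 8000), 2 * series_flux_no_influx(g5, 4000))
  # hand-assembled 5-term series resistance at alpha = 2, 6 kPa
  K <- const$krogh_K
  resist <- sum(g5$lengths_m / (K * g5$counts * pi * g5$radii_m^2))
  expect_equal(series_flux_no_influx(g5, 6000),
               6000 / resist * 3.6e12, tolerance = 1e-12)
})

test_that("no influx degenerates to the series solution", {
  g <- build_geometry(1)
  sol <- solve_steady_state(g, boundary_conditions(influx_levels = integer(0)))
  expect_equal(sol$phi, 0)
  expect_equal(sol$flux_at_level_top[1] * 3.6e12,
               series_flux_no_influx(g, 6000), tolerance = 1e-12)
  expect_equal(length(unique(sol$flux_at_level_top)), 1L)  # constant flux
})

test_that("the steady state satisfies its boundary conditions and conservation", {
  for (alpha in c(1, 2, 3)) {
    sol <- solve_steady_state(build_geometry(alpha))
    # pressure pinned at both ends
    expect_equal(sol$junction_pressures[1], 0)
    expect_equal(sol$junction_pressures[6], 6000, tolerance = 1e-8)
    # nothing lies distal to the closed level-5 tips; flux grows outward
    expect_equal(sol$S[5], 0)
    expect_true(all(diff(sol$flux_at_level_top) <= 0))
    # spiracle flux identity: J(0) = phi x total influx wall area
    expect_equal(sol$flux_at_level_top[1], sol$phi * sum(sol$w * sol$L),
                 tolerance = 1e-12)
    # conservation at level boundaries: J_l - J_{l+1} = wall influx of level l
    influx_l <- sol$phi * sol$w * sol$L
    expect_equal(-diff(sol$flux_at_level_top), influx_l[-5], tolerance = 1e-10)
  }
})

test_that("the analytic solution matches the finite-difference oracle", {
  const <- physical_constants()
  for (alpha in c(1, 2, 3)) {
    for (sac in list(NULL, 3, 4)) {
      bc <- boundary_conditions(6000, air_sac_level = sac)
      sol <- solve_steady_state(build_geometry(alpha), bc, const)
      ora <- fd_steady_state(build_geometry(alpha), bc, const, nodes = 1e4)
      expect_equal(sol$phi, ora$phi, tolerance = 1e-4)
      expect_equal(sol$flux_at_level_top, ora$flux_at_level_top,
                   tolerance = 1e-4)
    }
  }
  # pressure profile agrees along the whole chain
  sol <- solve_steady_state(build_geometry(1))
  ora <- fd_steady_state(build_geometry(1), boundary_conditions(), const)
  prof <- steady_state_pressure(sol, n_per_level = 200)
  interp <- approx(ora$x, ora$pressure, xout = prof$x_m)$y
  expect_lt(max(abs(prof$p_pa - interp)) / 6000, 1e-4)
})

test_that("whole-organism flux decreases from area-reducing to area-increasing", {
  flux <- vapply(c(1, 2, 3), function(a) {
    prof <- flux_profile(solve_steady_state(build_geometry(a)))
    prof$flux_ul_h[prof$level == 1]
  }, numeric(1))
  expect_true(all(diff(flux) < 0))
  ref <- metabolic_reference()
  expect_gt(flux[1], ref$resting_flux)   # area-reducing meets resting demand
  expect_lt(flux[3], ref$resting_flux)   # area-increasing does not
})

test_that("flux profiles multiply spiracles and project across air sacs", {
  sol <- solve_steady_state(build_geometry(1))
  prof <- flux_profile(sol)
  expect_equal(prof$flux_ul_h,
               sol$flux_at_level_top * 3.6e12 * 12)
  expect_gte(prof$flux_ul_h[prof$level == 1],
             prof$flux_ul_h[prof$level == 5])

  sac <- flux_profile(solve_steady_state(
    build_geometry(1), boundary_conditions(air_sac_level = 4)))
  expect_equal(sac$level, 1:5)
  expect_true(all(sac$projected[1:3]))
  expect_false(any(sac$projected[4:5]))
  # projected levels carry the sac-entry flux unchanged
  expect_equal(unique(sac$flux_ul_h[1:4]), sac$flux_ul_h[4])
})

test_that("airway volume follows the geometry", {
  g <- build_geometry(1)
  expect_equal(tracheal_volume(g) * 1e9, 0.016363375, tolerance = 1e-6)
  g2 <- g; g2$radii_m <- 2 * g$radii_m
  expect_equal(tracheal_volume(g2), 4 * tracheal_volume(g))
  single <- g
  single$counts <- c(1, 0, 0, 0, 0)
  expect_equal(tracheal_volume(single),
               pi * g$radii_m[1]^2 * g$lengths_m[1])
})

test_that("convection reproduces the reported per-spiracle flux", {
  sol <- solve_steady_state(build_geometry(1), boundary_conditions(6000))
  cv <- convective_flux(sol)
  expect_equal(cv$convective_flux_ul_h, 0.241, tolerance = 0.01)
  expect_equal(cv$whole_organism_flux_ul_h, 12 * cv$convective_flux_ul_h)

  # linear in frequency and in evacuation fraction
  expect_equal(convective_flux(sol, frequency = 0.52)$convective_flux_ul_h,
               2 * cv$convective_flux_ul_h)
  expect_equal(convective_flux(sol, evacuation_fraction = 0.33)$convective_flux_ul_h,
               cv$convective_flux_ul_h / 2)
  expect_error(convective_flux(sol, frequency = 0), "positive")

  # flux identity: breaths/h x evacuated volume x mean gas fraction
  expect_equal(cv$convective_flux_ul_h,
               3600 * 0.26 * 0.66 * cv$per_spiracle_volume_m3 * 1e9 *
                 cv$mean_pp_pa / 101325, tolerance = 1e-12)
  # the volume-weighted variant is lower: most volume sits near the spiracle
  expect_lt(convective_flux(sol, pp_averaging = "volume")$convective_flux_ul_h,
            cv$convective_flux_ul_h)
})

test_that("metabolic rate conversions and tissue-level flux", {
  expect_equal(convert_metabolic_rate(10, "ul_co2_per_h"), 10)
  expect_equal(convert_metabolic_rate(10, "ul_o2_per_h",
                                      respiratory_quotient = 1), 10)
  expect_equal(convert_metabolic_rate(10, "ul_o2_per_h"), 8.4)
  expect_equal(convert_metabolic_rate(20.1, "uW", respiratory_quotient = 1),
               3.6)
  expect_error(convert_metabolic_rate(-1, "uW"), "non-negative")

  expect_equal(tissue_level_flux(7, 10), 1)
  expect_equal(tissue_level_flux(0, 5), 0)
  expect_equal(tissue_level_flux(10.63, 1), 10.63 / 0.7)
  expect_error(tissue_level_flux(1, 0), "positive")
})

test_that("the scenario sweep covers the factorial grid and is linear in dpp", {
  sweep <- scenario_sweep()
  expect_equal(nrow(sweep), 27L)
  for (a in c(1, 2, 3)) {
    for (sac in c("none", "3", "4")) {
      f4 <- sweep$flux_ul_h[sweep$alpha == a & sweep$delta_pp_kpa == 4 &
                              sweep$air_sac_level == sac]
      f8 <- sweep$flux_ul_h[sweep$alpha == a & sweep$delta_pp_kpa == 8 &
                              sweep$air_sac_level == sac]
      expect_equal(f8, 2 * f4, tolerance = 1e-10)
    }
  }
  # at 6 kPa without an air sac, only the area-reducing exponent meets the
  # resting threshold (a sac removes proximal resistance for any exponent)
  at6 <- sweep[sweep$delta_pp_kpa == 6 & sweep$air_sac_level == "none", ]
  expect_true(all(at6$meets_resting[at6$alpha == 1]))
  expect_false(any(at6$meets_resting[at6$alpha %in% c(2, 3)]))
  profiles <- attr(sweep, "profiles")
  expect_equal(nrow(profiles), 27L * 5L)
})
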