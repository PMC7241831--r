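#' Physical constants of the gas-exchange model
#'
#' @param krogh_K Krogh's diffusion constant for CO2 in air: the combined
#'   diffusivity-solubility coefficient converting a partial-pressure
#'   gradient into volumetric flux, m^2 s^-1 Pa^-1.
#' @param flux_conversion m^3 s^-1 to ul h^-1 (3600 s/h x 1e9 ul/m^3).
#' @param atmospheric_pressure total pressure used to convert a CO2
#'   partial pressure into a gas volume fraction, Pa.
#' @param spiracle_pairs number of abdominal spiracle pairs; whole-
#'   organism fluxes multiply the per-spiracle flux by `2 * spiracle_pairs`.
#' @return a list of class `physical_constants`.
#' @export
physical_constants <- function(krogh_K = 1.428104e-10,
                               flux_conversion = 3.6e12,
                               atmospheric_pressure = 101325,
                               spiracle_pairs = 6) {
  stopifnot(krogh_K > 0, flux_conversion > 0, atmospheric_pressure > 0,
            spiracle_pairs > 0)
  structure(list(krogh_K = krogh_K, flux_conversion = flux_conversion,
                 atmospheric_pressure = atmospheric_pressure,
                 spiracle_pairs = spiracle_pairs),
            class = "physical_constants")
}

#' Metabolic CO2 flux reference points
#'
#' Whole-organism CO2 production rates an average ant must void: at rest
#' and while walking/running (means over literature estimates), plus the
#' fraction of body mass treated as metabolically active tissue.
#'
#' @param resting_flux ul CO2 h^-1 at rest.
#' @param active_flux ul CO2 h^-1 walking/running.
#' @param tissue_active_fraction fraction of mass that is metabolically
#'   active (the rest, e.g. cuticle, is treated as inert).
#' @return a list of class `metabolic_reference`.
#' @export
metabolic_reference <- function(resting_flux = 10.63, active_flux = 115,
                                tissue_active_fraction = 0.7) {
  stopifnot(resting_flux > 0, active_flux > resting_flux,
            tissue_active_fraction > 0, tissue_active_fraction <= 1)
  structure(list(resting_flux = resting_flux, active_flux = active_flux,
                 tissue_active_fraction = tissue_active_fraction),
            class = "metabolic_reference")
}

#' Build the symmetric five-level model tracheal geometry
#'
#' The model ant tracheal network behind one spiracle: five bifurcating
#' levels, level 1 at the spiracle and level 5 the deepest (tissue)
#' level, with `n_l = 2^(l-1)` branches per level. Radii follow the
#' branching-exponent rule outward from the deepest radius:
#' `r_l = 2^((5-l)/alpha) * r_5`, so `alpha = 1` doubles the radius at
#' each outward level (area-decreasing network), `alpha = 2` multiplies
#' by sqrt(2) (area-preserving) and `alpha = 3` by 2^(1/3)
#' (area-increasing).
#'
#' @param alpha branching exponent (> 0).
#' @param r5_um deepest-level branch radius, um.
#' @param lengths_um branch lengths level 1 to 5, um (defaults sum to
#'   3694 um).
#' @return a list of class `tracheal_geometry`: `alpha`, `lengths_m`,
#'   `radii_m`, `counts` (branches per level, per spiracle), `levels`.
#' @examples
#' build_geometry(1)$radii_m * 1e6   # 48 24 12 6 3
#' @export
build_geometry <- function(alpha, r5_um = 3,
                           lengths_um = c(1569, 976, 586, 352, 211)) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be positive", call. = FALSE)
  stopifnot(r5_um > 0, length(lengths_um) == 5, all(lengths_um > 0))
  l <- 1:5
  structure(list(
    alpha = alpha,
    lengths_m = lengths_um * 1e-6,
    radii_m = 2^((5 - l) / alpha) * r5_um * 1e-6,
    counts = 2^(l - 1),
    levels = l
  ), class = "tracheal_geometry")
}

#' @export
print.tracheal_geometry <- function(x, ...) {
  cat(sprintf("tracheal_geometry (alpha = %g): radii %s um, lengths %s um\n",
              x$alpha, paste(signif(x$radii_m * 1e6, 4), collapse = "/"),
              paste(signif(x$lengths_m * 1e6, 4), collapse = "/")))
  invisible(x)
}

#' Boundary conditions of the steady-state diffusion model
#'
#' All pressures are CO2 partial pressures above the external
#' environment (external air is the zero of the pressure coordinate; a
#' CO2-rich environment is represented by a smaller gradient).
#'
#' @param delta_pp CO2 partial-pressure difference between the deepest
#'   level and the outside, Pa (4000/6000/8000 in the study scenarios).
#' @param influx_levels levels receiving distributed CO2 influx from the
#'   tissue (influx is known to occur at levels 3-5).
#' @param air_sac_level `NULL` (no sac) or 3 or 4: an air sac at the
#'   proximal end of that level acts as a pressure release, truncating
#'   the modelled domain; efflux proximal to the sac is projected.
#' @return a list of class `boundary_conditions`.
#' @export
boundary_conditions <- function(delta_pp = 6000, influx_levels = 3:5,
                                air_sac_level = NULL) {
  stopifnot(delta_pp > 0, all(influx_levels %in% 1:5))
  if (!is.null(air_sac_level) && !(air_sac_level %in% c(3, 4))) {
    stop("air_sac_level must be NULL, 3 or 4", call. = FALSE)
  }
  structure(list(delta_pp = delta_pp,
                 influx_levels = sort(unique(as.integer(influx_levels))),
                 air_sac_level = if (is.null(air_sac_level)) NULL else
                   as.integer(air_sac_level)),
            class = "boundary_conditions")
}

#' Series-resistance flux with no wall influx
#'
#' Treats the five levels as fluidic channels in series under Fick
#' diffusion (`J = (A / L) K dpp` per channel): the flux through the
#' whole chain is `delta_pp / sum_l [L_l / (K n_l pi r_l^2)]`. This is
#' the no-influx degenerate case of [solve_steady_state()] and an
#' independent check of the resistance assembly.
#'
#' @param geometry a [build_geometry()] object.
#' @param delta_pp driving partial-pressure difference, Pa.
#' @param constants a [physical_constants()] object.
#' @return flux per spiracle in ul h^-1.
#' @export
series_flux_no_influx <- function(geometry, delta_pp = 6000,
                                  constants = physical_constants()) {
  a <- geometry$counts * pi * geometry$radii_m^2
  resistance <- sum(geometry$lengths_m / (constants$krogh_K * a))
  delta_pp / resistance * constants$flux_conversion
}

#' Total airway volume of the model geometry
#'
#' @param geometry a [build_geometry()] object.
#' @return volume per spiracle, m^3 (`sum_l n_l pi r_l^2 L_l`).
#' @export
tracheal_volume <- function(geometry) {
  sum(geometry$counts * pi * geometry$radii_m^2 * geometry$lengths_m)
}

#' Steady-state diffusion with distributed tissue influx
#'
#' Reduces the symmetric bifurcating tree behind one spiracle to a 1-D
#' serial chain with effective cross-section `a_l = n_l pi r_l^2` per
#' level. Within each level, steady Fick diffusion with a uniform wall
#' source of strength `phi` (volumetric CO2 influx per unit wall area;
#' optionally per unit branch length):
#'
#' `d/dx (K a_l dp/dx) = -phi w_l` on influx levels, `w_l = n_l 2 pi r_l`
#'
#' with outward flux `J(x) = K a_l dp/dx`. Boundary conditions: zero flux
#' at the closed level-5 tips, `p = 0` at the open (spiracle or air-sac)
#' end, and `p = delta_pp` at the level-5 tip. Because the solution is
#' linear in `phi`, the influx density satisfying all three conditions is
#' closed-form, and the pressure profile is piecewise quadratic. With an
#' air sac the domain is the levels from the sac inward, with the sac at
#' external pressure.
#'
#' When `influx_levels` is empty the tip condition is dropped and the
#' solution degenerates to the series-resistance flux with `phi = 0`.
#'
#' @param geometry a [build_geometry()] object.
#' @param bc a [boundary_conditions()] object.
#' @param constants a [physical_constants()] object.
#' @param influx_mode `"wall_area"` (source proportional to wall area,
#'   default) or `"length"` (per unit branch length).
#' @return a list of class `steady_state_solution`: `phi` (m^3 CO2 m^-2
#'   s^-1), `levels` (modelled levels, sac to tip), `junction_pressures`
#'   (Pa, at the proximal end of each modelled level plus the tip),
#'   `flux_at_level_top` (m^3 s^-1 per spiracle at each modelled level's
#'   proximal end), plus the inputs and per-level coefficients needed to
#'   evaluate the piecewise-quadratic profile.
#' @export
solve_steady_state <- function(geometry, bc = boundary_conditions(),
                               constants = physical_constants(),
                               influx_mode = c("wall_area", "length")) {
  influx_mode <- match.arg(influx_mode)
  levels <- if (is.null(bc$air_sac_level)) 1:5 else bc$air_sac_level:5
  K <- constants$krogh_K
  a <- (geometry$counts * pi * geometry$radii_m^2)[levels]
  L <- geometry$lengths_m[levels]
  w <- switch(influx_mode,
              wall_area = (geometry$counts * 2 * pi * geometry$radii_m)[levels],
              length = geometry$counts[levels])
  w[!(levels %in% bc$influx_levels)] <- 0

  nl <- length(levels)
  ## influx source (per unit phi) strictly distal to each level
  S <- rev(cumsum(rev(w * L))) - w * L
  if (all(w == 0)) {
    J <- bc$delta_pp / sum(L / (K * a))          # series degenerate case
    phi <- 0
    pressures <- c(0, cumsum(J * L / (K * a)))
    flux_top <- rep(J, nl)
  } else {
    ## p(tip) - p(open end) = phi * sum_l [S_l L_l + w_l L_l^2 / 2] / (K a_l)
    phi <- K * bc$delta_pp / sum((S * L + w * L^2 / 2) / a)
    pressures <- c(0, cumsum(phi * (S * L + w * L^2 / 2) / (K * a)))
    flux_top <- phi * (S + w * L)
  }
  structure(list(
    phi = phi,
    levels = levels,
    junction_pressures = pressures,
    flux_at_level_top = flux_top,
    geometry = geometry, bc = bc, constants = constants,
    influx_mode = influx_mode,
    a = a, w = w, S = S, L = L
  ), class = "steady_state_solution")
}

#' @export
print.steady_state_solution <- function(x, ...) {
  cat(sprintf(
    "steady_state_solution: levels %s, delta_pp %g Pa, phi %.4g m3 m-2 s-1\n",
    paste(range(x$levels), collapse = "-"), x$bc$delta_pp, x$phi))
  cat(sprintf("flux at open end: %.4g ul/h per spiracle\n",
              x$flux_at_level_top[1] * x$constants$flux_conversion))
  invisible(x)
}

#' Evaluate the piecewise-quadratic pressure profile
#'
#' @param solution a [solve_steady_state()] result.
#' @param n_per_level sample points per modelled level.
#' @return a data frame (`level`, `x_m` distance from the open end, `p_pa`).
#' @export
steady_state_pressure <- function(solution, n_per_level = 50) {
  K <- solution$constants$krogh_K
  x0 <- 0
  out <- list()
  for (i in seq_along(solution$levels)) {
    t <- seq(0, solution$L[i], length.out = n_per_level)
    p <- solution$junction_pressures[i] + solution$phi / (K * solution$a[i]) *
      (solution$S[i] * t + solution$w[i] * (solution$L[i] * t - t^2 / 2))
    if (solution$phi == 0) {  # series case: linear profile
      J <- solution$flux_at_level_top[i]
      p <- solution$junction_pressures[i] + J * t / (K * solution$a[i])
    }
    out[[i]] <- data.frame(level = solution$levels[i], x_m = x0 + t, p_pa = p)
    x0 <- x0 + solution$L[i]
  }
  do.call(rbind, out)
}

#' Whole-organism flux profile across tracheal levels
#'
#' Converts a per-spiracle steady state into the whole-organism CO2
#' efflux available at each tracheal level (`x 2 * spiracle_pairs`,
#' in ul h^-1) and classifies each against the resting and walking
#' metabolic thresholds. Levels proximal to an air sac are not modelled:
#' they carry the flux entering the sac, flagged `projected` (the sac
#' removes the hydraulic resistance of the proximal levels).
#'
#' @param solution a [solve_steady_state()] result.
#' @param reference a [metabolic_reference()].
#' @return a data frame of class `flux_profile` (`level`, `flux_ul_h`,
#'   `projected`, `meets_resting`, `meets_walking`).
#' @export
flux_profile <- function(solution, reference = metabolic_reference()) {
  const <- solution$constants
  n_spir <- 2 * const$spiracle_pairs
  flux <- solution$flux_at_level_top * const$flux_conversion * n_spir
  level <- solution$levels
  projected <- rep(FALSE, length(level))
  if (min(level) > 1L) {  # air sac: project the sac-entry flux outward
    proximal <- seq_len(min(level) - 1L)
    level <- c(proximal, level)
    flux <- c(rep(flux[1], length(proximal)), flux)
    projected <- c(rep(TRUE, length(proximal)), projected)
  }
  out <- data.frame(
    level = level, flux_ul_h = flux, projected = projected,
    meets_resting = flux >= reference$resting_flux,
    meets_walking = flux >= reference$active_flux)
  class(out) <- c("flux_profile", "data.frame")
  out
}

#' Periodic-convection CO2 flux
#'
#' Models discontinuous convective ventilation: each exhalation expels a
#' fraction of the entire airway volume, carrying CO2 at the local
#' steady-state partial pressures. The expelled CO2 volume per breath is
#' `evacuation_fraction * V_airway * mean_pp / P_atm`, with `mean_pp`
#' the mean of the steady-state profile `p(x)` along the airway path
#' (`pp_averaging = "length"`, default) or weighted by local
#' cross-sectional area (`"volume"`). Hourly flux is breaths per hour
#' times the per-breath volume; flux is exactly linear in both frequency
#' and evacuation fraction.
#'
#' @param solution a [solve_steady_state()] result (no-sac steady state
#'   in the study configuration).
#' @param frequency tracheal contraction frequency, Hz.
#' @param evacuation_fraction fraction of the airway expelled per breath.
#' @param pp_averaging `"length"` or `"volume"` (see Details).
#' @return a list of class `convection_result`: `per_spiracle_volume_m3`,
#'   `mean_pp_pa`, `per_breath_co2_m3`, `convective_flux_ul_h` (per
#'   spiracle), `whole_organism_flux_ul_h`, `frequency`,
#'   `evacuation_fraction`.
#' @export
convective_flux <- function(solution, frequency = 0.26,
                            evacuation_fraction = 0.66,
                            pp_averaging = c("length", "volume")) {
  pp_averaging <- match.arg(pp_averaging)
  if (frequency <= 0 || evacuation_fraction <= 0) {
    stop("frequency and evacuation_fraction must be positive", call. = FALSE)
  }
  K <- solution$constants$krogh_K
  L <- solution$L; a <- solution$a
  ## per-level integrals of p(t) dt and a p(t) dt (piecewise quadratic)
  int_p <- numeric(length(L))
  for (i in seq_along(L)) {
    P0 <- solution$junction_pressures[i]
    if (solution$phi == 0) {
      J <- solution$flux_at_level_top[i]
      int_p[i] <- P0 * L[i] + J * L[i]^2 / (2 * K * a[i])
    } else {
      int_p[i] <- P0 * L[i] + solution$phi / (K * a[i]) *
        (solution$S[i] * L[i]^2 / 2 + solution$w[i] * L[i]^3 / 3)
    }
  }
  vol <- sum(a * L)
  mean_pp <- switch(pp_averaging,
                    length = sum(int_p) / sum(L),
                    volume = sum(a * int_p) / vol)
  per_breath <- evacuation_fraction * vol * mean_pp /
    solution$constants$atmospheric_pressure
  per_spiracle <- per_breath * frequency * 3600 * 1e9   # m3/breath -> ul/h
  structure(list(
    per_spiracle_volume_m3 = vol,
    mean_pp_pa = mean_pp,
    pp_averaging = pp_averaging,
    per_breath_co2_m3 = per_breath,
    convective_flux_ul_h = per_spiracle,
    whole_organism_flux_ul_h = per_spiracle *
      2 * solution$constants$spiracle_pairs,
    frequency = frequency,
    evacuation_fraction = evacuation_fraction
  ), class = "convection_result")
}

#' @export
print.convection_result <- function(x, ...) {
  cat(sprintf(
    "convection: %.3g ul/h per spiracle (%.3g whole organism) at %g Hz, %g%% evacuation\n",
    x$convective_flux_ul_h, x$whole_organism_flux_ul_h, x$frequency,
    100 * x$evacuation_fraction))
  invisible(x)
}

#' Convert a metabolic-rate record to a CO2 flux
#'
#' Literature metabolic rates come as CO2 production, O2 consumption or
#' metabolic power; all are converted to ul CO2 h^-1 (O2 scaled by the
#' respiratory quotient; power via the oxyjoule equivalent).
#'
#' @param value the measured rate (>= 0).
#' @param unit `"ul_co2_per_h"`, `"ul_o2_per_h"` or `"uW"`.
#' @param respiratory_quotient CO2 produced per O2 consumed.
#' @param joule_per_ml_o2 oxyjoule equivalent, J per ml O2.
#' @return CO2 flux in ul h^-1.
#' @export
convert_metabolic_rate <- function(value,
                                   unit = c("ul_co2_per_h", "ul_o2_per_h", "uW"),
                                   respiratory_quotient = 0.84,
                                   joule_per_ml_o2 = 20.1) {
  unit <- match.arg(unit)
  if (any(value < 0)) stop("metabolic rate must be non-negative", call. = FALSE)
  switch(unit,
    ul_co2_per_h = value,
    ul_o2_per_h = value * respiratory_quotient,
    uW = {
      ul_o2_per_h <- value * 1e-6 * 3600 / joule_per_ml_o2 * 1000
      ul_o2_per_h * respiratory_quotient
    })
}

#' Mass-specific flux of active tissue
#'
#' @param whole_flux whole-organism CO2 flux, ul h^-1.
#' @param mass_g body mass, g.
#' @param active_fraction metabolically active fraction of mass.
#' @return flux per gram of active tissue, ul h^-1 g^-1.
#' @export
tissue_level_flux <- function(whole_flux, mass_g, active_fraction = 0.7) {
  if (any(mass_g <= 0)) stop("mass must be positive", call. = FALSE)
  whole_flux / (active_fraction * mass_g)
}

#' Factorial sweep over exponents, gradients and air-sac placements
#'
#' Evaluates the steady-state model over the full factorial grid of
#' branching exponents, partial-pressure gradients and air-sac
#' configurations, summarising each scenario by the whole-organism
#' efflux at its exit and its sufficiency against the metabolic
#' thresholds.
#'
#' @param alphas branching exponents.
#' @param delta_pps partial-pressure gradients, Pa.
#' @param sac_levels list of air-sac placements (`NA` for none, else 3
#'   or 4).
#' @param constants a [physical_constants()].
#' @param reference a [metabolic_reference()].
#' @param influx_levels levels receiving tissue influx.
#' @param influx_mode see [solve_steady_state()].
#' @return a data frame with one row per scenario (`alpha`,
#'   `delta_pp_kpa`, `air_sac_level`, `flux_ul_h` whole-organism,
#'   `meets_resting`, `meets_walking`); attribute `profiles` holds the
#'   long per-level table (`level`, `flux_ul_per_h`, `projected`, ...).
#' @export
scenario_sweep <- function(alphas = c(1, 2, 3),
                           delta_pps = c(4000, 6000, 8000),
                           sac_levels = c(NA, 3, 4),
                           constants = physical_constants(),
                           reference = metabolic_reference(),
                           influx_levels = 3:5,
                           influx_mode = "wall_area") {
  rows <- list(); profiles <- list()
  for (a in alphas) {
    geom <- build_geometry(a)
    for (dpp in delta_pps) {
      for (sac in sac_levels) {
        sac_arg <- if (is.na(sac)) NULL else sac
        bc <- boundary_conditions(delta_pp = dpp,
                                  influx_levels = influx_levels,
                                  air_sac_level = sac_arg)
        sol <- solve_steady_state(geom, bc, constants, influx_mode)
        prof <- flux_profile(sol, reference)
        exit_flux <- prof$flux_ul_h[prof$level == min(sol$levels)]
        rows[[length(rows) + 1L]] <- data.frame(
          alpha = a, delta_pp_kpa = dpp / 1000,
          air_sac_level = if (is.na(sac)) "none" else as.character(sac),
          flux_ul_h = exit_flux,
          meets_resting = exit_flux >= reference$resting_flux,
          meets_walking = exit_flux >= reference$active_flux,
          stringsAsFactors = FALSE)
        profiles[[length(profiles) + 1L]] <- cbind(
          alpha = a, delta_pp_kpa = dpp / 1000,
          air_sac_level = if (is.na(sac)) "none" else as.character(sac),
          prof)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "profiles") <- do.call(rbind, profiles)
  out
}
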