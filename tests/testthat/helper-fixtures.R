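# Worked-example radii (um) from the tomography renders: a trifurcating
# Camponotus-like individual and a bifurcating Myrmecia-like individual.
trifurcation_event <- function() {
  branching_event(29.15, c(13.87, 10.11, 5.59), "L1_2", "camponotus_like")
}
bifurcation_event <- function() {
  branching_event(32.83, c(17.67, 14.44), "L1_2", "myrmecia_like")
}

# All three events of the bifurcating individual (level-3 radii included).
bifurcating_individual_events <- function() {
  list(
    branching_event(32.83, c(17.67, 14.44), "L1_2", "myrmecia_like"),
    branching_event(17.67, c(11.78, 8.13), "L2a_3", "myrmecia_like"),
    branching_event(14.44, c(6.19, 6.61), "L2b_3", "myrmecia_like"))
}

# 8-record toy table: 1 parent, 3 children, 4 grandchildren under 2a/2b.
toy_measurement_df <- function() {
  data.frame(
    individual_id = "cs01",
    species = "C_suffusus",
    level = c(1L, 2L, 2L, 2L, 3L, 3L, 3L, 3L),
    branch_path = c("1", "2a", "2b", "2c", "3a1", "3a2", "3b1", "3b2"),
    radius_um = c(29.15, 13.87, 10.11, 5.59, 6.35, 8.02, 5.40, 5.24),
    stringsAsFactors = FALSE)
}

toy_measurement_file <- function() {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(toy_measurement_df(), path, row.names = FALSE, quote = FALSE)
  path
}

# Independent bisection oracle for the exponent (no shared code with the
# package solver): 200 plain bisection steps on g(a) = sum((rj/ri)^a) - 1.
bisect_alpha <- function(ri, rj, lo = 1e-6, hi = 64) {
  g <- function(a) sum((rj / ri)^a) - 1
  for (i in 1:200) {
    m <- (lo + hi) / 2
    if (g(m) > 0) lo <- m else hi <- m
  }
  (lo + hi) / 2
}

# Independent finite-difference/quadrature oracle for the steady state:
# J(x) = phi * W(x) follows from mass conservation alone; the pressure
# drop is integrated on a fine grid, and phi rescaled so the tip sits at
# delta_pp. Shares no algebra with the closed-form solution.
fd_steady_state <- function(geometry, bc, constants, nodes = 1e4,
                            influx_mode = "wall_area") {
  levels <- if (is.null(bc$air_sac_level)) 1:5 else bc$air_sac_level:5
  a <- (geometry$counts * pi * geometry$radii_m^2)[levels]
  L <- geometry$lengths_m[levels]
  w <- switch(influx_mode,
              wall_area = (geometry$counts * 2 * pi * geometry$radii_m)[levels],
              length = geometry$counts[levels])
  w[!(levels %in% bc$influx_levels)] <- 0
  total <- sum(L)
  x <- seq(0, total, length.out = nodes)
  edges <- c(0, cumsum(L))
  lev_of <- findInterval(x, edges, rightmost.closed = TRUE)
  a_x <- a[lev_of]; w_x <- w[lev_of]
  # W(x): influx wall measure distal to x (per unit phi), trapezoid tail sum
  dx <- diff(x)
  seg <- (w_x[-1] + w_x[-length(x)]) / 2 * dx
  W <- rev(c(0, cumsum(rev(seg))))
  integrand <- W / (constants$krogh_K * a_x)
  p_unit <- c(0, cumsum((integrand[-1] + integrand[-length(x)]) / 2 * dx))
  phi <- bc$delta_pp / p_unit[length(x)]
  W_at <- stats::approx(x, W, xout = edges[-length(edges)])$y
  list(phi = phi,
       flux_at_level_top = phi * W_at,
       levels = levels,
       pressure = phi * p_unit, x = x)
}
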