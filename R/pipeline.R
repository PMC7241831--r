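#' Configuration for the full analysis pipeline
#'
#' Exactly one of `input` (a measurement CSV path) or `generator` (a
#' [generator_config()]) must be supplied as the data source.
#'
#' @param input path to a measurement CSV, or `NULL`.
#' @param generator a [generator_config()], or `NULL`.
#' @param event_classes event classes to analyse.
#' @param alphas candidate exponents for the regression grid.
#' @param outlier_k IQR fence multiplier ([exclude_outliers()]).
#' @param references log10-scale reference exponents for the t-tests.
#' @param delta_pps gradients for the model sweep, Pa.
#' @param sac_levels air-sac placements for the sweep.
#' @param constants a [physical_constants()].
#' @param reference a [metabolic_reference()].
#' @param seed seed recorded in the provenance header and used for any
#'   randomness (overrides the generator's own seed).
#' @param output_dir directory for CSV/report output, or `NULL` to skip
#'   writing.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, generator = NULL,
                            event_classes = c("L1_2", "L2a_3", "L2b_3"),
                            alphas = c(1, 2, 3), outlier_k = 3,
                            references = c(0.30, 0.48),
                            delta_pps = c(4000, 6000, 8000),
                            sac_levels = c(NA, 3, 4),
                            constants = physical_constants(),
                            reference = metabolic_reference(),
                            seed = 1L, output_dir = NULL) {
  if (is.null(input) && is.null(generator)) {
    stop("pipeline needs either an input file or a generator config",
         call. = FALSE)
  }
  if (!is.null(input) && !file.exists(input)) {
    stop("input file does not exist: ", input, call. = FALSE)
  }
  if (!is.null(generator)) {
    stopifnot(inherits(generator, "generator_config"))
    generator$seed <- as.integer(seed)
  }
  structure(list(input = input, generator = generator,
                 event_classes = event_classes, alphas = alphas,
                 outlier_k = outlier_k, references = references,
                 delta_pps = delta_pps, sac_levels = sac_levels,
                 constants = constants, reference = reference,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

config_digest <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  slim <- config[!(names(config) %in% "output_dir")]
  jsonlite::write_json(slim, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages in analysis order: load or generate the
#' measurement table; solve the branching exponent per event with
#' per-class summaries and reference t-tests; fit the exponent-candidate
#' regression grid; run the gas-exchange scenario sweep and the
#' convection model (area-decreasing geometry, 6 kPa, no sac). The
#' bundle is a pure function of the configuration and seed.
#'
#' @param config a [pipeline_config()].
#' @return a list of class `pipeline_bundle`: `table`, `estimates`,
#'   `summaries` (per event class), `pooled_alpha` (per individual),
#'   `regression_grid`, `sweep`, `convection`, `provenance`. If
#'   `config$output_dir` is set, CSVs and a text report are written
#'   there, each with a provenance comment header.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  table <- if (!is.null(config$generator)) {
    generate_dataset(config$generator)
  } else {
    read_measurement_table(config$input)
  }

  estimates <- list(); summaries <- list()
  for (cl in config$event_classes) {
    events <- extract_events(table, cl)
    if (length(events) == 0L) next
    est <- solve_events(events)
    estimates[[cl]] <- est
    if (sum(est$converged) >= 3L) {
      summaries[[cl]] <- summarize_exponents(est, config$references)
    }
  }
  est_df <- do.call(rbind, c(estimates, list(make.row.names = FALSE)))

  pooled <- vapply(unique(table$individual_id), function(id) {
    ev <- Filter(function(e) max(e$child_radii) < e$parent_radius,
                 Filter(function(e) e$individual_id == id,
                        extract_all_events(table)))
    if (length(ev) == 0L) return(NA_real_)
    as.numeric(pooled_individual_alpha(ev))
  }, numeric(1))

  grid <- compare_alphas(table, config$alphas,
                         intersect(config$event_classes,
                                   c("L1_2", "L2a_3", "L2b_3")),
                         config$outlier_k)
  sweep <- scenario_sweep(config$alphas, config$delta_pps,
                          config$sac_levels, config$constants,
                          config$reference)
  conv <- convective_flux(
    solve_steady_state(build_geometry(1),
                       boundary_conditions(delta_pp = 6000),
                       config$constants))

  bundle <- structure(list(
    table = table, estimates = est_df, summaries = summaries,
    pooled_alpha = pooled, regression_grid = grid, sweep = sweep,
    convection = conv,
    provenance = list(
      package = "tracheoflux",
      version = as.character(utils::packageVersion("tracheoflux")),
      seed = config$seed,
      config_digest = config_digest(config))
  ), class = "pipeline_bundle")

  if (!is.null(config$output_dir)) {
    write_pipeline_outputs(bundle, config$output_dir)
  }
  bundle
}

provenance_header <- function(bundle) {
  p <- bundle$provenance
  c(sprintf("# package: %s %s", p$package, p$version),
    sprintf("# seed: %d", p$seed),
    sprintf("# config: %s", p$config_digest))
}

write_csv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Write the pipeline outputs to a directory
#'
#' One CSV per stage (`estimates.csv`, `regression_grid.csv`,
#' `sweep.csv`, `sweep_profiles.csv`) plus `report.txt`, each headed by
#' provenance comment lines (package version, seed, config digest), so
#' re-running an identical configuration reproduces the files
#' byte-identically.
#'
#' @param bundle a [run_full_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- provenance_header(bundle)
  write_csv_with_header(bundle$estimates, file.path(dir, "estimates.csv"), hdr)
  write_csv_with_header(bundle$regression_grid,
                        file.path(dir, "regression_grid.csv"), hdr)
  write_csv_with_header(bundle$sweep, file.path(dir, "sweep.csv"), hdr)
  write_csv_with_header(attr(bundle$sweep, "profiles"),
                        file.path(dir, "sweep_profiles.csv"), hdr)
  writeLines(c(hdr, render_summary(bundle)), file.path(dir, "report.txt"))
  invisible(dir)
}

#' Render a human-readable pipeline report
#'
#' @param bundle a [run_full_pipeline()] result.
#' @return a character vector of report lines.
#' @export
render_summary <- function(bundle) {
  lines <- c("== tracheal branching analysis ==",
             provenance_header(bundle), "")
  if (is.null(bundle$estimates) || nrow(bundle$estimates) == 0L) {
    lines <- c(lines, "no events: nothing to summarise")
    return(lines)
  }
  lines <- c(lines, "-- branching exponents --")
  for (cl in names(bundle$summaries)) {
    s <- bundle$summaries[[cl]]
    lines <- c(lines, sprintf(
      "%s: n = %d, median alpha = %.3f, skewness = %.2f, mean log10 = %.4f [%.4f, %.4f]",
      cl, s$n, s$median_alpha, s$skewness, s$mean_log10_alpha,
      s$ci95_log10[1], s$ci95_log10[2]))
    for (i in seq_len(nrow(s$t_vs_ref))) {
      r <- s$t_vs_ref[i, ]
      lines <- c(lines, sprintf("    vs %.2f: t = %.2f, df = %d, p = %.3g",
                                r$reference, r$t, r$df, r$p))
    }
  }
  pooled <- bundle$pooled_alpha[is.finite(bundle$pooled_alpha)]
  if (length(pooled) > 0L) {
    lines <- c(lines, sprintf(
      "pooled per-individual alpha: n = %d, median = %.3f",
      length(pooled), stats::median(pooled)))
  }
  lines <- c(lines, "", "-- slope grid (slope closest to 1 wins) --")
  g <- bundle$regression_grid
  for (i in seq_len(nrow(g))) {
    lines <- c(lines, sprintf(
      "%s alpha=%g %-10s slope = %.4f [%.4f, %.4f]%s",
      g$event_class[i], g$alpha[i], g$method[i], g$slope[i], g$ci_lo[i],
      g$ci_hi[i], if (g$best[i]) "  <- best" else ""))
  }
  best_counts <- table(g$alpha[g$best])
  best_alpha <- names(best_counts)[which.max(best_counts)]
  lines <- c(lines, sprintf("best-supported exponent: alpha = %s", best_alpha),
             "", "-- gas-exchange sweep (whole-organism efflux) --")
  s <- bundle$sweep
  for (i in seq_len(nrow(s))) {
    lines <- c(lines, sprintf(
      "alpha=%g dpp=%g kPa sac=%-4s flux = %8.3f ul/h  rest:%s walk:%s",
      s$alpha[i], s$delta_pp_kpa[i], s$air_sac_level[i], s$flux_ul_h[i],
      ifelse(s$meets_resting[i], "yes", "no"),
      ifelse(s$meets_walking[i], "yes", "no")))
  }
  cv <- bundle$convection
  lines <- c(lines, "", sprintf(
    "convection (alpha=1, 6 kPa, no sac): %.3f ul/h per spiracle, %.2f whole organism",
    cv$convective_flux_ul_h, cv$whole_organism_flux_ul_h))
  lines
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat(render_summary(x), sep = "\n")
  invisible(x)
}
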