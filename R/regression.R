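#' Power-transformed parent/child pairs
#'
#' For the regression test of branching geometry, each event is reduced
#' to the two sides of the branching relation at a candidate exponent:
#' `x = r_parent^alpha` against `y = sum_j r_child_j^alpha`. If the data
#' branch with exponent `alpha`, the points fall on the identity line, so
#' the candidate whose fitted slope is closest to 1 has the greatest
#' empirical support.
#'
#' @param events list of [branching_event()]s.
#' @param alpha candidate exponent (1, 2 or 3 in the classical laws).
#' @return a data frame (`individual_id`, `event_class`, `parent_radius`,
#'   `x`, `y`, `alpha_used`, `outlier_flag` initialised `FALSE`).
#' @export
transform_power <- function(events, alpha) {
  stopifnot(length(alpha) == 1L, alpha > 0)
  data.frame(
    individual_id = vapply(events, `[[`, character(1), "individual_id"),
    event_class = vapply(events, `[[`, character(1), "event_class"),
    parent_radius = vapply(events, `[[`, numeric(1), "parent_radius"),
    x = vapply(events, function(e) e$parent_radius^alpha, numeric(1)),
    y = vapply(events, function(e) sum(e$child_radii^alpha), numeric(1)),
    alpha_used = alpha,
    outlier_flag = FALSE,
    stringsAsFactors = FALSE)
}

#' Flag size outliers by an IQR fence on parent radius
#'
#' Pairs whose parent radius lies beyond `k` interquartile ranges outside
#' the quartiles of their event class are flagged (never dropped); the
#' default `k = 3` is a conservative reading of "clearly outside the
#' size range of most of the data". All regressions report how many
#' flagged pairs they left out.
#'
#' @param pairs a data frame from [transform_power()].
#' @param k fence multiplier.
#' @return `pairs` with `outlier_flag` set; attribute `exclusion_report`
#'   is a data frame of per-class flag counts.
#' @export
exclude_outliers <- function(pairs, k = 3) {
  stopifnot(nrow(pairs) >= 4)
  for (cl in unique(pairs$event_class)) {
    idx <- pairs$event_class == cl
    q <- stats::quantile(pairs$parent_radius[idx], c(0.25, 0.75), names = FALSE)
    fence <- c(q[1] - k * (q[2] - q[1]), q[2] + k * (q[2] - q[1]))
    pairs$outlier_flag[idx] <- pairs$parent_radius[idx] < fence[1] |
      pairs$parent_radius[idx] > fence[2]
  }
  report <- stats::aggregate(outlier_flag ~ event_class, pairs, sum)
  names(report)[2] <- "n_flagged"
  attr(pairs, "exclusion_report") <- report
  pairs
}

regression_result <- function(method, slope, intercept, slope_se, ci95,
                              n_used, n_excluded, extra = list()) {
  structure(c(list(method = method, slope = slope, intercept = intercept,
                   slope_se = slope_se, ci95_slope = ci95,
                   n_used = n_used, n_excluded = n_excluded), extra),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("%s: slope %.4f", x$method, x$slope))
  if (!is.na(x$slope_se)) cat(sprintf(" (SE %.4f)", x$slope_se))
  cat(sprintf(", 95%% CI [%.4f, %.4f], n = %d (+%d excluded)\n",
              x$ci95_slope[1], x$ci95_slope[2], x$n_used, x$n_excluded))
  invisible(x)
}

#' Ordinary least squares through the origin
#'
#' Model I regression of `y` on `x` with the intercept forced through the
#' origin: `slope = sum(xy)/sum(x^2)`, standard error
#' `sqrt(sum((y - bx)^2) / (n - 1) / sum(x^2))`, CI from the t
#' distribution with `n - 1` df. Flagged outliers are left out.
#'
#' @param pairs data frame with `x`, `y` and `outlier_flag` columns.
#' @param conf confidence level.
#' @return a `regression_result`.
#' @export
ols_through_origin <- function(pairs, conf = 0.95) {
  used <- pairs[!pairs$outlier_flag, , drop = FALSE]
  n <- nrow(used)
  if (n < 2L) stop("need at least 2 unflagged pairs", call. = FALSE)
  if (all(used$x == 0)) stop("all x are zero", call. = FALSE)
  fit <- stats::lm(y ~ 0 + x, data = used)
  slope <- unname(stats::coef(fit)[1])
  se <- unname(summary(fit)$coefficients[1, 2])
  ci <- unname(stats::confint(fit, level = conf)[1, ])
  regression_result("OLS-origin", slope, 0, se, ci, n,
                    nrow(pairs) - n, list(fit = fit))
}

## Exact F-based CI for the Major Axis slope (Jolicoeur's rotation test,
## inverted in closed form). Rotating the data by theta, the covariance
## between residual and axis scores is suv(theta) = R cos(2 theta - psi),
## while suu*svv - suv^2 equals the (rotation-invariant) covariance
## determinant; the test F = (n-2) r_uv^2 / (1 - r_uv^2) crosses its
## critical value where suv^2 = Fcrit * det / (n-2), i.e. at the axis
## angle +/- asin(sqrt(q))/2.
ma_slope_ci_F <- function(slope, sxx, syy, sxy, n, conf) {
  det <- sxx * syy - sxy^2
  R2 <- ((syy - sxx) / 2)^2 + sxy^2
  q <- stats::qf(conf, 1, n - 2) * det / ((n - 2) * R2)
  if (det <= 0 || q < .Machine$double.eps) return(c(slope, slope))  # exact fit
  if (q >= 1) return(c(-Inf, Inf))  # axis orientation unresolved
  sort(tan(atan(slope) + c(-1, 1) * 0.5 * asin(sqrt(q))))
}

#' Major Axis (Model II) regression
#'
#' Fits the major axis of the bivariate scatter, appropriate when the
#' same measurement error is expected in both variables (both sides of
#' the branching relation are powers of radii measured identically).
#' Slope is the first principal axis,
#' `((s_yy - s_xx) + sqrt((s_yy - s_xx)^2 + 4 s_xy^2)) / (2 s_xy)`, the
#' intercept is free (`ybar - slope * xbar`). The default confidence
#' interval inverts the exact F rotation test (the slope values whose
#' residual/axis correlation is compatible with zero at the given
#' level); `ci = "bootstrap"` gives a percentile bootstrap instead.
#'
#' @param pairs data frame with `x`, `y`, `outlier_flag`.
#' @param conf confidence level.
#' @param ci `"F"` (exact rotation test, default) or `"bootstrap"`.
#' @param n_boot bootstrap replicates when `ci = "bootstrap"`.
#' @return a `regression_result` (the `slope_se` slot is `NA`: Model II
#'   slopes are summarised by their CI).
#' @export
major_axis <- function(pairs, conf = 0.95, ci = c("F", "bootstrap"),
                       n_boot = 1999) {
  ci <- match.arg(ci)
  used <- pairs[!pairs$outlier_flag, , drop = FALSE]
  n <- nrow(used)
  if (n < 3L) stop("need at least 3 unflagged pairs", call. = FALSE)
  sxx <- stats::var(used$x); syy <- stats::var(used$y)
  sxy <- stats::cov(used$x, used$y)
  if (sxy == 0) stop("undefined Major Axis slope: zero covariance", call. = FALSE)
  slope <- ((syy - sxx) + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  intercept <- mean(used$y) - slope * mean(used$x)

  if (ci == "bootstrap") {
    reps <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      sx <- stats::var(used$x[i]); sy <- stats::var(used$y[i])
      sv <- stats::cov(used$x[i], used$y[i])
      if (sv == 0) return(NA_real_)
      ((sy - sx) + sqrt((sy - sx)^2 + 4 * sv^2)) / (2 * sv)
    }, numeric(1))
    lims <- stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                            na.rm = TRUE, names = FALSE)
  } else {
    lims <- ma_slope_ci_F(slope, sxx, syy, sxy, n, conf)
  }
  regression_result("MajorAxis", slope, intercept, NA_real_, lims, n,
                    nrow(pairs) - n)
}

#' Species random-intercept check
#'
#' Fits `y ~ x` with a per-species random intercept (restricted maximum
#' likelihood, via `nlme::lme`) to check that the fitted slope is not an
#' artefact of between-species differences in size. With a single
#' species, or when the mixed fit degenerates (estimated between-species
#' standard deviation ~ 0), the fit falls back to ordinary least squares
#' with a warning / by construction gives the OLS slope.
#'
#' @param pairs data frame with `x`, `y`, `outlier_flag`.
#' @param species character vector of species labels, one per row of
#'   `pairs`.
#' @param conf confidence level for the slope interval.
#' @return a `regression_result` with extra elements `species_sd` (the
#'   between-species standard deviation), `species_sd_ci` (its interval,
#'   `NA` on fallback) and `fallback_ols`.
#' @export
random_intercept_fit <- function(pairs, species, conf = 0.95) {
  used <- !pairs$outlier_flag
  df <- data.frame(x = pairs$x[used], y = pairs$y[used],
                   species = as.character(species[used]),
                   stringsAsFactors = FALSE)
  n <- nrow(df)
  ols_fallback <- function() {
    fit <- stats::lm(y ~ x, data = df)
    regression_result(
      "RandomIntercept", unname(stats::coef(fit)[2]),
      unname(stats::coef(fit)[1]),
      unname(summary(fit)$coefficients[2, 2]),
      unname(stats::confint(fit, level = conf)[2, ]), n,
      nrow(pairs) - n,
      list(species_sd = 0, species_sd_ci = c(NA_real_, NA_real_),
           fallback_ols = TRUE))
  }
  if (length(unique(df$species)) < 2L) {
    warning("only one species: falling back to OLS", call. = FALSE)
    return(ols_fallback())
  }
  fit <- tryCatch(
    nlme::lme(y ~ x, random = ~ 1 | species, data = df, method = "REML"),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("mixed model failed to converge: falling back to OLS",
            call. = FALSE)
    return(ols_fallback())
  }
  fx <- nlme::fixef(fit)
  sm <- summary(fit)$tTable
  sd_sp <- as.numeric(nlme::VarCorr(fit)["(Intercept)", "StdDev"])
  sd_ci <- tryCatch({
    iv <- nlme::intervals(fit, level = conf, which = "var-cov")
    as.numeric(iv$reStruct$species[c("lower", "upper")])
  }, error = function(e) c(NA_real_, NA_real_))
  se <- sm["x", "Std.Error"]
  tq <- stats::qt(1 - (1 - conf) / 2, sm["x", "DF"])
  regression_result(
    "RandomIntercept", unname(fx["x"]), unname(fx["(Intercept)"]), se,
    unname(fx["x"]) + c(-1, 1) * tq * se, n, nrow(pairs) - n,
    list(species_sd = sd_sp, species_sd_ci = sd_ci, fallback_ols = FALSE,
         fit = fit))
}

#' Slope grid over candidate exponents and regression methods
#'
#' For each event class in the table and each candidate exponent, fits
#' the origin-forced OLS and the Major Axis regression of the summed
#' child term on the parent term, and identifies the exponent whose
#' slope is closest to 1 per class and method.
#'
#' @param table a `measurement_table`.
#' @param alphas candidate exponents.
#' @param event_classes classes to analyse (defaults to all with >= 4
#'   events).
#' @param outlier_k IQR fence multiplier, see [exclude_outliers()];
#'   `NULL` disables exclusion.
#' @return a data frame with one row per class x exponent x method
#'   (`slope`, `slope_se`, `ci_lo`, `ci_hi`, `abs_dev = |slope - 1|`,
#'   `n_used`, `n_excluded`, `best` flagging the winning exponent).
#' @export
compare_alphas <- function(table, alphas = c(1, 2, 3),
                           event_classes = c("L1_2", "L2a_3", "L2b_3"),
                           outlier_k = 3) {
  rows <- list()
  for (cl in event_classes) {
    events <- extract_events(table, cl)
    if (length(events) < 4L) next
    for (a in alphas) {
      pairs <- transform_power(events, a)
      if (!is.null(outlier_k)) pairs <- exclude_outliers(pairs, k = outlier_k)
      for (m in c("OLS-origin", "MajorAxis")) {
        fit <- if (m == "OLS-origin") ols_through_origin(pairs) else
          major_axis(pairs)
        rows[[length(rows) + 1L]] <- data.frame(
          event_class = cl, alpha = a, method = m, slope = fit$slope,
          slope_se = fit$slope_se, ci_lo = fit$ci95_slope[1],
          ci_hi = fit$ci95_slope[2], abs_dev = abs(fit$slope - 1),
          n_used = fit$n_used, n_excluded = fit$n_excluded,
          stringsAsFactors = FALSE)
      }
    }
  }
  grid <- do.call(rbind, rows)
  grid$best <- FALSE
  for (cl in unique(grid$event_class)) {
    for (m in unique(grid$method)) {
      idx <- which(grid$event_class == cl & grid$method == m)
      grid$best[idx[which.min(grid$abs_dev[idx])]] <- TRUE
    }
  }
  grid
}
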