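#' Solve for the branching exponent of one event
#'
#' The branching exponent `alpha` relates a parent branch radius to the
#' radii of its children through `r_parent^alpha = sum_j r_child_j^alpha`
#' (two children for a bifurcation, extended to the 3- and 4-child
#' events). Dividing by the parent radius, `alpha` is the root of
#'
#' `g(alpha) = sum_j (r_j / r_i)^alpha - 1`,
#'
#' which is strictly decreasing in `alpha` when every child is smaller
#' than its parent, so the root is unique. The root is bracketed and
#' refined with [stats::uniroot()], expanding the upper bound when the
#' children are nearly as large as the parent, and polished until
#' `|g(alpha)| <= tolerance`.
#'
#' `alpha = 2` corresponds to area-preserving branching (Da Vinci's
#' rule), `alpha = 3` to area-increasing branching (Murray's law) and
#' `alpha = 1` to radius-conserving, area-decreasing branching.
#'
#' @param event a [branching_event()], or a single parent radius when
#'   `child_radii` is given.
#' @param child_radii child radii when `event` is a bare parent radius.
#' @param tolerance convergence criterion on `|g(alpha)|`.
#' @param bracket initial search interval for the root.
#' @return a list of class `exponent_estimate`: `alpha`, `converged`,
#'   `residual` (`|g|` expressed on the normalised scale), `n_children`,
#'   `event_class`, `individual_id`.
#' @examples
#' solve_branching_exponent(branching_event(2, c(1, 1)))$alpha    # 1
#' solve_branching_exponent(sqrt(2), c(1, 1))$alpha               # 2
#' @export
solve_branching_exponent <- function(event, child_radii = NULL,
                                     tolerance = 1e-10,
                                     bracket = c(1e-6, 64)) {
  if (!inherits(event, "branching_event")) {
    event <- branching_event(event, child_radii, "L1_2")
  }
  ri <- event$parent_radius
  rj <- event$child_radii
  if (max(rj) >= ri) {
    stop("no root: a child radius (", signif(max(rj), 6),
         ") is >= the parent radius (", signif(ri, 6), ")", call. = FALSE)
  }
  ratios <- rj / ri
  g <- function(a) sum(ratios^a) - 1
  lo <- bracket[1]; hi <- bracket[2]
  while (g(hi) > 0 && hi < 1e6) hi <- hi * 2   # children ~ parent: root beyond 64
  converged <- FALSE
  alpha <- NA_real_
  if (g(hi) <= 0) {
    root <- stats::uniroot(g, c(lo, hi), tol = .Machine$double.eps^0.75)
    alpha <- root$root
    ## one or two Newton polishes push |g| to the requested tolerance
    for (k in 1:3) {
      if (abs(g(alpha)) <= tolerance) break
      deriv <- sum(log(ratios) * ratios^alpha)
      alpha <- alpha - g(alpha) / deriv
    }
    converged <- abs(g(alpha)) <= tolerance
  }
  structure(list(alpha = alpha, converged = converged,
                 residual = abs(g(alpha)),
                 n_children = length(rj),
                 event_class = event$event_class,
                 individual_id = event$individual_id),
            class = "exponent_estimate")
}

#' Closed-form exponent for a symmetric event
#'
#' When all `n` children share one radius, the branching relation
#' collapses to `ratio^alpha = n` with `ratio` the parent/child radius
#' ratio, so `alpha = log(n) / log(ratio)`. Serves as an independent
#' check of the root-finding solver.
#'
#' @param n_children number of equal children (>= 2).
#' @param ratio parent/child radius ratio (> 1).
#' @return the exponent.
#' @export
closed_form_symmetric_alpha <- function(n_children, ratio) {
  stopifnot(n_children >= 2)
  if (any(ratio <= 1)) stop("ratio must exceed 1", call. = FALSE)
  log(n_children) / log(ratio)
}

#' Solve every event in a list
#'
#' Events whose largest child is not smaller than the parent admit no
#' root and are excluded (and counted), not imputed.
#'
#' @param events a list of [branching_event()]s.
#' @param ... passed to [solve_branching_exponent()].
#' @return a data frame with one row per solvable event
#'   (`individual_id`, `event_class`, `alpha`, `converged`, `residual`,
#'   `n_children`) and attribute `n_excluded`.
#' @export
solve_events <- function(events, ...) {
  keep <- vapply(events, function(e) max(e$child_radii) < e$parent_radius,
                 logical(1))
  est <- lapply(events[keep], solve_branching_exponent, ...)
  out <- data.frame(
    individual_id = vapply(est, `[[`, character(1), "individual_id"),
    event_class = vapply(est, `[[`, character(1), "event_class"),
    alpha = vapply(est, `[[`, numeric(1), "alpha"),
    converged = vapply(est, `[[`, logical(1), "converged"),
    residual = vapply(est, `[[`, numeric(1), "residual"),
    n_children = vapply(est, `[[`, integer(1), "n_children"),
    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(!keep)
  out
}

## moment skewness m3 / m2^(3/2); the common default moment estimator
moment_skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m3 / m2^1.5
}

#' Summarise a sample of branching exponents
#'
#' Reproduces the study's summary pipeline: median and skewness of the
#' raw exponents, then a log10 transform (the raw distribution is
#' right-skewed) and one-sample two-sided t-tests of the mean log10
#' exponent against the reference values log10(2) = 0.30 (area-preserving)
#' and log10(3) = 0.48 (area-increasing), with the 95% CI of the mean.
#'
#' @param estimates a data frame from [solve_events()], or a numeric
#'   vector of exponents.
#' @param references log10-scale reference values to test against.
#' @return a list of class `exponent_summary`: `n`, `median_alpha`,
#'   `skewness`, `mean_log10_alpha`, `sd_log10_alpha`, `ci95_log10`,
#'   and `t_vs_ref` (data frame `reference`, `t`, `df`, `p`; `t` is `NA`
#'   and `degenerate` is set when the sample is constant).
#' @export
summarize_exponents <- function(estimates, references = c(0.30, 0.48)) {
  alpha <- if (is.data.frame(estimates)) {
    estimates$alpha[estimates$converged]
  } else {
    as.numeric(estimates)
  }
  alpha <- alpha[is.finite(alpha)]
  if (length(alpha) < 3L) stop("need at least 3 converged estimates", call. = FALSE)
  l10 <- log10(alpha)
  n <- length(l10)
  degenerate <- stats::sd(l10) == 0
  tests <- lapply(references, function(ref) {
    if (degenerate) {
      return(data.frame(reference = ref, t = NA_real_, df = n - 1L,
                        p = NA_real_))
    }
    tt <- stats::t.test(l10, mu = ref)
    data.frame(reference = ref, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value)
  })
  ci <- if (degenerate) rep(mean(l10), 2) else
    as.numeric(stats::t.test(l10)$conf.int)
  structure(list(
    n = n,
    median_alpha = stats::median(alpha),
    skewness = moment_skewness(alpha),
    mean_log10_alpha = mean(l10),
    sd_log10_alpha = stats::sd(l10),
    ci95_log10 = ci,
    t_vs_ref = do.call(rbind, tests),
    degenerate = degenerate
  ), class = "exponent_summary")
}

#' @export
print.exponent_summary <- function(x, ...) {
  cat(sprintf("n = %d, median alpha = %.3f, skewness = %.2f\n",
              x$n, x$median_alpha, x$skewness))
  cat(sprintf("log10 alpha: mean %.4f (95%% CI %.4f to %.4f)\n",
              x$mean_log10_alpha, x$ci95_log10[1], x$ci95_log10[2]))
  for (i in seq_len(nrow(x$t_vs_ref))) {
    r <- x$t_vs_ref[i, ]
    cat(sprintf("  vs %.2f: t = %.2f, df = %d, p = %.3g\n",
                r$reference, r$t, r$df, r$p))
  }
  invisible(x)
}

#' Pooled exponent across all events of one individual
#'
#' Solves for a single exponent across several branching events
#' simultaneously by minimising the sum of squared residuals of
#' `g_e(alpha) = sum_j (r_j/r_i)^alpha - 1` over the individual's events
#' (each event normalised by its own parent radius, so events on
#' different scales weigh equally). With a single event this reduces to
#' the exact root.
#'
#' @param events list of the individual's [branching_event()]s.
#' @param interval search interval for the exponent.
#' @return the pooled exponent (numeric scalar) with attribute `ssr`.
#' @export
pooled_individual_alpha <- function(events, interval = c(1e-3, 64)) {
  if (length(events) == 0L) stop("no events", call. = FALSE)
  resid_one <- function(e, a) sum((e$child_radii / e$parent_radius)^a) - 1
  ssr <- function(a) sum(vapply(events, resid_one, numeric(1), a = a)^2)
  opt <- stats::optimize(ssr, interval, tol = 1e-10)
  ## optimize can stall on flat shoulders; refine around the minimum
  opt2 <- stats::optimize(ssr, pmax(c(opt$minimum / 2, opt$minimum * 2),
                                    interval[1]), tol = 1e-12)
  best <- if (opt2$objective < opt$objective) opt2 else opt
  structure(best$minimum, ssr = best$objective)
}
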