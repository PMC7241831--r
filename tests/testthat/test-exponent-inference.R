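test_that("the solver reproduces closed-form and worked-example exponents", {
  expect_equal(solve_branching_exponent(2.0, c(1, 1))$alpha, 1.0,
               tolerance = 1e-9)
  expect_equal(solve_branching_exponent(sqrt(2), c(1, 1))$alpha, 2.0,
               tolerance = 1e-9)
  # frozen values from a 200-step bisection oracle
  expect_equal(solve_branching_exponent(bifurcation_event())$alpha,
               0.9687854, tolerance = 1e-6)
  expect_equal(solve_branching_exponent(trifurcation_event())$alpha,
               1.0139996, tolerance = 1e-6)
  est <- solve_branching_exponent(bifurcation_event())
  expect_true(est$converged)
  expect_lte(est$residual, 1e-10)
})

test_that("domain errors are raised for unsolvable events", {
  expect_error(solve_branching_exponent(2, c(1, 2.5)), ">=")
  expect_error(solve_branching_exponent(2, c(2, 1)), ">=")
  expect_error(branching_event(2, 1), "2-4")
  expect_error(closed_form_symmetric_alpha(2, 0.9), "exceed 1")
  expect_equal(closed_form_symmetric_alpha(2, 2.0), 1.0)
  expect_equal(closed_form_symmetric_alpha(2, sqrt(2)), 2.0, tolerance = 1e-6)
  expect_equal(closed_form_symmetric_alpha(3, 3.0), 1.0)
})

test_that("solver agrees with the symmetric closed form on random events", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(2:4, 1)
    ratio <- runif(1, 1.05, 6)
    est <- solve_branching_exponent(ratio, rep(1, n))
    expect_lt(abs(est$alpha - closed_form_symmetric_alpha(n, ratio)), 1e-8)
  }
})

test_that("the root is scale-invariant and monotone in child radii", {
  set.seed(7)
  for (i in 1:50) {
    ri <- runif(1, 10, 50)
    rj <- ri * sort(runif(sample(2:4, 1), 0.2, 0.95))
    base <- solve_branching_exponent(ri, rj)$alpha
    for (c_scale in c(1e-3, 0.5, 7, 1e3)) {
      expect_equal(solve_branching_exponent(ri * c_scale, rj * c_scale)$alpha,
                   base, tolerance = 1e-10)
    }
    # growing one child (still below the parent) increases the exponent
    rj2 <- rj
    k <- sample(length(rj), 1)
    rj2[k] <- rj2[k] + 0.5 * (ri - rj2[k])
    expect_gt(solve_branching_exponent(ri, rj2)$alpha, base)
  }
})

test_that("near-parent children need the expanded bracket and still solve", {
  est <- solve_branching_exponent(10, c(9.99, 9.99))  # root ~ 693
  expect_true(est$converged)
  expect_lte(est$residual, 1e-10)
  expect_gt(est$alpha, 64)  # beyond the default bracket
  expect_equal(est$alpha, closed_form_symmetric_alpha(2, 10 / 9.99),
               tolerance = 1e-8)
})

test_that("exponent summaries reproduce the t-test pipeline", {
  # hand-checked: log10 alpha {0, 0, 0.3} vs 0.3 -> t = -2, df = 2
  s <- summarize_exponents(10^c(0, 0, 0.3), references = 0.3)
  expect_equal(s$t_vs_ref$t, -2, tolerance = 1e-10)
  expect_equal(s$t_vs_ref$df, 2)

  # mean equals the reference -> t = 0
  s0 <- summarize_exponents(10^c(0.25, 0.30, 0.35), references = 0.3)
  expect_equal(s0$t_vs_ref$t, 0, tolerance = 1e-10)

  # df = n - 1 and CI contains the mean
  set.seed(1)
  alphas <- exp(rnorm(165, 0, 0.3))
  s165 <- summarize_exponents(alphas)
  expect_equal(unique(s165$t_vs_ref$df), 164)
  expect_gte(s165$mean_log10_alpha, s165$ci95_log10[1])
  expect_lte(s165$mean_log10_alpha, s165$ci95_log10[2])

  # constant sample vs a different reference: flagged, not thrown
  sc <- summarize_exponents(c(2, 2, 2), references = 0.3)
  expect_true(sc$degenerate)
  expect_true(is.na(sc$t_vs_ref$t))
})

test_that("the skewness estimator matches the independent implementation", {
  set.seed(2)
  x <- rlnorm(200, 0, 0.4)
  ours <- summarize_exponents(x)$skewness
  expect_equal(ours, e1071::skewness(x, type = 1), tolerance = 1e-12)
})

test_that("pooled individual exponent minimises the joint residual", {
  # single event reduces to the exact root
  expect_equal(as.numeric(pooled_individual_alpha(
    list(branching_event(2, c(1, 1))))), 1.0, tolerance = 1e-6)

  # consistent noiseless events recover the construction exponent
  set.seed(3)
  evs <- replicate(4, generate_event(runif(1, 10, 40), 2, 2), simplify = FALSE)
  expect_equal(as.numeric(pooled_individual_alpha(evs)), 2.0, tolerance = 1e-6)

  # worked-example individual: frozen 1e-4 grid-search oracle value
  pooled <- pooled_individual_alpha(bifurcating_individual_events())
  expect_equal(as.numeric(pooled), 0.9873, tolerance = 1e-3)
})

test_that("solve_events excludes and counts unsolvable events", {
  evs <- list(branching_event(2, c(1, 1)), branching_event(2, c(2.5, 1)))
  est <- solve_events(evs)
  expect_equal(nrow(est), 1L)
  expect_equal(attr(est, "n_excluded"), 1L)
})
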