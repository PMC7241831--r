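make_pairs <- function(x, y, class = "L1_2") {
  data.frame(individual_id = as.character(seq_along(x)), event_class = class,
             parent_radius = x, x = x, y = y, alpha_used = 1,
             outlier_flag = FALSE, stringsAsFactors = FALSE)
}

test_that("power transform evaluates both sides of the branching relation", {
  evs <- list(branching_event(2, c(1, 1)))
  p1 <- transform_power(evs, 1)
  expect_equal(c(p1$x, p1$y), c(2, 2))
  p2 <- transform_power(evs, 2)
  expect_equal(c(p2$x, p2$y), c(4, 2))
  p3 <- transform_power(list(trifurcation_event()), 1)
  expect_equal(p3$x, 29.15)
  expect_equal(p3$y, 13.87 + 10.11 + 5.59)  # 29.57
})

test_that("the IQR fence flags implanted extremes and nothing else", {
  set.seed(20)
  x <- runif(20, 10, 20)
  pairs <- make_pairs(x, x)
  expect_equal(sum(exclude_outliers(pairs)$outlier_flag), 0L)

  pairs$parent_radius[1] <- pairs$x[1] <- 150  # 10x the rest
  flagged <- exclude_outliers(pairs)
  expect_true(flagged$outlier_flag[1])
  expect_equal(sum(flagged$outlier_flag), 1L)

  # 165 homogeneous pairs with 6 implanted extremes
  x165 <- c(runif(159, 20, 30), runif(6, 200, 300))
  p165 <- exclude_outliers(make_pairs(x165, x165), k = 3)
  expect_equal(sum(p165$outlier_flag), 6L)
  expect_true(all(which(p165$outlier_flag) > 159))
  rep <- attr(p165, "exclusion_report")
  expect_equal(rep$n_flagged[rep$event_class == "L1_2"], 6)
})

test_that("origin-forced OLS matches the closed form", {
  exact <- suppressWarnings(   # lm warns on the exact fit
    ols_through_origin(make_pairs(c(1, 2, 3), c(2, 4, 6))))
  expect_equal(exact$slope, 2)
  expect_equal(exact$slope_se, 0)

  hand <- ols_through_origin(make_pairs(c(1, 2), c(1, 3)))
  expect_equal(hand$slope, 7 / 5)   # sum(xy)/sum(x^2)
  b <- hand$slope
  se_hand <- sqrt(sum((c(1, 3) - b * c(1, 2))^2) / (2 - 1) / sum(c(1, 2)^2))
  expect_equal(hand$slope_se, se_hand)
  expect_equal(hand$n_used + hand$n_excluded, 2L)
})

test_that("Major Axis slope matches the closed form and its symmetry", {
  ident <- major_axis(make_pairs(c(0, 1, 2), c(0, 1, 2)))
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0)

  hand <- major_axis(make_pairs(c(1, 2, 3), c(3, 5, 7)))
  expect_equal(hand$slope, 2)  # sxx=1, syy=4, sxy=2

  set.seed(4)
  x <- runif(30); y <- 0.6 * x + rnorm(30, 0, 0.1)
  fwd <- major_axis(make_pairs(x, y))
  rev <- major_axis(make_pairs(y, x))
  expect_equal(rev$slope, 1 / fwd$slope, tolerance = 1e-10)

  expect_error(major_axis(make_pairs(c(1, 1, 2, 2), c(1, 1, 1, 1))),
               "covariance")
})

test_that("the F-based MA interval brackets the slope and matches bootstrap", {
  set.seed(5)
  x <- runif(120, 1, 3); y <- 1.5 * x + rnorm(120, 0, 0.3)
  pairs <- make_pairs(x, y)
  f_ci <- major_axis(pairs, ci = "F")
  expect_lt(f_ci$ci95_slope[1], f_ci$slope)
  expect_gt(f_ci$ci95_slope[2], f_ci$slope)
  b_ci <- major_axis(pairs, ci = "bootstrap", n_boot = 3999)
  expect_equal(f_ci$ci95_slope, b_ci$ci95_slope, tolerance = 0.06)
})

test_that("OLS and MA agree on data exactly on a line through the origin", {
  x <- seq(1, 10)
  pairs <- make_pairs(x, 1.7 * x)
  ols <- suppressWarnings(ols_through_origin(pairs))  # exact-fit warning
  expect_lt(abs(ols$slope - major_axis(pairs)$slope), 1e-6)
})

test_that("the species random-intercept fit degenerates to OLS cleanly", {
  set.seed(6)
  x <- runif(60, 1, 5)
  y <- 2 * x + rnorm(60, 0, 0.2)
  species <- rep(sprintf("sp%d", 1:6), each = 10)
  pairs <- make_pairs(x, y)
  mixed <- suppressWarnings(random_intercept_fit(pairs, species))
  ols <- coef(lm(y ~ x))[2]
  if (mixed$species_sd < 1e-6) {
    expect_equal(mixed$slope, unname(ols), tolerance = 1e-8)
  } else {
    expect_equal(mixed$slope, unname(ols), tolerance = 0.05)
  }
  expect_warning(random_intercept_fit(pairs, rep("only_one", 60)),
                 "one species")
})

test_that("the random-intercept fit recovers a species variance component", {
  set.seed(8)
  n_sp <- 20; per <- 10
  species <- rep(sprintf("sp%02d", 1:n_sp), each = per)
  b_sp <- rnorm(n_sp, 0, 0.3)[rep(1:n_sp, each = per)]
  x <- runif(n_sp * per, 1, 5)
  y <- 1 + 1 * x + b_sp + rnorm(n_sp * per, 0, 0.1)
  fit <- random_intercept_fit(make_pairs(x, y), species)
  expect_false(fit$fallback_ols)
  expect_gte(0.3, fit$species_sd_ci[1])
  expect_lte(0.3, fit$species_sd_ci[2])
  expect_equal(fit$slope, 1, tolerance = 0.05)
})

test_that("compare_alphas selects the generating exponent", {
  for (true_a in c(1, 2)) {
    tab <- generate_dataset(generator_config(
      n_individuals = 60, true_alpha = true_a, noise_log_sd = 0,
      seed = 30 + true_a))
    grid <- suppressWarnings(  # noiseless data: exact-fit lm warnings
      compare_alphas(tab, event_classes = "L1_2"))
    best <- grid[grid$best, ]
    expect_true(all(best$alpha == true_a))
    expect_equal(best$slope[best$method == "OLS-origin"], 1, tolerance = 1e-9)
  }
})

test_that("noisy data still separate the exponents decisively", {
  tab <- generate_dataset(generator_config(
    n_individuals = 200, true_alpha = 1, noise_log_sd = 0.05, seed = 14))
  grid <- compare_alphas(tab, event_classes = "L1_2")
  ols <- grid[grid$method == "OLS-origin", ]
  expect_equal(ols$alpha[which.min(ols$abs_dev)], 1)
  expect_lt(ols$abs_dev[ols$alpha == 1], 0.03)
  for (a in 2:3) {
    row <- ols[ols$alpha == a, ]
    expect_gt(row$abs_dev, 5 * row$slope_se)
  }
  expect_true(all(grid$n_used + grid$n_excluded ==
                    length(extract_events(tab, "L1_2"))))
})

test_that("the winning exponent is stable across noise levels", {
  wins <- vapply(1:40, function(r) {
    tab <- generate_dataset(generator_config(
      n_individuals = 60, true_alpha = 1, noise_log_sd = 0.1,
      seed = 1000 + r))
    grid <- compare_alphas(tab, event_classes = "L1_2")
    ols <- grid[grid$method == "OLS-origin", ]
    ols$alpha[which.min(ols$abs_dev)] == 1
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})
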