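test_that("focal proportion handles ordinary and degenerate counts", {
  expect_equal(focal_proportion(3, 1)$p, 0.75)
  expect_equal(focal_proportion(0, 7)$p, 0)
  zero <- focal_proportion(0, 0)
  expect_false(zero$defined)
  expect_true(is.na(zero$p))
  expect_equal(zero$n_total, 0)
})

test_that("population estimates pool counts before dividing", {
  est <- population_estimate(data.frame(focal = c(1, 5), gfp = c(3, 1)),
                             "p1", source = "model")
  expect_equal(est$pooled_p, 0.6)
  expect_equal(est$per_image_p, c(0.25, 5 / 6))
  expect_equal(est$sd_p, sd(c(0.25, 5 / 6)))
  expect_equal(round(est$sd_p, 4), 0.4125)
  # 10 identical images
  same <- population_estimate(data.frame(focal = rep(2, 10), gfp = rep(2, 10)))
  expect_equal(same$pooled_p, 0.5)
  expect_equal(same$sd_p, 0)
  # pooled_p is the total-weighted mean of per-image proportions
  counts <- data.frame(focal = c(2, 8, 1), gfp = c(6, 2, 9))
  est2 <- population_estimate(counts)
  tot <- counts$focal + counts$gfp
  expect_equal(est2$pooled_p, weighted.mean(counts$focal / tot, tot))
  # empty images are excluded from per-image p but kept in pooled sums
  est3 <- population_estimate(data.frame(focal = c(3, 0), gfp = c(1, 0)))
  expect_equal(length(est3$per_image_p), 1L)
  expect_equal(est3$n_excluded, 1L)
  expect_equal(est3$pooled_p, 0.75)
  expect_error(population_estimate(data.frame(focal = 0, gfp = 0)), "empty")
})

test_that("proportion differences require one model and one by-eye estimate", {
  m <- focal_proportion(6, 4, "model")
  e <- focal_proportion(5, 5, "by_eye")
  expect_equal(proportion_difference(m, e), 0.1)
  expect_equal(proportion_difference(m, focal_proportion(6, 4, "by_eye")), 0)
  expect_error(proportion_difference(m, focal_proportion(1, 1, "model")),
               "source")
  expect_error(proportion_difference(m, focal_proportion(0, 0, "by_eye")),
               "undefined")
})

test_that("ols_fit reproduces exact lines and textbook closed forms", {
  fit <- ols_fit(c(0, 1, 2), c(2, 5, 8))
  expect_equal(fit$a, 2)
  expect_equal(fit$b, 3)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$df, 1L)
  # constant y: flat line, R^2 = 0 by convention
  flat <- ols_fit(c(0, 1, 2, 3), c(4, 4, 4, 4))
  expect_equal(flat$b, 0)
  expect_equal(flat$r_squared, 0)
  expect_equal(flat$p_value, 1)
  # closed forms b = cov/var, a = ybar - b xbar on random data
  withr::with_seed(5, {
    x <- rnorm(40)
    y <- 1.5 - 2 * x + rnorm(40)
    f <- ols_fit(x, y)
    expect_equal(f$b, cov(x, y) / var(x), tolerance = 1e-12)
    expect_equal(f$a, mean(y) - f$b * mean(x), tolerance = 1e-12)
  })
  expect_error(ols_fit(c(1, 1, 1), c(1, 2, 3)), "singular|constant")
  expect_error(ols_fit(c(1, 2), c(1, 2)), "at least 3")
})

test_that("recovered regression slope sits within 3 SE on noisy simulations", {
  withr::with_seed(17, {
    x <- runif(550, 0, 1)
    y <- 0.3 + 0.8 * x + rnorm(550, 0, 0.2)
    fit <- ols_fit(x, y)
    expect_lt(abs(fit$b - 0.8), 3 * fit$se_b)
    expect_equal(fit$df, 548L)
  })
})

test_that("wilcoxon_paired handles the documented conventions", {
  # all pairs equal: no signal, p = 1
  eq <- wilcoxon_paired(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$p_value, 1)
  expect_equal(eq$n_effective, 0L)
  # 3 pairs, all differences negative, no ties: exact two-sided p = 2/8
  res <- wilcoxon_paired(c(1, 2, 3), c(2, 4, 7))
  expect_equal(res$p_value, 0.25)
  expect_equal(res$n_effective, 3L)
  expect_error(wilcoxon_paired(1:3, 1:4), "equal length")
})

test_that("exact branch equals enumeration for n <= 10 and matches wilcox.test", {
  withr::with_seed(23, {
    for (n in c(3, 5, 8, 10)) {
      for (rep in 1:3) {
        x <- round(rnorm(n), 1)
        y <- round(rnorm(n), 1)
        if (all(x == y)) next
        got <- wilcoxon_paired(x, y)
        expect_equal(got$p_value, oracle_wilcoxon_enum(x, y),
                     tolerance = 1e-12,
                     label = sprintf("n=%d rep=%d", n, rep))
        # tie-free cases also agree with the standard exact test
        d <- x - y
        d <- d[d != 0]
        if (!any(duplicated(abs(d))) && length(d) > 0) {
          ref <- suppressWarnings(wilcox.test(x, y, paired = TRUE,
                                              exact = TRUE))
          expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
        }
      }
    }
  })
})

test_that("exact and normal branches agree closely at the crossover size", {
  withr::with_seed(29, {
    diffs <- numeric(10)
    for (rep in 1:10) {
      x <- rnorm(25)
      y <- rnorm(25)
      exact <- wilcoxon_paired(x, y, exact_max = 25L)
      approx <- wilcoxon_paired(x, y, exact_max = 0L)
      diffs[rep] <- abs(exact$p_value - approx$p_value)
    }
    expect_lt(max(diffs), 0.01)
  })
})

test_that("variability comparison is degenerate on identical methods", {
  counts <- lapply(1:4, function(i) {
    withr::with_seed(40 + i, data.frame(
      focal = rpois(10, 20), gfp = rpois(10, 15)
    ))
  })
  pops_m <- lapply(1:4, function(i) {
    population_estimate(counts[[i]], sprintf("p%d", i), "model")
  })
  pops_e <- lapply(1:4, function(i) {
    population_estimate(counts[[i]], sprintf("p%d", i), "by_eye")
  })
  vc <- variability_comparison(pops_m, pops_e)
  expect_equal(vc$wilcoxon_proportions$p_value, 1)
  expect_equal(vc$wilcoxon_sds$p_value, 1)
  expect_equal(vc$regression_model$b, vc$regression_eye$b)
})

test_that("per-image proportion SD follows the binomial law across p", {
  # binomial sampling: sd of per-image proportions ~ sqrt(p(1-p)/n)
  withr::with_seed(53, {
    n_per_image <- 60
    for (p in c(0.2, 0.5, 0.8)) {
      focal <- rbinom(400, n_per_image, p)
      est <- population_estimate(
        data.frame(focal = focal, gfp = n_per_image - focal)
      )
      expect_equal(est$sd_p, sqrt(p * (1 - p) / n_per_image),
                   tolerance = 0.15)
    }
  })
})
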