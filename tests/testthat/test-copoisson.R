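# Poisson/binomial co-expression model and the lambda estimator.

test_that("expression_probability matches closed form and Monte Carlo", {
  expect_identical(expression_probability(0, 3), 0)
  expect_equal(expression_probability(3 * log(2), 3), 0.5)

  # Monte-Carlo oracle: frequency of m >= 1 under Poisson(7.9 / 3)
  mc <- withr::with_seed(42, mean(rpois(1e6, 7.9 / 3) >= 1))
  p <- expression_probability(7.9, 3)
  expect_equal(p, 1 - exp(-7.9 / 3))
  expect_lt(abs(p - mc), 4 * sqrt(p * (1 - p) / 1e6))

  # strictly increasing in lambda, approaching 1
  grid <- expression_probability(seq(0.1, 60, length.out = 50), 3)
  expect_true(all(diff(grid) > 0))
  expect_gt(expression_probability(1e3, 3), 1 - 1e-12)

  expect_error(expression_probability(-1, 3), class = "cotransduce_invalid")
  expect_error(expression_probability(1, 1), class = "cotransduce_invalid")
})

test_that("color_count_pmf equals the truncated-enumeration oracle", {
  expect_equal(color_count_pmf(0, 3), c(1, 0, 0, 0))
  expect_equal(color_count_pmf(3 * log(2), 3), c(1, 3, 3, 1) / 8)

  for (lam in c(0.5, 2, 5, 10, 20)) {
    pmf <- color_count_pmf(lam, 3)
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
    expect_equal(pmf, oracle_color_pmf(lam, 3), tolerance = 1e-10)
  }
  # k != 3 sanity against the same oracle
  expect_equal(color_count_pmf(4, 5), oracle_color_pmf(4, 5),
               tolerance = 1e-10)
})

test_that("estimate_lambda reproduces the published in-vitro values", {
  t1 <- table1_counts()
  expect_equal(round_half_up(estimate_lambda(t1$low)$lambda_hat, 1), 7.9)
  expect_equal(round_half_up(estimate_lambda(t1$mid)$lambda_hat, 1), 12.4)

  sat <- estimate_lambda(t1$high)
  expect_true(sat$saturated)
  expect_false(is.finite(sat$lambda_hat))

  expect_identical(estimate_lambda(c(100, 0, 0, 0))$lambda_hat, 0)
  expect_error(estimate_lambda(c(0, 0, 0, 0)),
               class = "cotransduce_degenerate")
})

test_that("estimator is the exact inverse of the forward model", {
  rel_err <- vapply(seq(0.4, 40, length.out = 100), function(lam) {
    lam_hat <- estimate_lambda(expected_counts(lam, 1000))$lambda_hat
    abs(lam_hat - lam) / lam
  }, numeric(1))
  expect_lt(max(rel_err), 1e-9)
})

test_that("lambda_hat is strictly increasing in the expressed-color total", {
  n <- 500
  lams <- vapply(1:(3 * n - 1), function(s) {
    full <- s %/% 3
    rem <- s %% 3
    r <- c(n - full - (rem > 0), 0, 0, full)
    if (rem > 0) r[rem + 1] <- 1
    estimate_lambda(color_count_table(r))$lambda_hat
  }, numeric(1))
  expect_true(all(diff(lams) > 0))
})

test_that("bootstrap_ci gives seeded percentile intervals", {
  tab <- color_count_table(table1_counts()$low, label = "1e10")
  est1 <- bootstrap_ci(tab, n_boot = 2000, seed = 7)
  est2 <- bootstrap_ci(tab, n_boot = 2000, seed = 7)
  expect_identical(est1$ci_low, est2$ci_low)
  expect_true(est1$ci_low <= est1$lambda_hat &&
                est1$lambda_hat <= est1$ci_high)
  expect_true(est1$ci_low < 7.88 && est1$ci_high > 7.88)

  deg <- bootstrap_ci(c(50, 0, 0, 0), n_boot = 500, seed = 1)
  expect_identical(c(deg$ci_low, deg$ci_high), c(0, 0))

  expect_error(bootstrap_ci(c(0, 0, 0, 10), seed = 1),
               class = "cotransduce_degenerate")
  expect_error(bootstrap_ci(table1_counts()$low),
               class = "cotransduce_invalid")  # missing seed
})

test_that("binomial lower bound solves the exact tail equation", {
  n <- 1791
  lb <- lambda_lower_bound(c(0, 0, 0, n), alpha = 0.05)
  expect_identical(lb$method, "lower_bound_binomial")
  # closed form for m = 0: p = alpha^(1/(3N))
  p <- expression_probability(lb$lambda_hat, 3)
  expect_equal(p^(3 * n), 0.05, tolerance = 1e-6)

  # Monte-Carlo oracle: at lambda_LB, ~95% of experiments of n cells
  # contain at least one non-three-color cell
  hit <- withr::with_seed(11, {
    reps <- 4000
    m <- matrix(rpois(reps * n * 3, lb$lambda_hat / 3) >= 1, ncol = 3)
    all3 <- rowSums(m) == 3
    grp <- rep(seq_len(reps), each = n)
    mean(tapply(all3, grp, function(z) any(!z)))
  })
  expect_lt(abs(hit - 0.95), 4 * sqrt(0.95 * 0.05 / 4000) + 0.005)

  # decreasing in alpha, increasing in N (m = 0)
  lb10 <- lambda_lower_bound(c(0, 0, 0, n), alpha = 0.10)$lambda_hat
  expect_gt(lb10, lb$lambda_hat)
  lb_small <- lambda_lower_bound(c(0, 0, 0, 100), alpha = 0.05)$lambda_hat
  expect_lt(lb_small, lb$lambda_hat)

  # general m > 0 case satisfies the binomial tail equation
  tab <- c(0, 0, 3, 997)
  lbm <- lambda_lower_bound(tab, alpha = 0.05)
  p2 <- expression_probability(lbm$lambda_hat, 3)
  expect_equal(pbinom(3, 1000, 1 - p2^3), 0.05, tolerance = 1e-6)

  expect_error(lambda_lower_bound(c(10, 0, 0, 0)),
               class = "cotransduce_degenerate")
})

test_that("extrapolation lower bound matches a hand two-point fit", {
  t1 <- table1_counts()
  series <- dose_series(list(
    color_count_table(t1$low, dose = 1e10, label = "low"),
    color_count_table(t1$mid, dose = 5e10, label = "mid")
  ))
  lb <- lambda_lower_bound(color_count_table(t1$high, dose = 5e11),
                           method = "extrapolation", series = series)
  expect_identical(lb$method, "lower_bound_extrapolation")

  # independent closed-form two-point fit + numeric inversion
  f2 <- c(184 / 1750, 52 / 1773)
  slope <- diff(log(f2)) / diff(log(c(1e10, 5e10)))
  f2_hat <- exp(log(f2[2]) + slope * log(5e11 / 5e10))
  p_root <- uniroot(function(p) 3 * p^2 * (1 - p) - f2_hat,
                    c(2 / 3 + 1e-9, 1 - 1e-12), tol = 1e-12)$root
  expect_equal(lb$lambda_hat, -3 * log(1 - p_root), tolerance = 1e-6)
  expect_true(is.finite(lb$lambda_hat) && lb$lambda_hat > 0)

  # predicted fraction outside the invertible range signals
  flat <- dose_series(list(
    color_count_table(c(0, 0, 500, 500), dose = 1, label = "a"),
    color_count_table(c(0, 0, 500, 500), dose = 2, label = "b")
  ))
  expect_error(
    lambda_lower_bound(color_count_table(c(0, 0, 0, 100), dose = 4),
                       method = "extrapolation", series = flat),
    class = "cotransduce_degenerate")
})

test_that("expected_counts scales the pmf and closes the loop", {
  expect_equal(expected_counts(0, 100), c(100, 0, 0, 0))
  expect_equal(expected_counts(7, 0), c(0, 0, 0, 0))
  # fitted expected counts at the mid-dose lambda reproduce the
  # expressed-color total S exactly (the statistic the estimator
  # inverts) and the dominant class within binomial sampling error;
  # the real minor classes are overdispersed relative to the model.
  obs <- table1_counts()$mid
  lam <- estimate_lambda(obs)$lambda_hat
  cnt <- expected_counts(lam, sum(obs))
  expect_equal(sum(cnt), sum(obs))
  expect_equal(sum((0:3) * cnt), sum((0:3) * obs), tolerance = 1e-12)
  p3 <- color_count_pmf(lam)[4]
  expect_lt(abs(cnt[4] - obs[4]), 3 * sqrt(sum(obs) * p3 * (1 - p3)))
})

test_that("count-table CSV round trip is lossless", {
  tabs <- list(color_count_table(c(1, 2, 3, 4), label = "a", dose = 1e9),
               color_count_table(c(0, 0, 5, 95), label = "b", dose = 2e9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_color_counts(tabs, path)
  back <- read_color_counts(path)
  expect_equal(back[[1]]$counts, tabs[[1]]$counts)
  expect_equal(back[[2]]$dose, 2e9)
  expect_identical(back[[1]]$label, "a")
})
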