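# First-principles two-group log-rank oracle: observed-minus-expected and
# hypergeometric variance accumulated over the risk-set table.
logrank_oracle_stat <- function(t, e, g) {
  O <- 0; E <- 0; V <- 0
  for (tt in sort(unique(t[e == 1]))) {
    at_risk <- t >= tt
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    d <- sum(t == tt & e == 1)
    d1 <- sum(t == tt & e == 1 & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

test_that("KM reduces to one minus the ECDF without censoring", {
  t <- c(2, 5, 3, 8, 1, 7)
  cv <- km_curve(t, rep(1L, 6))
  for (i in seq_along(cv$event_times)) {
    expect_equal(cv$survival[i], mean(t > cv$event_times[i]))
  }
  expect_true(all(diff(cv$survival) <= 0))
  expect_true(all(cv$ci_lower <= cv$survival + 1e-12 &
                    cv$survival <= cv$ci_upper + 1e-12, na.rm = TRUE))
})

test_that("a fully censored sample has flat survival and unreached median", {
  cv <- km_curve(c(3, 6, 9), c(0L, 0L, 0L))
  expect_true(all(cv$survival == 1))
  med <- km_median(cv)
  expect_true(is.na(med$median))
})

test_that("KM tracks the exponential survivor function and its median", {
  set.seed(101)
  t <- rexp(2000, rate = log(2) / 10)
  cv <- km_curve(t, rep(1L, 2000))
  for (tt in c(5, 10, 20)) {
    i <- max(which(cv$event_times <= tt))
    expect_lt(abs(cv$survival[i] - exp(-tt * log(2) / 10)), 0.03)
  }
  med <- km_median(cv)
  expect_gt(med$median, 9); expect_lt(med$median, 11)
  expect_true(med$ci[1] <= med$median && med$median <= med$ci[2])
})

test_that("median lands on an exact 0.5 step and is invariant to tie order", {
  # 4 patients, events at 1,2,3,4: survival hits exactly 0.5 at t = 2
  cv <- km_curve(1:4, rep(1L, 4))
  expect_equal(km_median(cv)$median, 2)
  # permuting tied records leaves the curve unchanged
  t <- c(2, 2, 2, 5, 5, 7); e <- c(1L, 0L, 1L, 1L, 0L, 1L)
  p <- c(3, 1, 2, 6, 4, 5)
  a <- km_curve(t, e); b <- km_curve(t[p], e[p])
  expect_equal(a$survival, b$survival)
  expect_equal(a$event_times, b$event_times)
})

test_that("log-rank matches a hand-built risk-set oracle and is symmetric", {
  # 6-patient worked example with censoring
  ta <- c(1, 3, 5); ea <- c(1L, 0L, 1L)
  tb <- c(2, 4, 6); eb <- c(1L, 1L, 0L)
  res <- logrank(ta, ea, tb, eb)
  oracle <- logrank_oracle_stat(c(ta, tb), c(ea, eb),
                                c(0, 0, 0, 1, 1, 1))
  expect_equal(res$statistic, oracle, tolerance = 1e-9)
  expect_equal(res$p_value, pchisq(oracle, 1, lower.tail = FALSE))
  # group swap leaves the statistic unchanged
  expect_equal(logrank(tb, eb, ta, ea)$statistic, res$statistic)
  # identical groups: statistic 0, p 1
  same <- logrank(ta, ea, ta, ea)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)
  expect_error(logrank(ta, c(0L, 0L, 0L), tb, c(0L, 0L, 0L)), "zero events")
})

test_that("Cox fit maximizes the partial likelihood (grid oracle)", {
  set.seed(55)
  n <- 50
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.1 * exp(log(2) * x))
  e <- rep(1L, n)
  fit <- cox_fit(data.frame(x = x), t, e)
  # brute-force grid maximization of the tie-free partial log-likelihood
  pll <- function(beta) {
    sum(vapply(which(e == 1), function(i) {
      risk <- t >= t[i]
      beta * x[i] - log(sum(exp(beta * x[risk])))
    }, numeric(1)))
  }
  grid <- seq(-3, 3, by = 0.001)
  beta_grid <- grid[which.max(vapply(grid, pll, numeric(1)))]
  expect_lt(abs(fit$coefficients[["x"]] - beta_grid), 1e-3)
})

test_that("Cox recovers generating and null effects at n = 2000", {
  set.seed(56)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  z <- rnorm(n)                      # independent of survival
  t <- rexp(n, 0.08 * exp(log(2) * x))
  cens <- rexp(n, 0.02)
  fit <- cox_fit(data.frame(x = x, z = z), pmin(t, cens),
                 as.integer(t <= cens))
  expect_true(fit$converged)
  expect_lt(abs(fit$coefficients[["x"]] - log(2)), 0.15)
  expect_lt(abs(fit$coefficients[["z"]]), 0.1)
  # centering covariates leaves coefficients unchanged
  fit_c <- cox_fit(data.frame(x = x - mean(x), z = z - mean(z)),
                   pmin(t, cens), as.integer(t <= cens))
  expect_equal(unname(fit_c$coefficients), unname(fit$coefficients),
               tolerance = 1e-6)
})

test_that("log-rank chi-square matches the Cox score test without ties", {
  set.seed(57)
  n <- 80
  g <- rep(0:1, each = n / 2)
  t <- rexp(n, 0.1 * exp(0.5 * g))
  e <- rep(1L, n)
  lr <- logrank(t[g == 0], e[g == 0], t[g == 1], e[g == 1])
  sc <- summary(survival::coxph(survival::Surv(t, e) ~ g))$sctest[["test"]]
  expect_lt(abs(lr$statistic - sc) / sc, 1e-6)
})

test_that("perfect separation is flagged rather than raised", {
  t <- c(1, 2, 3, 10, 11, 12)
  e <- rep(1L, 6)
  x <- c(1, 1, 1, 0, 0, 0)   # all early deaths in one group
  fit <- cox_fit(data.frame(x = x), t, e)
  expect_false(fit$converged)
  expect_error(cox_fit(data.frame(x = rep(1, 6)), t, e), "constant")
})

test_that("the nested likelihood-ratio test behaves at its boundaries", {
  set.seed(58)
  n <- 120
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.1 * exp(0.7 * x))
  e <- rep(1L, n)
  fit1 <- cox_fit(data.frame(x = x), t, e)
  same <- nested_lr_test(fit1, fit1)
  expect_equal(same$lr_statistic, 0)
  expect_equal(same$df, 0)
  expect_equal(same$p_value, 1)

  z <- rnorm(n)
  fit2 <- cox_fit(data.frame(x = x, z = z), t, e)
  nt <- nested_lr_test(fit1, fit2)
  expect_equal(nt$df, 1)
  expect_gte(nt$lr_statistic, 0)
  expect_error(nested_lr_test(fit2, fit1), "nested")
})

test_that("adding the generating effect is detected in most replicates", {
  hits <- 0L
  for (s in 1:50) {
    set.seed(600 + s)
    n <- 300
    x <- rbinom(n, 1, 0.5)
    w <- rbinom(n, 1, 0.3)
    t <- rexp(n, 0.08 * exp(log(2) * x + 0.3 * w))
    e <- rep(1L, n)
    red <- cox_fit(data.frame(w = w), t, e)
    ful <- cox_fit(data.frame(w = w, x = x), t, e)
    if (nested_lr_test(red, ful)$p_value <= 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 40)
})

test_that("significance banding matches the four-symbol legend exactly", {
  expect_equal(significance_band(0.3), "-")
  expect_equal(significance_band(0.025), "+")
  expect_equal(significance_band(0.0001), "+++")
  # boundaries are inclusive on the <= side
  expect_equal(significance_band(c(0.05, 0.005, 0.0005)),
               c("+", "++", "+++"))
  expect_equal(significance_band(0.050001), "-")
  expect_error(significance_band(0), "0, 1")
  expect_error(significance_band(1.2), "0, 1")
})
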