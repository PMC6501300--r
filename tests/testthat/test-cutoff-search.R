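test_that("candidate grid is the sorted unique observed scores", {
  expect_equal(candidate_cutoffs(c(3, 1, 2, 2)), c(1, 2, 3))
  s <- runif(40)
  expect_equal(length(candidate_cutoffs(s)), length(unique(s)))
  # prevalence sweeps from 1 down to 1/n as the cutoff rises
  n <- 25
  set.seed(71)
  s <- runif(n)
  prev <- vapply(candidate_cutoffs(s), function(cc) mean(s >= cc), numeric(1))
  expect_equal(prev[1], 1)
  expect_equal(prev[length(prev)], 1 / n)
  expect_true(all(diff(prev) < 0))
  expect_error(candidate_cutoffs(5), "2")
})

test_that("exact binomial PPV interval matches its boundary identities", {
  r <- ppv_with_ci(26, 11)
  expect_equal(r$ppv, 11 / 26)
  expect_equal(round(r$ppv, 2), 0.42)
  # cross-check against the exact binomial test
  bt <- binom.test(11, 26)$conf.int
  expect_equal(c(r$lo, r$hi), as.numeric(bt), tolerance = 1e-9)

  z <- ppv_with_ci(10, 0)
  expect_equal(z$ppv, 0); expect_equal(z$lo, 0)
  o <- ppv_with_ci(10, 10)
  expect_equal(o$ppv, 1); expect_equal(o$hi, 1)
  expect_true(is.na(ppv_with_ci(0, 0)$ppv))
  expect_error(ppv_with_ci(5, 6), "exceed")
})

test_that("cutoff evaluation recounts PPV and flags degenerate splits", {
  co <- small_cohort(n = 80, seed = 13)
  scores <- co$cd8_density * co$pdl1_density
  cuts <- quantile(scores, c(0.3, 0.5, 0.8))
  for (cc in cuts) {
    ev <- evaluate_cutoff(co, scores, cc)
    pos <- scores >= cc
    expect_equal(ev$ppv, sum(co$response[pos]) / sum(pos))
    expect_equal(ev$prevalence, mean(pos))
    expect_equal(ev$n_positive, sum(pos))
    expect_true(ev$ppv_lo <= ev$ppv && ev$ppv <= ev$ppv_hi)
    expect_equal(ev$prevalence * nrow(co), round(ev$prevalence * nrow(co)))
  }
  # below the minimum score: everyone positive, log-rank undefined
  ev0 <- evaluate_cutoff(co, scores, min(scores) - 1)
  expect_equal(ev0$prevalence, 1)
  expect_true(is.na(ev0$p_os))
  expect_false(ev0$feasible)
  expect_match(ev0$reason, "degenerate")
  # prevalence outside the 30-70% band is infeasible
  cc25 <- sort(scores, decreasing = TRUE)[round(0.25 * length(scores))]
  ev25 <- evaluate_cutoff(co, scores, cc25)
  expect_equal(ev25$prevalence, 0.25)
  expect_false(ev25$feasible)
})

test_that("optimization agrees with brute force on seeded cohorts", {
  for (s in 1:8) {
    n <- sample(c(30, 60, 100), 1)
    co <- small_cohort(n = n, seed = 900 + s)
    scores <- co$cd8_density * co$pdl1_density
    res <- optimize_cutoff(co, scores)
    bf <- brute_force_cutoff(co, scores)
    expect_equal(res$n_candidates, length(unique(scores)))
    if (is.null(bf)) {
      expect_null(res$best)
    } else {
      expect_equal(res$best$cutoff, bf$cutoff)
      expect_equal(res$best$ppv, bf$ppv)
    }
  }
})

test_that("optimization is invariant to patient order", {
  co <- small_cohort(n = 60, seed = 77)
  scores <- co$cd8_density * co$pdl1_density
  res <- optimize_cutoff(co, scores)
  set.seed(5); p <- sample(nrow(co))
  res_p <- optimize_cutoff(co[p, ], scores[p])
  expect_equal(res_p$best$cutoff, res$best$cutoff)
  expect_equal(res_p$best$ppv, res$best$ppv)
})

test_that("raising the cutoff never increases prevalence", {
  co <- small_cohort(n = 50, seed = 14)
  scores <- co$cd8_density * co$pdl1_density
  res <- optimize_cutoff(co, scores)
  ev <- res$all_evaluations
  expect_true(all(diff(ev$prevalence[order(ev$cutoff)]) <= 0))
})

test_that("infeasible settings yield a complete table and no best", {
  co <- small_cohort(n = 40, seed = 15)
  scores <- co$cd8_density * co$pdl1_density
  # an impossibly narrow prevalence band no candidate can hit
  tight <- search_constraints(prevalence_min = 0.401,
                              prevalence_max = 0.402)
  res <- optimize_cutoff(co, scores, tight)
  expect_null(res$best)
  expect_equal(nrow(res$all_evaluations), length(unique(scores)))

  # zero responders: feasible candidates (if any) have PPV 0
  co0 <- co; co0$response <- 0L
  res0 <- optimize_cutoff(co0, scores)
  if (!is.null(res0$best)) expect_equal(res0$best$ppv, 0)
  expect_error(search_constraints(prevalence_min = 0.7,
                                  prevalence_max = 0.3),
               "prevalence_min")
})
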