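test_that("Cox loss matches closed-form toy cases", {
  expect_equal(coxLoss(c(0, 0, 0), c(1, 2, 3), c(1, 1, 1)), log(6),
               tolerance = 1e-12)
  expect_equal(coxLoss(5, 2, 1), 0, tolerance = 1e-12)
  expect_equal(coxLoss(c(1, 0), c(1, 2), c(1, 0)), log(exp(1) + 1) - 1,
               tolerance = 1e-12)
})

test_that("Cox loss agrees with the brute-force oracle on random instances", {
  for (i in 1:100) {
    n <- sample(2:30, 1)
    s <- rSurv(n, seed = 1000 + i, tie_prob = if (i %% 3 == 0) 0.5 else 0)
    expect_equal(coxLoss(s$risks, s$times, s$events),
                 oracleCoxLoss(s$risks, s$times, s$events),
                 tolerance = 1e-10)
  }
})

test_that("Cox loss is shift-invariant and numerically stable at large risks", {
  s <- rSurv(15, seed = 7)
  for (c0 in c(-3, 1e-4, 17))
    expect_equal(coxLoss(s$risks + c0, s$times, s$events),
                 coxLoss(s$risks, s$times, s$events), tolerance = 1e-9)
  big <- coxLoss(c(1e3, -1e3, 900), c(1, 2, 3), c(1, 1, 1))
  expect_true(is.finite(big))
  expect_warning(z <- coxLoss(c(1, 2), c(1, 2), c(0, 0)), "no events")
  expect_identical(z, 0)
})

test_that("Cox gradient matches central finite differences", {
  for (i in 1:20) {
    n <- sample(3:25, 1)
    s <- rSurv(n, seed = 2000 + i, tie_prob = if (i %% 4 == 0) 0.5 else 0)
    g <- coxLossGradient(s$risks, s$times, s$events)
    fd <- centralDiff(function(r) coxLoss(r, s$times, s$events), s$risks)
    expect_lt(max(abs(g - fd)), 1e-6)
  }
  expect_warning(g0 <- coxLossGradient(c(1, 2), c(1, 2), c(0, 0)))
  expect_identical(g0, c(0, 0))
})

test_that("concordance index handles perfect orderings and censoring", {
  expect_equal(concordanceIndex(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 1.0)
  expect_equal(concordanceIndex(c(1, 2, 3), c(1, 2, 3), c(1, 1, 1)), 0.0)
  # pair (2,3) not comparable: subject 2 is censored
  expect_equal(concordanceIndex(c(2, 1, 3), c(1, 2, 3), c(1, 0, 1)), 0.5)
  expect_error(concordanceIndex(1, 5, 1), "comparable")
  expect_error(concordanceIndex(c(1, 2), c(3, 3), c(1, 1)), "comparable")
})

test_that("concordance index equals pair enumeration, with complement symmetry", {
  for (i in 1:40) {
    n <- sample(4:25, 1)
    s <- rSurv(n, seed = 3000 + i, tie_prob = 0.5)
    if (i %% 2 == 0) s$risks <- round(s$risks)        # force risk ties
    ci <- concordanceIndex(s$risks, s$times, s$events)
    expect_identical(ci, oraclePairCindex(s$risks, s$times, s$events))
    if (!any(duplicated(s$risks)))
      expect_equal(ci + concordanceIndex(-s$risks, s$times, s$events), 1)
  }
})

test_that("concordance index matches the survival package on an untied case", {
  s <- rSurv(40, seed = 99)
  cf <- survival::concordance(survival::Surv(s$times, s$events) ~ s$risks,
                              reverse = TRUE)
  expect_equal(concordanceIndex(s$risks, s$times, s$events),
               unname(cf$concordance), tolerance = 1e-12)
})

test_that("median stratification uses the >= threshold rule", {
  expect_identical(as.character(stratifyByMedian(c(1, 2, 3), c(0, 2, 5))),
                   c("low", "high", "high"))
  lab <- stratifyByMedian(c(1, 2, 3, 4), 2.5)
  expect_identical(as.character(lab), "high")      # even-count midpoint
  expect_equal(attr(lab, "threshold"), 2.5)
  expect_identical(as.character(stratifyByMedian(c(5, 6, 7), c(1, 2))),
                   c("low", "low"))
  expect_error(stratifyByMedian(numeric(0), 1), "empty")
})

test_that("Kaplan-Meier matches hand product-limit computations", {
  km <- kaplanMeier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$time, c(1, 2, 3))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$at_risk, c(3, 2, 1))
  # censoring at t=1 causes no drop; the event at t=2 empties the risk set
  km2 <- kaplanMeier(c(1, 2), c(0, 1))
  expect_equal(km2$time, 2)
  expect_equal(km2$survival, 0)
  km3 <- kaplanMeier(c(4, 5, 6), c(0, 0, 0))
  expect_equal(nrow(km3), 0)
})

test_that("log-rank test matches the O-E oracle and is symmetric", {
  tA <- c(1, 2, 3); tB <- c(10, 11, 12)
  lr <- logrankTest(tA, c(1, 1, 1), tB, c(1, 1, 1))
  or <- oracleLogrank(tA, c(1, 1, 1), tB, c(1, 1, 1))
  expect_equal(lr$statistic, or$statistic, tolerance = 1e-8)
  expect_equal(lr$p_value, or$p, tolerance = 1e-8)
  expect_lt(lr$p_value, 0.05)

  same <- logrankTest(tA, c(1, 1, 1), tA, c(1, 1, 1))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)

  s <- rSurv(30, seed = 5); g <- rep(c(TRUE, FALSE), 15)
  a <- logrankTest(s$times[g], s$events[g], s$times[!g], s$events[!g])
  b <- logrankTest(s$times[!g], s$events[!g], s$times[g], s$events[g])
  expect_equal(a$statistic, b$statistic)
  or2 <- oracleLogrank(s$times[g], s$events[g], s$times[!g], s$events[!g])
  expect_equal(a$statistic, or2$statistic, tolerance = 1e-8)
  perm <- sample(sum(g))
  c2 <- logrankTest(s$times[g][perm], s$events[g][perm],
                    s$times[!g], s$events[!g])
  expect_equal(a$statistic, c2$statistic)
  expect_error(logrankTest(1, 0, 2, 0), "no events")
})
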