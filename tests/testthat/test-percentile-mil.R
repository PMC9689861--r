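test_that("scenario schemes reproduce the published percentile lists", {
  expect_equal(scenarioScheme(1)@percentiles, c(0, 100))
  expect_equal(scenarioScheme(4)@percentiles,
               c(0, 0.1, 1, 5, 95, 99, 99.9, 100))
  expect_equal(scenarioScheme(7)@percentiles,
               c(0, 0.1, 1, 5, 10, 25, 50, 75, 90, 95, 99, 99.9, 100))
  expect_equal(vapply(1:7, function(i) length(scenarioScheme(i)@percentiles),
                      integer(1)),
               c(2L, 4L, 6L, 8L, 10L, 12L, 13L))
  expect_error(scenarioScheme(8), "1..7")
  expect_error(percentileScheme(c(0, 50), 2), "odd")
  expect_error(percentileScheme(c(50, 10)), "increasing")
})

test_that("instance scorer is per-instance and matches hand arithmetic", {
  zero <- list(W1 = matrix(0, 3, 4), b1 = rep(0, 4),
               W2 = matrix(0, 4, 1), b2 = 0)
  X <- matrix(rnorm(15), 5, 3)
  expect_equal(scoreInstances(X, zero), rep(0, 5))

  # 1-feature scorer: layer1 w=1 b=0 (rectified), layer2 w=2 b=1
  hand <- list(W1 = matrix(1, 1, 1), b1 = 0, W2 = matrix(2, 1, 1), b2 = 1)
  expect_equal(scoreInstances(matrix(c(1, -1), 2, 1), hand), c(3, 1))

  m <- newDisMISLModel(6, seed = 3)
  X2 <- matrix(rnorm(60), 10, 6)
  perm <- sample(10)
  expect_equal(scoreInstances(X2[perm, ], m), scoreInstances(X2, m)[perm])
  expect_error(scoreInstances(matrix(0, 2, 5), m), "width")
})

test_that("percentile selection matches its toy contracts", {
  sc <- percentileScheme(c(0, 50, 100), 1)
  for (ord in list(1:5, 5:1, c(3, 1, 5, 2, 4))) {
    v <- selectPercentileInstances(c(10, 20, 30, 40, 50)[ord], sc)
    expect_equal(as.numeric(v), c(10, 30, 50))
  }
  v <- selectPercentileInstances(c(10, 20, 30, 40, 50), percentileScheme(100, 3))
  expect_equal(as.numeric(v), c(30, 40, 50))       # shifted inward at the top
  s <- sample(12000)
  v <- selectPercentileInstances(s, percentileScheme(50, 1))
  expect_equal(as.numeric(v), 6001)                # ascending rank 6000, 0-based
  expect_error(selectPercentileInstances(numeric(0), sc), "empty")
})

test_that("percentile selection equals the rank-and-shift oracle everywhere", {
  set.seed(44)
  for (n in c(1:50, 12000)) {
    scores <- rnorm(n)
    for (sid in 1:7) {
      P <- scenarioScheme(sid)@percentiles
      for (k in c(1L, 3L, 5L, 7L)) {
        got <- selectPercentileInstances(scores, percentileScheme(P, k))
        expect_equal(as.numeric(got), oracleSelect(scores, P, k))
      }
    }
  }
})

test_that("adding a constant shifts every selected value by that constant", {
  set.seed(5)
  scores <- rnorm(37)
  sch <- scenarioScheme(6, 3)
  base <- as.numeric(selectPercentileInstances(scores, sch))
  for (c0 in c(-2.5, 0.1, 10))
    expect_equal(as.numeric(selectPercentileInstances(scores + c0, sch)),
                 base + c0, tolerance = 1e-12)
})

test_that("risk prediction composes scorer, selection and head", {
  co <- rCohort(n_bags = 4, bag_size = 30, d = 5, seed = 21)
  m <- newDisMISLModel(5, scenarioScheme(7, 5), seed = 2)
  expect_equal(nrow(m@head[[1]]$W), 65)             # 13 x 5 inputs

  # zero head: risk equals the final bias for every bag
  m0 <- m
  for (i in seq_along(m0@head))
    m0@head[[i]] <- list(W = m0@head[[i]]$W * 0,
                         b = m0@head[[i]]$b * 0)
  m0@head[[length(m0@head)]]$b <- 0.7
  expect_equal(unname(predictRisk(m0, co)), rep(0.7, 4))

  # permutation invariance of the full composition
  r0 <- predictRisk(m, co)
  co2 <- co
  set.seed(1)
  for (i in seq_along(co2@bags))
    co2@bags[[i]] <- co2@bags[[i]][sample(nrow(co2@bags[[i]])), ]
  expect_equal(predictRisk(m, co2), r0, tolerance = 1e-7)

  # doubling every instance leaves the extremes unchanged
  mx <- newDisMISLModel(5, percentileScheme(c(0, 100), 1), seed = 4)
  dup <- co
  for (i in seq_along(dup@bags))
    dup@bags[[i]] <- rbind(dup@bags[[i]], dup@bags[[i]])
  expect_equal(predictRisk(mx, dup), predictRisk(mx, co), tolerance = 1e-12)

  expect_error(predictRisk(m, rCohort(d = 3, seed = 1)), "width")
})

test_that("end-to-end parameter gradient matches finite differences", {
  co <- rCohort(n_bags = 3, bag_size = 15, d = 3, seed = 31,
                events = c(1, 1, 1))
  s <- survivalData(co)
  for (agg in c("dismisl", "meanpool", "mesonet_topbottom10", "attention")) {
    if (agg == "mesonet_topbottom10") {
      co2 <- rCohort(n_bags = 3, bag_size = 25, d = 3, seed = 32,
                     events = c(1, 1, 1))
      s2 <- survivalData(co2)
    } else {
      co2 <- co; s2 <- s
    }
    m <- newDisMISLModel(3, percentileScheme(c(0, 50, 100), 3),
                         aggregator = agg, scorer_hidden = 4,
                         head_hidden = 5, seed = 6)
    prep <- DisMISL:::.prepCohort(co2)
    lg <- DisMISL:::.lossAndGradient(m, prep, s2$time, s2$event)
    params <- DisMISL:::.flattenParams(m)
    for (nm in names(params)) {
      fd <- vapply(seq_along(params[[nm]]), function(j) {
        h <- 1e-5
        pp <- params; pp[[nm]][j] <- pp[[nm]][j] + h
        up <- DisMISL:::.forwardCohort(DisMISL:::.applyParams(m, pp), prep)$O
        pm <- params; pm[[nm]][j] <- pm[[nm]][j] - h
        dn <- DisMISL:::.forwardCohort(DisMISL:::.applyParams(m, pm), prep)$O
        (coxLoss(up, s2$time, s2$event, normalize = TRUE) -
           coxLoss(dn, s2$time, s2$event, normalize = TRUE)) / (2 * h)
      }, numeric(1))
      expect_lt(max(abs(as.numeric(lg$grads[[nm]]) - fd) /
                      pmax(1, abs(fd))), 1e-4)
    }
  }
})

test_that("attention aggregation normalizes within windows and reduces to k=1", {
  sch1 <- percentileScheme(c(0, 25, 75, 100), 1)
  att <- newDisMISLModel(4, sch1, aggregator = "attention", seed = 8)
  dml <- newDisMISLModel(4, sch1, aggregator = "dismisl", seed = 8)
  dml@scorer <- att@scorer
  dml@head <- att@head
  co <- rCohort(n_bags = 3, bag_size = 20, d = 4, seed = 12)
  expect_equal(predictRiskAttention(att, co), predictRisk(dml, co),
               tolerance = 1e-12)

  # hand softmax-weighted-mean oracle for one k=3 window
  att3 <- newDisMISLModel(2, percentileScheme(50, 3),
                          aggregator = "attention", seed = 9)
  bag <- matrix(rnorm(12), 6, 2)
  sc <- scoreInstances(bag, att3)
  win <- sort(sc)[DisMISL:::.schemeRanks(6, 50, 3)]
  e <- att3@attention$v * tanh(att3@attention$u * win + att3@attention$b)
  a <- exp(e - max(e)) / sum(exp(e - max(e)))
  expect_equal(sum(a), 1, tolerance = 1e-12)
  prep <- DisMISL:::.prepCohort(BagCohort(list(x = bag),
    data.frame(bag_id = "x", time = 1, event = 1)))
  fw <- DisMISL:::.forwardCohort(att3, prep)
  expect_equal(unname(fw$B[1, 1]), sum(a * win), tolerance = 1e-12)
  expect_error(predictRiskAttention(dml, co), "attention")
})
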