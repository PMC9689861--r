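test_that("k-fold splits are balanced, exhaustive and seeded", {
  f <- kfoldSplit(100, k = 5, seed = 1)
  expect_equal(unname(table(f)), rep(20L, 5), ignore_attr = TRUE)
  f2 <- kfoldSplit(101, k = 5, seed = 1)
  expect_equal(sort(as.integer(table(f2)), decreasing = TRUE),
               c(21L, 20L, 20L, 20L, 20L))
  expect_identical(kfoldSplit(50, 5, seed = 9), kfoldSplit(50, 5, seed = 9))
  expect_false(identical(kfoldSplit(50, 5, seed = 9),
                         kfoldSplit(50, 5, seed = 10)))
  co <- rCohort(n_bags = 12, seed = 3, events = rep(c(0, 1), 6))
  fs <- kfoldSplit(co, 3, seed = 2, stratify = TRUE)
  ev <- survivalData(co)$event
  expect_equal(unname(table(fs[ev == 1])), rep(2L, 3), ignore_attr = TRUE)
  expect_error(kfoldSplit(4, 5), "exceed")
  expect_error(kfoldSplit(10, 1), "at least 2")
})

test_that("early stopping keeps the best epoch under the patience rule", {
  # validation loss rising from epoch 2 with patience 1: stop at epoch 2,
  # best parameters from epoch 1
  es <- DisMISL:::.earlyStop(c(1.0, 1.1), patience = 1)
  expect_true(es$stop)
  expect_equal(es$best, 1)
  es2 <- DisMISL:::.earlyStop(c(1.0, 1.1, 0.9, 0.95), patience = 2)
  expect_false(es2$stop)
  expect_equal(es2$best, 3)
  es3 <- DisMISL:::.earlyStop(c(1.0, 1.1, 0.9, 0.95, 0.96), patience = 2)
  expect_true(es3$stop)
})

test_that("training reduces the loss, is deterministic, and respects budgets", {
  g <- generateCohort(generatorConfig(n_bags = 40, bag_size = 25,
                                      feature_dim = 6, seed = 3))
  sp <- splitCohort(g$cohort, c(train = 0.7, val = 0.3), seed = 3)
  cfg <- trainConfig(scheme = scenarioScheme(3, 1), max_epochs = 25,
                     patience = 25, scorer_hidden = 8, head_hidden = 8,
                     learning_rate = 5e-3, seed = 11)
  fit <- trainModel(sp$train, sp$val, cfg)
  expect_lte(fit$log$train_loss[fit$best_epoch], fit$log$train_loss[1])
  expect_lte(nrow(fit$log), 25)
  expect_equal(fit$best_epoch, which.min(fit$log$val_loss))

  fit2 <- trainModel(sp$train, sp$val, cfg)
  expect_identical(predictRisk(fit$model, sp$val),
                   predictRisk(fit2$model, sp$val))

  cens <- sp$train
  cens@survival$event <- 0
  expect_error(trainModel(cens, sp$val, cfg), "event")
})

test_that("mini-batch training accepts partial risk sets", {
  g <- generateCohort(generatorConfig(n_bags = 30, bag_size = 20,
                                      feature_dim = 6, seed = 13))
  sp <- splitCohort(g$cohort, c(train = 0.7, val = 0.3), seed = 13)
  cfg <- trainConfig(scheme = scenarioScheme(1, 1), max_epochs = 5,
                     patience = 5, scorer_hidden = 8, head_hidden = 8,
                     batch_size = 8, seed = 5)
  fit <- suppressWarnings(trainModel(sp$train, sp$val, cfg))
  expect_equal(nrow(fit$log), 5)
  expect_true(all(is.finite(predictRisk(fit$model, sp$val))))
})

test_that("scenario sweep returns one row per configuration with fold stats", {
  g <- generateCohort(generatorConfig(n_bags = 30, bag_size = 20,
                                      feature_dim = 6, seed = 21))
  cfg <- trainConfig(max_epochs = 4, patience = 4, scorer_hidden = 8,
                     head_hidden = 8)
  out <- withr::local_tempfile(fileext = ".csv")
  res <- runScenarioSweep(g$cohort, scenarios = c(1, 7),
                          neighborhoods = c(1, 3), k_folds = 2,
                          seed = 2, config = cfg, out = out)
  expect_equal(nrow(res), 4)
  expect_named(res, c("scenario", "neighborhood", "fold1", "fold2",
                      "mean", "sd"))
  expect_equal(res$mean, rowMeans(res[, c("fold1", "fold2")]))
  expect_true(file.exists(out))
  back <- utils::read.csv(out)
  expect_equal(back$mean, res$mean, tolerance = 1e-12)
})

test_that("interpretation table covers risk groups x percentiles", {
  g <- generateCohort(generatorConfig(n_bags = 40, bag_size = 20,
                                      feature_dim = 6, seed = 33))
  m <- newDisMISLModel(6, scenarioScheme(2, 1), seed = 3)
  tab <- interpretPercentileRisk(m, g$cohort, n_risk_groups = 4)
  expect_equal(nrow(tab), 4 * 4)
  expect_equal(sort(unique(tab$risk_group)), 1:4)
  expect_equal(sort(unique(tab$percentile)),
               scenarioScheme(2)@percentiles)
  expect_error(interpretPercentileRisk(m, g$cohort, 100), "groups")

  # constant-risk model: every selected score is the same constant
  m0 <- m
  m0@scorer <- lapply(m0@scorer, function(x) x * 0)
  m0@scorer$b2 <- 1.5
  tab0 <- interpretPercentileRisk(m0, g$cohort, n_risk_groups = 4)
  expect_equal(tab0$mean_score, rep(1.5, 16))
})

test_that("stratified evaluation composes the median-split pipeline", {
  g <- generateCohort(cohortPreset("strong", n_bags = 80, bag_size = 30,
                                   seed = 17))
  sp <- splitCohort(g$cohort, c(train = 0.5, val = 0.25, eval = 0.25),
                    seed = 17)
  cfg <- trainConfig(scheme = scenarioScheme(7, 1), scorer_hidden = 16,
                     head_hidden = 16, max_epochs = 40, patience = 40,
                     learning_rate = 5e-3, seed = 7)
  fit <- trainModel(sp$train, sp$val, cfg)
  res <- evaluateStratification(fit$model, sp$train, sp$eval)
  expect_setequal(as.character(unique(res$groups)), c("low", "high"))
  expect_true(all(c("low", "high") %in% names(res$km)))
  expect_true(res$logrank$p_value >= 0 && res$logrank$p_value <= 1)
  expect_equal(length(res$groups), nBags(sp$eval))

  # constant risks put every evaluation bag in the high group
  m0 <- fit$model
  m0@scorer <- lapply(m0@scorer, function(x) x * 0)
  for (i in seq_along(m0@head))
    m0@head[[i]] <- lapply(m0@head[[i]], function(x) x * 0)
  expect_error(evaluateStratification(m0, sp$train, sp$eval), "degenerate")
})

test_that("percentile scores trend monotonically with predicted risk", {
  gcfg <- cohortPreset("mid_quantile", n_bags = 120, seed = 55)
  g <- generateCohort(gcfg)
  sp <- splitCohort(g$cohort, c(train = 0.8, val = 0.2), seed = 55)
  fit <- trainModel(sp$train, sp$val,
                    experimentConfig(7, 1, seed = 55))
  tab <- interpretPercentileRisk(fit$model, g$cohort, n_risk_groups = 10)
  rho <- vapply(split(tab, tab$percentile), function(d)
    stats::cor(d$risk_group, d$mean_score, method = "spearman"), numeric(1))
  # at least one percentile's mean selected score tracks the risk ranking
  expect_gt(max(abs(rho)), 0.8)
})

test_that("held-out runs report concordance on untouched bags", {
  r <- runHeldOut(generatorConfig(n_bags = 40, bag_size = 20,
                                  feature_dim = 6, seed = 23),
                  trainConfig(scheme = scenarioScheme(1, 1),
                              scorer_hidden = 8, head_hidden = 8,
                              max_epochs = 5, patience = 5, seed = 23))
  expect_true(r$cindex >= 0 && r$cindex <= 1)
  expect_equal(nBags(r$splits$train) + nBags(r$splits$val) +
                 nBags(r$splits$eval), 40)
  expect_length(intersect(bagIds(r$splits$train), bagIds(r$splits$eval)), 0)
})
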