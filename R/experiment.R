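#' Split a cohort into train / validation / evaluation parts
#'
#' Seeded random partition by bag, with fractions normalized to sum to 1.
#'
#' @param cohort a [BagCohort-class].
#' @param fractions named numeric fractions (default 60/20/20
#'   train/val/eval).
#' @param seed integer seed.
#' @return named list of [BagCohort-class] objects.
#' @export
splitCohort <- function(cohort,
                        fractions = c(train = 0.6, val = 0.2, eval = 0.2),
                        seed = 1L) {
  stopifnot(is(cohort, "BagCohort"), length(fractions) >= 2)
  fr <- fractions / sum(fractions)
  n <- nBags(cohort)
  sizes <- floor(fr * n)
  rem <- n - sum(sizes)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  if (any(sizes < 1)) stop("cohort too small for the requested split")
  restore <- .withSeed(seed)
  on.exit(restore())
  perm <- sample.int(n)
  out <- vector("list", length(fr))
  names(out) <- names(fr)
  at <- 0L
  for (i in seq_along(fr)) {
    out[[i]] <- cohort[sort(perm[at + seq_len(sizes[i])])]
    at <- at + sizes[i]
  }
  out
}

#' k-fold cross-validation of one model configuration
#'
#' For every fold: train on the remaining bags (80% for k = 5), monitor the
#' held-out fold for early stopping, and report the concordance index on
#' that fold — the published evaluation protocol.
#'
#' @param cohort a [BagCohort-class].
#' @param config a [trainConfig()]; the training seed is offset by the fold
#'   number so folds are independent but reproducible.
#' @param k_folds number of folds (default 5).
#' @param seed seed for the fold assignment.
#' @return data.frame with one row per fold: \code{fold}, \code{cindex},
#'   \code{best_epoch}.
#' @export
crossValidate <- function(cohort, config = trainConfig(), k_folds = 5L,
                          seed = 1L) {
  folds <- kfoldSplit(cohort, k_folds, seed = seed)
  out <- data.frame(fold = seq_len(k_folds), cindex = NA_real_,
                    best_epoch = NA_integer_)
  for (f in seq_len(k_folds)) {
    tr <- cohort[which(folds != f)]
    ev <- cohort[which(folds == f)]
    cfg <- config
    cfg$seed <- config$seed + f
    fit <- trainModel(tr, ev, cfg)
    risks <- predictRisk(fit$model, ev)
    s <- survivalData(ev)
    out$cindex[f] <- concordanceIndex(risks, s$time, s$event)
    out$best_epoch[f] <- fit$best_epoch
  }
  out
}

#' Sweep percentile scenarios and neighborhood widths
#'
#' Cross-validates every (scenario, neighborhood) pair and tabulates
#' per-fold and mean +/- sd concordance, the experiment behind the central
#' claim that reading more of the score distribution improves survival
#' prediction.
#'
#' @param cohort a [BagCohort-class].
#' @param scenarios integer vector of scenario ids (subset of 1..7).
#' @param neighborhoods odd integer vector of window widths.
#' @param k_folds folds per configuration (default 5).
#' @param seed seed for fold assignment and training.
#' @param config base [trainConfig()]; its scheme is replaced per pair.
#' @param out optional path: the table is also written as CSV.
#' @return data.frame with one row per (scenario, neighborhood):
#'   \code{scenario}, \code{neighborhood}, \code{fold1..foldK},
#'   \code{mean}, \code{sd}.
#' @export
runScenarioSweep <- function(cohort, scenarios = 1:7, neighborhoods = 1L,
                             k_folds = 5L, seed = 1L,
                             config = trainConfig(), out = NULL) {
  grid <- expand.grid(scenario = scenarios, neighborhood = neighborhoods)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- config
    cfg$scheme <- scenarioScheme(grid$scenario[i], grid$neighborhood[i])
    cfg$aggregator <- "dismisl"
    cfg$seed <- config$seed + seed
    cv <- crossValidate(cohort, cfg, k_folds = k_folds, seed = seed)
    ci <- cv$cindex
    row <- c(list(scenario = grid$scenario[i],
                  neighborhood = grid$neighborhood[i]),
             stats::setNames(as.list(ci), paste0("fold", seq_len(k_folds))),
             list(mean = mean(ci), sd = stats::sd(ci)))
    rows[[i]] <- as.data.frame(row)
  }
  res <- do.call(rbind, rows)
  if (!is.null(out))
    utils::write.csv(res, out, row.names = FALSE, quote = FALSE)
  res
}

#' One held-out run of a generator + model configuration
#'
#' Generates a synthetic cohort, splits it into train and early-stop
#' validation parts (plus an evaluation part unless \code{eval_fresh} is
#' used), trains one model, and reports the held-out concordance. The
#' building block behind the scenario and neighborhood recovery checks.
#'
#' With \code{eval_fresh > 0} the evaluation cohort is drawn freshly from
#' the same generator (a different seed), the strongest form of held-out
#' testing: a large evaluation sample keeps the concordance estimate's
#' sampling noise well below the effects being measured, and the full
#' 80/20 train/validation split is kept for fitting.
#'
#' @param gen_config a [generatorConfig()].
#' @param config a [trainConfig()].
#' @param fractions split fractions, see [splitCohort()]; ignored in favor
#'   of an 80/20 train/validation split when \code{eval_fresh > 0}.
#' @param grid if TRUE, select learning rate and weight decay with
#'   [trainModelGrid()] instead of a single [trainModel()] fit.
#' @param eval_fresh number of freshly generated evaluation bags (0 =
#'   evaluate on the held-out part of the generated cohort).
#' @return list with \code{cindex} (held-out), \code{fit} (from
#'   [trainModel()]), the \code{splits} (including \code{$eval}), and
#'   \code{truth} (of the training cohort).
#' @export
runHeldOut <- function(gen_config, config = trainConfig(),
                       fractions = c(train = 0.6, val = 0.2, eval = 0.2),
                       grid = FALSE, eval_fresh = 0L) {
  g <- generateCohort(gen_config)
  if (eval_fresh > 0L) {
    sp <- splitCohort(g$cohort, c(train = 0.8, val = 0.2),
                      seed = gen_config$seed)
    evcfg <- gen_config
    evcfg$n_bags <- as.integer(eval_fresh)
    evcfg$seed <- gen_config$seed + 500000L
    sp$eval <- generateCohort(evcfg)$cohort
  } else {
    sp <- splitCohort(g$cohort, fractions, seed = gen_config$seed)
  }
  fit <- if (grid) trainModelGrid(sp$train, sp$val, config)
         else trainModel(sp$train, sp$val, config)
  ev <- sp$eval
  risks <- predictRisk(fit$model, ev)
  s <- survivalData(ev)
  list(cindex = concordanceIndex(risks, s$time, s$event), fit = fit,
       splits = sp, truth = g$truth)
}

#' Desk-scale experiment configuration
#'
#' The training configuration used by the package's synthetic validation
#' experiments: a 64-wide scorer hidden layer (proportionate to the
#' 16-feature synthetic bags), validation-selected learning rate over
#' \{1e-3, 5e-3\}, no weight decay, and a 120-epoch budget per fit. See the
#' methods vignette for the rationale behind these desk-scale choices.
#'
#' @param scenario scenario id in 1..7 (see [scenarioScheme()]).
#' @param neighborhood odd window width k.
#' @param aggregator aggregation rule (see [newDisMISLModel()]).
#' @param seed integer seed.
#' @return a [trainConfig()].
#' @export
experimentConfig <- function(scenario = 7L, neighborhood = 1L,
                             aggregator = "dismisl", seed = 1L) {
  trainConfig(scheme = scenarioScheme(scenario, neighborhood),
              aggregator = aggregator, scorer_hidden = 64L,
              batch_size = 30L, max_epochs = 120L,
              lr_grid = c(1e-3, 5e-3), wd_grid = 0, seed = seed)
}

#' Mean selected score per percentile and risk group
#'
#' Ranks bags by predicted risk, splits them into equal-count risk groups,
#' and reports for every group and every percentile location of the model's
#' scheme the mean selected instance score (averaging each k-window). The
#' table behind the percentile-vs-risk interpretation curves.
#'
#' @param model a trained [DisMISLModel-class] with a percentile aggregator.
#' @param cohort a [BagCohort-class].
#' @param n_risk_groups number of equal-count groups (default 10); group 1
#'   has the lowest predicted risk. Ties and remainders are resolved by
#'   stable order.
#' @param out optional CSV path.
#' @return data.frame with \code{n_risk_groups * length(P)} rows:
#'   \code{risk_group}, \code{percentile}, \code{mean_score}.
#' @export
interpretPercentileRisk <- function(model, cohort, n_risk_groups = 10L,
                                    out = NULL) {
  stopifnot(is(model, "DisMISLModel"), is(cohort, "BagCohort"))
  if (!model@aggregator %in% c("dismisl", "attention"))
    stop("interpretation requires a percentile-based aggregator")
  nb <- nBags(cohort)
  if (n_risk_groups > nb) stop("more risk groups than bags")
  risks <- predictRisk(model, cohort)
  sch <- model@scheme
  P <- sch@percentiles
  k <- sch@neighborhood
  ## per bag: mean score within each percentile window
  win <- t(vapply(bags(cohort), function(m) {
    s <- scoreInstances(m, model)
    v <- selectPercentileInstances(s, sch)
    colMeans(matrix(v, nrow = k))
  }, numeric(length(P))))
  ord <- order(risks)                       # stable; ties by position
  bnd <- round(seq(0, nb, length.out = n_risk_groups + 1L))
  grp <- integer(nb)
  grp[ord] <- rep(seq_len(n_risk_groups), diff(bnd))
  res <- expand.grid(risk_group = seq_len(n_risk_groups),
                     percentile = P, KEEP.OUT.ATTRS = FALSE)
  res$mean_score <- mapply(function(g, p)
    mean(win[grp == g, match(p, P)]), res$risk_group, res$percentile)
  res <- res[order(res$risk_group, res$percentile), ]
  rownames(res) <- NULL
  if (!is.null(out))
    utils::write.csv(res, out, row.names = FALSE, quote = FALSE)
  res
}

#' Risk stratification with Kaplan-Meier curves and log-rank test
#'
#' Composes the published stratification pipeline: predict risks, split the
#' evaluation cohort at the training-set median risk, estimate one
#' Kaplan-Meier curve per group, and compare them with the log-rank test.
#'
#' @param model a fitted model ([DisMISLModel-class] or
#'   [PenalizedCoxModel-class]).
#' @param train a [BagCohort-class] providing the median threshold.
#' @param eval a [BagCohort-class] to stratify and evaluate.
#' @return list with \code{cindex}, \code{groups} (factor low/high),
#'   \code{threshold}, \code{km} (list of per-group curves), and
#'   \code{logrank} (statistic + p-value).
#' @export
evaluateStratification <- function(model, train, eval) {
  risks_tr <- predictRisk(model, train)
  risks_ev <- predictRisk(model, eval)
  groups <- stratifyByMedian(risks_tr, risks_ev)
  if (any(table(factor(groups, levels = c("low", "high"))) == 0))
    stop("degenerate stratification: one risk group is empty")
  s <- survivalData(eval)
  lo <- groups == "low"
  km <- list(low = kaplanMeier(s$time[lo], s$event[lo]),
             high = kaplanMeier(s$time[!lo], s$event[!lo]))
  lr <- logrankTest(s$time[lo], s$event[lo], s$time[!lo], s$event[!lo])
  list(cindex = concordanceIndex(risks_ev, s$time, s$event),
       groups = groups, threshold = attr(groups, "threshold"),
       km = km, logrank = lr)
}
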