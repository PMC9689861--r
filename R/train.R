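#' Training configuration
#'
#' Collects the optimization settings shared by all neural aggregators:
#' full-cohort (or mini-batch) Adam on the event-normalized Cox loss, with
#' patience-based early stopping on the validation loss.
#'
#' @param scheme a [PercentileScheme-class] for the percentile aggregators.
#' @param aggregator aggregation rule (see [newDisMISLModel()]).
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty added to weight-matrix gradients.
#' @param batch_size bags per optimization step; \code{NULL} (default) uses
#'   the whole training cohort, so Cox risk sets are exact.
#' @param max_epochs upper bound on training epochs.
#' @param patience epochs without validation improvement before stopping.
#' @param clip_norm global gradient-norm ceiling (rescale above it); keeps
#'   full-batch steps stable when a few large risks dominate the risk sets.
#' @param scorer_hidden,head_hidden architecture widths (see
#'   [newDisMISLModel()]).
#' @param lr_grid,wd_grid grids searched by [trainModelGrid()].
#' @param seed seed controlling initialization and any batch shuffling.
#' @return a list of class \code{trainConfig}.
#' @export
trainConfig <- function(scheme = scenarioScheme(7), aggregator = "dismisl",
                        learning_rate = 1e-3, weight_decay = 0,
                        batch_size = NULL, max_epochs = 200L, patience = 20L,
                        clip_norm = 5,
                        scorer_hidden = 128L, head_hidden = c(128L, 64L),
                        lr_grid = c(1e-3, 1e-4), wd_grid = c(0, 1e-4),
                        seed = 1L) {
  stopifnot(learning_rate > 0, weight_decay >= 0, max_epochs >= 1,
            patience >= 1)
  structure(list(scheme = scheme, aggregator = aggregator,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = batch_size, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), clip_norm = clip_norm,
                 scorer_hidden = as.integer(scorer_hidden),
                 head_hidden = as.integer(head_hidden),
                 lr_grid = lr_grid, wd_grid = wd_grid,
                 seed = as.integer(seed)),
            class = "trainConfig")
}

## ---- parameter flattening for the optimizer ----

.flattenParams <- function(model) {
  p <- list(s.W1 = model@scorer$W1, s.b1 = model@scorer$b1,
            s.W2 = model@scorer$W2, s.b2 = model@scorer$b2)
  for (i in seq_along(model@head)) {
    p[[sprintf("h%d.W", i)]] <- model@head[[i]]$W
    p[[sprintf("h%d.b", i)]] <- model@head[[i]]$b
  }
  if (model@aggregator == "attention") {
    p$a.u <- model@attention$u
    p$a.b <- model@attention$b
    p$a.v <- model@attention$v
  }
  p
}

.applyParams <- function(model, p) {
  model@scorer <- list(W1 = p$s.W1, b1 = p$s.b1, W2 = p$s.W2, b2 = p$s.b2)
  for (i in seq_along(model@head))
    model@head[[i]] <- list(W = p[[sprintf("h%d.W", i)]],
                            b = p[[sprintf("h%d.b", i)]])
  if (model@aggregator == "attention")
    model@attention <- list(u = p$a.u, b = p$a.b, v = p$a.v)
  model
}

## ---- backward pass ----

## loss and exact gradient of the event-normalized Cox loss with respect to
## every parameter, over a prepared cohort
.lossAndGradient <- function(model, prep, times, events) {
  fw <- .forwardCohort(model, prep)
  loss <- coxLoss(fw$O, times, events, normalize = TRUE)
  dO <- coxLossGradient(fw$O, times, events, normalize = TRUE)

  ## head backward
  head <- model@head
  L <- length(head)
  acts <- fw$headActs
  delta <- matrix(dO, ncol = 1L)
  g <- list()
  for (i in L:1) {
    g[[sprintf("h%d.W", i)]] <- crossprod(acts[[i]], delta)
    g[[sprintf("h%d.b", i)]] <- colSums(delta)
    delta <- delta %*% t(head[[i]]$W)
    if (i > 1L) delta <- delta * (acts[[i]] > 0)
  }
  dB <- delta                                  # n_bags x m

  ## route bag-feature gradients back to instance scores
  N <- length(fw$sf$S)
  da_u <- 0; da_b <- 0; da_v <- 0
  selAll <- vector("list", length(prep$sizes))
  valAll <- vector("list", length(prep$sizes))
  for (b in seq_along(prep$sizes)) {
    agg <- fw$aggs[[b]]
    if (!is.null(agg$attn)) {
      at <- agg$attn
      dOut <- dB[b, ]                          # one value per percentile
      one_th2 <- 1 - at$th^2
      M <- sweep(at$a * sweep(at$vm, 2L, at$f, "-"), 2L, dOut, "*")
      ds <- sweep(at$a, 2L, dOut, "*") +
        M * (model@attention$v * model@attention$u * one_th2)
      da_u <- da_u + sum(M * model@attention$v * one_th2 * at$vm)
      da_b <- da_b + sum(M * model@attention$v * one_th2)
      da_v <- da_v + sum(M * at$th)
      selAll[[b]] <- at$sel
      valAll[[b]] <- as.numeric(ds)            # column-major matches sel
    } else {
      selAll[[b]] <- agg$sel
      valAll[[b]] <- dB[b, agg$rows] * agg$w
    }
  }
  sel <- unlist(selAll, use.names = FALSE)
  val <- unlist(valAll, use.names = FALSE)
  acc <- rowsum(val, sel)                      # duplicates accumulate
  dS <- numeric(N)
  dS[as.integer(rownames(acc))] <- acc[, 1L]

  ## scorer backward, restricted to instances that received gradient
  nz <- which(dS != 0)
  if (length(nz) == 0L) nz <- 1L               # degenerate but keep shapes
  H_nz <- fw$sf$H[nz, , drop = FALSE]
  X_nz <- prep$X[nz, , drop = FALSE]
  ds_nz <- dS[nz]
  g$s.W2 <- crossprod(H_nz, ds_nz)
  g$s.b2 <- sum(ds_nz)
  dZ <- outer(ds_nz, drop(model@scorer$W2)) * (H_nz > 0)
  g$s.W1 <- crossprod(X_nz, dZ)
  g$s.b1 <- colSums(dZ)
  if (model@aggregator == "attention") {
    g$a.u <- da_u; g$a.b <- da_b; g$a.v <- da_v
  }
  list(loss = loss, grads = g, risks = fw$O)
}

## restrict a prepared cohort to a subset of bags (mini-batch support)
.subsetPrep <- function(prep, keep) {
  rows <- unlist(lapply(keep, function(b) prep$starts[b]:prep$ends[b]),
                 use.names = FALSE)
  sizes <- prep$sizes[keep]
  ends <- cumsum(sizes)
  list(X = prep$X[rows, , drop = FALSE], sizes = sizes,
       starts = ends - sizes + 1L, ends = ends, ids = prep$ids[keep])
}

## early-stopping bookkeeping: returns index of the best epoch so far and
## whether training should stop, given the validation-loss history
.earlyStop <- function(val_losses, patience) {
  best <- which.min(val_losses)
  list(best = best, stop = (length(val_losses) - best) >= patience)
}

#' Train a distribution-MIL survival model
#'
#' Minimizes the event-normalized Cox negative log partial likelihood with
#' Adam over full-cohort (default) or mini-batch risk sets. After every
#' epoch the validation loss is evaluated; training stops when it has not
#' improved for \code{patience} epochs, and the parameters from the best
#' validation epoch are returned. Deterministic given the config seed.
#'
#' @param train a [BagCohort-class] used for gradient steps.
#' @param val a [BagCohort-class] monitored for early stopping (never used
#'   for gradients).
#' @param config a [trainConfig()] list.
#' @return list with \code{model} (the best-epoch [DisMISLModel-class]),
#'   \code{log} (data.frame of epoch, train_loss, val_loss) and
#'   \code{best_epoch}.
#' @export
trainModel <- function(train, val, config = trainConfig()) {
  stopifnot(is(train, "BagCohort"), is(val, "BagCohort"))
  strain <- survivalData(train)
  sval <- survivalData(val)
  if (sum(strain$event) == 0 || sum(sval$event) == 0)
    stop("training and validation cohorts must each contain at least one event")

  restore <- .withSeed(config$seed)
  on.exit(restore())
  model <- newDisMISLModel(featureDim(train), scheme = config$scheme,
                           aggregator = config$aggregator,
                           scorer_hidden = config$scorer_hidden,
                           head_hidden = config$head_hidden,
                           seed = config$seed)
  prep <- .prepCohort(train)
  prep_val <- .prepCohort(val)
  params <- .flattenParams(model)
  mA <- lapply(params, function(x) x * 0)
  vA <- mA
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  wd <- config$weight_decay
  nb <- nBags(train)
  bs <- if (is.null(config$batch_size)) nb else min(config$batch_size, nb)
  step <- 0L
  val_hist <- numeric(0)
  train_hist <- numeric(0)
  best_params <- params

  for (epoch in seq_len(config$max_epochs)) {
    batches <- if (bs >= nb) list(seq_len(nb)) else {
      perm <- sample.int(nb)
      split(perm, ceiling(seq_along(perm) / bs))
    }
    ep_loss <- 0
    for (batch in batches) {
      model <- .applyParams(model, params)
      bprep <- if (length(batch) == nb && bs >= nb) prep
               else .subsetPrep(prep, batch)
      lg <- .lossAndGradient(model, bprep, strain$time[batch],
                             strain$event[batch])
      ep_loss <- ep_loss + lg$loss * length(batch)
      step <- step + 1L
      gn <- sqrt(sum(vapply(lg$grads, function(g) sum(g^2), numeric(1))))
      scale <- if (is.finite(gn) && gn > config$clip_norm)
        config$clip_norm / gn else 1
      for (nm in names(params)) {
        gr <- lg$grads[[nm]]
        if (is.null(gr)) gr <- params[[nm]] * 0
        gr <- gr * scale
        if (wd > 0 && grepl("W", nm)) gr <- gr + wd * params[[nm]]
        mA[[nm]] <- b1 * mA[[nm]] + (1 - b1) * gr
        vA[[nm]] <- b2 * vA[[nm]] + (1 - b2) * gr^2
        mhat <- mA[[nm]] / (1 - b1^step)
        vhat <- vA[[nm]] / (1 - b2^step)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    model <- .applyParams(model, params)
    fw_val <- .forwardCohort(model, prep_val)
    vloss <- coxLoss(fw_val$O, sval$time, sval$event, normalize = TRUE)
    val_hist <- c(val_hist, vloss)
    train_hist <- c(train_hist, ep_loss / nb)
    es <- .earlyStop(val_hist, config$patience)
    if (es$best == epoch) best_params <- params
    if (es$stop) break
  }
  best <- which.min(val_hist)
  list(model = .applyParams(model, best_params),
       log = data.frame(epoch = seq_along(val_hist),
                        train_loss = train_hist, val_loss = val_hist),
       best_epoch = best, best_val_loss = val_hist[best])
}

#' Grid search over learning rate and weight decay
#'
#' Trains one model per (learning rate, weight decay) pair in the config's
#' grids and returns the fit with the lowest best-epoch validation loss.
#'
#' @inheritParams trainModel
#' @return as [trainModel()], plus \code{grid} (the settings tried and their
#'   validation losses).
#' @export
trainModelGrid <- function(train, val, config = trainConfig()) {
  grid <- expand.grid(lr = config$lr_grid, wd = config$wd_grid)
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- config
    cfg$learning_rate <- grid$lr[i]
    cfg$weight_decay <- grid$wd[i]
    fits[[i]] <- trainModel(train, val, cfg)
  }
  losses <- vapply(fits, `[[`, numeric(1), "best_val_loss")
  best <- which.min(losses)
  out <- fits[[best]]
  out$grid <- cbind(grid, val_loss = losses)
  out
}

#' Seeded k-fold split
#'
#' Randomly partitions a cohort into k folds whose sizes differ by at most
#' one; optionally stratified by event status.
#'
#' @param x a [BagCohort-class], a character vector of bag_ids, or an
#'   integer count.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @param stratify if TRUE, balance event/censored status across folds.
#' @return named integer vector of fold assignments (1..k).
#' @export
kfoldSplit <- function(x, k = 5L, seed = 1L, stratify = FALSE) {
  ids <- if (is(x, "BagCohort")) bagIds(x)
         else if (is.character(x)) x
         else as.character(seq_len(x))
  n <- length(ids)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k must not exceed the number of bags")
  restore <- .withSeed(seed)
  on.exit(restore())
  folds <- integer(n)
  if (stratify && is(x, "BagCohort")) {
    ev <- survivalData(x)$event
    for (g in unique(ev)) {
      w <- which(ev == g)
      folds[w] <- sample(rep_len(seq_len(k), length(w)))
    }
  } else {
    folds <- sample(rep_len(seq_len(k), n))
  }
  stats::setNames(folds, ids)
}
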