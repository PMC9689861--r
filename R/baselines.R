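#' Mean-pooling aggregation
#'
#' Collapses a bag's score distribution to its arithmetic mean, the feature
#' fed to the risk head by the mean-pooling comparator.
#'
#' @param scores numeric vector of instance scores.
#' @return length-1 numeric vector.
#' @export
meanpoolFeatures <- function(scores) {
  if (length(scores) < 1L) stop("empty scores")
  mean(scores)
}

#' Top-k max-pooling aggregation
#'
#' The k largest instance scores in descending order (k = 1 and k = 10 are
#' the published comparators).
#'
#' @param scores numeric vector of instance scores.
#' @param k number of top instances, \code{1 <= k <= length(scores)}.
#' @return numeric vector of length k, descending.
#' @export
maxpoolTopkFeatures <- function(scores, k) {
  n <- length(scores)
  if (n < 1L) stop("empty scores")
  if (k < 1L || k > n) stop("k must satisfy 1 <= k <= length(scores)")
  sort(scores, decreasing = TRUE)[seq_len(k)]
}

#' Top/bottom-k aggregation
#'
#' Concatenation of the k largest scores (descending) and the k smallest
#' scores (ascending); with k = 10 this is the MesoNet-style comparator that
#' feeds the extremes of the score distribution to the head.
#'
#' @param scores numeric vector of instance scores.
#' @param k instances taken from each tail; requires
#'   \code{length(scores) >= 2k}.
#' @return numeric vector of length 2k.
#' @export
topBottomKFeatures <- function(scores, k = 10L) {
  n <- length(scores)
  if (n < 1L) stop("empty scores")
  if (n < 2L * k) stop("need at least 2k instances")
  s <- sort(scores)
  c(s[n:(n - k + 1L)], s[seq_len(k)])
}

#' Bag-level mean feature vector
#'
#' Column-wise mean of a bag's feature matrix, the input representation for
#' the penalized-Cox comparator.
#'
#' @param bag numeric matrix (n x d) or a single-bag [BagCohort-class].
#' @return numeric vector of length d.
#' @export
meanFeatureVector <- function(bag) {
  if (is(bag, "BagCohort")) {
    if (nBags(bag) != 1L) stop("meanFeatureVector expects a single bag")
    bag <- bags(bag)[[1]]
  }
  colMeans(as.matrix(bag))
}

#' Bag-level design matrix of mean feature vectors
#'
#' @param cohort a [BagCohort-class].
#' @return n_bags x d matrix, rows named by bag_id.
#' @export
meanFeatureDesign <- function(cohort) {
  stopifnot(is(cohort, "BagCohort"))
  t(vapply(bags(cohort), colMeans, numeric(featureDim(cohort))))
}

#' L1-penalized Cox regression on bag-level features
#'
#' The mean-feature comparator: fits a LASSO Cox proportional-hazards model
#' (via glmnet) to bag-level mean feature vectors, choosing the penalty by
#' internal cross-validation over glmnet's geometric lambda grid unless a
#' fixed \code{l1_strength} is given.
#'
#' @param design numeric matrix, one row per bag (e.g. from
#'   [meanFeatureDesign()]).
#' @param times,events survival labels aligned with the design rows.
#' @param l1_strength optional fixed penalty lambda; \code{NULL} (default)
#'   selects \code{lambda.min} by cross-validation.
#' @param cv_folds folds for the internal penalty selection (default 5).
#' @param seed seed for the internal fold assignment.
#' @return a [PenalizedCoxModel-class].
#' @export
fitPenalizedCox <- function(design, times, events, l1_strength = NULL,
                            cv_folds = 5L, seed = 1L) {
  design <- as.matrix(design)
  if (nrow(design) != length(times) || length(times) != length(events))
    stop("design rows must match survival labels")
  if (sum(events) < 2) stop("need at least two events for a Cox fit")
  if (all(apply(design, 2L, stats::sd) == 0))
    stop("degenerate design: all columns have zero variance")
  y <- survival::Surv(times, events)
  if (is.null(l1_strength)) {
    restore <- .withSeed(seed)
    on.exit(restore())
    foldid <- sample(rep(seq_len(cv_folds), length.out = nrow(design)))
    cv <- glmnet::cv.glmnet(design, y, family = "cox", alpha = 1,
                            foldid = foldid)
    lam <- cv$lambda.min
    beta <- as.numeric(stats::coef(cv, s = "lambda.min"))
  } else {
    fit <- glmnet::glmnet(design, y, family = "cox", alpha = 1)
    lam <- l1_strength
    beta <- as.numeric(stats::coef(fit, s = lam, exact = FALSE))
  }
  names(beta) <- colnames(design)
  new("PenalizedCoxModel", beta = beta, lambda = lam)
}

#' @describeIn predictRisk linear risk \code{x'beta} of each bag-level mean
#'   feature vector.
#' @export
setMethod("predictRisk", "PenalizedCoxModel", function(object, cohort, ...) {
  X <- if (is(cohort, "BagCohort")) meanFeatureDesign(cohort)
       else as.matrix(cohort)
  drop(X %*% object@beta)
})
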