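#' @import methods
NULL

#' PercentileScheme: which ranked instances feed the risk head
#'
#' A percentile scheme is an ordered list of percentile locations P (in
#' [0, 100]) together with an odd neighborhood width k. For every location p
#' the k consecutively ranked instances centered on the nearest-rank position
#' of p in the ascending per-bag score distribution are selected, so the head
#' input width is \code{length(P) * k} (for the attention variant each window
#' collapses to one value, width \code{length(P)}).
#'
#' @slot percentiles numeric, strictly increasing, in [0, 100].
#' @slot neighborhood odd positive integer, number of instances per location.
#'
#' @seealso [percentileScheme()], [scenarioScheme()],
#'   [selectPercentileInstances()]
#' @export
setClass("PercentileScheme",
  representation(percentiles = "numeric", neighborhood = "integer"),
  validity = function(object) {
    p <- object@percentiles
    k <- object@neighborhood
    if (length(p) < 1L) return("need at least one percentile")
    if (anyNA(p) || any(!is.finite(p))) return("percentiles must be finite")
    if (any(p < 0) || any(p > 100)) return("percentiles must lie in [0, 100]")
    if (any(diff(p) <= 0)) return("percentiles must be strictly increasing")
    if (length(k) != 1L || is.na(k) || k < 1L || k %% 2L == 0L)
      return("neighborhood must be a single odd positive integer")
    TRUE
  }
)

#' BagCohort: a cohort of feature bags with censored survival labels
#'
#' One bag per patient: an n x d matrix of instance (patch) feature vectors,
#' keyed by \code{bag_id}, plus one right-censored survival record per bag
#' (observed time > 0 and event indicator, 1 = death observed, 0 = censored).
#' The feature dimension d is constant across the cohort; the number of
#' instances n may vary between bags.
#'
#' @slot bags named list of numeric matrices (rows = instances).
#' @slot survival data.frame with columns \code{bag_id}, \code{time},
#'   \code{event}, one row per bag, in the same order as \code{bags}.
#'
#' @seealso [BagCohort()], [loadCohort()], [writeCohort()], [resampleBag()]
#' @export
setClass("BagCohort",
  representation(bags = "list", survival = "data.frame"),
  validity = function(object) {
    b <- object@bags
    s <- object@survival
    if (length(b) == 0L) return("cohort must contain at least one bag")
    ids <- names(b)
    if (is.null(ids) || any(!nzchar(ids))) return("bags must be named by bag_id")
    if (anyDuplicated(ids)) return("bag_ids must be unique")
    if (!all(c("bag_id", "time", "event") %in% names(s)))
      return("survival must have columns bag_id, time, event")
    if (nrow(s) != length(b) || !identical(as.character(s$bag_id), ids))
      return("survival rows must match bags one-to-one, in order")
    if (any(!is.finite(s$time)) || any(s$time <= 0))
      return("survival times must be positive and finite")
    if (!all(s$event %in% c(0, 1))) return("event indicators must be 0 or 1")
    d <- unique(vapply(b, ncol, integer(1)))
    if (length(d) != 1L) return("feature dimension must be constant across bags")
    for (i in seq_along(b)) {
      m <- b[[i]]
      if (!is.matrix(m) || !is.numeric(m))
        return(sprintf("bag '%s' is not a numeric matrix", ids[i]))
      if (nrow(m) < 1L) return(sprintf("bag '%s' has no instances", ids[i]))
      if (any(!is.finite(m)))
        return(sprintf("bag '%s' contains non-finite feature values", ids[i]))
    }
    TRUE
  }
)

#' DisMISLModel: scorer, aggregation rule and risk head
#'
#' Holds the parameters of the distribution-based MIL survival model: a
#' two-layer instance scorer shared across instances (equivalent to
#' width-one 1-D convolutions), an aggregation rule (percentile selection,
#' one of the pooling comparators, or attention within percentile windows),
#' and the MLP risk head that maps aggregated features to a scalar risk.
#'
#' @slot scorer list with \code{W1} (d x h), \code{b1}, \code{W2} (h x 1),
#'   \code{b2}; layer 1 uses a rectified-linear activation, layer 2 is affine.
#' @slot head list of affine layers \code{list(W, b)}; hidden layers use
#'   rectified-linear activations, the last layer outputs the risk score.
#' @slot scheme the [PercentileScheme-class] used by percentile aggregators.
#' @slot aggregator one of \code{"dismisl"}, \code{"attention"},
#'   \code{"mesonet_topbottom10"}, \code{"meanpool"}, \code{"maxpool_top1"},
#'   \code{"maxpool_top10"}.
#' @slot attention list with \code{u}, \code{b}, \code{v} (affine + tanh
#'   instance attention scorer), empty unless \code{aggregator = "attention"}.
#' @slot config list echoing the architecture (dims, seed) so serialized
#'   models are self-describing.
#'
#' @seealso [newDisMISLModel()], [predictRisk()], [trainModel()]
#' @export
setClass("DisMISLModel",
  representation(scorer = "list", head = "list", scheme = "PercentileScheme",
                 aggregator = "character", attention = "list",
                 config = "list"),
  validity = function(object) {
    ok <- c("dismisl", "attention", "mesonet_topbottom10", "meanpool",
            "maxpool_top1", "maxpool_top10")
    if (length(object@aggregator) != 1L || !(object@aggregator %in% ok))
      return(sprintf("aggregator must be one of: %s", paste(ok, collapse = ", ")))
    sc <- object@scorer
    if (!all(c("W1", "b1", "W2", "b2") %in% names(sc)))
      return("scorer must have W1, b1, W2, b2")
    if (any(!vapply(sc, function(x) all(is.finite(x)), logical(1))))
      return("scorer weights must be finite")
    if (length(object@head) < 1L) return("head must have at least one layer")
    if (object@aggregator == "attention" &&
        !all(c("u", "b", "v") %in% names(object@attention)))
      return("attention aggregator requires attention parameters u, b, v")
    TRUE
  }
)

#' SyntheticTruth: generator-side ground truth for a synthetic cohort
#'
#' Kept alongside generated cohorts so that recovery tests can compare
#' fitted risks with the true per-bag log-hazard, and inspect the latent
#' instance structure (tissue-like type and latent scalar u per instance,
#' per-bag mixture proportions).
#'
#' @slot mixture n_bags x n_types matrix of per-bag mixture proportions.
#' @slot instances named list (per bag) of data.frames with columns
#'   \code{type} and \code{u}.
#' @slot logHazard named numeric, the true per-bag log-hazard r.
#'
#' @seealso [generateCohort()], [oracleCindex()]
#' @export
setClass("SyntheticTruth",
  representation(mixture = "matrix", instances = "list", logHazard = "numeric"),
  validity = function(object) {
    n <- nrow(object@mixture)
    if (length(object@instances) != n || length(object@logHazard) != n)
      return("mixture, instances and logHazard must cover the same bags")
    if (!identical(names(object@instances), names(object@logHazard)))
      return("instances and logHazard must share bag names")
    if (any(!is.finite(object@logHazard))) return("logHazard must be finite")
    TRUE
  }
)

#' PenalizedCoxModel: linear risk model from an L1-penalized Cox fit
#'
#' The bag-level comparator: column-wise mean feature vectors fitted with a
#' LASSO Cox regression. Predicts risk as the linear score x'beta.
#'
#' @slot beta named numeric coefficient vector (length d).
#' @slot lambda the penalty at which \code{beta} was extracted.
#'
#' @seealso [fitPenalizedCox()], [predictRisk()]
#' @export
setClass("PenalizedCoxModel",
  representation(beta = "numeric", lambda = "numeric"),
  validity = function(object) {
    if (any(!is.finite(object@beta))) return("coefficients must be finite")
    TRUE
  }
)

setMethod("show", "PercentileScheme", function(object) {
  cat("PercentileScheme:", length(object@percentiles), "locations, k =",
      object@neighborhood, "\n  P = [",
      paste(object@percentiles, collapse = ", "), "]\n")
})

setMethod("show", "BagCohort", function(object) {
  ns <- vapply(object@bags, nrow, integer(1))
  cat("BagCohort:", length(object@bags), "bags, d =",
      ncol(object@bags[[1]]), "features\n")
  cat("  instances per bag:", min(ns), "-", max(ns),
      sprintf("(median %g)", stats::median(ns)), "\n")
  cat("  events:", sum(object@survival$event), "of", nrow(object@survival),
      "\n")
})

setMethod("show", "DisMISLModel", function(object) {
  d <- nrow(object@scorer$W1); h <- ncol(object@scorer$W1)
  cat("DisMISLModel (", object@aggregator, ")\n", sep = "")
  cat("  scorer:", d, "->", h, "-> 1 (shared across instances)\n")
  cat("  head input width:", nrow(object@head[[1]]$W), "->",
      paste(vapply(object@head, function(l) ncol(l$W), integer(1)),
            collapse = " -> "), "\n")
  if (object@aggregator %in% c("dismisl", "attention")) show(object@scheme)
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", nrow(object@mixture), "bags,",
      ncol(object@mixture), "latent types\n")
  cat("  log-hazard range: [", sprintf("%.3f", min(object@logHazard)), ",",
      sprintf("%.3f", max(object@logHazard)), "]\n")
})
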