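#' Predict per-bag survival risk
#'
#' Computes one scalar risk score per bag (higher = predicted shorter
#' survival). For a [DisMISLModel-class] this runs the instance scorer, the
#' model's aggregation rule and the MLP head; for a
#' [PenalizedCoxModel-class] it scores the bag-level mean feature vector
#' linearly.
#'
#' @param object a fitted model.
#' @param cohort a [BagCohort-class].
#' @param ... further arguments passed to methods.
#' @return named numeric vector of risk scores, one per bag.
#' @export
setGeneric("predictRisk", function(object, cohort, ...)
  standardGeneric("predictRisk"))

#' @rdname BagCohort-accessors
#' @export
setGeneric("bagIds", function(x) standardGeneric("bagIds"))

#' @rdname BagCohort-accessors
#' @export
setGeneric("bags", function(x) standardGeneric("bags"))

#' @rdname BagCohort-accessors
#' @export
setGeneric("survivalData", function(x) standardGeneric("survivalData"))

#' @rdname BagCohort-accessors
#' @export
setGeneric("featureDim", function(x) standardGeneric("featureDim"))

#' @rdname BagCohort-accessors
#' @export
setGeneric("nBags", function(x) standardGeneric("nBags"))

#' @rdname BagCohort-accessors
#' @export
setGeneric("bagSizes", function(x) standardGeneric("bagSizes"))
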