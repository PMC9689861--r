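#' Construct a percentile scheme
#'
#' @param percentiles strictly increasing numeric vector in [0, 100].
#' @param neighborhood odd positive integer k: number of consecutively ranked
#'   instances selected around each percentile location.
#' @return a [PercentileScheme-class].
#' @examples
#' percentileScheme(c(0, 50, 100), 3)
#' @export
percentileScheme <- function(percentiles, neighborhood = 1L) {
  new("PercentileScheme", percentiles = as.numeric(percentiles),
      neighborhood = as.integer(neighborhood))
}

## the seven published percentile scenarios, from only the extremes
## (scenario 1) to the near-complete score distribution (scenario 7)
.SCENARIOS <- list(
  c(0, 100),
  c(0, 0.1, 99.9, 100),
  c(0, 0.1, 1, 99, 99.9, 100),
  c(0, 0.1, 1, 5, 95, 99, 99.9, 100),
  c(0, 0.1, 1, 5, 10, 90, 95, 99, 99.9, 100),
  c(0, 0.1, 1, 5, 10, 25, 75, 90, 95, 99, 99.9, 100),
  c(0, 0.1, 1, 5, 10, 25, 50, 75, 90, 95, 99, 99.9, 100)
)

#' The seven standard percentile scenarios
#'
#' Scenario 1 uses only the extremes [0, 100]; each later scenario adds
#' percentile locations symmetrically toward the middle of the score
#' distribution, up to scenario 7's 13 locations
#' [0, 0.1, 1, 5, 10, 25, 50, 75, 90, 95, 99, 99.9, 100].
#'
#' @param scenario_id integer in 1..7.
#' @param neighborhood odd positive integer k (default 1).
#' @return a [PercentileScheme-class].
#' @examples
#' scenarioScheme(1)      # extremes only
#' scenarioScheme(7, 5)   # full distribution, 5 instances per location
#' @export
scenarioScheme <- function(scenario_id, neighborhood = 1L) {
  if (length(scenario_id) != 1L || !scenario_id %in% 1:7)
    stop("scenario_id must be an integer in 1..7")
  percentileScheme(.SCENARIOS[[scenario_id]], neighborhood)
}

## 1-based positions into the ascending sort selected by a scheme.
## Nearest rank: center c = round(p/100 * (n-1)), half away from zero
## (p >= 0 so floor(x + 0.5)); windows of k consecutive ranks centered on c
## are shifted inward at the boundaries so the output width is always
## length(P) * k; bags with n < k repeat the boundary ranks.
.schemeRanks <- function(n, percentiles, k) {
  half <- (k - 1L) %/% 2L
  out <- integer(0)
  for (p in percentiles) {
    ctr <- floor(p / 100 * (n - 1) + 0.5)
    idx <- if (n >= k) {
      lo <- min(max(ctr - half, 0), n - k)
      lo + 0:(k - 1)
    } else {
      pmin(pmax(ctr - half + 0:(k - 1), 0), n - 1)
    }
    out <- c(out, idx)
  }
  out + 1L
}

#' Select instance scores at percentile locations
#'
#' Sorts the per-bag scores ascending (stable sort, original index breaks
#' ties) and extracts, for every percentile location p of the scheme, the
#' window of k consecutively ranked scores centered on the nearest rank
#' \code{round(p/100 * (n-1))} (half away from zero). Windows are shifted
#' inward, never truncated, at the distribution boundaries, so the output
#' always has length \code{length(P) * k}; when \code{n < k} the boundary
#' values are repeated.
#'
#' @param scores numeric vector of instance scores (any order).
#' @param scheme a [PercentileScheme-class].
#' @return numeric vector of length \code{length(P) * k}, windows in scheme
#'   order, each window in ascending rank order; attribute \code{indices}
#'   gives the original position of each selected score.
#' @examples
#' selectPercentileInstances(c(30, 10, 50, 20, 40),
#'                           percentileScheme(c(0, 50, 100)))  # 10 30 50
#' @export
selectPercentileInstances <- function(scores, scheme) {
  if (length(scores) < 1L) stop("empty scores")
  stopifnot(is(scheme, "PercentileScheme"))
  ord <- order(scores)                  # stable; ties by original index
  ranks <- .schemeRanks(length(scores), scheme@percentiles,
                        scheme@neighborhood)
  out <- scores[ord][ranks]
  attr(out, "indices") <- ord[ranks]
  out
}

## fan-in-scaled uniform initialization
.initAffine <- function(n_in, n_out) {
  lim <- 1 / sqrt(n_in)
  list(W = matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out),
       b = numeric(n_out))
}

.headInputWidth <- function(aggregator, scheme) {
  switch(aggregator,
    dismisl = length(scheme@percentiles) * scheme@neighborhood,
    attention = length(scheme@percentiles),
    mesonet_topbottom10 = 20L,
    meanpool = 1L,
    maxpool_top1 = 1L,
    maxpool_top10 = 10L,
    stop("unknown aggregator: ", aggregator))
}

#' Create an untrained distribution-MIL survival model
#'
#' Builds the shared-scorer architecture: two instance-level affine layers
#' (d -> h with rectified-linear activation, then h -> 1, shared across
#' instances), the chosen aggregation rule, and an MLP risk head. Parameters
#' are drawn from a fan-in-scaled uniform distribution, deterministically
#' given \code{seed}.
#'
#' @param feature_dim number of feature columns d of the input bags.
#' @param scheme a [PercentileScheme-class] (used by the \code{"dismisl"}
#'   and \code{"attention"} aggregators).
#' @param aggregator aggregation rule: \code{"dismisl"} (percentile
#'   selection), \code{"attention"} (attention within percentile windows),
#'   or a comparator: \code{"mesonet_topbottom10"}, \code{"meanpool"},
#'   \code{"maxpool_top1"}, \code{"maxpool_top10"}.
#' @param scorer_hidden width h of the scorer's hidden layer (default 128).
#' @param head_hidden integer vector of head hidden widths (default
#'   c(128, 64)); use \code{128} for the single-hidden-layer variant.
#' @param seed integer seed for parameter initialization.
#' @return an untrained [DisMISLModel-class].
#' @examples
#' newDisMISLModel(16, scenarioScheme(7, 3))
#' @export
newDisMISLModel <- function(feature_dim, scheme = scenarioScheme(7),
                            aggregator = "dismisl", scorer_hidden = 128L,
                            head_hidden = c(128L, 64L), seed = 1L) {
  stopifnot(feature_dim >= 1, scorer_hidden >= 1, all(head_hidden >= 1))
  restore <- .withSeed(seed)
  on.exit(restore())
  l1 <- .initAffine(feature_dim, scorer_hidden)
  l2 <- .initAffine(scorer_hidden, 1L)
  scorer <- list(W1 = l1$W, b1 = l1$b, W2 = l2$W, b2 = l2$b)
  m <- .headInputWidth(aggregator, scheme)
  widths <- c(m, head_hidden, 1L)
  head <- lapply(seq_len(length(widths) - 1L),
                 function(i) .initAffine(widths[i], widths[i + 1L]))
  attn <- if (aggregator == "attention") {
    list(u = stats::runif(1, -1, 1), b = 0, v = stats::runif(1, -1, 1))
  } else list()
  new("DisMISLModel", scorer = scorer, head = head, scheme = scheme,
      aggregator = aggregator, attention = attn,
      config = list(feature_dim = feature_dim, scorer_hidden = scorer_hidden,
                    head_hidden = head_hidden, aggregator = aggregator,
                    percentiles = scheme@percentiles,
                    neighborhood = scheme@neighborhood, seed = seed))
}

#' Score every instance of a bag with the shared scorer
#'
#' Applies the two shared affine maps (rectified-linear after the first) to
#' each instance independently; the score of instance i depends only on row
#' i, so permuting the bag's rows permutes the scores identically.
#'
#' @param bag numeric matrix (n x d) or a single-bag [BagCohort-class].
#' @param scorer a [DisMISLModel-class] or a list with \code{W1}, \code{b1},
#'   \code{W2}, \code{b2}.
#' @return numeric vector of n raw scores (no activation after layer 2).
#' @export
scoreInstances <- function(bag, scorer) {
  if (is(scorer, "DisMISLModel")) scorer <- scorer@scorer
  if (is(bag, "BagCohort")) {
    if (nBags(bag) != 1L) stop("scoreInstances expects a single bag")
    bag <- bags(bag)[[1]]
  }
  bag <- as.matrix(bag)
  if (ncol(bag) != nrow(scorer$W1))
    stop("feature width ", ncol(bag), " does not match scorer input width ",
         nrow(scorer$W1))
  h <- pmax(sweep(bag %*% scorer$W1, 2L, scorer$b1, "+"), 0)
  drop(h %*% scorer$W2) + scorer$b2
}

## ---- forward machinery shared by prediction and training ----

## stack a cohort once; row ranges per bag
.prepCohort <- function(cohort) {
  sizes <- unname(bagSizes(cohort))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  list(X = do.call(rbind, bags(cohort)), sizes = sizes,
       starts = starts, ends = ends, ids = bagIds(cohort))
}

## scorer forward over stacked instances; returns scores + hidden cache
.scorerForward <- function(scorer, X) {
  Z <- sweep(X %*% scorer$W1, 2L, scorer$b1, "+")
  H <- pmax(Z, 0)
  S <- drop(H %*% scorer$W2) + scorer$b2
  list(S = S, H = H)
}

## per-bag aggregation. Returns the feature row plus linear routing
## (sel = stacked-instance indices, w = weights) or an attention cache.
.aggregateBag <- function(s, model, offset) {
  n <- length(s)
  agg <- model@aggregator
  ord <- order(s)
  if (agg %in% c("dismisl", "attention")) {
    sch <- model@scheme
    k <- sch@neighborhood
    ranks <- .schemeRanks(n, sch@percentiles, k)
    sel <- ord[ranks]
    vals <- s[sel]
    if (agg == "dismisl")
      return(list(f = vals, sel = offset + sel, rows = seq_along(vals),
                  w = rep(1, length(vals))))
    ## attention: softmax(v * tanh(u*s + b)) within each k-window
    ap <- model@attention
    P <- length(sch@percentiles)
    vm <- matrix(vals, nrow = k)        # k x P, one column per window
    th <- tanh(ap$u * vm + ap$b)
    e <- ap$v * th
    e <- sweep(e, 2L, apply(e, 2L, max), "-")
    a <- sweep(exp(e), 2L, colSums(exp(e)), "/")
    f <- colSums(a * vm)
    return(list(f = f, attn = list(vm = vm, th = th, a = a, f = f,
                                   sel = offset + sel, k = k, P = P)))
  }
  if (agg == "meanpool")
    return(list(f = mean(s), sel = offset + seq_len(n), rows = rep(1L, n),
                w = rep(1 / n, n)))
  if (agg == "maxpool_top1")
    return(list(f = s[ord[n]], sel = offset + ord[n], rows = 1L, w = 1))
  if (agg == "maxpool_top10") {
    if (n < 10L) stop("maxpool_top10 needs at least 10 instances per bag")
    sel <- ord[n:(n - 9L)]
    return(list(f = s[sel], sel = offset + sel, rows = 1:10, w = rep(1, 10)))
  }
  if (agg == "mesonet_topbottom10") {
    if (n < 20L) stop("mesonet_topbottom10 needs at least 20 instances per bag")
    sel <- c(ord[n:(n - 9L)], ord[1:10])
    return(list(f = s[sel], sel = offset + sel, rows = 1:20, w = rep(1, 20)))
  }
  stop("unknown aggregator: ", agg)
}

## head forward on the bag-level feature matrix B (n_bags x m)
.headForward <- function(head, B) {
  acts <- list(B)
  A <- B
  L <- length(head)
  for (i in seq_len(L)) {
    Z <- sweep(A %*% head[[i]]$W, 2L, head[[i]]$b, "+")
    A <- if (i < L) pmax(Z, 0) else Z
    acts[[i + 1L]] <- A
  }
  list(O = drop(acts[[L + 1L]]), acts = acts)
}

## full forward pass over a prepared cohort
.forwardCohort <- function(model, prep) {
  sf <- .scorerForward(model@scorer, prep$X)
  nb <- length(prep$sizes)
  aggs <- vector("list", nb)
  for (b in seq_len(nb)) {
    s <- sf$S[prep$starts[b]:prep$ends[b]]
    aggs[[b]] <- .aggregateBag(s, model, offset = prep$starts[b] - 1L)
  }
  B <- do.call(rbind, lapply(aggs, `[[`, "f"))
  hf <- .headForward(model@head, B)
  list(O = hf$O, sf = sf, aggs = aggs, B = B, headActs = hf$acts)
}

#' @describeIn predictRisk risk scores from the scorer + aggregation + head
#'   composition; invariant to instance permutation within each bag.
#' @export
setMethod("predictRisk", "DisMISLModel", function(object, cohort, ...) {
  stopifnot(is(cohort, "BagCohort"))
  if (featureDim(cohort) != nrow(object@scorer$W1))
    stop("cohort feature width ", featureDim(cohort),
         " does not match scorer input width ", nrow(object@scorer$W1))
  prep <- .prepCohort(cohort)
  fw <- .forwardCohort(object, prep)
  stats::setNames(fw$O, prep$ids)
})

#' Risk prediction with attention aggregation
#'
#' The attention variant of the percentile model: within each percentile
#' window the k selected instance scores are combined by normalized
#' attention weights (softmax of an affine + tanh instance scorer) into one
#' value per percentile location, so every location contributes equal prior
#' weight and the head input width is \code{length(P)}.
#'
#' @param model a [DisMISLModel-class] with \code{aggregator = "attention"}.
#' @param cohort a [BagCohort-class].
#' @return named numeric vector of risk scores.
#' @export
predictRiskAttention <- function(model, cohort) {
  if (model@aggregator != "attention")
    stop("model was not built with the attention aggregator")
  predictRisk(model, cohort)
}
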