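.checkSurvArgs <- function(risks, times, events) {
  if (length(risks) < 1L) stop("empty input")
  if (length(times) != length(risks) || length(events) != length(risks))
    stop("risks, times and events must have equal length")
  if (any(!is.finite(risks))) stop("risks must be finite")
  if (any(!is.finite(times)) || any(times <= 0)) stop("times must be positive")
  if (!all(events %in% c(0, 1))) stop("events must be 0 or 1")
}

## risk-set log-sum-exp denominators, Breslow ties: risk set for subject i is
## {j : t_j >= t_i}, subjects tied with t_i included. Returns per-subject
## pieces in the original order.
.coxPieces <- function(risks, times) {
  n <- length(risks)
  o <- order(times)
  r <- risks[o]
  t_s <- times[o]
  m <- max(r)
  w <- exp(r - m)
  ## reverse cumulative sum; subjects tied on time share the denominator of
  ## the first member of their tie group
  cs <- rev(cumsum(rev(w)))
  first <- match(t_s, t_s)              # first index of each tie group
  denom <- cs[first]
  list(order = o, shifted = r, max = m, w = w, denom = denom, times = t_s)
}

#' Cox negative log partial likelihood
#'
#' The training objective for proportional-hazards risk scores:
#' \deqn{L = -\sum_i \delta_i \left( O_i - \log \sum_{j : t_j \ge t_i} e^{O_j} \right)}
#' with the risk set of subject i including i itself and all subjects tied on
#' time (Breslow handling of ties). The inner sum is computed with a
#' max-shifted log-sum-exp so risks with magnitude up to about 1e3 do not
#' overflow.
#'
#' @param risks numeric risk scores O (higher = shorter predicted survival).
#' @param times positive observed times.
#' @param events 0/1 event indicators (1 = death observed, 0 = censored).
#' @param normalize if TRUE, divide by the number of events so magnitudes are
#'   comparable across cohort sizes (used during training); the default FALSE
#'   returns the plain sum.
#' @return a non-negative scalar. With no events the partial likelihood is
#'   empty; 0 is returned with a warning.
#' @examples
#' cox_loss <- coxLoss(c(0, 0, 0), c(1, 2, 3), c(1, 1, 1))  # log(6)
#' @export
coxLoss <- function(risks, times, events, normalize = FALSE) {
  .checkSurvArgs(risks, times, events)
  if (sum(events) == 0) {
    warning("no events: Cox partial likelihood is empty, returning 0")
    return(0)
  }
  p <- .coxPieces(risks, times)
  d <- events[p$order]
  ll <- sum(d * (p$shifted - (p$max + log(p$denom))))
  out <- -ll
  if (normalize) out <- out / sum(events)
  out
}

#' Gradient of the Cox negative log partial likelihood
#'
#' Exact analytic gradient of [coxLoss()] with respect to each risk score:
#' \deqn{\partial L / \partial O_i = -\delta_i +
#'   e^{O_i} \sum_{k : \delta_k = 1,\ t_k \le t_i} 1 / \sum_{j : t_j \ge t_k} e^{O_j}}
#'
#' @inheritParams coxLoss
#' @return numeric vector, same length and order as \code{risks}. All-censored
#'   input returns the zero vector (with the same warning as [coxLoss()]).
#' @export
coxLossGradient <- function(risks, times, events, normalize = FALSE) {
  .checkSurvArgs(risks, times, events)
  n <- length(risks)
  if (sum(events) == 0) {
    warning("no events: Cox partial likelihood is empty, returning 0 gradient")
    return(numeric(n))
  }
  p <- .coxPieces(risks, times)
  d <- events[p$order]
  ## G_i = sum over event subjects k with t_k <= t_i of 1/denom_k;
  ## ties: subjects tied with t_i are all included (they satisfy t_k <= t_i)
  cum <- cumsum(d / p$denom)
  t_s <- p$times
  last <- length(t_s) + 1L - match(t_s, rev(t_s))  # last index of tie group
  G <- cum[last]
  g_sorted <- -d + p$w * G
  g <- numeric(n)
  g[p$order] <- g_sorted
  if (normalize) g <- g / sum(events)
  g
}

#' Harrell's concordance index
#'
#' Fraction of comparable subject pairs whose predicted risks order the same
#' way as their survival times. A pair (i, j) is comparable when
#' \code{t_i < t_j} and subject i had the event; it is concordant when
#' \code{O_i > O_j}, and tied predicted risks count 1/2. Pairs with equal
#' observed times are not comparable.
#'
#' @inheritParams coxLoss
#' @return a scalar in [0, 1]; 0.5 is chance level.
#' @examples
#' concordanceIndex(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1))  # 1
#' @export
concordanceIndex <- function(risks, times, events) {
  .checkSurvArgs(risks, times, events)
  ## comparable[i, j]: t_i < t_j and event_i = 1
  comp <- outer(times, times, "<") & (events == 1)
  nc <- sum(comp)
  if (nc == 0) stop("no comparable pair: concordance index is undefined")
  gt <- outer(risks, risks, ">")
  eq <- outer(risks, risks, "==")
  (sum(comp & gt) + 0.5 * sum(comp & eq)) / nc
}

#' Median-threshold risk stratification
#'
#' Computes the median risk score on the training set (midpoint of the two
#' central order statistics for even counts) and labels each evaluation bag
#' high-risk when its risk is greater than or equal to that threshold.
#'
#' @param train_risks numeric risks from the training cohort.
#' @param eval_risks numeric risks to stratify (may be the same vector).
#' @return factor with levels \code{low}, \code{high}, plus attribute
#'   \code{threshold}.
#' @examples
#' stratifyByMedian(c(1, 2, 3), c(0, 2, 5))  # low high high
#' @export
stratifyByMedian <- function(train_risks, eval_risks) {
  if (length(train_risks) < 1L) stop("empty training risks")
  if (any(!is.finite(train_risks)) || any(!is.finite(eval_risks)))
    stop("risks must be finite")
  thr <- stats::median(train_risks)
  out <- factor(ifelse(eval_risks >= thr, "high", "low"),
                levels = c("low", "high"))
  names(out) <- names(eval_risks)
  attr(out, "threshold") <- thr
  out
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function. Survival drops only at
#' event times; censored subjects leave the risk set after their observed
#' time without causing a drop.
#'
#' @inheritParams coxLoss
#' @return data.frame with columns \code{time} (event times, increasing),
#'   \code{survival} (non-increasing, in [0, 1]) and \code{at_risk} (risk-set
#'   size just before each event time). With no events, a zero-row curve
#'   (flat at 1).
#' @examples
#' kaplanMeier(c(1, 2, 3), c(1, 1, 1))  # 2/3, 1/3, 0
#' @export
kaplanMeier <- function(times, events) {
  if (length(times) < 1L) stop("empty input")
  if (any(!is.finite(times)) || any(times <= 0)) stop("times must be positive")
  if (!all(events %in% c(0, 1))) stop("events must be 0 or 1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  keep <- fit$n.event > 0
  data.frame(time = fit$time[keep], survival = fit$surv[keep],
             at_risk = fit$n.risk[keep])
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison of two survival curves: observed minus
#' expected events accumulated over the pooled event times, referred to a
#' chi-square distribution with one degree of freedom.
#'
#' @param timesA,eventsA times and 0/1 event indicators for group A.
#' @param timesB,eventsB times and 0/1 event indicators for group B.
#' @return list with \code{statistic} (chi-square, 1 df) and \code{p_value}.
#' @export
logrankTest <- function(timesA, eventsA, timesB, eventsB) {
  if (length(timesA) < 1L || length(timesB) < 1L)
    stop("both groups must be non-empty")
  if (sum(eventsA) + sum(eventsB) == 0)
    stop("no events: log-rank test is undefined")
  time <- c(timesA, timesB)
  event <- c(eventsA, eventsB)
  group <- rep(c("A", "B"), c(length(timesA), length(timesB)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, rho = 0)
  stat <- unname(sd$chisq)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Export risk scores with group labels
#'
#' Writes \code{bag_id,risk,group} rows for downstream plotting.
#'
#' @param risks named numeric risks.
#' @param groups factor of group labels aligned with \code{risks}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeRiskTable <- function(risks, groups, path) {
  stopifnot(length(risks) == length(groups))
  utils::write.csv(data.frame(bag_id = names(risks), risk = unname(risks),
                              group = as.character(groups)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a Kaplan-Meier curve
#'
#' Writes \code{time,survival,at_risk} rows as produced by [kaplanMeier()].
#'
#' @param curve data.frame from [kaplanMeier()].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeKMCurve <- function(curve, path) {
  utils::write.csv(curve, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
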