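# Independent brute-force oracles used to check the package's numerics.
# These deliberately use naive loops and their own rank/shift arithmetic so
# they share no code path with the implementation.

oracleCoxLoss <- function(risks, times, events) {
  tot <- 0
  for (i in seq_along(risks)) {
    if (events[i] == 1) {
      rs <- which(times >= times[i])
      tot <- tot - (risks[i] - log(sum(exp(risks[rs]))))
    }
  }
  tot
}

oraclePairCindex <- function(risks, times, events) {
  num <- 0
  den <- 0
  n <- length(risks)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && times[i] < times[j] && events[i] == 1) {
        den <- den + 1
        if (risks[i] > risks[j]) num <- num + 1
        else if (risks[i] == risks[j]) num <- num + 0.5
      }
    }
  }
  num / den
}

# nearest-rank percentile windows via explicit while-loop shifting
oracleSelect <- function(scores, P, k) {
  n <- length(scores)
  s <- sort(scores)
  out <- numeric(0)
  for (p in P) {
    ctr <- trunc(p / 100 * (n - 1) + 0.5)   # half away from zero, x >= 0
    lo <- ctr - (k - 1) / 2
    hi <- ctr + (k - 1) / 2
    if (n >= k) {
      while (lo < 0) { lo <- lo + 1; hi <- hi + 1 }
      while (hi > n - 1) { lo <- lo - 1; hi <- hi - 1 }
      idx <- lo:hi
    } else {
      idx <- vapply(lo:hi, function(i) min(max(i, 0), n - 1), numeric(1))
    }
    out <- c(out, s[idx + 1])
  }
  out
}

# two-group log-rank from the O-E / hypergeometric-variance table
oracleLogrank <- function(tA, eA, tB, eB) {
  evt <- sort(unique(c(tA[eA == 1], tB[eB == 1])))
  O_A <- 0; E_A <- 0; V <- 0
  for (t in evt) {
    nA <- sum(tA >= t); nB <- sum(tB >= t); n <- nA + nB
    dA <- sum(tA == t & eA == 1); d <- dA + sum(tB == t & eB == 1)
    O_A <- O_A + dA
    E_A <- E_A + d * nA / n
    if (n > 1) V <- V + d * (nA / n) * (nB / n) * (n - d) / (n - 1)
  }
  chisq <- (O_A - E_A)^2 / V
  list(statistic = chisq,
       p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

centralDiff <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- x[i] + h
    xm[i] <- x[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# small random survival instance with at least one event
rSurv <- function(n, seed, tie_prob = 0) {
  set.seed(seed)
  times <- round(rexp(n) + 0.05, if (tie_prob > 0) 1 else 6)
  events <- rbinom(n, 1, 0.6)
  if (sum(events) == 0) events[sample.int(n, 1)] <- 1
  list(risks = rnorm(n), times = times, events = events)
}

# small random cohort builder
rCohort <- function(n_bags = 6, bag_size = 12, d = 4, seed = 42,
                    events = NULL) {
  set.seed(seed)
  ids <- sprintf("b%02d", seq_len(n_bags))
  bags <- stats::setNames(lapply(seq_len(n_bags), function(i)
    matrix(rnorm(bag_size * d), bag_size)), ids)
  ev <- if (is.null(events)) rbinom(n_bags, 1, 0.7) else events
  if (all(ev == 0)) ev[1] <- 1
  BagCohort(bags, data.frame(bag_id = ids, time = rexp(n_bags) + 0.1,
                             event = ev))
}
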