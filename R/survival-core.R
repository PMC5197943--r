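#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survivor function from right-censored times. At each
#' distinct event time `t_i`, with `d_i` events among `r_i` subjects at risk,
#' the conditional probability of dying in the interval is `d_i / r_i` and
#' the survivor function is the running product
#' `S(t_i) = prod_{j <= i} (1 - d_j / r_j)`. Subjects censored at `t_i`
#' remain at risk for the events at `t_i` (events precede censorings at tied
#' times); the curve is flat after the last observation.
#'
#' @param times Non-negative finite survival times (months).
#' @param statuses Event indicators: 1 = event observed, 0 = censored.
#' @return A [KMCurve-class].
#' @examples
#' km <- kmEstimate(c(26.6, 15.7, 32.2, 2.3), c(1, 1, 0, 1))
#' km  # S = 0.75, 0.50, 0.25 at 2.3, 15.7, 26.6
#' @export
kmEstimate <- function(times, statuses) {
  times <- as.numeric(times)
  statuses <- as.numeric(statuses)
  if (length(times) == 0)
    stop("kmEstimate: empty input")
  if (length(times) != length(statuses))
    stop("kmEstimate: times and statuses must have equal length")
  if (anyNA(times) || any(!is.finite(times)) || any(times < 0))
    stop("kmEstimate: times must be finite and >= 0")
  if (anyNA(statuses) || !all(statuses == 0 | statuses == 1))
    stop("kmEstimate: statuses must be 0 or 1")
  te <- sort(unique(times[statuses == 1]))
  if (length(te)) {
    d <- vapply(te, function(t) sum(times == t & statuses == 1), numeric(1))
    r <- vapply(te, function(t) sum(times >= t), numeric(1))
    s <- cumprod(1 - d / r)
  } else {
    d <- r <- s <- numeric(0)
  }
  new("KMCurve", eventTimes = te, nAtRisk = r, nEvents = d, survival = s,
      censorTimes = sort(times[statuses == 0]), nTotal = length(times))
}

#' @rdname medianSurvival
#' @export
setMethod("medianSurvival", "KMCurve", function(curve) {
  i <- which(curve@survival <= 0.5 + 1e-9)
  if (length(i)) curve@eventTimes[[min(i)]] else NA_real_
})

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' Step-function lookup: `S(t)` equals the survival after the latest event
#' time `<= t`, 1 before the first event, and stays flat after the last
#' observation.
#'
#' @param curve A [KMCurve-class].
#' @param t Numeric vector of times (months).
#' @return Numeric vector of survival probabilities.
#' @export
survivalAt <- function(curve, t) {
  stopifnot(is(curve, "KMCurve"))
  heights <- c(1, curve@survival)
  heights[findInterval(t, curve@eventTimes) + 1L]
}

# validate one (times, statuses) group for the comparison functions
.checkGroup <- function(g, label) {
  if (!is.list(g) || is.null(g$times) || is.null(g$statuses))
    stop("each group must be a list with elements 'times' and 'statuses'")
  times <- as.numeric(g$times)
  statuses <- as.numeric(g$statuses)
  if (length(times) == 0)
    stop("group '", label, "' is empty")
  if (length(times) != length(statuses))
    stop("group '", label, "': times and statuses must have equal length")
  if (anyNA(times) || any(!is.finite(times)) || any(times < 0))
    stop("group '", label, "': times must be finite and >= 0")
  if (anyNA(statuses) || !all(statuses == 0 | statuses == 1))
    stop("group '", label, "': statuses must be 0 or 1")
  list(times = times, statuses = statuses)
}

# Mantel-Cox O/E/variance table over k groups.
# At each distinct event time t_j (d_j pooled events, r_j pooled at risk,
# r_gj at risk in group g): E_g += d_j r_gj / r_j and
# V += d_j (r_j - d_j) / (r_j - 1) * (diag(p) - p p'), p = r_.j / r_j.
.logrankTable <- function(groups) {
  k <- length(groups)
  times <- unlist(lapply(groups, `[[`, "times"), use.names = FALSE)
  status <- unlist(lapply(groups, `[[`, "statuses"), use.names = FALSE)
  gidx <- rep(seq_len(k), vapply(groups, function(g) length(g$times),
                                 integer(1)))
  te <- sort(unique(times[status == 1]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in te) {
    atRisk <- times >= t
    r <- sum(atRisk)
    rg <- tabulate(gidx[atRisk], k)
    ev <- atRisk & status == 1 & times == t
    d <- sum(ev)
    O <- O + tabulate(gidx[ev], k)
    E <- E + d * rg / r
    if (r > 1) {
      p <- rg / r
      V <- V + d * (r - d) / (r - 1) * (diag(p, nrow = k) - outer(p, p))
    }
  }
  list(observed = O, expected = E, variance = V,
       totalEvents = sum(status == 1))
}

# pseudo-inverse via SVD, for singular variance submatrices
.pinv <- function(m, tol = 1e-10) {
  s <- svd(m)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Mantel-Cox log-rank test
#'
#' Compares the survival experience of two or more groups. At each distinct
#' event time the expected events in group g are `d * r_g / r`; for two
#' groups the statistic is `(O_1 - E_1)^2 / Var` with the hypergeometric
#' variance (1 df), and for k groups the standard quadratic form of the
#' `(O - E)` vector against the variance-covariance matrix (k - 1 df).
#' P-values come from the upper tail of the chi-square distribution; no
#' continuity correction is applied. With zero events overall the comparison
#' is uninformative: the result is flagged degenerate with `statistic = 0`
#' and `pValue = 1` rather than raising an error, so a whole-matrix screen
#' cannot crash on one probe.
#'
#' @param groups List (length >= 2) of groups, each a list with elements
#'   `times` and `statuses` (1 = event, 0 = censored). Names, if present,
#'   label the O/E table.
#' @return A [LogRankResult-class].
#' @examples
#' a <- list(times = c(1, 2), statuses = c(1, 1))
#' b <- list(times = c(3, 4), statuses = c(1, 1))
#' logrankTest(list(A = a, B = b))  # chisq = 49/17, p ~ 0.090
#' @export
logrankTest <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("logrankTest: at least two groups are required")
  labels <- names(groups) %||% paste0("group", seq_along(groups))
  labels[labels == ""] <- paste0("group", which(labels == ""))
  groups <- Map(.checkGroup, groups, labels)
  k <- length(groups)
  tab <- .logrankTable(groups)
  O <- setNames(tab$observed, labels)
  E <- setNames(tab$expected, labels)
  df <- as.integer(k - 1)
  if (tab$totalEvents == 0)
    return(new("LogRankResult", statistic = 0, df = df, pValue = 1,
               observed = O, expected = E, degenerate = TRUE))
  idx <- seq_len(k - 1)
  vsub <- tab$variance[idx, idx, drop = FALSE]
  oe <- (tab$observed - tab$expected)[idx]
  if (max(abs(vsub)) < 1e-300)
    return(new("LogRankResult", statistic = 0, df = df, pValue = 1,
               observed = O, expected = E, degenerate = TRUE))
  inv <- tryCatch(solve(vsub), error = function(e) .pinv(vsub))
  stat <- max(0, drop(t(oe) %*% inv %*% oe))
  new("LogRankResult", statistic = stat, df = df,
      pValue = pchisq(stat, df = df, lower.tail = FALSE),
      observed = O, expected = E, degenerate = FALSE)
}

#' Observed/expected hazard ratio between two groups
#'
#' Estimates the relative event rate of group A versus group B from the
#' log-rank O/E table: `HR = (O_a / E_a) / (O_b / E_b)`. The estimate is
#' flagged undefined when any of the four terms is zero (e.g. a group with
#' no observed events); no proportional-hazards model is fitted.
#'
#' @param groupA,groupB Lists with elements `times` and `statuses`.
#' @param labels Length-2 character vector of group labels.
#' @return An [HRResult-class].
#' @examples
#' a <- list(times = c(1, 2), statuses = c(1, 1))
#' b <- list(times = c(3, 4), statuses = c(1, 1))
#' hazardRatio(a, b)  # (2 / (5/6)) / (2 / (19/6)) = 3.8
#' @export
hazardRatio <- function(groupA, groupB, labels = c("A", "B")) {
  labels <- as.character(labels)
  ga <- .checkGroup(groupA, labels[1])
  gb <- .checkGroup(groupB, labels[2])
  tab <- .logrankTable(list(ga, gb))
  oA <- tab$observed[1]; eA <- tab$expected[1]
  oB <- tab$observed[2]; eB <- tab$expected[2]
  defined <- oA > 0 && eA > 0 && oB > 0 && eB > 0
  new("HRResult",
      hazardRatio = if (defined) (oA / eA) / (oB / eB) else NA_real_,
      defined = defined, groupA = labels[1], groupB = labels[2],
      oA = oA, eA = eA, oB = oB, eB = eB)
}
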