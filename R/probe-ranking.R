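## Whole-matrix screen: per-probe grouping, overall and pairwise log-rank
## tests, O/E hazard ratios, and ranking by the minimum pairwise p-value.

.EMPTY_PAIRWISE <- data.frame(
  groupA = character(0), groupB = character(0), statistic = numeric(0),
  df = integer(0), pValue = numeric(0), hazardRatio = numeric(0),
  hrDefined = logical(0), oA = numeric(0), eA = numeric(0), oB = numeric(0),
  eB = numeric(0), degenerate = logical(0))

# analysis core shared by analyzeProbe() and rankProbes(); operates on a
# pre-canonicalized call row so the screen normalizes the matrix only once
.analyzeProbeCore <- function(probeId, endpoint, canon, ids, time, status,
                              minGroupSize) {
  usable <- .usableMask(canon, time, status)
  groups <- .orderedGenotypeSplit(canon, usable, ids)
  idx <- lapply(groups, match, ids)
  sizes <- lengths(groups)
  events <- vapply(idx, function(j) sum(status[j] == 1), numeric(1))
  medians <- vapply(idx, function(j)
    medianSurvival(kmEstimate(time[j], status[j])), numeric(1))
  comparable <- sizes >= minGroupSize
  groupsDf <- data.frame(
    genotype = names(groups) %||% character(0),
    size = as.integer(sizes), events = as.integer(events),
    median = as.numeric(medians), comparable = as.logical(comparable),
    row.names = NULL)

  skippedResult <- function(reason)
    new("ProbeResult", probeId = probeId, endpoint = endpoint,
        groups = groupsDf, overall = NULL, pairwise = .EMPTY_PAIRWISE,
        rankP = NA_real_, skipped = TRUE, skipReason = reason)

  comp <- names(groups)[comparable]
  if (length(comp) < 2)
    return(skippedResult(if (length(groups) < 2) "fewer than 2 genotype groups"
                         else "fewer than 2 comparable genotype groups"))

  gdata <- lapply(idx[comp], function(j)
    list(times = time[j], statuses = status[j]))
  overall <- logrankTest(gdata)

  pairs <- utils::combn(comp, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    lr <- logrankTest(gdata[pr])
    hr <- hazardRatio(gdata[[pr[1]]], gdata[[pr[2]]], labels = pr)
    data.frame(groupA = pr[1], groupB = pr[2], statistic = lr@statistic,
               df = lr@df, pValue = lr@pValue,
               hazardRatio = hr@hazardRatio, hrDefined = hr@defined,
               oA = hr@oA, eA = hr@eA, oB = hr@oB, eB = hr@eB,
               degenerate = lr@degenerate)
  })
  pairwise <- do.call(rbind, rows)
  informative <- !pairwise$degenerate
  if (!any(informative)) {
    res <- skippedResult("no informative pairwise comparison")
    res@pairwise <- pairwise
    res@overall <- overall
    return(res)
  }
  new("ProbeResult", probeId = probeId, endpoint = endpoint,
      groups = groupsDf, overall = overall, pairwise = pairwise,
      rankP = min(pairwise$pValue[informative]), skipped = FALSE,
      skipReason = NA_character_)
}

#' Analyze one probe
#'
#' Groups the probe's samples by genotype, estimates per-group Kaplan-Meier
#' curves and medians, and, when at least two groups reach `minGroupSize`,
#' computes the k-group overall log-rank test plus all `choose(k, 2)`
#' pairwise log-rank tests and O/E hazard ratios. Groups below
#' `minGroupSize` are reported but excluded from testing. The probe's
#' ranking key (`rankP`) is the minimum pairwise p-value over
#' non-degenerate comparisons.
#'
#' @param dataset An [OSDataset-class].
#' @param probeId Probe identifier.
#' @param endpoint `"OS"` or `"PFS"`.
#' @param minGroupSize Minimum group size for a group to enter testing
#'   (default 2: a single-sample group makes the variance term degenerate).
#' @param specialSymbols See [dmetSpecialSymbols()].
#' @return A [ProbeResult-class]; carries the skipped marker when fewer
#'   than two comparable groups exist.
#' @export
analyzeProbe <- function(dataset, probeId, endpoint = c("OS", "PFS"),
                         minGroupSize = 2,
                         specialSymbols = dmetSpecialSymbols()) {
  endpoint <- .matchEndpoint(endpoint)
  if (minGroupSize < 1) stop("minGroupSize must be >= 1")
  i <- match(probeId, probeIds(dataset))
  if (is.na(i)) stop("unknown probe: ", probeId)
  canon <- .canonicalizeCalls(genotypeCalls(dataset)[i, ], specialSymbols)
  ep <- .endpointData(dataset, endpoint)
  .analyzeProbeCore(probeId, endpoint, canon, sampleIds(dataset),
                    ep$time, ep$status, minGroupSize)
}

#' Screen and rank all probes
#'
#' Runs [analyzeProbe()] over every probe of the matrix for one endpoint and
#' returns the results ranked by ascending minimum pairwise log-rank p-value
#' (ties broken by probe identifier). Probes with fewer than two comparable
#' genotype groups are listed separately and never ranked. Output is
#' deterministic for a fixed input.
#'
#' @inheritParams analyzeProbe
#' @return A [RankedReport-class].
#' @examples
#' sim <- simulateCohort(cohortConfig(nSamples = 40, nProbes = 8, seed = 7))
#' rankProbes(sim$dataset, "OS")
#' @export
rankProbes <- function(dataset, endpoint = c("OS", "PFS"), minGroupSize = 2,
                       specialSymbols = dmetSpecialSymbols()) {
  stopifnot(is(dataset, "OSDataset"))
  endpoint <- .matchEndpoint(endpoint)
  if (minGroupSize < 1) stop("minGroupSize must be >= 1")
  calls <- genotypeCalls(dataset)
  canonAll <- .canonicalizeCalls(calls, specialSymbols)
  dim(canonAll) <- dim(calls)
  ep <- .endpointData(dataset, endpoint)
  ids <- sampleIds(dataset)
  results <- lapply(seq_len(nrow(dataset)), function(i)
    .analyzeProbeCore(rownames(calls)[i], endpoint, canonAll[i, ], ids,
                      ep$time, ep$status, minGroupSize))
  skipped <- vapply(results, slot, logical(1), "skipped")
  ranked <- results[!skipped]
  if (length(ranked)) {
    p <- vapply(ranked, slot, numeric(1), "rankP")
    id <- vapply(ranked, slot, character(1), "probeId")
    ranked <- ranked[order(p, id)]
  }
  new("RankedReport", endpoint = endpoint, results = ranked,
      skippedResults = results[skipped], adjustMethod = "none",
      adjustedP = numeric(0), minGroupSize = as.integer(minGroupSize),
      runId = as.character(metadata(dataset)$runId %||% NA_character_))
}

#' Multiplicity adjustment of ranking p-values
#'
#' Adds multiplicity-adjusted ranking p-values to a report without changing
#' the ordering. The default workflow ranks raw p-values (`method =
#' "none"`, the identity); Benjamini-Hochberg and Bonferroni are available
#' as explicit extensions over the ranked (non-skipped) probes.
#'
#' @param report A [RankedReport-class].
#' @param method `"none"`, `"benjamini-hochberg"`, or `"bonferroni"`.
#' @return The report, with `adjustedP` filled in unless `method = "none"`.
#' @export
adjustPvalues <- function(report,
                          method = c("none", "benjamini-hochberg",
                                     "bonferroni")) {
  stopifnot(is(report, "RankedReport"))
  method <- match.arg(method)
  if (method == "none") return(report)
  p <- vapply(report@results, slot, numeric(1), "rankP")
  report@adjustedP <- p.adjust(
    p, method = if (method == "benjamini-hochberg") "BH" else "bonferroni")
  report@adjustMethod <- method
  report
}

#' @rdname reportTable
#' @export
setMethod("reportTable", "RankedReport", function(report) {
  hasAdj <- length(report@adjustedP) > 0
  rows <- lapply(seq_along(report@results), function(rk) {
    pr <- report@results[[rk]]
    pw <- pr@pairwise
    g <- pr@groups
    gi <- match(pw$groupA, g$genotype)
    gj <- match(pw$groupB, g$genotype)
    data.table::data.table(
      probe_id = pr@probeId, endpoint = pr@endpoint, rank = rk,
      rank_p = pr@rankP,
      adjusted_p = if (hasAdj) report@adjustedP[rk] else NA_real_,
      overall_statistic = pr@overall@statistic, overall_df = pr@overall@df,
      overall_p = pr@overall@pValue,
      group_a = pw$groupA, size_a = g$size[gi], events_a = g$events[gi],
      median_a = g$median[gi],
      group_b = pw$groupB, size_b = g$size[gj], events_b = g$events[gj],
      median_b = g$median[gj],
      statistic = pw$statistic, p_value = pw$pValue,
      hazard_ratio = pw$hazardRatio, degenerate = pw$degenerate)
  })
  header <- data.table::data.table(
    probe_id = character(0), endpoint = character(0), rank = integer(0),
    rank_p = numeric(0), adjusted_p = numeric(0),
    overall_statistic = numeric(0), overall_df = integer(0),
    overall_p = numeric(0), group_a = character(0), size_a = integer(0),
    events_a = integer(0), median_a = numeric(0), group_b = character(0),
    size_b = integer(0), events_b = integer(0), median_b = numeric(0),
    statistic = numeric(0), p_value = numeric(0), hazard_ratio = numeric(0),
    degenerate = logical(0))
  out <- as.data.frame(data.table::rbindlist(c(list(header), rows)))
  if (!hasAdj) out$adjusted_p <- NULL
  out
})
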