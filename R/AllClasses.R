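#' OSDataset: a genotype matrix joined to per-sample clinical outcomes
#'
#' An `OSDataset` holds a probe-by-sample matrix of raw genotype-call strings
#' (assay `"calls"`) together with one clinical record per sample (columns of
#' `colData`): `os_time` and `pfs_time` in months, `os_status` and
#' `pfs_status` (1 = event observed, 0 = censored), and an optional binary
#' `response` annotation (1 = metastasis present). The class extends
#' [SummarizedExperiment::SummarizedExperiment] so that each sample's single
#' clinical record is linked to all of its genotype calls without
#' duplication: subsetting, column reordering, and clinical edits propagate
#' to every probe.
#'
#' Structural requirements (enforced by the validity method): unique probe
#' and sample identifiers, a character `calls` assay, and numeric clinical
#' columns. Domain-level problems (a status of 2, a negative time) are
#' deliberately representable so that [validateOSDataset()] can report them;
#' analysis functions treat such entries as missing for the affected
#' endpoint.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [readOSDataset()], [validateOSDataset()], [rankProbes()]
#' @export
setClass("OSDataset", contains = "SummarizedExperiment")

.CLINICAL_COLS <- c("os_time", "os_status", "pfs_time", "pfs_status", "response")

setValidity("OSDataset", function(object) {
  msg <- character(0)
  if (!"calls" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'calls' is required")
  else if (!is.character(assay(object, "calls")))
    msg <- c(msg, "assay 'calls' must be a character matrix")
  if (nrow(object) > 0 &&
      (is.null(rownames(object)) || anyDuplicated(rownames(object))))
    msg <- c(msg, "probe identifiers (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample identifiers (colnames) must be present and unique")
  cd <- colData(object)
  missing <- setdiff(.CLINICAL_COLS, colnames(cd))
  if (length(missing))
    msg <- c(msg, paste0("missing clinical column(s): ",
                         paste(missing, collapse = ", ")))
  for (col in intersect(.CLINICAL_COLS, colnames(cd)))
    if (!is.numeric(cd[[col]]))
      msg <- c(msg, paste0("clinical column '", col, "' must be numeric"))
  if (length(msg)) msg else TRUE
})

#' Construct an OSDataset
#'
#' @param calls Character matrix of raw genotype-call strings; rownames are
#'   probe identifiers, colnames are sample identifiers.
#' @param clinical `data.frame` with one row per sample (rownames or order
#'   matching `colnames(calls)`) and columns `os_time`, `os_status`,
#'   `pfs_time`, `pfs_status`, and optionally `response`. Times are in
#'   months; statuses use 1 = event observed, 0 = censored.
#' @param metadata Optional named list stored in the object's metadata.
#' @return An [OSDataset-class] object.
#' @examples
#' calls <- matrix(c("G/A", "A/G", "A/G", "A/A"), nrow = 1,
#'                 dimnames = list("P1", paste0("S", 1:4)))
#' clin <- data.frame(os_time = c(26.6, 15.7, 32.2, 2.3),
#'                    os_status = c(1, 1, 0, 1),
#'                    pfs_time = c(16.6, 4.7, 3.8, 27.3),
#'                    pfs_status = c(1, 0, 0, 1),
#'                    response = c(1, 0, 0, 0))
#' ds <- OSDataset(calls, clin)
#' @export
OSDataset <- function(calls, clinical, metadata = list()) {
  if (!is.matrix(calls) || !is.character(calls))
    stop("'calls' must be a character matrix")
  if ((nrow(calls) > 0 && is.null(rownames(calls))) || is.null(colnames(calls)))
    stop("'calls' must have probe rownames and sample colnames")
  clinical <- as.data.frame(clinical)
  if (nrow(clinical) != ncol(calls))
    stop("'clinical' must have one row per sample column of 'calls'")
  if (!is.null(rownames(clinical)) &&
      !identical(rownames(clinical), as.character(seq_len(nrow(clinical))))) {
    if (!setequal(rownames(clinical), colnames(calls)))
      stop("rownames(clinical) must match colnames(calls)")
    clinical <- clinical[colnames(calls), , drop = FALSE]
  }
  if (!"response" %in% colnames(clinical))
    clinical$response <- NA_real_
  for (col in .CLINICAL_COLS) {
    if (!col %in% colnames(clinical))
      stop("clinical is missing required column '", col, "'")
    clinical[[col]] <- as.numeric(clinical[[col]])
  }
  rownames(clinical) <- colnames(calls)
  se <- SummarizedExperiment(assays = list(calls = calls),
                             colData = DataFrame(clinical),
                             metadata = metadata)
  new("OSDataset", se)
}

#' @describeIn OSDataset Compact display of dimensions and clinical summary.
#' @param object An `OSDataset`.
#' @export
setMethod("show", "OSDataset", function(object) {
  cat("OSDataset:", nrow(object), "probes x", ncol(object), "samples\n")
  cd <- colData(object)
  cat(sprintf("  OS : %d events / %d censored / %d incomplete\n",
              sum(cd$os_status == 1, na.rm = TRUE),
              sum(cd$os_status == 0, na.rm = TRUE),
              sum(is.na(cd$os_time) | is.na(cd$os_status))))
  cat(sprintf("  PFS: %d events / %d censored / %d incomplete\n",
              sum(cd$pfs_status == 1, na.rm = TRUE),
              sum(cd$pfs_status == 0, na.rm = TRUE),
              sum(is.na(cd$pfs_time) | is.na(cd$pfs_status))))
  invisible(NULL)
})

#' Kaplan-Meier product-limit curve
#'
#' Step-function estimate of the survivor function S(t). At each distinct
#' event time `t_i` the curve records the number at risk `r_i`, the number of
#' events `d_i`, and `S(t_i) = prod_{j <= i} (1 - d_j / r_j)`. Subjects
#' censored at an event time remain at risk at that time (events precede
#' censorings at ties); the curve is flat after the last observation.
#'
#' @slot eventTimes Strictly increasing distinct event times (months).
#' @slot nAtRisk Number at risk at each event time.
#' @slot nEvents Number of events at each event time.
#' @slot survival Estimated S(t_i) at each event time.
#' @slot censorTimes Sorted censoring times (one entry per censored subject).
#' @slot nTotal Number of subjects the curve is based on.
#' @seealso [kmEstimate()], [medianSurvival()], [survivalAt()]
#' @export
setClass("KMCurve", representation(
  eventTimes = "numeric", nAtRisk = "numeric", nEvents = "numeric",
  survival = "numeric", censorTimes = "numeric", nTotal = "integer"))

setValidity("KMCurve", function(object) {
  msg <- character(0)
  k <- length(object@eventTimes)
  if (length(object@nAtRisk) != k || length(object@nEvents) != k ||
      length(object@survival) != k)
    msg <- c(msg, "eventTimes, nAtRisk, nEvents, survival must share length")
  if (k > 1 && any(diff(object@eventTimes) <= 0))
    msg <- c(msg, "eventTimes must be strictly increasing")
  if (k > 0) {
    if (any(object@nEvents < 1)) msg <- c(msg, "all nEvents must be >= 1")
    if (any(object@nAtRisk < object@nEvents))
      msg <- c(msg, "nAtRisk must be >= nEvents")
    if (any(diff(c(1, object@survival)) > 1e-12))
      msg <- c(msg, "survival must be non-increasing from 1")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn KMCurve Print the per-event-time life table.
#' @param object A `KMCurve`.
#' @export
setMethod("show", "KMCurve", function(object) {
  cat(sprintf("KMCurve: %d subjects, %d events, %d censored\n",
              object@nTotal, as.integer(sum(object@nEvents)),
              length(object@censorTimes)))
  if (length(object@eventTimes)) {
    df <- data.frame(time = object@eventTimes, n.risk = object@nAtRisk,
                     n.event = object@nEvents,
                     survival = round(object@survival, 4))
    print(df, row.names = FALSE)
  } else cat("  (no events)\n")
  invisible(NULL)
})

#' Mantel-Cox log-rank test result
#'
#' @slot statistic Chi-square-scale test statistic (>= 0).
#' @slot df Degrees of freedom (number of groups - 1).
#' @slot pValue Upper-tail chi-square probability.
#' @slot observed Observed event count per group (named).
#' @slot expected Expected event count per group under the null (named).
#' @slot degenerate `TRUE` when the comparison was uninformative (no events,
#'   or zero variance); then `statistic = 0` and `pValue = 1`.
#' @seealso [logrankTest()]
#' @export
setClass("LogRankResult", representation(
  statistic = "numeric", df = "integer", pValue = "numeric",
  observed = "numeric", expected = "numeric", degenerate = "logical"))

#' @describeIn LogRankResult Print statistic, df, p, and the O/E table.
#' @param object A `LogRankResult`.
#' @export
setMethod("show", "LogRankResult", function(object) {
  cat(sprintf("Log-rank (Mantel-Cox): chisq = %.4g on %d df, p = %.4g%s\n",
              object@statistic, object@df, object@pValue,
              if (object@degenerate) " [degenerate]" else ""))
  print(data.frame(group = names(object@observed),
                   observed = object@observed, expected = object@expected),
        row.names = FALSE)
  invisible(NULL)
})

#' Observed/expected hazard-ratio result
#'
#' The hazard ratio of group A versus group B estimated from the log-rank
#' O/E table: `HR = (O_a / E_a) / (O_b / E_b)`. The estimate is undefined
#' (slot `defined = FALSE`, `hazardRatio = NA`) when any of the four terms is
#' zero, e.g. when one group has no events.
#'
#' @slot hazardRatio The estimate, or `NA` when undefined.
#' @slot defined Whether the estimate is defined.
#' @slot groupA,groupB Group labels (genotypes in the screening context).
#' @slot oA,eA,oB,eB Observed and expected event counts per group.
#' @seealso [hazardRatio()]
#' @export
setClass("HRResult", representation(
  hazardRatio = "numeric", defined = "logical",
  groupA = "character", groupB = "character",
  oA = "numeric", eA = "numeric", oB = "numeric", eB = "numeric"))

#' @describeIn HRResult Print the estimate and its O/E components.
#' @param object An `HRResult`.
#' @export
setMethod("show", "HRResult", function(object) {
  if (object@defined)
    cat(sprintf("HR(%s vs %s) = %.4g  [O/E: %g/%.3g vs %g/%.3g]\n",
                object@groupA, object@groupB, object@hazardRatio,
                object@oA, object@eA, object@oB, object@eB))
  else
    cat(sprintf("HR(%s vs %s) undefined (zero observed or expected events)\n",
                object@groupA, object@groupB))
  invisible(NULL)
})

#' Genotype grouping of one probe's samples
#'
#' The product of the per-probe projection: sample identifiers split by
#' canonical genotype, after removal of non-analyzable calls (special symbols
#' such as `NoCall`) and of samples lacking usable time/status for the chosen
#' endpoint. Groups are ordered by descending size, ties broken by genotype.
#' Only sample identifiers are stored; survival data are pulled from the
#' dataset's single clinical record per sample on demand (see
#' [survivalData()]), so a clinical edit is visible in every group containing
#' that sample.
#'
#' @slot probeId Probe identifier.
#' @slot endpoint `"OS"` or `"PFS"`.
#' @slot genotypes Canonical genotypes, in group order.
#' @slot sampleIds Named list (by genotype) of sample-identifier vectors.
#' @slot excluded Sample identifiers excluded at this probe.
#' @slot nSamples Total number of samples in the dataset.
#' @seealso [groupProbe()]
#' @export
setClass("GenotypeGrouping", representation(
  probeId = "character", endpoint = "character", genotypes = "character",
  sampleIds = "list", excluded = "character", nSamples = "integer"))

setValidity("GenotypeGrouping", function(object) {
  msg <- character(0)
  if (!identical(names(object@sampleIds), object@genotypes))
    msg <- c(msg, "sampleIds must be named by genotypes, in order")
  all_ids <- unlist(object@sampleIds, use.names = FALSE)
  if (anyDuplicated(all_ids))
    msg <- c(msg, "a sample may appear in at most one group")
  if (length(all_ids) + length(object@excluded) != object@nSamples)
    msg <- c(msg, "group sizes plus exclusions must account for every sample")
  if (length(msg)) msg else TRUE
})

#' @describeIn GenotypeGrouping Print group sizes and exclusions.
#' @param object A `GenotypeGrouping`.
#' @export
setMethod("show", "GenotypeGrouping", function(object) {
  cat(sprintf("GenotypeGrouping: probe %s, endpoint %s\n",
              object@probeId, object@endpoint))
  sizes <- lengths(object@sampleIds)
  for (g in object@genotypes)
    cat(sprintf("  %-8s n = %d\n", g, sizes[[g]]))
  cat(sprintf("  excluded: %d of %d samples\n",
              length(object@excluded), object@nSamples))
  invisible(NULL)
})

#' Per-probe screening result
#'
#' @slot probeId Probe identifier.
#' @slot endpoint `"OS"` or `"PFS"`.
#' @slot groups `data.frame` with one row per genotype group: `genotype`,
#'   `size`, `events`, `median` (months, `NA` = not reached), `comparable`
#'   (size >= the minimum group size used for testing).
#' @slot overall [LogRankResult-class] over all comparable groups, or `NULL`
#'   when the probe was skipped.
#' @slot pairwise `data.frame` with one row per pair of comparable groups:
#'   labels, log-rank statistic and p-value, O/E hazard ratio and its
#'   components, and a `degenerate` flag.
#' @slot rankP Ranking key: minimum non-degenerate pairwise p-value (`NA`
#'   when skipped).
#' @slot skipped Whether the probe had fewer than two comparable groups (or
#'   no informative comparison).
#' @slot skipReason Human-readable reason when skipped.
#' @seealso [analyzeProbe()], [rankProbes()]
#' @export
setClass("ProbeResult", representation(
  probeId = "character", endpoint = "character", groups = "data.frame",
  overall = "ANY", pairwise = "data.frame", rankP = "numeric",
  skipped = "logical", skipReason = "character"))

#' @describeIn ProbeResult Print groups and pairwise comparisons.
#' @param object A `ProbeResult`.
#' @export
setMethod("show", "ProbeResult", function(object) {
  cat(sprintf("ProbeResult: %s (%s)%s\n", object@probeId, object@endpoint,
              if (object@skipped) paste0(" [skipped: ", object@skipReason, "]")
              else sprintf("  rank p = %.4g", object@rankP)))
  print(object@groups, row.names = FALSE)
  if (nrow(object@pairwise)) {
    cat("pairwise:\n")
    print(object@pairwise[, c("groupA", "groupB", "statistic", "pValue",
                              "hazardRatio")], row.names = FALSE)
  }
  invisible(NULL)
})

#' Ranked whole-matrix screening report
#'
#' All probes' results for one endpoint, sorted by ascending ranking p-value
#' (ties broken by probe identifier); probes with fewer than two comparable
#' genotype groups are listed separately and never ranked.
#'
#' @slot endpoint `"OS"` or `"PFS"`.
#' @slot results List of ranked [ProbeResult-class] objects.
#' @slot skippedResults List of skipped [ProbeResult-class] objects.
#' @slot adjustMethod Multiplicity adjustment applied (`"none"` by default).
#' @slot adjustedP Adjusted ranking p-values aligned with `results`
#'   (length 0 when `adjustMethod == "none"`).
#' @slot minGroupSize Minimum group size used for comparability.
#' @slot runId Identifier linking a report to the simulation run that
#'   produced its input (`NA` for file-loaded data).
#' @seealso [rankProbes()], [adjustPvalues()], [reportTable()], [exportReport()]
#' @export
setClass("RankedReport", representation(
  endpoint = "character", results = "list", skippedResults = "list",
  adjustMethod = "character", adjustedP = "numeric",
  minGroupSize = "integer", runId = "character"))

#' @describeIn RankedReport Print the top of the ranking.
#' @param object A `RankedReport`.
#' @export
setMethod("show", "RankedReport", function(object) {
  cat(sprintf("RankedReport (%s): %d ranked, %d skipped probes\n",
              object@endpoint, length(object@results),
              length(object@skippedResults)))
  n <- min(5L, length(object@results))
  if (n > 0) {
    top <- data.frame(
      probe_id = vapply(object@results[seq_len(n)], slot, "", "probeId"),
      rank_p = vapply(object@results[seq_len(n)], slot, 0, "rankP"))
    cat("top probes:\n")
    print(top, row.names = FALSE)
  }
  invisible(NULL)
})

#' Validation report for an OSDataset
#'
#' @slot errors `data.frame` (`locator`, `message`): invariant violations.
#' @slot warnings `data.frame` (`locator`, `message`): non-fatal issues.
#' @slot nProbes,nSamples,nCells Structural counts; `nCells = nProbes *
#'   nSamples`.
#' @seealso [validateOSDataset()]
#' @export
setClass("ValidationReport", representation(
  errors = "data.frame", warnings = "data.frame",
  nProbes = "integer", nSamples = "integer", nCells = "integer"))

#' @describeIn ValidationReport Print counts and any findings.
#' @param object A `ValidationReport`.
#' @export
setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport: %d probes x %d samples (%d genotype cells)\n",
              object@nProbes, object@nSamples, object@nCells))
  cat(sprintf("  %d error(s), %d warning(s)\n",
              nrow(object@errors), nrow(object@warnings)))
  if (nrow(object@errors)) print(object@errors, row.names = FALSE)
  if (nrow(object@warnings)) print(object@warnings, row.names = FALSE)
  invisible(NULL)
})

#' Step-curve plotting specification for one probe
#'
#' Exact step coordinates for the per-genotype Kaplan-Meier curves of one
#' probe: horizontal segments between event times, vertical drops only at
#' event times, and censor tick marks placed exactly on the current step
#' height. Rendered by [plotProbeKM()].
#'
#' @slot probeId Probe identifier.
#' @slot endpoint `"OS"` or `"PFS"`.
#' @slot groups Named list (by genotype); each element holds `x`, `y` step
#'   coordinates, `censorX`, `censorY` tick positions, and `n`.
#' @seealso [curvePlotSpec()]
#' @export
setClass("CurvePlotSpec", representation(
  probeId = "character", endpoint = "character", groups = "list"))

#' @describeIn CurvePlotSpec Print a one-line summary per curve.
#' @param object A `CurvePlotSpec`.
#' @export
setMethod("show", "CurvePlotSpec", function(object) {
  cat(sprintf("CurvePlotSpec: probe %s (%s), %d curve(s)\n",
              object@probeId, object@endpoint, length(object@groups)))
  for (g in names(object@groups))
    cat(sprintf("  %-8s n = %d, %d censor tick(s)\n", g,
                object@groups[[g]]$n, length(object@groups[[g]]$censorX)))
  invisible(NULL)
})
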