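#' Accessors for OSDataset components
#'
#' `genotypeCalls()` returns the raw probe-by-sample character matrix of
#' genotype calls; `clinicalData()` the per-sample clinical records as a
#' `data.frame`; `probeIds()` and `sampleIds()` the row/column identifiers.
#'
#' @param x An [OSDataset-class].
#' @return See individual descriptions.
#' @examples
#' sim <- simulateCohort(cohortConfig(nSamples = 10, nProbes = 5, seed = 1))
#' dim(genotypeCalls(sim$dataset))
#' head(clinicalData(sim$dataset))
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' @rdname genotypeCalls
#' @export
setGeneric("clinicalData", function(x) standardGeneric("clinicalData"))

#' @rdname genotypeCalls
#' @export
setGeneric("probeIds", function(x) standardGeneric("probeIds"))

#' @rdname genotypeCalls
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname genotypeCalls
#' @export
setMethod("genotypeCalls", "OSDataset", function(x) assay(x, "calls"))

#' @rdname genotypeCalls
#' @export
setMethod("clinicalData", "OSDataset",
          function(x) as.data.frame(colData(x)))

#' @rdname genotypeCalls
#' @export
setMethod("probeIds", "OSDataset", function(x) rownames(x))

#' @rdname genotypeCalls
#' @export
setMethod("sampleIds", "OSDataset", function(x) colnames(x))

#' Median survival time of a Kaplan-Meier curve
#'
#' The smallest event time `t` with `S(t) <= 0.5` (the boundary `S(t) = 0.5`
#' counts), or `NA` when the curve never drops to 0.5 ("not reached").
#'
#' @param curve A [KMCurve-class].
#' @return Median survival in months, or `NA_real_` when not reached.
#' @examples
#' km <- kmEstimate(c(26.6, 15.7, 32.2, 2.3), c(1, 1, 0, 1))
#' medianSurvival(km)  # 15.7
#' @export
setGeneric("medianSurvival", function(curve) standardGeneric("medianSurvival"))

#' Tabulate a ranked report
#'
#' Flattens a [RankedReport-class] into a `data.frame` with one row per
#' pairwise genotype comparison of each ranked probe, carrying per-group
#' sizes, event counts and medians, the pairwise log-rank statistic and
#' p-value, the O/E hazard ratio, the probe's overall (k-group) test, its
#' ranking p-value and rank, and adjusted p-values when present.
#'
#' @param report A [RankedReport-class].
#' @return A `data.frame`; zero rows (with full header) for an empty report.
#' @seealso [exportReport()]
#' @export
setGeneric("reportTable", function(report) standardGeneric("reportTable"))
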