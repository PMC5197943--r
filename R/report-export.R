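#' Export a ranked report to file
#'
#' Writes the flattened report (see [reportTable()]) losslessly and
#' deterministically: the same report always produces byte-identical files.
#' Not-reached medians are written as `"NR"`. The JSON export additionally
#' carries the endpoint, the adjustment method, and the skipped probes, and
#' re-imports with the ranking order and values intact.
#'
#' @param report A [RankedReport-class].
#' @param path Output path.
#' @param format `"tsv"` (default), `"csv"`, or `"json"`.
#' @return `path`, invisibly.
#' @examples
#' sim <- simulateCohort(cohortConfig(nSamples = 30, nProbes = 5, seed = 2))
#' rep <- rankProbes(sim$dataset, "OS")
#' out <- exportReport(rep, tempfile(fileext = ".tsv"))
#' @export
exportReport <- function(report, path, format = c("tsv", "csv", "json")) {
  stopifnot(is(report, "RankedReport"))
  format <- match.arg(format)
  tab <- reportTable(report)
  # medians print as NR when the curve never reaches 0.5
  for (col in c("median_a", "median_b")) {
    v <- tab[[col]]
    tab[[col]] <- ifelse(is.na(v), "NR", as.character(v))
  }
  if (format == "json") {
    payload <- list(
      endpoint = report@endpoint,
      min_group_size = report@minGroupSize,
      adjust_method = report@adjustMethod,
      n_ranked = length(report@results),
      n_skipped = length(report@skippedResults),
      skipped_probes = vapply(report@skippedResults, slot, "", "probeId"),
      results = tab)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", dataframe = "rows")
  } else {
    data.table::fwrite(data.table::as.data.table(tab), path,
                       sep = if (format == "tsv") "\t" else ",",
                       quote = if (format == "tsv") FALSE else "auto",
                       na = "NA")
  }
  invisible(path)
}

#' Step-curve coordinates for one probe
#'
#' Builds the exact plotting geometry of the per-genotype Kaplan-Meier
#' curves: each curve starts at (0, 1), runs horizontally between event
#' times, and drops vertically only at event times — never at
#' pure-censoring times. Censored subjects appear as tick marks placed
#' exactly on the current step height, `S(t)` at the censoring time.
#'
#' @param dataset An [OSDataset-class].
#' @param probeId Probe identifier.
#' @param endpoint `"OS"` or `"PFS"`.
#' @param minGroupSize Smallest genotype group to include as a curve
#'   (default 1: plotting has no variance requirement).
#' @param specialSymbols See [dmetSpecialSymbols()].
#' @return A [CurvePlotSpec-class].
#' @seealso [plotProbeKM()]
#' @export
curvePlotSpec <- function(dataset, probeId, endpoint = c("OS", "PFS"),
                          minGroupSize = 1,
                          specialSymbols = dmetSpecialSymbols()) {
  endpoint <- .matchEndpoint(endpoint)
  grouping <- groupProbe(dataset, probeId, endpoint, specialSymbols)
  sdata <- survivalData(dataset, grouping)
  sdata <- sdata[vapply(sdata, function(g) length(g$times), 0L) >=
                   minGroupSize]
  groups <- lapply(sdata, function(g) {
    km <- kmEstimate(g$times, g$statuses)
    te <- km@eventTimes
    heights <- c(1, km@survival)
    tmax <- max(g$times)
    x <- c(0, rep(te, each = 2))
    y <- rep(heights, each = 2)[seq_along(x)]
    if (tmax > (if (length(te)) te[length(te)] else 0)) {
      x <- c(x, tmax)
      y <- c(y, heights[length(heights)])
    }
    list(x = x, y = y,
         censorX = km@censorTimes,
         censorY = survivalAt(km, km@censorTimes),
         n = km@nTotal)
  })
  new("CurvePlotSpec", probeId = probeId, endpoint = endpoint,
      groups = groups)
}

#' Plot per-genotype survival curves for one probe
#'
#' Renders a [curvePlotSpec()] with base graphics: one step curve per
#' genotype group, censor tick marks on the curves, and a genotype legend.
#' When `file` is given, the plot is written to a device chosen by
#' extension (`.pdf` or `.png`).
#'
#' @inheritParams curvePlotSpec
#' @param file Optional output file; `NULL` draws on the current device.
#' @param col Colors, one per group (defaults to a built-in palette).
#' @param main Plot title (defaults to "probe (endpoint)").
#' @return The [CurvePlotSpec-class], invisibly.
#' @export
plotProbeKM <- function(dataset, probeId, endpoint = c("OS", "PFS"),
                        file = NULL, minGroupSize = 1, col = NULL,
                        main = NULL,
                        specialSymbols = dmetSpecialSymbols()) {
  spec <- curvePlotSpec(dataset, probeId, endpoint, minGroupSize,
                        specialSymbols)
  if (!length(spec@groups))
    stop("probe ", probeId, " has no plottable genotype group")
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    if (ext == "png") grDevices::png(file, width = 800, height = 600)
    else grDevices::pdf(file, width = 8, height = 6)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  if (is.null(col))
    col <- rep_len(c("#1b9e77", "#d95f02", "#7570b3", "#e7298a", "#66a61e"),
                   length(spec@groups))
  xmax <- max(vapply(spec@groups, function(g) max(g$x), 0))
  graphics::plot(NA, xlim = c(0, max(xmax, 1e-9)), ylim = c(0, 1),
                 xlab = sprintf("%s time (months)", spec@endpoint),
                 ylab = "Survival probability",
                 main = main %||% sprintf("%s (%s)", spec@probeId,
                                          spec@endpoint))
  for (i in seq_along(spec@groups)) {
    g <- spec@groups[[i]]
    graphics::lines(g$x, g$y, col = col[i], lwd = 2)
    if (length(g$censorX))
      graphics::points(g$censorX, g$censorY, pch = 3, col = col[i])
  }
  graphics::legend("bottomleft",
                   legend = sprintf("%s (n = %d)", names(spec@groups),
                                    vapply(spec@groups, `[[`, 0L, "n")),
                   col = col[seq_along(spec@groups)], lwd = 2, bty = "n")
  invisible(spec)
}
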