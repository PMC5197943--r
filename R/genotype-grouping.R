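#' Special genotype symbols excluded from analysis
#'
#' Default set of non-genotype call symbols emitted by DMET-style genotyping
#' pipelines. Cells carrying one of these (matched case-insensitively after
#' trimming), or an empty value, are not analyzable and are removed from the
#' affected probe's groups. The vocabulary is open-ended, so every function
#' that consumes it accepts a custom vector.
#'
#' @return Character vector of special symbols.
#' @export
dmetSpecialSymbols <- function() {
  c("NoCall", "ZeroCopyNumber", "RareAllele", "PossibleRareAllele")
}

# canonicalize a character vector of raw calls: canonical "X/Y" with alleles
# sorted by .ALLELE_ORDER, or NA for special/unparseable cells
.canonicalizeCalls <- function(raw, specialSymbols = dmetSpecialSymbols()) {
  u <- unique(raw)
  up <- toupper(trimws(u))
  up[is.na(up)] <- ""
  canon <- rep(NA_character_, length(u))
  pat <- "^([ACGT-])[/]([ACGT-])$"
  ok <- !(up %in% c("", toupper(trimws(specialSymbols)))) & grepl(pat, up)
  if (any(ok)) {
    a1 <- sub(pat, "\\1", up[ok])
    a2 <- sub(pat, "\\2", up[ok])
    swap <- match(a1, .ALLELE_ORDER) > match(a2, .ALLELE_ORDER)
    lo <- ifelse(swap, a2, a1)
    hi <- ifelse(swap, a1, a2)
    canon[ok] <- paste0(lo, "/", hi)
  }
  canon[match(raw, u)]
}

#' Normalize raw genotype calls
#'
#' Maps raw call strings to a canonical unordered form: whitespace trimmed,
#' case folded to upper, and the two alleles sorted into the fixed order
#' `-`, `A`, `C`, `G`, `T`, so that `"G/A"` and `"A/G"` share the canonical
#' form `"A/G"`. Special symbols (see [dmetSpecialSymbols()]), empty cells,
#' and anything else that is not an allele pair over `{A, C, G, T, -}` are
#' flagged non-analyzable (canonical form `NA`).
#'
#' @param raw Character vector of raw genotype-call strings.
#' @param specialSymbols Symbols treated as non-analyzable
#'   (case-insensitive).
#' @return `data.frame` with columns `raw`, `canonical` (`NA` when
#'   non-analyzable), and logical `analyzable`.
#' @examples
#' normalizeGenotype(c("G/A", "NoCall", "a/a", "t/C"))
#' @export
normalizeGenotype <- function(raw, specialSymbols = dmetSpecialSymbols()) {
  raw <- as.character(raw)
  canonical <- .canonicalizeCalls(raw, specialSymbols)
  data.frame(raw = raw, canonical = canonical,
             analyzable = !is.na(canonical))
}

# time/status vectors for one endpoint
.endpointData <- function(dataset, endpoint) {
  cd <- colData(dataset)
  if (endpoint == "OS") list(time = cd$os_time, status = cd$os_status)
  else list(time = cd$pfs_time, status = cd$pfs_status)
}

.matchEndpoint <- function(endpoint) {
  endpoint <- toupper(endpoint[1])
  if (!endpoint %in% c("OS", "PFS"))
    stop("endpoint must be \"OS\" or \"PFS\"")
  endpoint
}

# usable-sample mask for an endpoint: analyzable genotype plus complete,
# in-domain survival data
.usableMask <- function(canon, time, status) {
  !is.na(canon) & !is.na(time) & !is.na(status) &
    is.finite(time) & time >= 0 & (status == 0 | status == 1)
}

# split usable samples by canonical genotype; descending size, ties by
# genotype string
.orderedGenotypeSplit <- function(canon, usable, ids) {
  groups <- split(ids[usable], canon[usable])
  if (length(groups)) {
    ord <- order(-lengths(groups), names(groups))
    groups <- groups[ord]
  }
  groups
}

#' Group one probe's samples by genotype
#'
#' Splits the samples into genotype groups at a single probe, linking each
#' group to the samples' survival data for the chosen endpoint. Samples whose
#' call at this probe is non-analyzable (special symbol, empty, or
#' unparseable), or whose time/status for the endpoint is missing or out of
#' domain, are excluded from this probe only. For a biallelic probe at most
#' three groups can arise (e.g. alleles A and G give A/A, A/G, G/G).
#'
#' @param dataset An [OSDataset-class].
#' @param probeId Probe identifier.
#' @param endpoint `"OS"` or `"PFS"`.
#' @param specialSymbols See [dmetSpecialSymbols()].
#' @return A [GenotypeGrouping-class]; groups ordered by descending size,
#'   ties by genotype.
#' @seealso [survivalData()] to materialize each group's times and statuses.
#' @export
groupProbe <- function(dataset, probeId, endpoint = c("OS", "PFS"),
                       specialSymbols = dmetSpecialSymbols()) {
  endpoint <- .matchEndpoint(endpoint)
  i <- match(probeId, probeIds(dataset))
  if (is.na(i))
    stop("unknown probe: ", probeId)
  canon <- .canonicalizeCalls(genotypeCalls(dataset)[i, ], specialSymbols)
  ep <- .endpointData(dataset, endpoint)
  usable <- .usableMask(canon, ep$time, ep$status)
  ids <- sampleIds(dataset)
  groups <- .orderedGenotypeSplit(canon, usable, ids)
  new("GenotypeGrouping", probeId = probeId, endpoint = endpoint,
      genotypes = names(groups) %||% character(0), sampleIds = groups,
      excluded = ids[!usable], nSamples = ncol(dataset))
}

#' Materialize survival data for a genotype grouping
#'
#' Pulls each group's times and statuses from the dataset's clinical records
#' at call time. Because a [GenotypeGrouping-class] stores only sample
#' identifiers, survival data are never duplicated per probe: an edit to a
#' sample's clinical record is reflected in every grouping that contains the
#' sample.
#'
#' @param dataset The [OSDataset-class] the grouping was derived from.
#' @param grouping A [GenotypeGrouping-class].
#' @return Named list (by genotype) of lists with elements `sampleIds`,
#'   `times`, `statuses`.
#' @export
survivalData <- function(dataset, grouping) {
  stopifnot(is(grouping, "GenotypeGrouping"))
  ep <- .endpointData(dataset, grouping@endpoint)
  all_ids <- sampleIds(dataset)
  lapply(grouping@sampleIds, function(ids) {
    j <- match(ids, all_ids)
    list(sampleIds = ids, times = as.numeric(ep$time[j]),
         statuses = as.numeric(ep$status[j]))
  })
}
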