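## Reading/writing the clinically annotated genotype-matrix layout:
## row 1 = sample identifiers; then clinical rows OS, Status-OS, PFS,
## Status-PFS, Response (label matching is case-insensitive and treats
## "-", "_", " " as equivalent); remaining rows = probe id + genotype calls.

.CLINICAL_KEYS <- c(OS = "os_time", STATUSOS = "os_status",
                    PFS = "pfs_time", STATUSPFS = "pfs_status",
                    RESPONSE = "response")
.CLINICAL_LABELS <- c(os_time = "OS", os_status = "Status-OS",
                      pfs_time = "PFS", pfs_status = "Status-PFS",
                      response = "Response")

.labelKey <- function(x) toupper(gsub("[-_ ]", "", trimws(x)))

.resolveDialect <- function(path, dialect) {
  dialect <- match.arg(dialect, c("auto", "tab", "csv", "xlsx"))
  if (dialect != "auto") return(dialect)
  ext <- tolower(tools::file_ext(path))
  if (ext == "xlsx") return("xlsx")
  if (ext == "csv") return("csv")
  if (ext %in% c("txt", "tsv", "tab")) return("tab")
  # sniff the header line: tab wins over comma
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0) stop("empty file: ", path)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header)))
  n_com <- lengths(regmatches(header, gregexpr(",", header)))
  if (n_tab >= n_com && n_tab > 0) "tab"
  else if (n_com > 0) "csv"
  else "tab"
}

# read the raw cell grid (header row included) as a character matrix
.readCellMatrix <- function(path, dialect) {
  if (dialect == "xlsx") return(.readXlsxMatrix(path))
  if (dialect == "csv") {
    # base reader: full RFC-4180 quote handling (embedded quotes, newlines)
    df <- utils::read.csv(path, header = FALSE, colClasses = "character",
                          check.names = FALSE, na.strings = character(0),
                          blank.lines.skip = FALSE)
    m <- as.matrix(df)
  } else {
    dt <- data.table::fread(path, sep = "\t", quote = "", header = FALSE,
                            colClasses = "character", na.strings = NULL,
                            strip.white = FALSE, blank.lines.skip = FALSE,
                            fill = FALSE, data.table = TRUE)
    m <- as.matrix(dt)
  }
  dimnames(m) <- NULL
  m[is.na(m)] <- ""
  m
}

.readXlsxMatrix <- function(path) {
  # values only: reject workbooks with formula cells
  entries <- utils::unzip(path, list = TRUE)$Name
  sheets <- grep("^xl/worksheets/.*\\.xml$", entries, value = TRUE)
  if (length(sheets)) {
    tmp <- tempfile("xlsxchk")
    dir.create(tmp)
    on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
    utils::unzip(path, files = sheets, exdir = tmp)
    for (s in sheets) {
      xml <- paste(readLines(file.path(tmp, s), warn = FALSE), collapse = "")
      if (grepl("<f[ >]", xml, fixed = FALSE))
        stop("xlsx input contains formula cells; values are required")
    }
  }
  tb <- suppressMessages(
    readxl::read_excel(path, sheet = 1, col_names = FALSE,
                       col_types = "text", trim_ws = FALSE))
  m <- as.matrix(tb)
  dimnames(m) <- NULL
  m[is.na(m)] <- ""
  m
}

# parse one clinical row of strings to numeric; blank = missing
.parseClinicalRow <- function(values, label, sample_ids, statusRow) {
  out <- rep(NA_real_, length(values))
  nonblank <- !is.na(values) & trimws(values) != ""
  parsed <- suppressWarnings(as.numeric(values[nonblank]))
  bad <- is.na(parsed)
  if (any(bad)) {
    i <- which(nonblank)[which(bad)[1]]
    stop(sprintf("row '%s', sample '%s': non-numeric value '%s'",
                 label, sample_ids[i], values[i]))
  }
  if (statusRow && any(parsed != 0 & parsed != 1)) {
    j <- which(parsed != 0 & parsed != 1)[1]
    i <- which(nonblank)[j]
    stop(sprintf("row '%s', sample '%s': status must be 0 or 1 (found '%s')",
                 label, sample_ids[i], values[i]))
  }
  out[nonblank] <- parsed
  out
}

#' Read an OS-dataset file
#'
#' Parses the annotated genotype-matrix layout: the first row holds sample
#' identifiers; clinical rows labelled `OS`, `Status-OS`, `PFS`,
#' `Status-PFS`, and optionally `Response` (case-insensitive; `-`, `_`, and
#' spaces are interchangeable) precede the probe rows. Genotype cells are
#' preserved verbatim; normalization happens later, at analysis time. A
#' blank time or status cell marks the sample as excluded from that
#' endpoint's analysis rather than invalidating the file.
#'
#' @param path Path to the file.
#' @param dialect `"tab"`, `"csv"`, `"xlsx"`, or `"auto"` (resolve by file
#'   extension, then by sniffing the delimiter of the header line).
#' @return An [OSDataset-class].
#' @section Errors:
#' Missing required clinical row, non-numeric time, status outside
#' `{0, 1}`, and duplicate sample or probe identifiers are structural errors
#' naming the offending row/cell. A missing `Response` row only raises a
#' warning (it is carried as metadata and drives no test).
#' @seealso [writeOSDataset()], [validateOSDataset()]
#' @export
readOSDataset <- function(path, dialect = c("auto", "tab", "csv", "xlsx")) {
  if (!file.exists(path)) stop("file not found: ", path)
  dialect <- .resolveDialect(path, match.arg(dialect))
  m <- .readCellMatrix(path, dialect)
  if (ncol(m) < 2) stop("no sample columns found")
  sample_ids <- trimws(m[1, -1])
  if (any(sample_ids == "")) stop("blank sample identifier in header row")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifier: ",
         sample_ids[duplicated(sample_ids)][1])

  labels <- if (nrow(m) > 1) m[-1, 1] else character(0)
  keys <- .labelKey(labels)
  clinical <- list()
  probeStart <- NA_integer_
  for (i in seq_along(keys)) {
    if (keys[i] %in% names(.CLINICAL_KEYS)) {
      if (!is.na(probeStart))
        stop("clinical row '", labels[i], "' appears after probe rows")
      col <- .CLINICAL_KEYS[[keys[i]]]
      if (col %in% names(clinical))
        stop("duplicate clinical row: ", labels[i])
      clinical[[col]] <- .parseClinicalRow(
        m[i + 1, -1], .CLINICAL_LABELS[[col]], sample_ids,
        statusRow = col %in% c("os_status", "pfs_status"))
    } else if (is.na(probeStart)) {
      probeStart <- i
    }
  }
  required <- c("os_time", "os_status", "pfs_time", "pfs_status")
  for (col in required)
    if (!col %in% names(clinical))
      stop("missing clinical row ", .CLINICAL_LABELS[[col]])
  if (!"response" %in% names(clinical)) {
    warning("missing clinical row Response; carried as all-missing")
    clinical$response <- rep(NA_real_, length(sample_ids))
  }

  if (is.na(probeStart)) {
    calls <- matrix(character(0), nrow = 0, ncol = length(sample_ids),
                    dimnames = list(NULL, sample_ids))
  } else {
    probeRows <- probeStart:length(keys)
    probe_ids <- trimws(labels[probeRows])
    if (any(probe_ids == "")) stop("blank probe identifier")
    if (anyDuplicated(probe_ids))
      stop("duplicate probe identifier: ",
           probe_ids[duplicated(probe_ids)][1])
    calls <- m[probeRows + 1, -1, drop = FALSE]
    dimnames(calls) <- list(probe_ids, sample_ids)
  }
  OSDataset(calls, as.data.frame(clinical, row.names = sample_ids))
}

#' Write an OS-dataset file
#'
#' Serializes an [OSDataset-class] in the annotated-matrix layout so that
#' [readOSDataset()] reproduces it cell-for-cell (round-trip identity).
#' Missing clinical values are written as blank cells; numeric values use
#' the shortest representation that parses back to the same double. In the
#' CSV dialect, cells containing the delimiter, quotes, or newlines are
#' RFC-4180 quoted; the tab dialect has no quoting convention, so cells
#' containing tabs or newlines are rejected.
#'
#' @param dataset An [OSDataset-class].
#' @param path Output path.
#' @param dialect `"tab"`, `"csv"`, or `"xlsx"`.
#' @return `path`, invisibly.
#' @export
writeOSDataset <- function(dataset, path, dialect = c("tab", "csv", "xlsx")) {
  stopifnot(is(dataset, "OSDataset"))
  dialect <- match.arg(dialect)
  cd <- colData(dataset)
  fmt <- function(x) ifelse(is.na(x), "", as.character(x))
  grid <- rbind(
    c("Samples", sampleIds(dataset)),
    c("OS", fmt(cd$os_time)),
    c("Status-OS", fmt(cd$os_status)),
    c("PFS", fmt(cd$pfs_time)),
    c("Status-PFS", fmt(cd$pfs_status)),
    c("Response", fmt(cd$response)))
  if (nrow(dataset) > 0)
    grid <- rbind(grid, cbind(probeIds(dataset), genotypeCalls(dataset)))
  if (dialect == "xlsx") {
    .writeXlsxMatrix(grid, path)
  } else {
    if (dialect == "tab" && any(grepl("[\t\n\r]", grid)))
      stop("cells containing tabs or newlines are not representable ",
           "in the tab dialect")
    data.table::fwrite(data.table::as.data.table(grid), path,
                       sep = if (dialect == "tab") "\t" else ",",
                       quote = if (dialect == "tab") FALSE else "auto",
                       col.names = FALSE, na = "")
  }
  invisible(path)
}

.xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.colLetter <- function(j) {
  out <- character(length(j))
  for (i in seq_along(j)) {
    n <- j[i]
    s <- ""
    while (n > 0) {
      s <- paste0(LETTERS[(n - 1) %% 26 + 1], s)
      n <- (n - 1) %/% 26
    }
    out[i] <- s
  }
  out
}

# minimal single-sheet xlsx (inline strings only), packaged with zip::zip
.writeXlsxMatrix <- function(grid, path) {
  ns <- "http://schemas.openxmlformats.org/spreadsheetml/2006/main"
  rels_ns <- "http://schemas.openxmlformats.org/package/2006/relationships"
  doc_rel <- "http://schemas.openxmlformats.org/officeDocument/2006/relationships"
  letters <- .colLetter(seq_len(ncol(grid)))
  rows <- vapply(seq_len(nrow(grid)), function(i) {
    vals <- grid[i, ]
    keep <- which(!is.na(vals) & vals != "")
    cells <- sprintf(
      '<c r="%s%d" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
      letters[keep], i, .xmlEscape(vals[keep]))
    sprintf('<row r="%d">%s</row>', i, paste(cells, collapse = ""))
  }, character(1))
  sheet <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<worksheet xmlns="', ns, '"><sheetData>',
    paste(rows, collapse = ""), '</sheetData></worksheet>')
  parts <- list(
    "[Content_Types].xml" = paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
      '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
      '<Default Extension="xml" ContentType="application/xml"/>',
      '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
      '<Override PartName="/xl/worksheets/sheet1.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
      '<Override PartName="/xl/styles.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.styles+xml"/>',
      '</Types>'),
    "_rels/.rels" = paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<Relationships xmlns="', rels_ns, '">',
      '<Relationship Id="rId1" Type="', doc_rel,
      '/officeDocument" Target="xl/workbook.xml"/>',
      '</Relationships>'),
    "xl/workbook.xml" = paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<workbook xmlns="', ns, '" xmlns:r="', doc_rel, '">',
      '<sheets><sheet name="Sheet1" sheetId="1" r:id="rId1"/></sheets>',
      '</workbook>'),
    "xl/_rels/workbook.xml.rels" = paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<Relationships xmlns="', rels_ns, '">',
      '<Relationship Id="rId1" Type="', doc_rel,
      '/worksheet" Target="worksheets/sheet1.xml"/>',
      '<Relationship Id="rId2" Type="', doc_rel,
      '/styles" Target="styles.xml"/>',
      '</Relationships>'),
    "xl/styles.xml" = paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<styleSheet xmlns="', ns, '">',
      '<fonts count="1"><font/></fonts><fills count="1"><fill/></fills>',
      '<borders count="1"><border/></borders>',
      '<cellStyleXfs count="1"><xf/></cellStyleXfs>',
      '<cellXfs count="1"><xf/></cellXfs></styleSheet>'),
    "xl/worksheets/sheet1.xml" = sheet)
  staging <- tempfile("xlsxpkg")
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  for (name in names(parts)) {
    full <- file.path(staging, name)
    dir.create(dirname(full), recursive = TRUE, showWarnings = FALSE)
    writeLines(parts[[name]], full, sep = "")
  }
  if (file.exists(path)) unlink(path)
  zip::zip(file.path(normalizePath(dirname(path), mustWork = TRUE),
                     basename(path)),
           files = names(parts), root = staging, mode = "mirror")
  invisible(path)
}

#' Validate an OS-dataset
#'
#' Reports (never throws) all domain violations of the clinical records —
#' statuses outside `{0, 1}`, negative or non-finite times — together with
#' non-fatal findings (missing `Response`, samples lacking complete data for
#' an endpoint) and the structural counts, including the total number of
#' genotype cells (`nProbes * nSamples`). The dataset is not modified.
#'
#' @param dataset An [OSDataset-class].
#' @return A [ValidationReport-class].
#' @export
validateOSDataset <- function(dataset) {
  stopifnot(is(dataset, "OSDataset"))
  cd <- colData(dataset)
  ids <- sampleIds(dataset)
  err <- list()
  wrn <- list()
  addErr <- function(locator, message)
    err[[length(err) + 1]] <<- data.frame(locator = locator, message = message)
  addWrn <- function(locator, message)
    wrn[[length(wrn) + 1]] <<- data.frame(locator = locator, message = message)

  for (col in c("os_status", "pfs_status")) {
    v <- cd[[col]]
    bad <- which(!is.na(v) & v != 0 & v != 1)
    for (i in bad)
      addErr(paste0(.CLINICAL_LABELS[[col]], ", sample ", ids[i]),
             sprintf("status must be 0 or 1 (found %s)", v[i]))
  }
  for (col in c("os_time", "pfs_time")) {
    v <- cd[[col]]
    bad <- which(!is.na(v) & (!is.finite(v) | v < 0))
    for (i in bad)
      addErr(paste0(.CLINICAL_LABELS[[col]], ", sample ", ids[i]),
             sprintf("time must be finite and >= 0 (found %s)", v[i]))
  }
  rv <- cd$response
  if (all(is.na(rv))) {
    addWrn("Response", "row missing or empty (optional annotation)")
  } else {
    bad <- which(!is.na(rv) & rv != 0 & rv != 1)
    for (i in bad)
      addWrn(paste0("Response, sample ", ids[i]),
             sprintf("expected 0 or 1 (found %s)", rv[i]))
  }
  incOS <- which(is.na(cd$os_time) | is.na(cd$os_status))
  if (length(incOS))
    addWrn("OS", paste0("sample(s) excluded from OS analysis: ",
                        paste(ids[incOS], collapse = ", ")))
  incPFS <- which(is.na(cd$pfs_time) | is.na(cd$pfs_status))
  if (length(incPFS))
    addWrn("PFS", paste0("sample(s) excluded from PFS analysis: ",
                         paste(ids[incPFS], collapse = ", ")))

  empty <- data.frame(locator = character(0), message = character(0))
  new("ValidationReport",
      errors = if (length(err)) do.call(rbind, err) else empty,
      warnings = if (length(wrn)) do.call(rbind, wrn) else empty,
      nProbes = nrow(dataset), nSamples = ncol(dataset),
      nCells = nrow(dataset) * ncol(dataset))
}
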