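test_that("the printed four-sample fixture parses with values as printed", {
  for (cfg in list(list(sep = "\t", ext = ".txt", dialect = "tab"),
                   list(sep = ",", ext = ".csv", dialect = "csv"))) {
    path <- writeTable2File(cfg$sep, cfg$ext)
    ds <- readOSDataset(path, cfg$dialect)
    expect_s4_class(ds, "OSDataset")
    expect_identical(sampleIds(ds), paste0("S", 1:4))
    expect_identical(probeIds(ds), c("P1", "P2"))
    expect_equal(clinicalData(ds)$os_time, c(26.6, 15.7, 32.2, 2.3))
    expect_equal(clinicalData(ds)$os_status, c(1, 1, 0, 1))
    expect_equal(clinicalData(ds)$pfs_time, c(16.6, 4.7, 3.8, 27.3))
    # cells preserved verbatim: allele order not normalized at parse time
    expect_identical(unname(genotypeCalls(ds)["P1", ]),
                     c("G/A", "A/G", "A/G", "A/A"))
  }
})

test_that("dialect=auto resolves by extension, then by sniffing the header", {
  ds0 <- table2Dataset()
  byext <- writeTable2File("\t", ".txt")
  expect_same_dataset(readOSDataset(byext, "auto"), ds0)
  # unknown extension: sniff tab vs comma from the header line
  sniffTab <- writeTable2File("\t", ".dat")
  expect_same_dataset(readOSDataset(sniffTab, "auto"), ds0)
  sniffCsv <- writeTable2File(",", ".dat")
  expect_same_dataset(readOSDataset(sniffCsv, "auto"), ds0)
})

test_that("clinical-row labels match case-insensitively across separators", {
  lines <- table2Lines()
  lines[3] <- sub("Status-OS", "status_os", lines[3])
  lines[5] <- sub("Status-PFS", "STATUS PFS", lines[5])
  ds <- readOSDataset(writeTable2File(lines = lines), "tab")
  expect_equal(clinicalData(ds)$os_status, c(1, 1, 0, 1))
  expect_equal(clinicalData(ds)$pfs_status, c(1, 0, 0, 1))
})

test_that("structural problems are errors naming the offending row or cell", {
  noStatus <- table2Lines()[-3]
  expect_error(readOSDataset(writeTable2File(lines = noStatus)),
               "missing clinical row Status-OS")
  headerOnly <- table2Lines()[1]
  expect_error(readOSDataset(writeTable2File(lines = headerOnly)),
               "missing clinical row OS")
  badTime <- table2Lines()
  badTime[2] <- "OS\t26.6\tabc\t32.2\t2.3"
  expect_error(readOSDataset(writeTable2File(lines = badTime)),
               "'OS', sample 'S2': non-numeric")
  badStatus <- table2Lines()
  badStatus[3] <- "Status-OS\t1\t2\t0\t1"
  expect_error(readOSDataset(writeTable2File(lines = badStatus)),
               "'Status-OS', sample 'S2': status must be 0 or 1")
  dupSample <- sub("S2", "S1", table2Lines())
  expect_error(readOSDataset(writeTable2File(lines = dupSample)),
               "duplicate sample identifier")
  dupProbe <- sub("^P2", "P1", table2Lines())
  expect_error(readOSDataset(writeTable2File(lines = dupProbe)),
               "duplicate probe identifier")
})

test_that("a missing Response row warns and is carried as all-missing", {
  lines <- table2Lines()[-6]
  expect_warning(ds <- readOSDataset(writeTable2File(lines = lines)),
                 "Response")
  expect_true(all(is.na(clinicalData(ds)$response)))
  expect_identical(probeIds(ds), c("P1", "P2"))
})

test_that("blank time/status cells mark the sample excluded, not the file", {
  lines <- table2Lines()
  lines[2] <- "OS\t26.6\t\t32.2\t2.3"  # S2 has no OS time
  ds <- readOSDataset(writeTable2File(lines = lines))
  expect_true(is.na(clinicalData(ds)$os_time[2]))
  g <- groupProbe(ds, "P1", "OS")
  expect_true("S2" %in% g@excluded)
  # but S2 still participates in the PFS analysis
  gp <- groupProbe(ds, "P1", "PFS")
  expect_false("S2" %in% gp@excluded)
})

test_that("write/read round-trip is the identity for every dialect", {
  for (seed in 1:4) {
    ds <- randomDataset(seed, weird = (seed > 2))
    for (cfg in list(c("tab", ".txt"), c("csv", ".csv"), c("xlsx", ".xlsx"))) {
      if (cfg[1] == "tab" && seed > 2) next  # weird cells carry commas/quotes
      path <- tempfile(fileext = cfg[2])
      writeOSDataset(ds, path, cfg[1])
      expect_same_dataset(readOSDataset(path, "auto"), ds)
    }
  }
})

test_that("csv cells containing the delimiter are quoted exactly once", {
  calls <- table2Calls()
  calls["P1", "S1"] <- "A,G"
  ds <- OSDataset(calls, table2Clinical())
  path <- tempfile(fileext = ".csv")
  writeOSDataset(ds, path, "csv")
  expect_identical(genotypeCalls(readOSDataset(path))["P1", "S1"], "A,G")
  # and the quoted form survives a second round trip byte-for-byte
  path2 <- tempfile(fileext = ".csv")
  writeOSDataset(readOSDataset(path), path2, "csv")
  expect_identical(readLines(path), readLines(path2))
})

test_that("tab dialect rejects cells it cannot represent", {
  calls <- table2Calls()
  calls["P1", "S1"] <- "A\tG"
  ds <- OSDataset(calls, table2Clinical())
  expect_error(writeOSDataset(ds, tempfile(fileext = ".txt"), "tab"),
               "not representable")
})

test_that("xlsx files with formula cells are rejected", {
  path <- tempfile(fileext = ".xlsx")
  writeOSDataset(table2Dataset(), path, "xlsx")
  # splice a formula cell into the sheet and repackage
  tmp <- tempfile()
  utils::unzip(path, exdir = tmp)
  sheet <- file.path(tmp, "xl", "worksheets", "sheet1.xml")
  xml <- readLines(sheet, warn = FALSE)
  xml <- sub("</sheetData>",
             '<row r="99"><c r="A99"><f>SUM(B2:C2)</f><v>42</v></c></row></sheetData>',
             xml)
  writeLines(xml, sheet, sep = "")
  bad <- tempfile(fileext = ".xlsx")
  zip::zip(bad, files = list.files(tmp, recursive = TRUE), root = tmp,
           mode = "mirror")
  expect_error(readOSDataset(bad, "xlsx"), "formula")
})

test_that("parsed cell count is nProbes x nSamples and order is preserved", {
  ds <- randomDataset(9, nProbes = 13, nSamples = 7)
  path <- tempfile(fileext = ".csv")
  writeOSDataset(ds, path, "csv")
  back <- readOSDataset(path)
  vr <- validateOSDataset(back)
  expect_identical(vr@nCells, 13L * 7L)
  expect_identical(probeIds(back), probeIds(ds))
  expect_identical(sampleIds(back), sampleIds(ds))
})

test_that("validateOSDataset reports domain violations without throwing", {
  vr <- validateOSDataset(table2Dataset())
  expect_identical(nrow(vr@errors), 0L)
  expect_identical(vr@nSamples, 4L)
  expect_identical(vr@nCells, 8L)

  clin <- table2Clinical()
  clin$os_status[2] <- 2
  vr2 <- validateOSDataset(OSDataset(table2Calls(), clin))
  expect_identical(nrow(vr2@errors), 1L)
  expect_match(vr2@errors$locator, "Status-OS, sample S2")

  clin2 <- table2Clinical()
  clin2$os_time[1] <- -3
  vr3 <- validateOSDataset(OSDataset(table2Calls(), clin2))
  expect_identical(nrow(vr3@errors), 1L)
  expect_match(vr3@errors$locator, "OS, sample S1")
})
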