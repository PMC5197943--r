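# The four fully printed samples of the reference layout: clinical rows
# OS / Status-OS / PFS / Status-PFS / Response over samples S1..S4, followed
# by two probe rows. Used throughout as the hand-checkable fixture.

table2Clinical <- function() {
  data.frame(os_time = c(26.6, 15.7, 32.2, 2.3),
             os_status = c(1, 1, 0, 1),
             pfs_time = c(16.6, 4.7, 3.8, 27.3),
             pfs_status = c(1, 0, 0, 1),
             response = c(1, 0, 0, 0),
             row.names = paste0("S", 1:4))
}

table2Calls <- function() {
  matrix(c("G/A", "A/G", "A/G", "A/A",
           "T/C", "C/C", "T/T", "T/C"),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("P1", "P2"), paste0("S", 1:4)))
}

table2Dataset <- function() OSDataset(table2Calls(), table2Clinical())

# raw fixture text, written independently of writeOSDataset()
table2Lines <- function(sep = "\t") {
  rows <- list(c("Samples", paste0("S", 1:4)),
               c("OS", "26.6", "15.7", "32.2", "2.3"),
               c("Status-OS", "1", "1", "0", "1"),
               c("PFS", "16.6", "4.7", "3.8", "27.3"),
               c("Status-PFS", "1", "0", "0", "1"),
               c("Response", "1", "0", "0", "0"),
               c("P1", "G/A", "A/G", "A/G", "A/A"),
               c("P2", "T/C", "C/C", "T/T", "T/C"))
  vapply(rows, paste, "", collapse = sep)
}

writeTable2File <- function(sep = "\t", ext = ".txt",
                            lines = table2Lines(sep)) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# random dataset for round-trip and grouping property tests; includes
# special symbols, missing clinical cells, and (optionally) awkward cells
randomDataset <- function(seed, nProbes = 6, nSamples = 10, weird = FALSE) {
  set.seed(seed)
  pool <- c("A/A", "A/G", "G/A", "G/G", "T/C", "C/C", "-/A",
            dmetSpecialSymbols(), "")
  if (weird)
    pool <- c(pool, "a,g", "x\"y", "odd value", " C/T ")
  calls <- matrix(sample(pool, nProbes * nSamples, replace = TRUE),
                  nrow = nProbes,
                  dimnames = list(sprintf("P%03d", seq_len(nProbes)),
                                  paste0("S", seq_len(nSamples))))
  blank <- function(x) { x[runif(length(x)) < 0.1] <- NA; x }
  clinical <- data.frame(
    os_time = blank(round(rexp(nSamples, 0.05), 1)),
    os_status = blank(rbinom(nSamples, 1, 0.7)),
    pfs_time = blank(round(rexp(nSamples, 0.08), 1)),
    pfs_status = blank(rbinom(nSamples, 1, 0.7)),
    response = rbinom(nSamples, 1, 0.5),
    row.names = colnames(calls))
  OSDataset(calls, clinical)
}

expect_same_dataset <- function(a, b) {
  expect_identical(genotypeCalls(a), genotypeCalls(b))
  expect_identical(probeIds(a), probeIds(b))
  expect_identical(sampleIds(a), sampleIds(b))
  expect_equal(clinicalData(a), clinicalData(b))
}

# two-group censored sample for comparison tests
randomTwoGroups <- function(n1, n2, rate1 = 0.1, rate2 = 0.1,
                            censorRate = 0.05) {
  draw <- function(n, rate) {
    ev <- rexp(n, rate)
    cs <- rexp(n, censorRate)
    list(times = pmin(ev, cs), statuses = as.numeric(ev <= cs))
  }
  list(A = draw(n1, rate1), B = draw(n2, rate2))
}
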