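# dataset with prescribed genotype labels per sample at a single probe
probeFixture <- function(genos, times, statuses, pfsTimes = times,
                         pfsStatuses = statuses) {
  m <- length(genos)
  calls <- matrix(genos, nrow = 1,
                  dimnames = list("P1", paste0("S", seq_len(m))))
  clin <- data.frame(os_time = times, os_status = statuses,
                     pfs_time = pfsTimes, pfs_status = pfsStatuses,
                     response = 0, row.names = paste0("S", seq_len(m)))
  OSDataset(calls, clin)
}

test_that("three comparable genotype groups yield exactly three pairwise tests", {
  set.seed(3)
  ds <- probeFixture(rep(c("A/A", "A/G", "G/G"), each = 5),
                     round(rexp(15, 0.1), 1), rbinom(15, 1, 0.8))
  pr <- analyzeProbe(ds, "P1", "OS")
  expect_false(pr@skipped)
  expect_identical(nrow(pr@pairwise), 3L)
  expect_identical(pr@overall@df, 2L)
  expect_equal(pr@rankP, min(pr@pairwise$pValue))
})

test_that("pairwise count is k(k-1)/2 for k comparable groups", {
  set.seed(4)
  ds <- probeFixture(rep(c("A/A", "A/C", "C/C", "A/T"), each = 4),
                     round(rexp(16, 0.1), 1), rbinom(16, 1, 0.9))
  pr <- analyzeProbe(ds, "P1", "OS")
  expect_identical(nrow(pr@pairwise), 6L)  # choose(4, 2)
  expect_identical(pr@overall@df, 3L)
})

test_that("monomorphic probes carry the skipped marker and no tests", {
  ds <- probeFixture(rep("A/A", 6), c(1, 2, 3, 4, 5, 6), rep(1, 6))
  pr <- analyzeProbe(ds, "P1", "OS")
  expect_true(pr@skipped)
  expect_identical(nrow(pr@pairwise), 0L)
  expect_true(is.na(pr@rankP))
  expect_null(pr@overall)
})

test_that("groups below minGroupSize are reported but not tested", {
  set.seed(5)
  ds <- probeFixture(c(rep("A/A", 6), rep("A/G", 5), "G/G"),
                     round(rexp(12, 0.1), 1), rep(1, 12))
  pr <- analyzeProbe(ds, "P1", "OS", minGroupSize = 2)
  expect_identical(nrow(pr@groups), 3L)
  expect_identical(pr@groups$comparable, c(TRUE, TRUE, FALSE))
  expect_identical(nrow(pr@pairwise), 1L)   # only A/A vs A/G
  # with minGroupSize = 1 the singleton joins the tests
  pr1 <- analyzeProbe(ds, "P1", "OS", minGroupSize = 1)
  expect_identical(nrow(pr1@pairwise), 3L)
})

test_that("two groups with identical survival data rank at p = 1", {
  ds <- probeFixture(rep(c("A/A", "G/G"), each = 4),
                     rep(c(3, 6, 9, 12), 2), rep(c(1, 1, 0, 1), 2))
  pr <- analyzeProbe(ds, "P1", "OS")
  expect_equal(pr@rankP, 1)
})

test_that("probes whose comparisons are all degenerate are skipped", {
  ds <- probeFixture(rep(c("A/A", "G/G"), each = 3),
                     c(1, 2, 3, 4, 5, 6), rep(0, 6))  # everyone censored
  pr <- analyzeProbe(ds, "P1", "OS")
  expect_true(pr@skipped)
  expect_match(pr@skipReason, "no informative")
  rep_ <- rankProbes(ds, "OS")
  expect_length(rep_@results, 0L)
  expect_length(rep_@skippedResults, 1L)
})

test_that("the ranking is a sorted permutation of non-skipped probes", {
  sim <- simulateCohort(cohortConfig(nSamples = 60, nProbes = 25, seed = 6))
  rep_ <- rankProbes(sim$dataset, "OS")
  ids <- vapply(rep_@results, slot, "", "probeId")
  skippedIds <- vapply(rep_@skippedResults, slot, "", "probeId")
  expect_setequal(c(ids, skippedIds), probeIds(sim$dataset))
  p <- vapply(rep_@results, slot, 0, "rankP")
  expect_true(all(diff(p) >= 0))
  # deterministic for a fixed input
  rep2 <- rankProbes(sim$dataset, "OS")
  expect_identical(vapply(rep2@results, slot, "", "probeId"), ids)
  expect_equal(vapply(rep2@results, slot, 0, "rankP"), p)
})

test_that("zero-probe datasets produce an empty report, not an error", {
  calls <- matrix(character(0), nrow = 0, ncol = 4,
                  dimnames = list(NULL, paste0("S", 1:4)))
  ds <- OSDataset(calls, table2Clinical())
  rep_ <- rankProbes(ds, "OS")
  expect_length(rep_@results, 0L)
  expect_length(rep_@skippedResults, 0L)
  expect_identical(nrow(reportTable(rep_)), 0L)
})

test_that("swapping the OS and PFS records swaps the two reports", {
  sim <- simulateCohort(cohortConfig(nSamples = 50, nProbes = 15, seed = 8))
  ds <- sim$dataset
  cd <- clinicalData(ds)
  swapped <- OSDataset(genotypeCalls(ds),
                       data.frame(os_time = cd$pfs_time,
                                  os_status = cd$pfs_status,
                                  pfs_time = cd$os_time,
                                  pfs_status = cd$os_status,
                                  response = cd$response,
                                  row.names = rownames(cd)))
  a <- rankProbes(ds, "OS")
  b <- rankProbes(swapped, "PFS")
  expect_identical(vapply(a@results, slot, "", "probeId"),
                   vapply(b@results, slot, "", "probeId"))
  expect_equal(vapply(a@results, slot, 0, "rankP"),
               vapply(b@results, slot, 0, "rankP"))
})

test_that("p-value adjustment preserves order and matches hand BH values", {
  mkProbe <- function(id, p)
    new("ProbeResult", probeId = id, endpoint = "OS",
        groups = data.frame(), overall = NULL,
        pairwise = dmetsurv:::.EMPTY_PAIRWISE, rankP = p, skipped = FALSE,
        skipReason = NA_character_)
  rep_ <- new("RankedReport", endpoint = "OS",
              results = list(mkProbe("P1", 0.01), mkProbe("P2", 0.02),
                             mkProbe("P3", 0.03)),
              skippedResults = list(), adjustMethod = "none",
              adjustedP = numeric(0), minGroupSize = 2L,
              runId = NA_character_)
  # none is the identity
  expect_identical(adjustPvalues(rep_, "none"), rep_)
  bh <- adjustPvalues(rep_, "benjamini-hochberg")
  expect_equal(bh@adjustedP, c(0.03, 0.03, 0.03))
  expect_identical(vapply(bh@results, slot, "", "probeId"),
                   c("P1", "P2", "P3"))
  bf <- adjustPvalues(rep_, "bonferroni")
  expect_equal(bf@adjustedP, c(0.03, 0.06, 0.09))
  # single ranked probe: BH adjusted equals raw
  one <- new("RankedReport", endpoint = "OS",
             results = list(mkProbe("P1", 0.04)), skippedResults = list(),
             adjustMethod = "none", adjustedP = numeric(0),
             minGroupSize = 2L, runId = NA_character_)
  expect_equal(adjustPvalues(one, "benjamini-hochberg")@adjustedP, 0.04)
})

test_that("a strongly causal probe is ranked first among null probes", {
  hits <- 0L
  for (seed in 1:5) {
    cfg <- cohortConfig(nSamples = 200, nProbes = 21,
                        causalProbes = list(list(probe = 11,
                                                 multipliers = c(1, 2, 4))),
                        seed = seed)
    sim <- simulateCohort(cfg)
    rep_ <- rankProbes(sim$dataset, "OS")
    if (rep_@results[[1]]@probeId == "AM_00011") hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("under the null, single-comparison rank p-values look uniform", {
  # two-genotype probes so the ranking key is one log-rank p per probe
  set.seed(9)
  n <- 400; m <- 80
  calls <- matrix(sample(c("A/A", "A/G"), n * m, replace = TRUE),
                  nrow = n, dimnames = list(sprintf("P%04d", 1:n),
                                            paste0("S", 1:m)))
  clin <- data.frame(os_time = round(rexp(m, 0.05), 1),
                     os_status = rbinom(m, 1, 0.8),
                     pfs_time = round(rexp(m, 0.08), 1),
                     pfs_status = rbinom(m, 1, 0.8),
                     response = 0, row.names = paste0("S", 1:m))
  rep_ <- rankProbes(OSDataset(calls, clin), "OS")
  p <- vapply(rep_@results, slot, 0, "rankP")
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("null rank-p exceedance matches a permutation-based null rate", {
  sim <- simulateCohort(cohortConfig(nSamples = 100, nProbes = 300,
                                     specialSymbolRate = 0, seed = 10))
  ds <- sim$dataset
  rep_ <- rankProbes(ds, "OS")
  obs <- mean(vapply(rep_@results, slot, 0, "rankP") < 0.05)
  # empirical null: permute the clinical records across samples
  set.seed(11)
  o <- sample(ncol(ds))
  cd <- clinicalData(ds)[o, ]
  rownames(cd) <- sampleIds(ds)
  perm <- rankProbes(OSDataset(genotypeCalls(ds), cd), "OS")
  ref <- mean(vapply(perm@results, slot, 0, "rankP") < 0.05)
  # both are min-of-3 selection rates; they must agree within binomial error
  pbar <- (obs + ref) / 2
  expect_lt(abs(obs - ref), 4 * sqrt(2 * pbar * (1 - pbar) / 300) + 1e-9)
})
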