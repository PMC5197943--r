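#' Configuration for a synthetic genotyped cohort
#'
#' Defines the generating model for [simulateCohort()]. Defaults mirror the
#' reference study conditions: 80 patients genotyped on a 1936-probe panel.
#' Each probe is biallelic; a sample carries 0, 1, or 2 copies of the
#' alternate allele with Hardy-Weinberg class probabilities `(1-q)^2`,
#' `2q(1-q)`, `q^2` for allele frequency `q`, which naturally yields up to
#' three genotype groups per probe. Death and progression times are
#' exponential; for the probes named in `causalProbes` the per-sample hazard
#' is multiplied by the genotype-specific factor (1 elsewhere). Right
#' censoring combines an independent exponential drop-out process with an
#' administrative follow-up cap.
#'
#' @param nSamples Number of patients (default 80).
#' @param nProbes Number of probes (default 1936).
#' @param alleleFreq Alternate-allele frequency in (0, 1); scalar or one
#'   value per probe (default 0.3, a common SNP).
#' @param causalProbes List of `list(probe = <index>, multipliers =
#'   <length-3 positive vector>)`: hazard multipliers for the ref/ref,
#'   ref/alt, alt/alt genotype classes of that probe.
#' @param baselineHazard Baseline event hazard per month (default 0.03,
#'   median survival about 23 months — an advanced-cancer cohort).
#' @param progressionHazard Hazard per month of the progression process
#'   (default 0.05); progression-free survival is the minimum of the
#'   progression and death times, so PFS <= OS for every sample.
#' @param censorRate Target fraction in `[0, 1)` of baseline-hazard subjects
#'   whose follow-up ends by random drop-out before the event (default 0.2);
#'   0 disables drop-out.
#' @param followupCap Administrative censoring time in months (default 60;
#'   `Inf` disables the cap).
#' @param specialSymbolRate Fraction of genotype cells overwritten with a
#'   special symbol such as `NoCall` (default 0.02).
#' @param seed Integer seed; identical configurations produce identical
#'   datasets.
#' @return A validated configuration (classed list).
#' @export
cohortConfig <- function(nSamples = 80, nProbes = 1936, alleleFreq = 0.3,
                         causalProbes = list(), baselineHazard = 0.03,
                         progressionHazard = 0.05, censorRate = 0.2,
                         followupCap = 60, specialSymbolRate = 0.02,
                         seed = 1) {
  cfg <- list(nSamples = as.integer(nSamples), nProbes = as.integer(nProbes),
              alleleFreq = as.numeric(alleleFreq),
              causalProbes = causalProbes,
              baselineHazard = as.numeric(baselineHazard),
              progressionHazard = as.numeric(progressionHazard),
              censorRate = as.numeric(censorRate),
              followupCap = as.numeric(followupCap),
              specialSymbolRate = as.numeric(specialSymbolRate),
              seed = as.integer(seed))
  bad <- function(field, why) stop("invalid config field '", field, "': ", why)
  if (is.na(cfg$nSamples) || cfg$nSamples < 1) bad("nSamples", "need >= 1")
  if (is.na(cfg$nProbes) || cfg$nProbes < 0) bad("nProbes", "need >= 0")
  if (!length(cfg$alleleFreq) %in% c(1L, cfg$nProbes))
    bad("alleleFreq", "need one value, or one per probe")
  if (anyNA(cfg$alleleFreq) || any(cfg$alleleFreq <= 0 | cfg$alleleFreq >= 1))
    bad("alleleFreq", "values must lie in (0, 1)")
  if (!is.list(cfg$causalProbes)) bad("causalProbes", "must be a list")
  for (cp in cfg$causalProbes) {
    if (!is.list(cp) || is.null(cp$probe) || is.null(cp$multipliers))
      bad("causalProbes", "entries need 'probe' and 'multipliers'")
    if (cp$probe < 1 || cp$probe > cfg$nProbes)
      bad("causalProbes", "probe index out of range")
    if (length(cp$multipliers) != 3 || any(cp$multipliers <= 0))
      bad("causalProbes", "multipliers must be 3 positive values")
  }
  if (is.na(cfg$baselineHazard) || cfg$baselineHazard <= 0)
    bad("baselineHazard", "need > 0")
  if (is.na(cfg$progressionHazard) || cfg$progressionHazard <= 0)
    bad("progressionHazard", "need > 0")
  if (is.na(cfg$censorRate) || cfg$censorRate < 0 || cfg$censorRate >= 1)
    bad("censorRate", "need a value in [0, 1)")
  if (is.na(cfg$followupCap) || cfg$followupCap <= 0)
    bad("followupCap", "need > 0 (Inf allowed)")
  if (is.na(cfg$specialSymbolRate) || cfg$specialSymbolRate < 0 ||
      cfg$specialSymbolRate > 1)
    bad("specialSymbolRate", "need a value in [0, 1]")
  if (is.na(cfg$seed)) bad("seed", "need an integer")
  structure(cfg, class = "cohortConfig")
}

#' Simulate a genotyped cohort with known ground truth
#'
#' Draws an [OSDataset-class] from the generating model described in
#' [cohortConfig()], together with a ground-truth table of each probe's
#' alleles, allele frequency, and genotype hazard multipliers. Observed
#' times are the minimum of event, drop-out, and follow-up-cap times,
#' rounded to 0.1 month (the precision of clinical exports); statuses are 1
#' when the event precedes both censoring mechanisms. Heterozygous calls are
#' written in random allele order (`"G/A"` or `"A/G"`) to exercise
#' normalization downstream, and special symbols are sprinkled at the
#' configured rate.
#'
#' @param config A [cohortConfig()].
#' @return List with elements `dataset` (an [OSDataset-class], with a
#'   `runId` in its metadata), `truth` (a `data.frame` keyed by `probe_id`
#'   with columns `allele_ref`, `allele_alt`, `allele_freq`, `mult_refref`,
#'   `mult_refalt`, `mult_altalt`, `causal`, carrying the matching `runId`
#'   attribute), and `config`.
#' @examples
#' sim <- simulateCohort(cohortConfig(nSamples = 20, nProbes = 4, seed = 3))
#' sim$dataset
#' @export
simulateCohort <- function(config = cohortConfig()) {
  if (!inherits(config, "cohortConfig"))
    config <- do.call(cohortConfig, as.list(config))
  set.seed(config$seed)
  n <- config$nProbes
  m <- config$nSamples
  probe_ids <- sprintf("AM_%05d", seq_len(n))
  sample_ids <- paste0("S", seq_len(m))
  q <- rep_len(config$alleleFreq, n)

  # biallelic probes: two distinct alleles each, HWE genotype classes
  bases <- c("A", "C", "G", "T")
  ref <- bases[sample.int(4, n, replace = TRUE)]
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  class <- matrix(rbinom(n * m, 2, rep(q, times = m)), nrow = n)

  mult <- rep(1, m)
  truth_mult <- matrix(1, nrow = n, ncol = 3)
  for (cp in config$causalProbes) {
    truth_mult[cp$probe, ] <- cp$multipliers
    mult <- mult * cp$multipliers[class[cp$probe, ] + 1L]
  }

  death <- rexp(m, rate = config$baselineHazard * mult)
  progression <- rexp(m, rate = config$progressionHazard * mult)
  dropout <- if (config$censorRate > 0)
    rexp(m, rate = config$baselineHazard *
           config$censorRate / (1 - config$censorRate))
  else rep(Inf, m)
  cap <- config$followupCap
  censor <- pmin(dropout, cap)
  os_time <- round(pmin(death, censor), 1)
  os_status <- as.numeric(death <= censor)
  pfs_event <- pmin(progression, death)
  pfs_time <- round(pmin(pfs_event, censor), 1)
  pfs_status <- as.numeric(pfs_event <= censor)
  response <- rbinom(m, 1, 0.5)

  hetSwap <- matrix(runif(n * m) < 0.5, nrow = n)
  lo <- ifelse(match(ref, .ALLELE_ORDER) <= match(alt, .ALLELE_ORDER),
               ref, alt)
  hi <- ifelse(lo == ref, alt, ref)
  calls <- matrix("", nrow = n, ncol = m,
                  dimnames = list(probe_ids, sample_ids))
  calls[] <- paste0(lo, "/", lo)[row(calls)]
  het <- class == 1L
  hetFwd <- paste0(lo, "/", hi)
  hetRev <- paste0(hi, "/", lo)
  calls[het & hetSwap] <- hetRev[row(calls)[het & hetSwap]]
  calls[het & !hetSwap] <- hetFwd[row(calls)[het & !hetSwap]]
  hom_alt <- class == 2L
  calls[hom_alt] <- paste0(hi, "/", hi)[row(calls)[hom_alt]]
  if (config$specialSymbolRate > 0 && n > 0) {
    specials <- dmetSpecialSymbols()
    hit <- which(runif(n * m) < config$specialSymbolRate)
    calls[hit] <- specials[sample.int(length(specials), length(hit),
                                      replace = TRUE)]
  }

  runId <- sprintf("sim-%d-%dx%d", config$seed, n, m)
  clinical <- data.frame(os_time = os_time, os_status = os_status,
                         pfs_time = pfs_time, pfs_status = pfs_status,
                         response = response, row.names = sample_ids)
  dataset <- OSDataset(calls, clinical, metadata = list(runId = runId))
  truth <- data.frame(probe_id = probe_ids, allele_ref = lo, allele_alt = hi,
                      allele_freq = q, mult_refref = truth_mult[, 1],
                      mult_refalt = truth_mult[, 2],
                      mult_altalt = truth_mult[, 3],
                      causal = truth_mult[, 1] != 1 | truth_mult[, 2] != 1 |
                        truth_mult[, 3] != 1,
                      row.names = NULL)
  attr(truth, "runId") <- runId
  list(dataset = dataset, truth = truth, config = config)
}

#' Check causal-probe recovery against simulation ground truth
#'
#' Closes the simulation loop: given a [RankedReport-class] computed from a
#' simulated dataset and the generator's ground-truth table, reports the
#' fraction of causal probes ranked in the top `topK`, and compares each
#' causal probe's estimated O/E hazard ratio (largest-multiplier genotype
#' versus smallest) against the true multiplier ratio.
#'
#' @param report A [RankedReport-class] computed from the simulated dataset.
#' @param truth The `truth` table returned by [simulateCohort()].
#' @param topK Size of the top list (default 10).
#' @return List with `recovery` (fraction of causal probes in the top
#'   `topK`; `NA` when no probe is causal), `nCausal`, and `hrTable`
#'   (one row per causal probe: true and estimated hazard ratio).
#' @export
truthCheck <- function(report, truth, topK = 10) {
  stopifnot(is(report, "RankedReport"), is.data.frame(truth))
  truthRun <- attr(truth, "runId")
  if (!is.null(truthRun) && !is.na(report@runId) &&
      !identical(as.character(truthRun), report@runId))
    stop("report and truth come from different runs (",
         report@runId, " vs ", truthRun, ")")
  causal <- truth[truth$causal, , drop = FALSE]
  rankedIds <- vapply(report@results, slot, "", "probeId")
  if (nrow(causal) == 0)
    return(list(recovery = NA_real_, nCausal = 0L,
                hrTable = data.frame(probe_id = character(0),
                                     hr_true = numeric(0),
                                     hr_est = numeric(0))))
  top <- head(rankedIds, topK)
  hrRows <- lapply(seq_len(nrow(causal)), function(i) {
    row <- causal[i, ]
    mults <- c(row$mult_refref, row$mult_refalt, row$mult_altalt)
    genos <- c(paste0(row$allele_ref, "/", row$allele_ref),
               paste0(row$allele_ref, "/", row$allele_alt),
               paste0(row$allele_alt, "/", row$allele_alt))
    hiG <- genos[which.max(mults)]
    loG <- genos[which.min(mults)]
    est <- NA_real_
    j <- match(row$probe_id, rankedIds)
    if (!is.na(j)) {
      pw <- report@results[[j]]@pairwise
      k <- which(pw$groupA == hiG & pw$groupB == loG)
      if (length(k)) est <- pw$hazardRatio[k[1]]
      else {
        k <- which(pw$groupA == loG & pw$groupB == hiG)
        if (length(k)) est <- 1 / pw$hazardRatio[k[1]]
      }
    }
    data.frame(probe_id = row$probe_id, genotype_hi = hiG, genotype_lo = loG,
               hr_true = max(mults) / min(mults), hr_est = est)
  })
  list(recovery = mean(causal$probe_id %in% top),
       nCausal = nrow(causal),
       hrTable = do.call(rbind, hrRows))
}
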