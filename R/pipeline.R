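#' Assemble and validate a run configuration
#'
#' Defaults are the analysis constants of the method: TPM floor 25, allelic
#' window 0.3-0.7, nullisomic bound 0.1, alpha 0.05, QC gene floors 6000
#' (controls) / 4000 (micronucleation-related cells), ATAC fold-change
#' threshold 0.70 and 50 background peaks per peak. Simulation sizes default
#' to a 5 x 100 Mb genome with 100 genes per chromosome, depth 100 and 30
#' controls.
#'
#' @param ... Named overrides of any default.
#' @return Validated configuration list.
#' @export
mnRunConfig <- function(...) {
  cfg <- list(
    tpmFloor = 25, allelicWindow = c(0.3, 0.7), nullisomicBound = 0.1,
    alpha = 0.05, qcMinReads = 5, qcMinGenesControl = 6000,
    qcMinGenesMn = 4000, fcThreshold = 0.70, kBackground = 50,
    nPerm = 1e4, intervalMb = 10, atacAlpha = 1e-3,
    nChromosomes = 5, chromLength = 1e8, genesPerChromosome = 100,
    depth = 100, nControl = 30, seed = 1,
    nPeaks = 5000, nControlClones = 10, nCaseClones = 12,
    suppressionFactor = 0.5,
    suppressedInterval = list(chrom = "chr1", start = 2e7, end = 3e7),
    outDir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration option(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  with(cfg, {
    if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly in (0, 1)")
    if (atacAlpha <= 0 || atacAlpha >= 1) stop("atacAlpha must lie in (0, 1)")
    if (tpmFloor < 0) stop("tpmFloor must be >= 0")
    if (nullisomicBound <= 0) stop("nullisomicBound must be positive")
    if (fcThreshold <= 0 || fcThreshold > 1) stop("fcThreshold must be in (0, 1]")
    if (allelicWindow[1] < 0 || allelicWindow[2] > 1 ||
        allelicWindow[1] >= allelicWindow[2]) {
      stop("allelicWindow must be an increasing pair within [0, 1]")
    }
    if (kBackground < 2) stop("kBackground must be >= 2")
    if (!intervalMb %in% c(1, 5, 10)) stop("intervalMb must be 1, 5 or 10")
  })
  cfg
}

#' Run the single-cell micronucleus pipeline on simulated families
#'
#' Simulates a gene catalog, a control cohort and one family per scenario;
#' applies QC and gene filters; builds the normal and aneuploid references;
#' classifies every homologue of every family cell; infers each family's MN
#' chromosome; and estimates the MN chromatid yield. The summary tally counts
#' families by yield classification (defective = near-silent or reduced;
#' recovered = normal or consistent-with-normal).
#'
#' @param config List from \code{\link{mnRunConfig}}.
#' @param scenarios List of \code{\link{segregationScenario}} objects.
#' @return List: catalog, reference, aneuploidReference, qc, families (each
#'   with states, assignment, yield), tally, log. When \code{config$outDir}
#'   is set, result tables and a hashed file manifest are written there.
#' @export
runScPipeline <- function(config, scenarios) {
  if (!length(scenarios)) stop("no scenarios supplied")
  seed <- config$seed
  catalog <- generateGeneCatalog(config$nChromosomes, config$chromLength,
                                 config$genesPerChromosome, seed = seed)
  controls <- simulateControls(catalog, config$nControl, config$depth,
                               seed = .substream(seed, 11L))
  qcC <- qcFilterCell(controls, minReads = config$qcMinReads,
                      minGenesControl = config$qcMinGenesControl,
                      minGenesMn = config$qcMinGenesMn)
  controls <- controls[, qcC$pass]
  controlIds <- colData(controls)$cell_id
  if (length(controlIds) < 5) stop("fewer than 5 controls pass QC")
  retained <- geneFilters(controls, controlIds, tpmFloor = config$tpmFloor,
                          allelicWindow = config$allelicWindow)
  ctrlSum <- cellSummaries(controls, controls, retained = retained)
  ref <- buildReference(ctrlSum)
  aneuRef <- buildAneuploidReference(ctrlSum,
                                     nullisomicBound = config$nullisomicBound)
  families <- list()
  qcRows <- list(qcC)
  for (i in seq_along(scenarios)) {
    famId <- sprintf("F%03d", i)
    sim <- simulateFamily(catalog, scenarios[[i]], nControl = 0,
                          depth = config$depth,
                          seed = .substream(seed, 1000L + i),
                          familyId = famId)
    fam <- sim$family
    qcF <- qcFilterCell(fam, minReads = config$qcMinReads,
                        minGenesControl = config$qcMinGenesControl,
                        minGenesMn = config$qcMinGenesMn)
    qcRows[[length(qcRows) + 1L]] <- qcF
    fam <- fam[, qcF$pass]
    if (ncol(fam) < 2) {
      families[[famId]] <- list(states = NULL, assignment = NULL,
                                yield = NULL, skipped = "failed QC")
      next
    }
    famSum <- cellSummaries(fam, controls, retained = retained)
    states <- classifyCell(famSum, ref, aneuRef, alpha = config$alpha)
    roles <- cellRoles(fam)
    gen <- scenarios[[i]]$generation
    assignment <- inferMNChromosome(states, roles, gen, familyId = famId)
    yield <- if (assignment@confidence == "unresolved") NULL else
      estimateMNYield(famSum, assignment, roles, ref, aneuRef,
                      alpha = config$alpha)
    families[[famId]] <- list(states = states, assignment = assignment,
                              yield = yield, summaries = famSum)
  }
  cls <- vapply(families, function(f) {
    if (is.null(f$yield)) return(NA_character_)
    f$yield@classification
  }, character(1))
  tally <- c(defective = sum(cls %in% c("near-silent", "reduced")),
             recovered = sum(cls %in% c("normal", "consistent-with-normal")),
             unresolved = sum(is.na(cls)))
  qc <- do.call(rbind, qcRows)
  log <- list(seed = seed, n_scenarios = length(scenarios),
              n_controls_pass = length(controlIds),
              n_cells_fail_qc = sum(!qc$pass),
              n_genes_retained = length(retained),
              gene_filter_metrics = attr(retained, "metrics"))
  out <- list(catalog = catalog, reference = ref,
              aneuploidReference = aneuRef, qc = qc, families = families,
              tally = tally, log = log)
  if (!is.null(config$outDir)) .writeScOutputs(out, config$outDir)
  out
}

#' Run the clone ATAC suppression pipeline on simulated clones
#'
#' Simulates clone ATAC matrices with an injected suppressed interval,
#' quantile-normalizes and copy-number-corrects the counts, selects GC- and
#' accessibility-matched background peaks from the control clones, scans every
#' case clone in fixed genomic intervals with the permutation test, and flags
#' suppressed intervals.
#'
#' @param config List from \code{\link{mnRunConfig}}.
#' @param scanSamples Sample ids to scan; default all case clones.
#' @return List: peaks, normalized counts, background, results, flags, truth,
#'   log.
#' @export
runAtacPipeline <- function(config, scanSamples = NULL) {
  seed <- config$seed
  sim <- simulateAtacClones(
    nPeaks = config$nPeaks, nControlClones = config$nControlClones,
    nCaseClones = config$nCaseClones,
    suppressedInterval = config$suppressedInterval,
    suppressionFactor = config$suppressionFactor,
    seed = .substream(seed, 21L),
    nChromosomes = config$nChromosomes, chromLength = config$chromLength)
  norm <- normalizeAtacCounts(sim$counts, sim$peaks, sim$cn)
  ctrlIds <- sim$samples$sample_id[sim$samples$group == "control"]
  meanAccess <- rowMeans(norm[, ctrlIds, drop = FALSE], na.rm = TRUE)
  background <- selectBackgroundPeaks(sim$peaks, meanAccess,
                                      k = config$kBackground,
                                      seed = .substream(seed, 22L))
  if (is.null(scanSamples)) {
    scanSamples <- sim$samples$sample_id[sim$samples$group == "case"]
  }
  results <- do.call(rbind, lapply(seq_along(scanSamples), function(j) {
    atacIntervalScan(norm[, scanSamples[j]], sim$peaks, background,
                     intervalMb = config$intervalMb, nPerm = config$nPerm,
                     seed = .substream(seed, 30L + j),
                     sampleId = scanSamples[j])
  }))
  flags <- flagSuppressedIntervals(results, fcThreshold = config$fcThreshold,
                                   alpha = config$atacAlpha)
  log <- list(seed = seed, n_peaks = length(sim$peaks),
              n_samples_scanned = length(scanSamples),
              n_intervals = sum(!duplicated(
                paste(results$chrom, results$start))),
              n_ineligible = sum(!results$eligible),
              n_flagged = nrow(flags$flagged))
  out <- list(peaks = sim$peaks, normalized = norm, background = background,
              results = results, flags = flags, truth = sim$truth, log = log)
  if (!is.null(config$outDir)) .writeAtacOutputs(out, config$outDir)
  out
}

.writeTsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

.writeManifest <- function(dir, files) {
  hashes <- tools::md5sum(files)
  .writeTsv(data.frame(file = basename(files), md5 = unname(hashes)),
            file.path(dir, "manifest.tsv"))
}

.writeScOutputs <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  states <- do.call(rbind, lapply(out$families, `[[`, "states"))
  if (!is.null(states)) {
    f <- file.path(dir, "states.tsv"); .writeTsv(states, f)
    files <- c(files, f)
  }
  asn <- do.call(rbind, lapply(names(out$families), function(id) {
    a <- out$families[[id]]$assignment
    y <- out$families[[id]]$yield
    data.frame(family_id = id,
               chromosome = if (is.null(a)) NA else a@chromosome,
               haplotype = if (is.null(a)) NA else a@haplotype,
               pattern = if (is.null(a)) NA else a@pattern,
               confidence = if (is.null(a)) NA else a@confidence,
               yield_a = if (is.null(y)) NA else y@a,
               basis = if (is.null(y)) NA else y@basis,
               classification = if (is.null(y)) NA else y@classification)
  }))
  f <- file.path(dir, "assignments.tsv"); .writeTsv(asn, f)
  files <- c(files, f)
  f <- file.path(dir, "qc.tsv"); .writeTsv(out$qc, f)
  files <- c(files, f)
  .writeManifest(dir, files)
}

.writeAtacOutputs <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, "atac_intervals.tsv")
  .writeTsv(out$results, f1)
  f2 <- file.path(dir, "atac_flagged.tsv")
  .writeTsv(out$flags$flagged, f2)
  .writeManifest(dir, c(f1, f2))
}
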