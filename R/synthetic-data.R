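#' @importFrom stats rnorm rpois rbinom runif rlnorm median setNames rbeta
NULL

## Deterministic substream seeds derived from one global integer seed.
## Kept below 2^31 - 1 so set.seed() always accepts them.
.substream <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset * 16807) %% 2147483647)
}

.truncNoise <- function(n, sd, floor = 0.05) {
  ## symmetric multiplicative noise: mean = median = 1 (truncation at `floor`
  ## is > 3 s.d. away for all default dispersions, so skew is negligible)
  x <- rnorm(n, mean = 1, sd = sd)
  bad <- which(x < floor)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean = 1, sd = sd[bad])
    bad <- bad[x[bad] < floor]
  }
  x
}

#' Generate a synthetic gene catalog
#'
#' Genes are stratified over 10-Mb bins (round-robin assignment, uniform
#' placement within a bin) so that every 10-Mb interval of every chromosome is
#' populated. Baseline expression is log-normal (meanlog 4, sdlog 1), truncated
#' below at TPM 10 so the large majority of genes clear the TPM > 25 analysis
#' floor. Per-gene dispersion (the s.d. of symmetric multiplicative expression
#' noise) is drawn uniformly on \code{dispersionRange}.
#'
#' @param nChromosomes Number of chromosomes (>= 2).
#' @param chromLength Chromosome length in bp (default 100 Mb).
#' @param genesPerChromosome Genes per chromosome (>= 20).
#' @param seed Integer seed; identical seeds give identical catalogs.
#' @param tpmMeanlog,tpmSdlog Log-normal parameters of baseline TPM.
#' @param tpmTruncate Lower truncation of baseline TPM.
#' @param dispersionRange Range of per-gene noise s.d.
#' @param xChromosome Optional chromosome name to flag as the X analogue
#'   (its genes are exempt from the allelic-balance filter).
#' @return A \linkS4class{GeneCatalog}.
#' @export
generateGeneCatalog <- function(nChromosomes = 5, chromLength = 1e8,
                                genesPerChromosome = 100, seed = 1,
                                tpmMeanlog = 4, tpmSdlog = 1,
                                tpmTruncate = 10,
                                dispersionRange = c(0.1, 0.3),
                                xChromosome = NULL) {
  if (nChromosomes < 2 || genesPerChromosome < 20 || chromLength <= 0) {
    stop("sizing error: need nChromosomes >= 2, genesPerChromosome >= 20, ",
         "positive chromLength")
  }
  set.seed(.substream(seed, 1L))
  chroms <- paste0("chr", seq_len(nChromosomes))
  binSize <- 1e7
  nBins <- max(1L, as.integer(ceiling(chromLength / binSize)))
  perChrom <- lapply(chroms, function(ch) {
    bins <- rep(seq_len(nBins) - 1L, length.out = genesPerChromosome)
    lo <- pmin(bins * binSize, chromLength - 1)
    hi <- pmin((bins + 1) * binSize, chromLength)
    mids <- floor(runif(genesPerChromosome, lo, hi))
    w <- pmax(1000L, as.integer(runif(genesPerChromosome, 1e3, 1e5)))
    start <- pmax(0, mids - w %/% 2)
    end <- pmin(chromLength, start + w)
    ord <- order(start)
    data.frame(chrom = ch, start = start[ord], end = end[ord])
  })
  df <- do.call(rbind, perChrom)
  n <- nrow(df)
  tpm <- rlnorm(n, tpmMeanlog, tpmSdlog)
  low <- which(tpm < tpmTruncate)
  while (length(low)) {
    tpm[low] <- rlnorm(length(low), tpmMeanlog, tpmSdlog)
    low <- low[tpm[low] < tpmTruncate]
  }
  disp <- runif(n, dispersionRange[1], dispersionRange[2])
  gr <- GRanges(df$chrom,
                IRanges::IRanges(start = df$start + 1L, end = df$end),
                seqinfo = GenomeInfoDb::Seqinfo(chroms,
                                                rep(chromLength, nChromosomes)))
  mcols(gr)$gene_id <- sprintf("g%s_%03d", sub("^chr", "", df$chrom),
                               unlist(lapply(perChrom, function(x)
                                 seq_len(nrow(x)))))
  mcols(gr)$mean_tpm <- tpm
  mcols(gr)$dispersion <- disp
  mcols(gr)$x_linked <- as.character(seqnames(gr)) %in% xChromosome
  GeneCatalog(gr)
}

.normalizeDosage <- function(catalog, dosage) {
  chroms <- GenomeInfoDb::seqlevels(catalog)
  full <- matrix(0.5, nrow = length(chroms), ncol = 2,
                 dimnames = list(chroms, c("A", "B")))
  if (!is.null(dosage)) {
    unknown <- setdiff(names(dosage), chroms)
    if (length(unknown)) {
      stop("dosage references unknown chromosome(s): ",
           paste(unknown, collapse = ", "))
    }
    for (ch in names(dosage)) {
      d <- dosage[[ch]]
      if (length(d) != 2 || any(d < 0)) {
        stop("dosage for ", ch, " must be two non-negative values (A, B)")
      }
      full[ch, ] <- as.numeric(d)
    }
  }
  full
}

## One cell's assay columns; all randomness from the current RNG state.
.simulateCellColumns <- function(catalog, dosageMat, depth) {
  chrom <- as.character(seqnames(catalog))
  dA <- dosageMat[chrom, "A"]
  dB <- dosageMat[chrom, "B"]
  scale <- dA + dB
  mu <- mcols(catalog)$mean_tpm
  noise <- .truncNoise(length(mu), mcols(catalog)$dispersion)
  expr <- mu * scale * noise
  tpm <- if (sum(expr) > 0) expr / sum(expr) * 1e6 else expr
  reads <- rpois(length(mu), depth * expr / mean(mu))
  pA <- ifelse(scale > 0, dA / pmax(scale, .Machine$double.eps), 0)
  hapA <- rbinom(length(mu), reads, pA)
  list(tpm = tpm, hapA = hapA, hapB = reads - hapA, reads = reads)
}

.bindCells <- function(catalog, cells, colData, metadata = list()) {
  pull <- function(f) do.call(cbind, lapply(cells, `[[`, f))
  CellFamilyExperiment(tpm = pull("tpm"), hapA = pull("hapA"),
                       hapB = pull("hapB"), reads = pull("reads"),
                       catalog = catalog, colData = colData,
                       metadata = metadata)
}

#' Simulate one cell's expression table
#'
#' Per-gene expected expression scales linearly with total dosage (disomic
#' baseline is 0.5 + 0.5 normalized yield units per haplotype); haplotype read
#' counts are binomial with success probability equal to the haplotype's share
#' of the dosage; total per-gene reads are Poisson around \code{depth} scaled
#' by relative expression; the TPM column is renormalized to sum 1e6.
#'
#' @param catalog \linkS4class{GeneCatalog}.
#' @param dosage Named list: chromosome -> c(A, B) per-haplotype yields.
#'   Chromosomes not named are disomic c(0.5, 0.5).
#' @param depth Mean reads per gene in a disomic cell.
#' @param seed Integer seed.
#' @param cellId,role,familyId,generation Cell annotation.
#' @return A one-column \linkS4class{CellFamilyExperiment}.
#' @export
simulateCell <- function(catalog, dosage = NULL, depth = 100, seed = 1,
                         cellId = "cell1", role = "control",
                         familyId = NA_character_,
                         generation = NA_integer_) {
  dosageMat <- .normalizeDosage(catalog, dosage)
  set.seed(.substream(seed, 2L))
  cell <- .simulateCellColumns(catalog, dosageMat, depth)
  cd <- DataFrame(cell_id = cellId, role = role, family_id = familyId,
                  generation = as.integer(generation))
  .bindCells(catalog, list(cell), cd)
}

#' Simulate a control-cell cohort
#'
#' Disomic cells with role \code{"control"}.
#'
#' @inheritParams simulateCell
#' @param nControl Number of control cells.
#' @return A \linkS4class{CellFamilyExperiment} with \code{nControl} columns.
#' @export
simulateControls <- function(catalog, nControl = 30, depth = 100, seed = 1) {
  if (nControl < 1) stop("sizing error: nControl must be >= 1")
  dosageMat <- .normalizeDosage(catalog, NULL)
  set.seed(.substream(seed, 3L))
  cells <- lapply(seq_len(nControl), function(i)
    .simulateCellColumns(catalog, dosageMat, depth))
  cd <- DataFrame(cell_id = sprintf("ctrl%03d", seq_len(nControl)),
                  role = "control", family_id = NA_character_,
                  generation = NA_integer_)
  .bindCells(catalog, cells, cd)
}

#' Describe a mis-segregation scenario
#'
#' @param chromosome Chromosome carrying the micronucleus chromatid.
#' @param haplotype "A" or "B": the parental haplotype in the micronucleus.
#' @param pattern "1:3" (monosomic sister, trisomic MN cell) or "2:2".
#' @param generation 1 (MN cell + sister) or 2 (daughters + nieces).
#' @param a MN-chromatid transcriptional yield in normalized per-homologue
#'   units, in [0, 0.5] (0.5 = fully normal single chromatid).
#' @param split Generation 2 only: fraction of the MN chromatid's output
#'   re-incorporated in daughter 1, in [0, 1].
#' @return A validated scenario list.
#' @export
segregationScenario <- function(chromosome, haplotype = c("A", "B"),
                                pattern = c("1:3", "2:2"),
                                generation = 1L, a = 0, split = NA_real_) {
  haplotype <- match.arg(haplotype)
  pattern <- match.arg(pattern)
  generation <- as.integer(generation)
  if (!generation %in% c(1L, 2L)) stop("generation must be 1 or 2")
  if (a < 0 || a > 0.5) stop("MN chromatid yield 'a' must lie in [0, 0.5]")
  if (generation == 2L) {
    if (is.na(split) || split < 0 || split > 1) {
      stop("generation-2 scenarios need a reincorporation 'split' in [0, 1]")
    }
  } else if (!is.na(split)) {
    stop("'split' is defined only for generation 2")
  }
  list(chromosome = chromosome, haplotype = haplotype, pattern = pattern,
       generation = generation, a = a, split = split)
}

.scenarioDosages <- function(scenario) {
  h <- scenario$haplotype
  o <- setdiff(c("A", "B"), h)
  a <- scenario$a
  hapDose <- function(yh) {
    d <- c(0.5, 0.5)
    names(d) <- c(h, o)
    d[h] <- yh
    d[c("A", "B")]
  }
  ch <- scenario$chromosome
  if (scenario$generation == 1L) {
    if (scenario$pattern == "1:3") {
      list(mn_cell = setNames(list(hapDose(0.5 + a)), ch),
           mn_sister = setNames(list(hapDose(0)), ch))
    } else {
      list(mn_cell = setNames(list(hapDose(a)), ch),
           mn_sister = NULL)
    }
  } else {
    s <- scenario$split
    if (scenario$pattern == "1:3") {
      list(mn_daughter1 = setNames(list(hapDose(0.5 + a * s)), ch),
           mn_daughter2 = setNames(list(hapDose(0.5 + a * (1 - s))), ch),
           mn_niece1 = setNames(list(hapDose(0)), ch),
           mn_niece2 = setNames(list(hapDose(0)), ch))
    } else {
      list(mn_daughter1 = setNames(list(hapDose(a * s)), ch),
           mn_daughter2 = setNames(list(hapDose(a * (1 - s))), ch),
           mn_niece1 = NULL, mn_niece2 = NULL)
    }
  }
}

#' Simulate a micronucleation family plus a control cohort
#'
#' Generation 1 produces an MN cell and its sister; generation 2 produces two
#' MN daughters and (optionally) two nieces. Per-role haplotype dosages follow
#' the segregation geometry: a 1:3 mis-segregation makes the sister (or both
#' nieces) nullisomic for the MN haplotype while the MN lineage carries
#' 0.5 + a; a 2:2 segregation leaves non-MN cells disomic while the MN lineage
#' carries only the MN chromatid's yield a (split across daughters in
#' generation 2). The ground-truth scenario is stored in the family metadata.
#'
#' @inheritParams simulateCell
#' @param scenario A \code{\link{segregationScenario}}.
#' @param nControl Control cells simulated alongside.
#' @param familyId Family identifier.
#' @param includeNieces Include niece cells for generation-2 families.
#' @return List with elements \code{family} and \code{controls}, both
#'   \linkS4class{CellFamilyExperiment}s.
#' @export
simulateFamily <- function(catalog, scenario, nControl = 30, depth = 100,
                           seed = 1, familyId = "F1", includeNieces = TRUE) {
  dosages <- .scenarioDosages(scenario)
  if (scenario$generation == 2L && !includeNieces) {
    dosages <- dosages[!grepl("niece", names(dosages))]
  }
  set.seed(.substream(seed, 4L))
  cells <- lapply(dosages, function(d)
    .simulateCellColumns(catalog, .normalizeDosage(catalog, d), depth))
  role <- sub("[0-9]+$", "", names(dosages))
  cd <- DataFrame(cell_id = paste0(familyId, "_", names(dosages)),
                  role = role, family_id = familyId,
                  generation = scenario$generation)
  family <- .bindCells(catalog, cells, cd,
                       metadata = list(scenario = scenario))
  controls <- if (nControl > 0) {
    simulateControls(catalog, nControl = nControl, depth = depth,
                     seed = .substream(seed, 5L))
  }
  list(family = family, controls = controls)
}

#' Simulate clone ATAC-seq data with an injected suppressed interval
#'
#' Peaks are placed uniformly along a synthetic genome with GC fractions in
#' [0.2, 0.8]; per-peak baseline accessibility depends smoothly on GC (so
#' GC-matched background selection is meaningful) with an independent
#' log-normal peak effect. Fragment counts are Poisson around the baseline
#' scaled by a per-clone size factor and the local DNA copy number; counts of
#' case clones inside \code{suppressedInterval} are multiplied by
#' \code{suppressionFactor} before Poisson sampling.
#'
#' @param nPeaks Total number of peaks (>= 500).
#' @param nControlClones,nCaseClones Clone counts.
#' @param suppressedInterval List or vector with chrom, start, end.
#' @param suppressionFactor Multiplier in (0, 1]; 1 simulates the null.
#' @param seed Integer seed.
#' @param nChromosomes,chromLength Genome geometry.
#' @param meanCount Baseline mean fragment count per peak.
#' @param cloneSizeSd Log-normal s.d. of per-clone library size factors.
#' @param cnLoss Optional list(samples, chrom, start, end, cn) injecting a
#'   copy-number change into the named samples.
#' @return List: \code{peaks} (GRanges with gc), \code{counts} (peak x sample
#'   matrix), \code{cn} (named list of copy-number GRanges, 250-kb bins),
#'   \code{samples} (DataFrame with sample_id, group), \code{truth}.
#' @export
simulateAtacClones <- function(nPeaks = 5000, nControlClones = 10,
                               nCaseClones = 12,
                               suppressedInterval = list(chrom = "chr1",
                                                         start = 2e7,
                                                         end = 3e7),
                               suppressionFactor = 0.5, seed = 1,
                               nChromosomes = 5, chromLength = 1e8,
                               meanCount = 100, cloneSizeSd = 0.2,
                               cnLoss = NULL) {
  if (nPeaks < 500) stop("sizing error: need nPeaks >= 500")
  if (suppressionFactor <= 0 || suppressionFactor > 1) {
    stop("suppressionFactor must be in (0, 1]")
  }
  si <- as.list(suppressedInterval)
  chroms <- paste0("chr", seq_len(nChromosomes))
  if (!si$chrom %in% chroms ||
      as.numeric(si$start) < 0 || as.numeric(si$end) > chromLength) {
    stop("suppressed interval lies outside the simulated genome")
  }
  set.seed(.substream(seed, 6L))
  perChrom <- rep(nPeaks %/% nChromosomes, nChromosomes)
  perChrom[seq_len(nPeaks %% nChromosomes)] <-
    perChrom[seq_len(nPeaks %% nChromosomes)] + 1L
  pos <- unlist(lapply(seq_len(nChromosomes), function(i)
    sort(floor(runif(perChrom[i], 150, chromLength - 150)))))
  peaks <- GRanges(rep(chroms, perChrom),
                   IRanges::IRanges(start = pos - 149L, width = 300L),
                   seqinfo = GenomeInfoDb::Seqinfo(chroms,
                                                   rep(chromLength,
                                                       nChromosomes)))
  gc <- 0.2 + 0.6 * rbeta(nPeaks, 2, 2)
  mcols(peaks)$gc <- gc
  mcols(peaks)$peak_id <- sprintf("peak%05d", seq_len(nPeaks))
  ## accessibility: smooth GC dependence plus a peak-specific effect
  lambda <- meanCount * exp(1.2 * (gc - 0.5)) * rlnorm(nPeaks, 0, 0.5)

  samples <- DataFrame(
    sample_id = c(sprintf("ctrl_clone%02d", seq_len(nControlClones)),
                  sprintf("case_clone%02d", seq_len(nCaseClones))),
    group = rep(c("control", "case"), c(nControlClones, nCaseClones)))
  nS <- nrow(samples)
  sizeFac <- rlnorm(nS, 0, cloneSizeSd)

  inInterval <- as.character(seqnames(peaks)) == si$chrom &
    mid(IRanges::ranges(peaks)) >= as.numeric(si$start) &
    mid(IRanges::ranges(peaks)) < as.numeric(si$end)

  cn <- .makeCnTracks(chroms, chromLength, samples$sample_id, cnLoss)
  cnPerPeak <- vapply(samples$sample_id, function(s) {
    .lookupCn(peaks, cn[[s]])
  }, numeric(nPeaks))

  counts <- matrix(0L, nPeaks, nS,
                   dimnames = list(mcols(peaks)$peak_id, samples$sample_id))
  for (j in seq_len(nS)) {
    supp <- rep(1, nPeaks)
    if (samples$group[j] == "case") supp[inInterval] <- suppressionFactor
    mu <- lambda * sizeFac[j] * (cnPerPeak[, j] / 2) * supp
    counts[, j] <- rpois(nPeaks, mu)
  }
  list(peaks = peaks, counts = counts, cn = cn, samples = samples,
       truth = list(interval = si, suppressionFactor = suppressionFactor,
                    nPeaksInInterval = sum(inInterval)))
}

.makeCnTracks <- function(chroms, chromLength, sampleIds, cnLoss,
                          binSize = 250000) {
  tile <- GenomicRanges::tileGenome(
    setNames(rep(chromLength, length(chroms)), chroms),
    tilewidth = binSize, cut.last.tile.in.chrom = TRUE)
  out <- lapply(sampleIds, function(s) {
    g <- tile
    mcols(g)$cn <- 2
    g
  })
  names(out) <- sampleIds
  if (!is.null(cnLoss)) {
    hit <- GRanges(cnLoss$chrom,
                   IRanges::IRanges(cnLoss$start + 1, cnLoss$end))
    for (s in cnLoss$samples) {
      if (!s %in% sampleIds) stop("cnLoss sample not simulated: ", s)
      ov <- IRanges::overlapsAny(out[[s]], hit)
      mcols(out[[s]])$cn[ov] <- cnLoss$cn
    }
  }
  out
}

.lookupCn <- function(peaks, cnTrack) {
  mids <- GRanges(seqnames(peaks),
                  IRanges::IRanges(mid(IRanges::ranges(peaks)), width = 1L))
  hits <- GenomicRanges::findOverlaps(mids, cnTrack, select = "first")
  cn <- rep(NA_real_, length(peaks))
  ok <- !is.na(hits)
  cn[ok] <- mcols(cnTrack)$cn[hits[ok]]
  cn
}
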