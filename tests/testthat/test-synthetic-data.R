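test_that("gene catalogs conserve counts, spread over bins, and are reproducible", {
  cat2 <- generateGeneCatalog(2, 1e8, 100, seed = 1)
  expect_length(cat2, 200)
  expect_false(anyDuplicated(S4Vectors::mcols(cat2)$gene_id) > 0)
  expect_identical(cat2, generateGeneCatalog(2, 1e8, 100, seed = 1))
  # every 10-Mb bin of every chromosome holds at least one gene
  cat5 <- generateGeneCatalog(5, 1e8, 200, seed = 7)
  mids <- GenomicRanges::start(cat5) +
    floor(GenomicRanges::width(cat5) / 2)
  bins <- paste(GenomicRanges::seqnames(cat5), (mids - 1) %/% 1e7)
  expect_length(unique(bins), 5 * 10)
  # majority of baseline TPMs clear the analysis floor
  expect_gt(mean(S4Vectors::mcols(cat5)$mean_tpm > 25), 0.8)
  expect_error(generateGeneCatalog(1, 1e8, 100), "sizing")
  expect_error(generateGeneCatalog(5, 1e8, 10), "sizing")
})

test_that("simulated cells follow the dosage model", {
  cat0 <- .fx$catalog
  # disomic: expected allele fraction 1/2; zero dosage: zero counts
  cell <- simulateCell(cat0, seed = 3)
  hapA <- SummarizedExperiment::assay(cell, "hapA")
  reads <- SummarizedExperiment::assay(cell, "reads")
  expect_equal(sum(hapA) / sum(reads), 0.5, tolerance = 0.02)
  expect_equal(sum(SummarizedExperiment::assay(cell, "tpm")), 1e6,
               tolerance = 1)
  lost <- simulateCell(cat0, dosage = list(chr1 = c(0.5, 0)), seed = 4)
  onChr1 <- as.character(GenomicRanges::seqnames(
    SummarizedExperiment::rowRanges(lost))) == "chr1"
  expect_true(all(SummarizedExperiment::assay(lost, "hapB")[onChr1, ] == 0))
  # trisomy with duplicated A: expected f_A = 2/3
  tri <- simulateCell(cat0, dosage = list(chr2 = c(1.0, 0.5)), seed = 5)
  onChr2 <- as.character(GenomicRanges::seqnames(
    SummarizedExperiment::rowRanges(tri))) == "chr2"
  fA <- sum(SummarizedExperiment::assay(tri, "hapA")[onChr2, ]) /
    sum(SummarizedExperiment::assay(tri, "reads")[onChr2, ])
  expect_equal(fA, 2 / 3, tolerance = 0.03)
  expect_error(simulateCell(cat0, dosage = list(chrZ = c(1, 1))), "chrZ")
  expect_identical(SummarizedExperiment::assay(simulateCell(cat0, seed = 3),
                                               "tpm"),
                   SummarizedExperiment::assay(cell, "tpm"))
})

test_that("mean simulated allele fraction stays within binomial error", {
  # >= 1e4 gene observations per dosage map
  bigCat <- generateGeneCatalog(5, 1e8, 400, seed = 11)
  for (dos in list(c(0.5, 0.5), c(1.0, 0.5), c(0.25, 0.5))) {
    cells <- lapply(1:5, function(i)
      simulateCell(bigCat, dosage = list(chr1 = dos, chr2 = dos, chr3 = dos,
                                         chr4 = dos, chr5 = dos),
                   seed = 100 + i, cellId = paste0("c", i)))
    hapA <- Reduce(`+`, lapply(cells, function(x)
      sum(SummarizedExperiment::assay(x, "hapA"))))
    n <- Reduce(`+`, lapply(cells, function(x)
      sum(SummarizedExperiment::assay(x, "reads"))))
    p <- dos[1] / sum(dos)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(hapA / n - p), 3 * se + 1e-12)
  }
})

test_that("family geometries set the role dosages of the scenario", {
  # 1:3, a = 0: the sister is nullisomic for the MN haplotype and the MN
  # cell keeps one transcribing copy
  sim <- simulateFamily(.fx$catalog,
                        segregationScenario("chr3", "B", "1:3", 1, a = 0),
                        nControl = 5, seed = 6)
  fam <- sim$family
  onChr3 <- as.character(GenomicRanges::seqnames(
    SummarizedExperiment::rowRanges(fam))) == "chr3"
  sis <- which(cellRoles(fam) == "mn_sister")
  expect_true(all(SummarizedExperiment::assay(fam, "hapB")[onChr3, sis] == 0))
  mn <- which(cellRoles(fam) == "mn_cell")
  fB <- sum(SummarizedExperiment::assay(fam, "hapB")[onChr3, mn]) /
    sum(SummarizedExperiment::assay(fam, "reads")[onChr3, mn])
  expect_equal(fB, 0.5, tolerance = 0.03)
  expect_equal(ncol(sim$controls), 5)
  # 2:2 gen 2, a = 0.5, split = 1: daughter 2 holds nothing of the MN
  # haplotype, daughter 1 looks disomic
  sim2 <- simulateFamily(.fx$catalog,
                         segregationScenario("chr2", "A", "2:2", 2,
                                             a = 0.5, split = 1),
                         nControl = 0, seed = 7)
  fam2 <- sim2$family
  onChr2 <- as.character(GenomicRanges::seqnames(
    SummarizedExperiment::rowRanges(fam2))) == "chr2"
  d2 <- which(colnames(fam2) == "F1_mn_daughter2")
  expect_true(all(SummarizedExperiment::assay(fam2, "hapA")[onChr2, d2] == 0))
  d1 <- which(colnames(fam2) == "F1_mn_daughter1")
  f1 <- sum(SummarizedExperiment::assay(fam2, "hapA")[onChr2, d1]) /
    sum(SummarizedExperiment::assay(fam2, "reads")[onChr2, d1])
  expect_equal(f1, 0.5, tolerance = 0.03)
})

test_that("combined daughter yield matches the simulated chromatid yield", {
  # averaged over families, total MN-haplotype output of both daughters
  # recovers a = 0.3
  tots <- vapply(1:60, function(i) {
    sim <- simulateFamily(.fx$catalog,
                          segregationScenario("chr4", "B", "2:2", 2,
                                              a = 0.3, split = 0.5),
                          nControl = 0, seed = 800 + i,
                          includeNieces = FALSE)
    fam <- sim$family
    onChr4 <- as.character(GenomicRanges::seqnames(
      SummarizedExperiment::rowRanges(fam))) == "chr4"
    hapB <- SummarizedExperiment::assay(fam, "hapB")[onChr4, ]
    reads <- SummarizedExperiment::assay(fam, "reads")[onChr4, ]
    tpm <- SummarizedExperiment::assay(fam, "tpm")
    # raw per-haplotype yield proxy: chromosome share of reads x allele frac
    sum(hapB) / sum(reads)
  }, numeric(1))
  # both daughters carry 0.5 normal + 0.15 MN haplotype: f_B = 0.3/1.3
  expect_equal(mean(tots), 0.3 / 1.3, tolerance = 0.02)
})

test_that("scenario validation enforces the geometry invariants", {
  expect_error(segregationScenario("chr1", "A", "1:3", 1, a = 0.6), "0, 0.5")
  expect_error(segregationScenario("chr1", "A", "1:3", 1, a = 0, split = 0.5),
               "generation 2")
  expect_error(segregationScenario("chr1", "A", "1:3", 2, a = 0), "split")
})

test_that("ATAC clone simulation injects a recoverable suppression", {
  sim <- simulateAtacClones(nPeaks = 1200, nControlClones = 4,
                            nCaseClones = 4,
                            suppressedInterval = list(chrom = "chr1",
                                                      start = 1e7, end = 2e7),
                            suppressionFactor = 0.5, seed = 3,
                            nChromosomes = 2, chromLength = 5e7)
  expect_gte(sim$truth$nPeaksInInterval, 100)  # >= 10 peaks per Mb
  gc <- S4Vectors::mcols(sim$peaks)$gc
  expect_true(all(gc >= 0.2 & gc <= 0.8))
  inIv <- as.character(GenomicRanges::seqnames(sim$peaks)) == "chr1" &
    GenomicRanges::start(sim$peaks) >= 1e7 &
    GenomicRanges::end(sim$peaks) <= 2e7
  caseIds <- sim$samples$sample_id[sim$samples$group == "case"]
  ctrlIds <- sim$samples$sample_id[sim$samples$group == "control"]
  # library size cancels in the within-sample interval/genome contrast
  relCase <- mean(colSums(sim$counts[inIv, caseIds]) /
                    colSums(sim$counts[!inIv, caseIds]))
  relCtrl <- mean(colSums(sim$counts[inIv, ctrlIds]) /
                    colSums(sim$counts[!inIv, ctrlIds]))
  expect_equal(relCase / relCtrl, 0.5, tolerance = 0.06)
  expect_error(simulateAtacClones(suppressedInterval = list(
    chrom = "chr9", start = 0, end = 1e7)), "outside")
  expect_error(simulateAtacClones(suppressionFactor = 1.5), "suppressionFactor")
  # identical seeds give identical matrices
  sim2 <- simulateAtacClones(nPeaks = 1200, nControlClones = 4,
                             nCaseClones = 4,
                             suppressedInterval = list(chrom = "chr1",
                                                       start = 1e7,
                                                       end = 2e7),
                             suppressionFactor = 0.5, seed = 3,
                             nChromosomes = 2, chromLength = 5e7)
  expect_identical(sim$counts, sim2$counts)
})

test_that("injected copy-number loss halves counts but not per-copy density", {
  sim <- simulateAtacClones(nPeaks = 1000, nControlClones = 3, nCaseClones = 3,
                            suppressedInterval = list(chrom = "chr1",
                                                      start = 1e7, end = 2e7),
                            suppressionFactor = 1, seed = 8,
                            nChromosomes = 2, chromLength = 5e7,
                            cnLoss = list(samples = "case_clone01",
                                          chrom = "chr2", start = 0,
                                          end = 1e7, cn = 1))
  norm <- normalizeAtacCounts(sim$counts, sim$peaks, sim$cn)
  inLoss <- as.character(GenomicRanges::seqnames(sim$peaks)) == "chr2" &
    GenomicRanges::end(sim$peaks) <= 1e7
  # raw counts halved in the CN-1 region of the affected clone
  rawRatio <- median(sim$counts[inLoss, "case_clone01"] /
                       pmax(1, sim$counts[inLoss, "case_clone02"]))
  expect_lt(rawRatio, 0.65)
  # per-copy normalized density is restored (joint quantile normalization
  # redistributes a few per cent when 10% of one sample's genome is shifted)
  normRatio <- median(norm[inLoss, "case_clone01"] /
                        norm[inLoss, "case_clone02"], na.rm = TRUE)
  expect_equal(normRatio, 1, tolerance = 0.12)
})
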