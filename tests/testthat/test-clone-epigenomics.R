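# Small ATAC fixture shared within this file.
.atac <- local({
  sim <- simulateAtacClones(nPeaks = 2000, nControlClones = 6, nCaseClones = 4,
                            suppressedInterval = list(chrom = "chr1",
                                                      start = 1e7, end = 2e7),
                            suppressionFactor = 0.5, seed = 5,
                            nChromosomes = 2, chromLength = 5e7)
  norm <- normalizeAtacCounts(sim$counts, sim$peaks, sim$cn)
  ctrl <- sim$samples$sample_id[sim$samples$group == "control"]
  meanAccess <- rowMeans(norm[, ctrl])
  bg <- selectBackgroundPeaks(sim$peaks, meanAccess, k = 50, seed = 6)
  list(sim = sim, norm = norm, ctrl = ctrl, meanAccess = meanAccess, bg = bg)
})

test_that("peak merging is transitive with a strict 400-bp gap rule", {
  gr <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(start = c(1000, 1600, 5000, 5701, 9000, 9600, 10200),
                     width = 300),
    gc = c(0.4, 0.6, 0.5, 0.5, 0.3, 0.5, 0.7))
  # gaps: 300 (merge), 400 (merge), then a 300-300 chain (transitive)
  m <- mergePeaks(gr)
  expect_equal(length(m), 4)
  expect_equal(S4Vectors::mcols(m)$n_merged, c(2L, 1L, 1L, 3L))
  # merged GC is the length-weighted mean (equal widths here)
  expect_equal(S4Vectors::mcols(m)$gc[1], 0.5)
  expect_equal(S4Vectors::mcols(m)$gc[4], 0.5)
  # 401-bp gaps stay separate
  gr2 <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = c(1000, 1701), width = 300),
    gc = c(0.4, 0.6))
  expect_equal(length(mergePeaks(gr2)), 2)
  # post-merge peaks are pairwise more than 400 bp apart
  gaps <- GenomicRanges::start(m)[-1] - GenomicRanges::end(m)[-length(m)] - 1
  expect_true(all(gaps[gaps > 0] > 400))
  expect_warning(mergePeaks(rev(gr)), "unsorted")
})

test_that("normalization equalizes columns and corrects copy number", {
  # identical columns are unchanged by quantile normalization
  x <- matrix(rpois(600, 50), 200, 3)
  x[, 2] <- x[, 1]; x[, 3] <- x[, 1]
  peaks <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = seq(1, by = 1000, length.out = 200),
                             width = 300), gc = runif(200, 0.2, 0.8))
  GenomeInfoDb::seqlengths(peaks) <- 2.5e5 + 1e3
  colnames(x) <- c("s1", "s2", "s3")
  norm <- normalizeAtacCounts(x, peaks)
  expect_equal(norm, x, ignore_attr = TRUE)
  # rank order within each sample is preserved
  y <- matrix(rpois(600, 80), 200, 3, dimnames = list(NULL, c("s1", "s2", "s3")))
  ny <- normalizeAtacCounts(y, peaks)
  for (j in 1:3) expect_equal(order(ny[, j]), order(y[, j]))
  # a copy-number-1 region doubles the per-copy density; CN 0 is masked
  cn <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 100001, 200001),
                             c(100000, 200000, 251000)),
    cn = c(1, 2, 0))
  n2 <- normalizeAtacCounts(y, peaks, cnTracks = list(s1 = cn))
  inCn1 <- GenomicRanges::start(peaks) <= 1e5
  inCn0 <- GenomicRanges::start(peaks) > 2e5
  base <- normalizeAtacCounts(y, peaks)
  expect_equal(n2[inCn1, "s1"], 2 * base[inCn1, "s1"])
  expect_true(all(is.na(n2[inCn0, "s1"])))
  expect_equal(n2[, "s2"], base[, "s2"])
})

test_that("background peaks are matched, self-free and of size k", {
  bg <- .atac$bg
  expect_equal(ncol(bg), 50)
  expect_false(any(bg == row(bg)))
  # matched sets track the anchor's GC closely
  gc <- S4Vectors::mcols(.atac$sim$peaks)$gc
  gcDiff <- abs(rowMeans(matrix(gc[bg], nrow(bg))) - gc)
  expect_lt(mean(gcDiff), 0.02)
  expect_lt(stats::quantile(gcDiff, 0.95), 0.05)
  expect_error(selectBackgroundPeaks(.atac$sim$peaks[1:100],
                                     .atac$meanAccess[1:100], k = 50),
               "need >= 500")
})

test_that("the interval permutation test recovers injected suppression", {
  iv <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1e7 + 1, 2e7))
  case <- .atac$sim$samples$sample_id[.atac$sim$samples$group == "case"][1]
  res <- intervalPermutationTest(.atac$norm[, case], .atac$sim$peaks, iv,
                                 .atac$bg, nPerm = 2000, seed = 7)
  expect_true(res$eligible)
  # joint quantile normalization compresses the contrast slightly (10% of
  # the genome is suppressed in case clones), so the recovered fold change
  # sits a little above the injected 0.5
  expect_equal(res$fold_change, 0.5, tolerance = 0.12)
  expect_equal(res$p, 1 / 2001)   # attainable floor
  # permutation-space arithmetic: k^n_peaks
  expect_equal(res$perm_space, 50^res$n_peaks)
  # an interval holding exactly 10 peaks with k = 50 spans ~9.8e16
  on2 <- which(as.character(GenomicRanges::seqnames(.atac$sim$peaks)) ==
                 "chr2")
  iv10 <- GenomicRanges::GRanges(
    "chr2", IRanges::IRanges(GenomicRanges::start(.atac$sim$peaks)[on2[1]],
                             GenomicRanges::end(.atac$sim$peaks)[on2[10]]))
  res10 <- intervalPermutationTest(.atac$norm[, case], .atac$sim$peaks, iv10,
                                   .atac$bg, nPerm = 100, seed = 7)
  expect_equal(res10$n_peaks, 10L)
  expect_equal(res10$perm_space, 9.765625e16)
  # intervals below the per-Mb peak floor are skipped with a reason
  sparse <- GenomicRanges::GRanges("chr2", IRanges::IRanges(1, 1e6))
  resTiny <- intervalPermutationTest(.atac$norm[, case], .atac$sim$peaks,
                                     sparse, .atac$bg, nPerm = 100, seed = 7,
                                     minPeaksPerMb = 1000)
  expect_false(resTiny$eligible)
  expect_match(resTiny$reason, "peaks")
})

test_that("permutation p-values ignore the scale of the counts column", {
  iv <- GenomicRanges::GRanges("chr2", IRanges::IRanges(2e7 + 1, 3e7))
  case <- .atac$sim$samples$sample_id[.atac$sim$samples$group == "case"][2]
  r1 <- intervalPermutationTest(.atac$norm[, case], .atac$sim$peaks, iv,
                                .atac$bg, nPerm = 500, seed = 8)
  r2 <- intervalPermutationTest(7.3 * .atac$norm[, case], .atac$sim$peaks, iv,
                                .atac$bg, nPerm = 500, seed = 8)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$fold_change, r2$fold_change, tolerance = 1e-12)
  # doubling permutations changes only the p resolution, not the fold change
  r3 <- intervalPermutationTest(.atac$norm[, case], .atac$sim$peaks, iv,
                                .atac$bg, nPerm = 1000, seed = 8)
  expect_equal(r1$observed, r3$observed)
  # fold change fluctuates only with the Monte-Carlo error of the null mean
  expect_equal(r1$fold_change, r3$fold_change, tolerance = 0.02)
})

test_that("null interval fold changes centre on one", {
  # a truly null clone set: no suppression anywhere
  sim <- simulateAtacClones(nPeaks = 1500, nControlClones = 5,
                            nCaseClones = 2,
                            suppressedInterval = list(chrom = "chr1",
                                                      start = 1e7,
                                                      end = 2e7),
                            suppressionFactor = 1, seed = 15,
                            nChromosomes = 2, chromLength = 5e7)
  norm <- normalizeAtacCounts(sim$counts, sim$peaks, sim$cn)
  ctrl <- sim$samples$sample_id[sim$samples$group == "control"]
  bg <- selectBackgroundPeaks(sim$peaks, rowMeans(norm[, ctrl]), k = 50,
                              seed = 16)
  case <- sim$samples$sample_id[sim$samples$group == "case"][1]
  scan <- atacIntervalScan(norm[, case], sim$peaks, bg, intervalMb = 5,
                           nPerm = 1000, seed = 17, sampleId = case)
  expect_equal(mean(scan$fold_change[scan$eligible]), 1, tolerance = 0.03)
  expect_gt(min(scan$p[scan$eligible]), 1 / 1001 - 1e-12)
})

test_that("suppression flagging applies the strict 0.70 rule", {
  res <- S4Vectors::DataFrame(
    chrom = "chr1", start = c(0, 1e7, 2e7, 3e7), end = c(1e7, 2e7, 3e7, 4e7),
    n_peaks = 100L, observed = 1, null_mean = 1,
    fold_change = c(0.70, 0.5, 0.69, 0.69),
    p = c(1e-5, 1e-5, 1e-5, 0.5),
    n_perm = 10000L, perm_space = 1e16, eligible = TRUE, reason = "",
    sample_id = "s1")
  fl <- flagSuppressedIntervals(res)
  # exactly 0.70 is not flagged; low fold change with weak p is not flagged
  expect_equal(fl$flagged$start, c(1e7, 2e7))
  expect_equal(nrow(fl$byInterval), 4)
  expect_equal(unname(sort(fl$byInterval$n_flagged)), c(0, 0, 1, 1))
})

test_that("per-copy expression separates dosage from epigenetic suppression", {
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = seq(1, by = 5e5, length.out = 40),
                             width = 1e4))
  tpm <- matrix(100, 40, 4,
                dimnames = list(NULL, c("parental", "same", "cnloss",
                                        "suppressed")))
  # CN loss over the first 10 genes with correspondingly halved expression
  tpm[1:10, "cnloss"] <- 50
  cn1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 5e6), cn = 1)
  cnFull <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 5e6 + 1), c(5e6, 2.1e7)), cn = c(1, 2))
  ratio <- perCopyExpression(tpm, genes,
                             cnTracks = list(cnloss = cnFull),
                             parent = "parental",
                             refGenes = c(rep(FALSE, 10), rep(TRUE, 30)))
  # identical sample: all ratios 1
  expect_equal(unname(ratio[, "same"]), rep(1, 40))
  # halved TPM fully explained by CN 1: per-copy ratio 1 (dosage-explained)
  expect_equal(unname(ratio[, "cnloss"]), rep(1, 40))
  # halved TPM at CN 2 with scaling anchored elsewhere: suppression signature
  tpm2 <- tpm
  tpm2[1:10, "suppressed"] <- 50
  tpm2[11:40, "suppressed"] <- 100
  ratio2 <- perCopyExpression(tpm2, genes, parent = "parental",
                              refGenes = c(rep(FALSE, 10), rep(TRUE, 30)))
  expect_equal(unname(ratio2[1:10, "suppressed"]), rep(0.5, 10))
  expect_equal(unname(ratio2[11:40, "suppressed"]), rep(1, 30))
  # genes outside the CN track are masked with a warning
  cnPart <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1e7), cn = 2)
  expect_warning(r3 <- perCopyExpression(tpm, genes,
                                         cnTracks = list(same = cnPart),
                                         parent = "parental",
                                         refGenes = rep(TRUE, 40)),
                 "masked")
  expect_true(any(is.na(r3[, "same"])))
  expect_error(perCopyExpression(tpm, genes, parent = "nope"), "parental")
})
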