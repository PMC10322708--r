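#' Merge nearby ATAC peaks into a unique peak list
#'
#' Transitively merges peaks lying within \code{gap} bp of each other (default
#' 400); post-merge peaks are pairwise separated by more than \code{gap} bp.
#' The GC fraction of a merged peak is the length-weighted mean of its parts.
#'
#' @param peaks GRanges with a \code{gc} metadata column; if unsorted it is
#'   sorted internally with a warning.
#' @param gap Maximum gap (bp) across which peaks are merged.
#' @return GRanges of merged peaks with gc and n_merged columns.
#' @export
mergePeaks <- function(peaks, gap = 400) {
  if (is.unsorted(order(peaks))) {
    warning("unsorted peak input; sorting internally")
  }
  peaks <- sort(peaks)
  merged <- GenomicRanges::reduce(peaks, min.gapwidth = gap + 1L,
                                  with.revmap = TRUE)
  rev <- mcols(merged)$revmap
  gc <- vapply(seq_along(merged), function(i) {
    idx <- rev[[i]]
    stats::weighted.mean(mcols(peaks)$gc[idx], width(peaks)[idx])
  }, numeric(1))
  mcols(merged)$revmap <- NULL
  mcols(merged)$gc <- gc
  mcols(merged)$n_merged <- lengths(rev)
  mcols(merged)$peak_id <- sprintf("mpeak%05d", seq_along(merged))
  merged
}

#' Quantile-normalize and copy-number-correct an ATAC count matrix
#'
#' Columns are quantile-normalized to a common distribution (all samples
#' jointly), then each peak's value is divided by the local DNA copy number in
#' 250-kb bins relative to the diploid baseline (cn / 2). Peaks falling in
#' copy-number-zero regions (homozygous deletions) are masked (NA), never
#' divided.
#'
#' @param counts Peak x sample numeric matrix.
#' @param peaks GRanges matching the rows.
#' @param cnTracks Named list (by sample) of copy-number GRanges with a
#'   \code{cn} column, or NULL for a uniformly diploid genome.
#' @return Normalized matrix; masked entries are NA.
#' @export
normalizeAtacCounts <- function(counts, peaks, cnTracks = NULL) {
  if (nrow(counts) != length(peaks)) {
    stop("counts rows must match the peak list")
  }
  norm <- limma::normalizeQuantiles(as.matrix(counts))
  dimnames(norm) <- dimnames(counts)
  if (!is.null(cnTracks)) {
    for (s in colnames(norm)) {
      if (!s %in% names(cnTracks)) next
      cn <- .lookupCn(peaks, cnTracks[[s]])
      rel <- cn / 2
      rel[!is.na(cn) & cn == 0] <- NA
      norm[, s] <- norm[, s] / rel
    }
  }
  norm
}

#' Select GC- and accessibility-matched background peaks
#'
#' For every peak, samples \code{k} background peaks from its neighbourhood in
#' standardized (GC, log mean control accessibility) space, with Gaussian
#' kernel weights (bandwidth in standardized units). A peak never draws
#' itself; sampling is with replacement and seeded.
#'
#' @param peaks GRanges with gc.
#' @param meanAccess Mean normalized accessibility per peak in the control
#'   samples.
#' @param k Background peaks per peak (default 50).
#' @param bandwidth Gaussian kernel bandwidth in standardized s.d. units.
#' @param seed Integer seed.
#' @return Integer matrix (nPeaks x k) of background peak indices.
#' @export
selectBackgroundPeaks <- function(peaks, meanAccess, k = 50, bandwidth = 0.1,
                                  seed = 1) {
  n <- length(peaks)
  if (n < 10 * k) {
    stop("too few peaks for background matching: need >= ", 10 * k,
         ", got ", n)
  }
  if (length(meanAccess) != n) stop("meanAccess must match the peak list")
  std <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) return(rep(0, length(v)))
    (v - mean(v)) / s
  }
  z1 <- std(mcols(peaks)$gc)
  z2 <- std(log1p(meanAccess))
  set.seed(.substream(seed, 7L))
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    d2 <- (z1 - z1[i])^2 + (z2 - z2[i])^2
    w <- exp(-d2 / (2 * bandwidth^2))
    w[i] <- 0
    if (sum(w) <= 0) {
      ## isolated peak: fall back to its nearest neighbours
      w[order(d2)[2:(k + 1)]] <- 1
    }
    out[i, ] <- sample.int(n, k, replace = TRUE, prob = w)
  }
  out
}

#' Background-peak permutation test for one genomic interval
#'
#' Builds the null distribution of the interval's mean accessibility by
#' repeatedly substituting every peak in the interval with one of its k
#' matched background peaks, then compares the observed mean density with the
#' null: fold change = observed / null mean, and a one-sided empirical p for
#' suppression with the add-one correction. The size of the permutation space
#' is k^(number of peaks). Intervals with fewer than \code{minPeaksPerMb}
#' peaks per Mb are skipped with a reason.
#'
#' @param density Named or plain numeric vector: one sample's normalized
#'   accessibility per peak.
#' @param peaks GRanges matching \code{density}.
#' @param interval GRanges of length 1.
#' @param background Index matrix from \code{\link{selectBackgroundPeaks}}.
#' @param nPerm Number of permutations (default 1e4).
#' @param seed Integer seed.
#' @param minPeaksPerMb Eligibility floor (default 10).
#' @return One-row DataFrame: chrom, start, end, n_peaks, observed, null_mean,
#'   fold_change, p, n_perm, perm_space, eligible, reason.
#' @export
intervalPermutationTest <- function(density, peaks, interval, background,
                                    nPerm = 1e4, seed = 1,
                                    minPeaksPerMb = 10) {
  if (length(interval) != 1) stop("one interval at a time")
  if (nPerm < 1) stop("nPerm must be >= 1")
  mids <- GRanges(seqnames(peaks),
                  IRanges::IRanges(mid(IRanges::ranges(peaks)), width = 1L))
  idx <- which(IRanges::overlapsAny(mids, interval))
  widthMb <- width(interval) / 1e6
  base <- DataFrame(chrom = as.character(seqnames(interval)),
                    start = start(interval) - 1L, end = end(interval),
                    n_peaks = length(idx))
  minPeaks <- minPeaksPerMb * widthMb
  if (length(idx) < minPeaks) {
    base$observed <- NA_real_; base$null_mean <- NA_real_
    base$fold_change <- NA_real_; base$p <- NA_real_
    base$n_perm <- 0L
    base$perm_space <- NA_real_
    base$eligible <- FALSE
    base$reason <- sprintf("only %d peaks; need >= %d for a %.0f-Mb interval",
                           length(idx), ceiling(minPeaks), widthMb)
    return(base)
  }
  keep <- idx[!is.na(density[idx])]
  obs <- mean(density[keep])
  k <- ncol(background)
  set.seed(.substream(seed, 8L))
  picks <- matrix(sample.int(k, length(keep) * nPerm, replace = TRUE),
                  nrow = length(keep))
  bgIdx <- background[cbind(rep(keep, nPerm), as.vector(picks))]
  nullVals <- colMeans(matrix(density[bgIdx], nrow = length(keep)),
                       na.rm = TRUE)
  nullMean <- mean(nullVals)
  base$observed <- obs
  base$null_mean <- nullMean
  base$fold_change <- obs / nullMean
  base$p <- empiricalP(sum(nullVals <= obs), nPerm)
  base$n_perm <- as.integer(nPerm)
  base$perm_space <- k^length(keep)
  base$eligible <- TRUE
  base$reason <- ""
  base
}

#' Scan a sample's genome in fixed intervals
#'
#' Tiles the genome into non-overlapping intervals anchored at coordinate 0
#' and runs \code{\link{intervalPermutationTest}} on each.
#'
#' @inheritParams intervalPermutationTest
#' @param intervalMb Interval width in Mb (1, 5 or 10).
#' @param sampleId Label recorded in the result.
#' @return DataFrame with one row per interval.
#' @export
atacIntervalScan <- function(density, peaks, background, intervalMb = 10,
                             nPerm = 1e4, seed = 1, sampleId = "sample",
                             minPeaksPerMb = 10) {
  sl <- GenomeInfoDb::seqlengths(peaks)
  if (any(is.na(sl))) stop("peaks need declared seqlengths for tiling")
  tiles <- GenomicRanges::tileGenome(sl, tilewidth = intervalMb * 1e6,
                                     cut.last.tile.in.chrom = TRUE)
  res <- lapply(seq_along(tiles), function(i) {
    intervalPermutationTest(density, peaks, tiles[i], background,
                            nPerm = nPerm, seed = .substream(seed, 100L + i),
                            minPeaksPerMb = minPeaksPerMb)
  })
  out <- do.call(rbind, res)
  out$sample_id <- sampleId
  out
}

#' Flag persistently suppressed intervals
#'
#' Flags intervals whose ATAC fold change is strictly below
#' \code{fcThreshold} (default 0.70) with an empirical p below \code{alpha}.
#' Also reports the cross-clone average fold change per interval.
#'
#' @param results DataFrame rows from \code{\link{atacIntervalScan}} over one
#'   or more samples.
#' @param fcThreshold Fold-change threshold (strict; default 0.70).
#' @param alpha Empirical-p threshold (default 1e-3).
#' @return List: \code{flagged} (subset of results), \code{byInterval}
#'   (per-interval cross-sample mean fold change and flag count).
#' @export
flagSuppressedIntervals <- function(results, fcThreshold = 0.70,
                                    alpha = 1e-3) {
  ok <- results$eligible & !is.na(results$fold_change)
  flag <- ok & results$fold_change < fcThreshold & results$p < alpha
  key <- paste(results$chrom, results$start, results$end)
  agg <- split(seq_len(nrow(results))[ok], key[ok])
  byInterval <- DataFrame(
    interval = names(agg),
    mean_fold_change = vapply(agg, function(i)
      mean(results$fold_change[i]), numeric(1)),
    n_samples = lengths(agg),
    n_flagged = vapply(agg, function(i) sum(flag[i]), numeric(1)))
  list(flagged = results[flag, , drop = FALSE], byInterval = byInterval)
}

#' Per-copy bulk expression ratios relative to a parental sample
#'
#' Scales every sample's TPM column by a constant matching the median
#' expression of a reference gene set (bi-allelically transcribed genes with
#' parental mean TPM between 1 and 1000 by default) to the parental median;
#' divides each gene's scaled TPM by its local DNA copy number (250-kb bins);
#' and reports the ratio to the parental per-copy value. Genes in
#' copy-number-zero regions or outside the track are masked with a warning.
#'
#' @param tpm Gene x sample matrix including the parental column.
#' @param geneRanges GRanges matching the rows.
#' @param cnTracks Named list of per-sample copy-number GRanges (cn column);
#'   samples without a track are assumed diploid.
#' @param parent Column name of the parental reference sample.
#' @param refGenes Optional gene index/logical vector for the scaling set;
#'   default: genes with parental TPM in [1, 1000].
#' @return Gene x sample matrix of per-copy TPM ratios (parent column ~ 1).
#' @export
perCopyExpression <- function(tpm, geneRanges, cnTracks = NULL,
                              parent = "parental", refGenes = NULL) {
  if (!parent %in% colnames(tpm)) stop("parental column not found: ", parent)
  if (nrow(tpm) != length(geneRanges)) stop("tpm rows must match geneRanges")
  if (is.null(refGenes)) {
    refGenes <- tpm[, parent] >= 1 & tpm[, parent] <= 1000
  }
  if (!any(refGenes)) stop("empty reference gene set for global scaling")
  target <- median(tpm[refGenes, parent])
  scaled <- vapply(colnames(tpm), function(s) {
    m <- median(tpm[refGenes, s])
    if (m <= 0) stop("zero median in scaling gene set for sample ", s)
    tpm[, s] * target / m
  }, numeric(nrow(tpm)))
  dimnames(scaled) <- dimnames(tpm)
  perCopy <- scaled
  for (s in colnames(scaled)) {
    cn <- if (!is.null(cnTracks) && s %in% names(cnTracks)) {
      .lookupCn(geneRanges, cnTracks[[s]])
    } else {
      rep(2, nrow(scaled))
    }
    bad <- is.na(cn)
    zero <- !bad & cn == 0
    if (any(bad)) {
      warning(sum(bad), " gene(s) outside the copy-number track of ", s,
              "; masked")
    }
    cnRel <- cn / 2
    cnRel[zero] <- NA
    perCopy[, s] <- scaled[, s] / cnRel
  }
  ratio <- perCopy / perCopy[, parent]
  dimnames(ratio) <- dimnames(tpm)
  ratio
}
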