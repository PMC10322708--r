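.MN_LABELS <- c("0", "1-", "1", "1+", "2")

#' Classify one homologue's transcriptional copy-number state
#'
#' Decision cascade: (i) yield below the nullisomic bound is "0" without a
#' test, since nullisomic transcription should be strictly zero and deviations
#' reflect technical error; (ii) a two-tailed z-test against the one-copy
#' (per-homologue normal) reference — a Bonferroni-corrected p >= alpha keeps
#' the label "1"; (iii) otherwise the yield is tested against the
#' duplicated-homologue (two-copy) reference, giving "2" when consistent;
#' (iv) yields rejected by both neighbouring integer states are intermediate,
#' signed by their position: "1-" below the one-copy mean, "1+" between the
#' one-copy and two-copy means. Yields beyond the two-copy mean are reported
#' as "2" (the label scale is capped there).
#'
#' @param y Observed normalized haplotype-specific transcription.
#' @param muMono,sigmaMono One-copy reference (per-homologue normal).
#' @param muDi,sigmaDi Two-copy (duplicated homologue) reference.
#' @param nTests Bonferroni family size: homologues tested in the cell.
#' @param nullBound Nullisomic bound (default 0.1).
#' @param alpha Significance level on corrected p (default 0.05).
#' @return List: label, z_mono, z_di, p_mono, p_di (corrected).
#' @export
classifyHomologue <- function(y, muMono, sigmaMono, muDi, sigmaDi,
                              nTests = 1, nullBound = 0.1, alpha = 0.05) {
  if (nTests < 1) stop("nTests must be >= 1")
  zMono <- (y - muMono) / sigmaMono
  zDi <- (y - muDi) / sigmaDi
  pMono <- bonferroniCorrect(zTestTwoTailed(y, muMono, sigmaMono), nTests)
  pDi <- bonferroniCorrect(zTestTwoTailed(y, muDi, sigmaDi), nTests)
  label <- if (y < nullBound) {
    pMono <- NA_real_; pDi <- NA_real_
    "0"
  } else if (pMono >= alpha) {
    "1"
  } else if (y < muMono) {
    "1-"
  } else if (pDi >= alpha) {
    "2"
  } else if (y < muDi) {
    "1+"
  } else {
    "2"
  }
  list(label = label, z_mono = zMono, z_di = zDi, p_mono = pMono, p_di = pDi)
}

#' Classify every homologue of every cell
#'
#' Runs \code{\link{classifyHomologue}} on each (chromosome, haplotype) of each
#' cell in a summary table. The Bonferroni family size defaults to the number
#' of homologues tested per cell. Homologues whose label differs from "1" are
#' flagged as candidate aberrations.
#'
#' @param summaries DataFrame from \code{\link{cellSummaries}}.
#' @param ref \linkS4class{ReferenceDistribution}.
#' @param aneuRef \linkS4class{AneuploidReference}.
#' @param nTests Bonferroni family size; default 2 x chromosomes per cell.
#' @param alpha Significance level (default 0.05).
#' @return DataFrame: cell_id, chrom, haplotype, yield, label, p_mono, p_di,
#'   flagged.
#' @export
classifyCell <- function(summaries, ref, aneuRef, nTests = NULL,
                         alpha = 0.05) {
  rs <- referenceStats(ref)
  tri <- aneuRef@trisomic
  nr <- nrow(summaries)
  ## long format: one row per (cell, chromosome, haplotype)
  cell <- rep(summaries$cell_id, 2)
  chrom <- rep(summaries$chrom, 2)
  hap <- rep(c("A", "B"), each = nr)
  yield <- c(summaries$y_A, summaries$y_B)
  ri <- match(paste(chrom, hap), paste(rs$chrom, rs$haplotype))
  chBase <- sub("[pq]$", "", chrom)
  ti <- match(chBase, tri$chrom)
  ti[is.na(ti)] <- match(chrom[is.na(ti)], tri$chrom)
  if (anyNA(ri) || anyNA(ti)) {
    bad <- which(is.na(ri) | is.na(ti))[1]
    stop("missing reference for homologue ", chrom[bad], "-", hap[bad])
  }
  n <- if (is.null(nTests)) {
    perCell <- table(summaries$cell_id)
    as.integer(2L * perCell[cell])
  } else {
    rep(as.integer(nTests), length(cell))
  }
  pMono <- pmin(1, zTestTwoTailed(yield, rs$mu[ri], rs$sigma[ri]) * n)
  pDi <- pmin(1, zTestTwoTailed(yield, tri$mu[ti], tri$sigma[ti]) * n)
  nb <- aneuRef@nullisomicBound
  label <- ifelse(yield < nb, "0",
           ifelse(pMono >= alpha, "1",
           ifelse(yield < rs$mu[ri], "1-",
           ifelse(pDi >= alpha, "2",
           ifelse(yield < tri$mu[ti], "1+", "2")))))
  isNull <- yield < nb
  pMono[isNull] <- NA_real_
  pDi[isNull] <- NA_real_
  ord <- order(match(cell, summaries$cell_id), chrom, hap)
  DataFrame(cell_id = cell, chrom = chrom, haplotype = hap, yield = yield,
            label = label, p_mono = pMono, p_di = pDi,
            flagged = label != "1")[ord, ]
}
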