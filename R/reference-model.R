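#' Build the per-homologue normal-transcription reference
#'
#' Fits mean and s.d. of normalized haplotype-specific transcription per
#' (chromosome, haplotype) across QC-passing control cells. For a designated
#' unstable chromosome (a chromosome that recurrently acquires copy-number
#' changes in the control line), controls whose yield on either homologue
#' deviates by more than \code{outlierK} first-pass s.d. are dropped from that
#' chromosome only and the statistics are refitted — an automated stand-in for
#' manual review of control karyotypes.
#'
#' Per-homologue variances estimated from a few dozen controls are noisy;
#' because the subsequent z-tests treat them as known, that noise inflates
#' tail rejections. The variances are therefore moderated toward their
#' across-homologue mean with \code{priorDf} prior degrees of freedom
#' (set \code{priorDf = 0} for raw per-homologue variances).
#'
#' @param summaries DataFrame from \code{\link{cellSummaries}} run on control
#'   cells (>= 5).
#' @param unstableChrom Optional chromosome name(s) receiving the two-pass
#'   outlier screen.
#' @param outlierK Deviation threshold in first-pass s.d. (default 3).
#' @param priorDf Prior degrees of freedom for variance moderation
#'   (default 30).
#' @param displayScaling Optional named per-chromosome scaling constants
#'   recorded with the reference (must match the ones used on the summaries).
#' @return A \linkS4class{ReferenceDistribution}.
#' @export
buildReference <- function(summaries, unstableChrom = NULL, outlierK = 3,
                           priorDf = 30, displayScaling = NULL) {
  cells <- unique(summaries$cell_id)
  if (length(cells) < 5) stop("need >= 5 QC-passing control cells")
  chroms <- unique(summaries$chrom)
  excluded <- setNames(vector("list", length(chroms)), chroms)
  rows <- list()
  for (ch in chroms) {
    sub <- summaries[summaries$chrom == ch, ]
    drop <- character(0)
    if (ch %in% unstableChrom) {
      for (hap in c("A", "B")) {
        y <- if (hap == "A") sub$y_A else sub$y_B
        mu0 <- mean(y); sd0 <- stats::sd(y)
        if (is.finite(sd0) && sd0 > 0) {
          drop <- union(drop, sub$cell_id[abs(y - mu0) > outlierK * sd0])
        }
      }
      if (length(sub$cell_id) - length(drop) < 5) {
        stop("unstable-chromosome screen leaves < 5 controls on ", ch)
      }
    }
    excluded[[ch]] <- drop
    use <- sub[!sub$cell_id %in% drop, ]
    for (hap in c("A", "B")) {
      y <- if (hap == "A") use$y_A else use$y_B
      rows[[length(rows) + 1L]] <- DataFrame(
        chrom = ch, haplotype = hap, mu = mean(y), sigma = stats::sd(y),
        n = nrow(use))
    }
  }
  stats <- do.call(rbind, rows)
  if (priorDf > 0 && nrow(stats) > 1) {
    v <- stats$sigma^2
    d <- stats$n - 1
    stats$sigma <- sqrt((d * v + priorDf * mean(v)) / (d + priorDf))
  }
  new("ReferenceDistribution", stats = stats,
      excluded = excluded,
      params = list(unstableChrom = unstableChrom, outlierK = outlierK,
                    priorDf = priorDf, displayScaling = displayScaling))
}

#' Build aneuploid (gain/loss) transcription references
#'
#' The duplicated-homologue (trisomic) reference is derived either from bona
#' fide de novo trisomies observed in families or, when none qualify, from the
#' distribution of total disomic transcription in control cells (the duplicated
#' homologue is expected to transcribe like two normal copies). A candidate
#' event qualifies only if (1) the chromosome-wide TPM ratio changed roughly
#' proportionally (within \code{ratioWindow} of 1.5), (2) its transcriptional
#' allele fraction matches the DNA fraction 2/3 within \code{fracTol}, and
#' (3) the event is sibling-supported (shared by siblings or mirrored by a
#' sibling monosomy). The nullisomic residual bound is fixed (default 0.1):
#' below it a haplotype is treated as transcriptionally absent without a test.
#'
#' @param controlSummaries DataFrame from \code{\link{cellSummaries}} on
#'   controls.
#' @param candidates Optional DataFrame of candidate trisomies with columns
#'   family_id, cell_id, chrom, haplotype, tpm_ratio, dup_frac, dup_yield,
#'   sibling_support.
#' @param nullisomicBound Yield below which a haplotype is nullisomic.
#' @param ratioWindow Acceptance window for the chromosome-wide TPM ratio.
#' @param fracTol Tolerance on |allele fraction - 2/3|.
#' @return An \linkS4class{AneuploidReference}.
#' @export
buildAneuploidReference <- function(controlSummaries, candidates = NULL,
                                    nullisomicBound = 0.1,
                                    ratioWindow = c(1.3, 1.7),
                                    fracTol = 0.08) {
  chroms <- unique(controlSummaries$chrom)
  rows <- lapply(chroms, function(ch) {
    tot <- controlSummaries$y_A[controlSummaries$chrom == ch] +
      controlSummaries$y_B[controlSummaries$chrom == ch]
    DataFrame(chrom = ch, mu = mean(tot), sigma = stats::sd(tot),
              n = length(tot))
  })
  trisomic <- do.call(rbind, rows)
  if (nrow(trisomic) > 1) {
    ## same variance moderation as the per-homologue reference
    v <- trisomic$sigma^2
    d <- trisomic$n - 1
    trisomic$sigma <- sqrt((d * v + 30 * mean(v)) / (d + 30))
  }
  strategy <- "disomic-total"
  accepted <- DataFrame(family_id = character(0), cell_id = character(0),
                        chrom = character(0), haplotype = character(0),
                        tpm_ratio = numeric(0), dup_frac = numeric(0),
                        dup_yield = numeric(0))
  if (!is.null(candidates) && nrow(candidates) > 0) {
    ok <- candidates$tpm_ratio >= ratioWindow[1] &
      candidates$tpm_ratio <= ratioWindow[2] &
      abs(candidates$dup_frac - 2 / 3) <= fracTol &
      candidates$sibling_support
    accepted <- candidates[ok, setdiff(colnames(candidates),
                                       "sibling_support"), drop = FALSE]
    if (nrow(accepted) >= 3) {
      ## events-based reference: one pooled duplicated-homologue distribution,
      ## applied to every chromosome (few events per chromosome are available)
      mu <- mean(accepted$dup_yield)
      sg <- stats::sd(accepted$dup_yield)
      if (is.finite(sg) && sg > 0) {
        trisomic$mu <- mu
        trisomic$sigma <- sg
        trisomic$n <- nrow(accepted)
        strategy <- "events"
      }
    } else {
      warning("no (or too few) bona fide trisomies qualify; ",
              "falling back to the disomic-total reference")
    }
  }
  new("AneuploidReference", trisomic = trisomic,
      nullisomicBound = nullisomicBound, provenance = accepted,
      strategy = strategy)
}
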