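#' Quality-control filter for single-cell libraries
#'
#' The primary QC metric is the number of genes covered by at least
#' \code{minReads} reads. Control cells must reach \code{minGenesControl}
#' qualifying genes (default 6000); micronucleation-related roles must reach
#' \code{minGenesMn} (default 4000). Boundaries are inclusive: a control cell
#' with exactly 6000 qualifying genes passes.
#'
#' @param se \linkS4class{CellFamilyExperiment}.
#' @param minReads Read floor per qualifying gene (default 5).
#' @param minGenesControl,minGenesMn Qualifying-gene floors by role.
#' @return DataFrame with cell_id, role, genes_covered, threshold, pass.
#' @export
qcFilterCell <- function(se, minReads = 5, minGenesControl = 6000,
                         minGenesMn = 4000) {
  if (!"reads" %in% SummarizedExperiment::assayNames(se)) {
    stop("no per-gene read-depth column: supply a 'reads' assay ",
         "(informative reads or depth) to QC cells")
  }
  covered <- colSums(assay(se, "reads") >= minReads)
  role <- colData(se)$role
  threshold <- ifelse(role == "control", minGenesControl, minGenesMn)
  DataFrame(cell_id = colData(se)$cell_id, role = role,
            genes_covered = as.integer(covered),
            threshold = as.integer(threshold),
            pass = covered >= threshold)
}

#' Gene-level analysis filters
#'
#' Retains genes whose mean TPM across control cells exceeds \code{tpmFloor}
#' (strictly; a control mean of exactly 25 is excluded) and whose pooled
#' control allele fraction lies inside \code{allelicWindow} (inclusive).
#' X-linked genes (catalog flag \code{x_linked}) are retained regardless of
#' allelic balance. Genes inside a declared clonal-trisomy region instead use
#' \code{trisomyWindow} for the single-copy haplotype's fraction.
#'
#' @param se \linkS4class{CellFamilyExperiment} containing the control cells.
#' @param controlIds Cell ids of the control cells (>= 5 required).
#' @param tpmFloor Control-mean TPM floor (exclusive), default 25.
#' @param allelicWindow Control allele-fraction window, default c(0.3, 0.7).
#' @param trisomyRegion Optional GRanges of a clonal trisomic segment.
#' @param trisomySingleHap Which haplotype is single-copy in that segment.
#' @param trisomyWindow Shifted window for the single-copy fraction.
#' @return Character vector of retained gene ids, with a \code{"metrics"}
#'   attribute recording per-filter exclusion counts.
#' @export
geneFilters <- function(se, controlIds, tpmFloor = 25,
                        allelicWindow = c(0.3, 0.7), trisomyRegion = NULL,
                        trisomySingleHap = c("B", "A"),
                        trisomyWindow = c(0.2, 0.4)) {
  trisomySingleHap <- match.arg(trisomySingleHap)
  ctrl <- match(controlIds, colData(se)$cell_id)
  if (anyNA(ctrl)) stop("unknown control cell id(s)")
  if (length(ctrl) < 5) stop("need >= 5 control cells for gene filters")
  tpm <- assay(se, "tpm")[, ctrl, drop = FALSE]
  hapA <- assay(se, "hapA")[, ctrl, drop = FALSE]
  hapB <- assay(se, "hapB")[, ctrl, drop = FALSE]
  meanTpm <- rowMeans(tpm)
  inf <- rowSums(hapA) + rowSums(hapB)
  fA <- ifelse(inf > 0, rowSums(hapA) / inf, NA_real_)

  passTpm <- meanTpm > tpmFloor
  passAllelic <- !is.na(fA) & fA >= allelicWindow[1] & fA <= allelicWindow[2]
  xLinked <- rowData(se)$x_linked
  passAllelic[xLinked] <- TRUE
  if (!is.null(trisomyRegion)) {
    inTri <- IRanges::overlapsAny(rowRanges(se), trisomyRegion)
    fSingle <- if (trisomySingleHap == "A") fA else 1 - fA
    passAllelic[inTri] <- !is.na(fSingle[inTri]) &
      fSingle[inTri] >= trisomyWindow[1] & fSingle[inTri] <= trisomyWindow[2]
  }
  keep <- passTpm & passAllelic
  if (!any(keep)) {
    stop("no genes survive the expression and allelic-balance filters")
  }
  out <- rowData(se)$gene_id[keep]
  attr(out, "metrics") <- c(n_total = length(keep),
                            fail_tpm = sum(!passTpm),
                            fail_allelic = sum(passTpm & !passAllelic),
                            retained = sum(keep))
  out
}

#' Per-cell global rescaling of TPM ratios
#'
#' Multiplies one cell's gene-level TPM ratios by a single constant so that the
#' typical (median) ratio of dosage-typical chromosomes equals 1, removing
#' global shifts caused by strong up- or down-regulation of a few highly
#' transcribed genes. When chromosome labels are supplied, per-chromosome
#' medians are first anchored on their across-chromosome median — a statistic
#' unaffected by any single aberrant chromosome — and chromosomes deviating
#' from the anchor by more than \code{deviantThreshold} (candidate
#' whole-chromosome dosage changes) are excluded before the gene-level median
#' is taken; without labels the factor is the plain inverse median.
#'
#' @param ratios Per-gene TPM ratios of one cell (>= 50 values).
#' @param chrom Optional chromosome label per gene.
#' @param weights Optional per-gene weights (currently unused by the screen,
#'   accepted for interface stability).
#' @param deviantThreshold Relative chromosome-level deviation from the anchor
#'   that triggers exclusion (default 0.1).
#' @return List with \code{ratios} (scaled) and \code{factor}.
#' @export
rescaleGlobal <- function(ratios, chrom = NULL, weights = NULL,
                          deviantThreshold = 0.1) {
  if (length(ratios) < 50) {
    stop("need >= 50 retained genes to estimate a scaling factor")
  }
  m0 <- median(ratios, na.rm = TRUE)
  if (!is.finite(m0) || m0 == 0) stop("median TPM ratio is zero")
  factor <- 1 / m0
  if (!is.null(chrom)) {
    if (length(chrom) != length(ratios)) stop("mismatched lengths")
    chromMed <- vapply(split(ratios, chrom), median, numeric(1),
                       na.rm = TRUE)
    anchor <- median(chromMed)
    typical <- names(chromMed)[abs(chromMed / anchor - 1) <= deviantThreshold]
    if (length(typical) && length(typical) < length(chromMed)) {
      keep <- chrom %in% typical
      if (sum(keep) >= 50) {
        m1 <- median(ratios[keep], na.rm = TRUE)
        if (is.finite(m1) && m1 > 0) factor <- 1 / m1
      }
    }
  }
  list(ratios = ratios * factor, factor = factor)
}

#' Weighted aggregation of per-gene values into groups
#'
#' Weighted mean per group (10-Mb bin, chromosome arm, or chromosome). Groups
#' with no contributing genes are absent from the output, never reported as
#' zero.
#'
#' @param values Numeric per-gene values.
#' @param weights Positive per-gene weights (same length).
#' @param group Grouping label per gene (same length).
#' @return DataFrame with group, value (weighted mean), n_genes.
#' @export
weightedAggregate <- function(values, weights, group) {
  if (length(values) != length(weights) || length(values) != length(group)) {
    stop("mismatched lengths of values, weights and group")
  }
  ok <- !is.na(values) & !is.na(weights)
  values <- values[ok]; weights <- weights[ok]; group <- group[ok]
  idx <- split(seq_along(values), as.character(group))
  DataFrame(group = names(idx),
            value = unname(vapply(idx, function(i)
              sum(values[i] * weights[i]) / sum(weights[i]), numeric(1))),
            n_genes = unname(lengths(idx)))
}

#' Inverse-variance gene weights from control cells
#'
#' \eqn{w_g = 1 / (\hat\sigma_g^2 + \epsilon)} with \eqn{\hat\sigma_g^2} the
#' variance of the gene's TPM ratio across control cells, winsorized at the
#' 95th percentile so no single stable gene dominates an interval.
#'
#' @param se \linkS4class{CellFamilyExperiment} with the controls.
#' @param controlIds Control cell ids.
#' @param epsilon Variance floor (default 0.01).
#' @param winsorize Upper quantile at which weights are capped.
#' @return Named numeric vector of weights (one per gene).
#' @export
geneWeights <- function(se, controlIds, epsilon = 0.01, winsorize = 0.95) {
  ctrl <- match(controlIds, colData(se)$cell_id)
  tpm <- assay(se, "tpm")[, ctrl, drop = FALSE]
  meanTpm <- rowMeans(tpm)
  r <- tpm / meanTpm
  v <- apply(r, 1, stats::var)
  w <- 1 / (v + epsilon)
  cap <- stats::quantile(w, winsorize, na.rm = TRUE)
  w <- pmin(w, cap)
  names(w) <- rowData(se)$gene_id
  w
}

#' Haplotype-specific transcription yield
#'
#' Multiplies a chromosome's (or bin's) average TPM ratio by the average
#' fraction of each haplotype: \eqn{y_h = \bar r \cdot \bar f_h}, so one
#' normally transcribing homologue contributes 0.5. Optional per-chromosome
#' display-scaling constants (e.g. 1.5 for a clonal trisomic segment, 0.6 for
#' the X) multiply both homologues; because the same constants enter the
#' reference distribution, classification is unaffected and only reported
#' values change.
#'
#' @param tpmRatio Average TPM ratio (vector).
#' @param fA Average haplotype-A fraction (same length).
#' @param scaling Optional multiplicative display constant(s).
#' @return DataFrame with y_A and y_B; y_A + y_B equals
#'   \code{tpmRatio * scaling} exactly.
#' @export
homologueYield <- function(tpmRatio, fA, scaling = 1) {
  if (length(tpmRatio) != length(fA)) stop("mismatched lengths")
  DataFrame(y_A = tpmRatio * fA * scaling,
            y_B = tpmRatio * (1 - fA) * scaling)
}

#' Per-cell chromosome-level transcription summaries
#'
#' The full quantification chain for every cell in \code{se}: gene filters from
#' the controls, per-gene TPM ratios against the control mean, per-cell global
#' rescaling, inverse-variance weighted aggregation of ratios and
#' read-count-weighted aggregation of allele fractions per chromosome (or arm),
#' and homologue yields.
#'
#' @param se \linkS4class{CellFamilyExperiment} holding the cells to summarize.
#' @param controls \linkS4class{CellFamilyExperiment} holding control cells
#'   (may be the same object).
#' @param retained Optional precomputed retained gene ids; default runs
#'   \code{\link{geneFilters}}.
#' @param byArm Split chromosomes at the centromere (synthetic genomes place
#'   it at the midpoint) and summarize arms instead of chromosomes.
#' @param displayScaling Optional named numeric vector of per-chromosome
#'   display constants.
#' @param readWinsorize Upper quantile capping per-gene informative-read
#'   weights in the allele-fraction average.
#' @param ... Passed to \code{\link{geneFilters}}.
#' @return DataFrame with cell_id, chrom, n_genes, tpm_ratio, f_A, y_A, y_B
#'   and the per-cell scaling factor.
#' @export
cellSummaries <- function(se, controls = se, retained = NULL, byArm = FALSE,
                          displayScaling = NULL, readWinsorize = 0.95, ...) {
  ctx <- .quantContext(se, controls, retained, ...)
  grp <- if (byArm) {
    sl <- GenomeInfoDb::seqlengths(rowRanges(se))
    centro <- sl[ctx$chrom] / 2
    paste0(ctx$chrom, ifelse(ctx$mids <= centro, "p", "q"))
  } else {
    ctx$chrom
  }
  .summarizeGroups(ctx, grp, displayScaling = displayScaling,
                   readWinsorize = readWinsorize)
}

## Shared, vectorized machinery: per-gene ratios against the control mean,
## per-cell rescaling, and weighted group aggregation for all cells at once.
.quantContext <- function(se, controls, retained, ...) {
  controlIds <- colData(controls)$cell_id[colData(controls)$role == "control"]
  if (is.null(retained)) {
    retained <- geneFilters(controls, controlIds, ...)
  }
  keep <- which(rowData(se)$gene_id %in% retained)
  gid <- rowData(se)$gene_id[keep]
  ord <- match(gid, rowData(controls)$gene_id)
  if (anyNA(ord)) stop("cells and controls must share one gene catalog")
  tpmC <- assay(controls, "tpm")[ord, match(controlIds,
                                            colData(controls)$cell_id),
                                 drop = FALSE]
  meanTpm <- rowMeans(tpmC)
  rC <- tpmC / meanTpm
  v <- rowSums((rC - rowMeans(rC))^2) / (ncol(rC) - 1)
  w <- 1 / (v + 0.01)
  w <- pmin(w, stats::quantile(w, 0.95, na.rm = TRUE))
  rr <- rowRanges(se)[keep]
  list(cellIds = colData(se)$cell_id,
       tpm = assay(se, "tpm")[keep, , drop = FALSE],
       hapA = assay(se, "hapA")[keep, , drop = FALSE],
       hapB = assay(se, "hapB")[keep, , drop = FALSE],
       meanTpm = meanTpm, w = w,
       chrom = as.character(seqnames(rr)),
       mids = mid(IRanges::ranges(rr)))
}

.summarizeGroups <- function(ctx, grp, displayScaling = NULL,
                             readWinsorize = 0.95) {
  nCell <- length(ctx$cellIds)
  R <- ctx$tpm / ctx$meanTpm
  factors <- numeric(nCell)
  for (j in seq_len(nCell)) {
    sc <- rescaleGlobal(R[, j], chrom = ctx$chrom, weights = ctx$w)
    R[, j] <- sc$ratios
    factors[j] <- sc$factor
  }
  gidx <- split(seq_along(grp), grp)
  groups <- names(gidx)
  nG <- lengths(gidx)
  wDen <- vapply(gidx, function(i) sum(ctx$w[i]), numeric(1))
  ratio <- do.call(rbind, lapply(gidx, function(i)
    colSums(R[i, , drop = FALSE] * ctx$w[i]))) / wDen
  inf <- ctx$hapA + ctx$hapB
  caps <- vapply(seq_len(nCell), function(j) {
    x <- inf[, j]
    if (!any(x > 0)) return(1)
    stats::quantile(x[x > 0], readWinsorize, na.rm = TRUE)
  }, numeric(1))
  infW <- pmin(inf, matrix(caps, nrow(inf), nCell, byrow = TRUE))
  fGene <- ifelse(inf > 0, ctx$hapA / pmax(inf, 1), 0)
  infW[inf == 0] <- 0
  fNum <- do.call(rbind, lapply(gidx, function(i)
    colSums(fGene[i, , drop = FALSE] * infW[i, , drop = FALSE])))
  fDen <- do.call(rbind, lapply(gidx, function(i)
    colSums(infW[i, , drop = FALSE])))
  f <- ifelse(fDen > 0, fNum / fDen, NA_real_)
  scale <- if (is.null(displayScaling)) rep(1, length(groups)) else {
    s <- displayScaling[sub("[pq]$", "", groups)]
    ifelse(is.na(s), 1, s)
  }
  DataFrame(cell_id = rep(ctx$cellIds, each = length(groups)),
            chrom = rep(groups, nCell),
            n_genes = rep(nG, nCell),
            tpm_ratio = as.vector(ratio) * scale,
            f_A = as.vector(f),
            y_A = as.vector(ratio * f) * scale,
            y_B = as.vector(ratio * (1 - f)) * scale,
            scaling_factor = rep(factors, each = length(groups)))
}

#' 10-Mb binned transcription summaries
#'
#' Like \code{\link{cellSummaries}} but grouped into fixed, 0-based half-open
#' 10-Mb genomic bins (gene assigned by midpoint). Bins without retained genes
#' are absent from the output.
#'
#' @inheritParams cellSummaries
#' @param binSize Bin width in bp (default 1e7).
#' @return DataFrame with cell_id, chrom, bin (0-based index), n_genes,
#'   tpm_ratio, f_A, y_A, y_B.
#' @export
binnedSummaries <- function(se, controls = se, retained = NULL,
                            binSize = 1e7, ...) {
  ctx <- .quantContext(se, controls, retained, ...)
  bin <- (ctx$mids - 1) %/% binSize
  grp <- paste0(ctx$chrom, ":", bin)
  out <- .summarizeGroups(ctx, grp)
  parts <- do.call(rbind, strsplit(out$chrom, ":", fixed = TRUE))
  out$chrom <- parts[, 1]
  out$bin <- as.integer(parts[, 2])
  out[, c("cell_id", "chrom", "bin", "n_genes", "tpm_ratio", "f_A",
          "y_A", "y_B")]
}
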