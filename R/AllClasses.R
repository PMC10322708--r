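#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end width mid
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowRanges rowData
NULL

.MN_ROLES <- c("control", "mn_cell", "mn_sister", "mn_daughter", "mn_niece")

#' GeneCatalog: an annotated gene set on a (synthetic or real) genome
#'
#' A \linkS4class{GRanges} with mandatory metadata columns \code{gene_id}
#' (unique), \code{mean_tpm} (baseline mean expression, TPM), \code{dispersion}
#' (gene-level multiplicative noise s.d.) and \code{x_linked} (logical,
#' X-chromosome exemption from the allelic-balance filter). Sequence lengths
#' must be declared so genes can be checked against chromosome bounds.
#'
#' @export
setClass("GeneCatalog", contains = "GRanges")

setValidity("GeneCatalog", function(object) {
  mc <- mcols(object)
  need <- c("gene_id", "mean_tpm", "dispersion", "x_linked")
  missing <- setdiff(need, colnames(mc))
  if (length(missing)) {
    return(paste("missing metadata columns:", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(mc$gene_id)) return("gene_id values must be unique")
  if (any(mc$mean_tpm <= 0)) return("mean_tpm must be positive")
  if (any(mc$dispersion <= 0)) return("dispersion must be positive")
  sl <- GenomeInfoDb::seqlengths(object)
  if (any(is.na(sl))) return("seqlengths must be declared for all chromosomes")
  if (any(end(object) > sl[as.character(seqnames(object))])) {
    return("genes extend beyond declared chromosome lengths")
  }
  if (!all(is.finite(sum(as.numeric(mc$mean_tpm))))) {
    return("baseline TPMs must have a finite sum")
  }
  TRUE
})

#' Construct a GeneCatalog
#'
#' @param gr GRanges carrying gene_id, mean_tpm, dispersion and x_linked
#'   metadata columns, with seqlengths set.
#' @return A validated \linkS4class{GeneCatalog}.
#' @export
GeneCatalog <- function(gr) {
  new("GeneCatalog", gr)
}

#' CellFamilyExperiment: haplotype-resolved expression of related single cells
#'
#' A \linkS4class{RangedSummarizedExperiment} whose rows are the genes of a
#' \linkS4class{GeneCatalog} and whose columns are cells, with assays
#' \code{tpm} (columns each summing to 1e6), \code{hapA} and \code{hapB}
#' (haplotype-assignable read counts) and \code{reads} (total per-gene reads,
#' the QC depth proxy). Column data carry \code{cell_id}, \code{role} (one of
#' control, mn_cell, mn_sister, mn_daughter, mn_niece), \code{family_id} and
#' \code{generation}. Simulated objects store their ground-truth
#' \code{scenario} in \code{metadata()}.
#'
#' @export
setClass("CellFamilyExperiment",
         contains = "RangedSummarizedExperiment")

setValidity("CellFamilyExperiment", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  need <- c("tpm", "hapA", "hapB", "reads")
  if (!all(need %in% an)) {
    return(paste("missing assays:", paste(setdiff(need, an), collapse = ", ")))
  }
  cd <- colData(object)
  needCols <- c("cell_id", "role", "family_id", "generation")
  if (!all(needCols %in% colnames(cd))) {
    return(paste("missing colData columns:",
                 paste(setdiff(needCols, colnames(cd)), collapse = ", ")))
  }
  if (!all(cd$role %in% .MN_ROLES)) {
    return(paste("role must be one of:", paste(.MN_ROLES, collapse = ", ")))
  }
  if (anyDuplicated(cd$cell_id)) return("cell_id values must be unique")
  if (ncol(object) > 0) {
    hap <- assay(object, "hapA") + assay(object, "hapB")
    if (any(hap > assay(object, "reads"))) {
      return("hapA + hapB may not exceed total reads")
    }
  }
  TRUE
})

#' Construct a CellFamilyExperiment
#'
#' @param tpm,hapA,hapB,reads Gene-by-cell matrices (same dimensions).
#' @param catalog \linkS4class{GeneCatalog} giving the row ranges.
#' @param colData DataFrame with cell_id, role, family_id, generation.
#' @param metadata Optional list (e.g. ground-truth scenario).
#' @return A validated \linkS4class{CellFamilyExperiment}.
#' @export
CellFamilyExperiment <- function(tpm, hapA, hapB, reads, catalog, colData,
                                 metadata = list()) {
  se <- SummarizedExperiment(
    assays = list(tpm = tpm, hapA = hapA, hapB = hapB, reads = reads),
    rowRanges = as(catalog, "GRanges"),
    colData = colData)
  colnames(se) <- colData$cell_id
  S4Vectors::metadata(se) <- metadata
  new("CellFamilyExperiment", se)
}

#' @describeIn CellFamilyExperiment cell roles, named by cell id
#' @param x A CellFamilyExperiment.
#' @export
cellRoles <- function(x) {
  stats::setNames(as.character(colData(x)$role), colData(x)$cell_id)
}

#' ReferenceDistribution: normal per-homologue transcription in controls
#'
#' Mean and s.d. of normalized haplotype-specific transcription for every
#' (chromosome, haplotype) across QC-passing control cells, with per-chromosome
#' lists of controls excluded by the unstable-chromosome review and the
#' display-scaling constants in force.
#'
#' @slot stats DataFrame with columns chrom, haplotype, mu, sigma, n.
#' @slot excluded Named list: chromosome -> character vector of excluded
#'   control cell ids.
#' @slot params List of fitting parameters (unstable chromosome, outlier k,
#'   display scalings).
#' @export
setClass("ReferenceDistribution",
         slots = c(stats = "DataFrame", excluded = "list", params = "list"))

setValidity("ReferenceDistribution", function(object) {
  st <- object@stats
  need <- c("chrom", "haplotype", "mu", "sigma", "n")
  if (!all(need %in% colnames(st))) {
    return(paste("stats needs columns:", paste(need, collapse = ", ")))
  }
  if (any(st$sigma <= 0)) return("sigma must be strictly positive")
  if (any(st$n < 5)) return("each reference entry needs n >= 5 controls")
  TRUE
})

#' @describeIn ReferenceDistribution the per-homologue statistics table
#' @param x A ReferenceDistribution.
#' @export
referenceStats <- function(x) x@stats

#' @describeIn ReferenceDistribution controls excluded per chromosome
#' @export
excludedControls <- function(x) x@excluded

#' AneuploidReference: transcription ranges for whole-chromosome gain/loss
#'
#' Per-chromosome reference for a duplicated (two-copy) homologue, derived
#' either from bona fide trisomies observed in families or, as a fallback, from
#' the distribution of total disomic transcription in control cells (the
#' duplicated homologue is expected to transcribe like two normal copies). Also
#' fixes the nullisomic residual bound below which a haplotype is treated as
#' transcriptionally absent.
#'
#' @slot trisomic DataFrame: chrom, mu, sigma, n (duplicated-homologue yield).
#' @slot nullisomicBound Numeric; yield below this is nullisomic (default 0.1).
#' @slot provenance DataFrame of the bona fide events used (may be empty).
#' @slot strategy "events" or "disomic-total" (the fallback).
#' @export
setClass("AneuploidReference",
         slots = c(trisomic = "DataFrame", nullisomicBound = "numeric",
                   provenance = "DataFrame", strategy = "character"))

setValidity("AneuploidReference", function(object) {
  if (length(object@nullisomicBound) != 1L || object@nullisomicBound <= 0) {
    return("nullisomicBound must be a single positive number")
  }
  if (!all(c("chrom", "mu", "sigma", "n") %in% colnames(object@trisomic))) {
    return("trisomic needs columns chrom, mu, sigma, n")
  }
  TRUE
})

#' MNAssignment: the inferred micronucleus chromosome for one family
#'
#' @slot familyId Character.
#' @slot chromosome,haplotype Character (NA when unresolved/invisible).
#' @slot pattern "1:3" or "2:2" (NA when unresolved/invisible).
#' @slot generation Integer (1 or 2).
#' @slot confidence One of direct, inferred-without-nieces, invisible-normal,
#'   unresolved.
#' @slot score Numeric constraint score of the accepted scenario.
#' @slot candidates DataFrame of all scored scenarios (ties are listed here).
#' @slot notes Character.
#' @export
setClass("MNAssignment",
         slots = c(familyId = "character", chromosome = "character",
                   haplotype = "character", pattern = "character",
                   generation = "integer", confidence = "character",
                   score = "numeric", candidates = "DataFrame",
                   notes = "character"))

setValidity("MNAssignment", function(object) {
  ok <- c("direct", "inferred-without-nieces", "invisible-normal", "unresolved")
  if (!object@confidence %in% ok) {
    return(paste("confidence must be one of:", paste(ok, collapse = ", ")))
  }
  TRUE
})

#' MNYieldEstimate: transcriptional yield of the micronucleus chromatid
#'
#' @slot a Estimated yield in normalized per-homologue units (0.5 = one normal
#'   homologue); NA when only a consistency statement is possible.
#' @slot basis One of direct-2:2, vs-disomic-3:1, combined-daughters,
#'   per-daughter-vs-mono-and-di, none.
#' @slot classification normal, reduced, near-silent, or
#'   consistent-with-normal.
#' @slot p Named numeric vector of the z-test p-values used.
#' @slot details List with per-cell yields entering the estimate.
#' @export
setClass("MNYieldEstimate",
         slots = c(a = "numeric", basis = "character",
                   classification = "character", p = "numeric",
                   details = "list"))

setMethod("show", "GeneCatalog", function(object) {
  cat(sprintf("GeneCatalog: %d genes on %d chromosome(s)\n",
              length(object),
              length(GenomeInfoDb::seqlevels(object))))
  callNextMethod()
})

setMethod("show", "ReferenceDistribution", function(object) {
  st <- object@stats
  cat(sprintf("ReferenceDistribution: %d homologue entries, n = %s controls\n",
              nrow(st), paste(unique(st$n), collapse = "/")))
  cat(sprintf("  mean mu = %.3f, mean sigma = %.3f\n",
              mean(st$mu), mean(st$sigma)))
  ex <- object@excluded[lengths(object@excluded) > 0]
  if (length(ex)) {
    cat("  excluded controls:",
        paste(sprintf("%s (%d)", names(ex), lengths(ex)), collapse = ", "),
        "\n")
  }
})

setMethod("show", "AneuploidReference", function(object) {
  cat(sprintf(
    "AneuploidReference (%s): %d chromosomes, nullisomic bound %.2f\n",
    object@strategy, nrow(object@trisomic), object@nullisomicBound))
})

setMethod("show", "MNAssignment", function(object) {
  cat(sprintf("MNAssignment [%s]: %s haplotype %s, pattern %s (gen %d)\n",
              object@familyId, object@chromosome, object@haplotype,
              object@pattern, object@generation))
  cat(sprintf("  confidence: %s (score %.1f)\n",
              object@confidence, object@score))
  if (nzchar(object@notes)) cat("  notes:", object@notes, "\n")
})

setMethod("show", "MNYieldEstimate", function(object) {
  cat(sprintf("MNYieldEstimate: a = %s (%s), classified %s\n",
              ifelse(is.na(object@a), "NA", sprintf("%.3f", object@a)),
              object@basis, object@classification))
})

#' @describeIn MNAssignment the inferred (chromosome, haplotype, pattern)
#' @param x An MNAssignment.
#' @export
mnCall <- function(x) {
  c(chromosome = x@chromosome, haplotype = x@haplotype, pattern = x@pattern,
    confidence = x@confidence)
}

#' @describeIn MNYieldEstimate the yield estimate and classification
#' @param x An MNYieldEstimate.
#' @export
mnYield <- function(x) {
  list(a = x@a, basis = x@basis, classification = x@classification)
}
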