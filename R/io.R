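#' Write a gene catalog as BED-like TSV
#'
#' Columns: chrom, start (0-based), end (half-open), gene_id, mean_tpm,
#' dispersion, x_linked, chrom_length.
#'
#' @param catalog \linkS4class{GeneCatalog}.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
writeGeneCatalog <- function(catalog, path) {
  df <- data.frame(chrom = as.character(seqnames(catalog)),
                   start = start(catalog) - 1L, end = end(catalog),
                   gene_id = mcols(catalog)$gene_id,
                   mean_tpm = mcols(catalog)$mean_tpm,
                   dispersion = mcols(catalog)$dispersion,
                   x_linked = mcols(catalog)$x_linked,
                   chrom_length = GenomeInfoDb::seqlengths(catalog)[
                     as.character(seqnames(catalog))])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene catalog written by \code{\link{writeGeneCatalog}}
#'
#' @param path TSV path.
#' @return \linkS4class{GeneCatalog}.
#' @export
readGeneCatalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  sl <- tapply(df$chrom_length, df$chrom, `[`, 1)
  gr <- GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end),
                seqinfo = GenomeInfoDb::Seqinfo(names(sl), as.numeric(sl)))
  mcols(gr)$gene_id <- df$gene_id
  mcols(gr)$mean_tpm <- df$mean_tpm
  mcols(gr)$dispersion <- df$dispersion
  mcols(gr)$x_linked <- as.logical(df$x_linked)
  GeneCatalog(gr)
}

#' Write per-cell expression tables and a family manifest
#'
#' One TSV per cell (gene_id, tpm, hapA_count, hapB_count, reads) plus
#' \code{manifest.tsv} (cell_id, family_id, role, generation, path).
#'
#' @param se \linkS4class{CellFamilyExperiment}.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
writeCellTables <- function(se, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cd <- colData(se)
  paths <- character(ncol(se))
  for (j in seq_len(ncol(se))) {
    df <- data.frame(gene_id = rowData(se)$gene_id,
                     tpm = assay(se, "tpm")[, j],
                     hapA_count = assay(se, "hapA")[, j],
                     hapB_count = assay(se, "hapB")[, j],
                     reads = assay(se, "reads")[, j])
    paths[j] <- file.path(dir, paste0(cd$cell_id[j], ".tsv"))
    utils::write.table(df, paths[j], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  manifest <- data.frame(cell_id = cd$cell_id, family_id = cd$family_id,
                         role = cd$role, generation = cd$generation,
                         path = basename(paths))
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(mpath)
}

#' Read cell tables from a family manifest
#'
#' @param manifestPath Path to manifest.tsv (cell paths relative to it).
#' @param catalog \linkS4class{GeneCatalog} the tables refer to.
#' @return \linkS4class{CellFamilyExperiment}.
#' @export
readCellTables <- function(manifestPath, catalog) {
  man <- utils::read.delim(manifestPath, stringsAsFactors = FALSE)
  need <- c("cell_id", "family_id", "role", "generation", "path")
  bad <- setdiff(need, colnames(man))
  if (length(bad)) {
    stop("malformed manifest: missing column(s) ", paste(bad, collapse = ", "))
  }
  badRole <- which(!man$role %in% .MN_ROLES)
  if (length(badRole)) {
    stop("malformed manifest: invalid role in row(s) ",
         paste(badRole, collapse = ", "))
  }
  base <- dirname(manifestPath)
  ids <- mcols(catalog)$gene_id
  cells <- lapply(man$path, function(p) {
    df <- utils::read.delim(file.path(base, p), stringsAsFactors = FALSE)
    i <- match(ids, df$gene_id)
    if (anyNA(i)) stop("cell table ", p, " does not cover the catalog")
    list(tpm = df$tpm[i], hapA = df$hapA_count[i], hapB = df$hapB_count[i],
         reads = df$reads[i])
  })
  cd <- DataFrame(cell_id = man$cell_id, role = man$role,
                  family_id = man$family_id,
                  generation = as.integer(man$generation))
  .bindCells(catalog, cells, cd)
}

#' Write chromosome summaries or state tables as TSV
#'
#' @param x DataFrame (e.g. from \code{\link{cellSummaries}} or
#'   \code{\link{classifyCell}}).
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
writeSummaryTable <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write/read an ATAC peak table (BED-like with GC)
#'
#' @param peaks GRanges with gc (and optionally peak_id).
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
writePeaks <- function(peaks, path) {
  df <- data.frame(chrom = as.character(seqnames(peaks)),
                   start = start(peaks) - 1L, end = end(peaks),
                   peak_id = if (!is.null(mcols(peaks)$peak_id))
                     mcols(peaks)$peak_id else
                       sprintf("peak%05d", seq_along(peaks)),
                   gc = mcols(peaks)$gc,
                   chrom_length = GenomeInfoDb::seqlengths(peaks)[
                     as.character(seqnames(peaks))])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePeaks
#' @export
readPeaks <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  sl <- tapply(df$chrom_length, df$chrom, `[`, 1)
  gr <- GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end),
                seqinfo = GenomeInfoDb::Seqinfo(names(sl), as.numeric(sl)))
  mcols(gr)$gc <- df$gc
  mcols(gr)$peak_id <- df$peak_id
  gr
}
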