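#' Read/write helpers for the pipeline's file formats
#'
#' Thin wrappers over Biostrings and base table I/O: FASTA genomes, FASTQ
#' read sets (constant quality, which the pipeline never uses), a
#' knownGenes-like tab-separated gene-model table, and BED output for
#' poly(A) sites (BED is written 0-based half-open).
#'
#' @param genome,reads,genes,sites Objects to write.
#' @param path File path.
#' @name tandemUTR-io
NULL

#' @rdname tandemUTR-io
#' @export
writeGenomeFasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname tandemUTR-io
#' @export
readGenomeFasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' @rdname tandemUTR-io
#' @param quality Single quality character applied to every base.
#' @export
writeReadsFastq <- function(reads, path, quality = "I") {
  q <- Biostrings::BStringSet(strrep(quality, Biostrings::width(reads)))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = q)
  invisible(path)
}

#' @rdname tandemUTR-io
#' @export
readReadsFastq <- function(path) {
  r <- Biostrings::readDNAStringSet(path, format = "fastq")
  names(r) <- sub("\\s.*$", "", names(r))
  r
}

#' @rdname tandemUTR-io
#' @export
writeGeneModels <- function(genes, path) {
  m <- mcols(genes)
  df <- data.frame(geneId = m$geneId,
                   chrom = as.character(seqnames(genes)),
                   strand = as.character(strand(genes)),
                   txStart = start(genes), txEnd = end(genes),
                   cdsStart = m$cdsStart, cdsEnd = m$cdsEnd,
                   exonStarts = m$exonStarts, exonEnds = m$exonEnds,
                   coding = m$coding)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname tandemUTR-io
#' @export
readGeneModels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  GRanges(df$chrom, IRanges(df$txStart, df$txEnd), strand = df$strand,
          geneId = df$geneId, coding = df$coding,
          cdsStart = df$cdsStart, cdsEnd = df$cdsEnd,
          exonStarts = df$exonStarts, exonEnds = df$exonEnds)
}

#' @rdname tandemUTR-io
#' @export
writeGeneModelsBed <- function(genes, path) {
  m <- mcols(genes)
  rows <- character(length(genes))
  for (i in seq_along(genes)) {
    exS <- .splitNum(m$exonStarts[i]); exE <- .splitNum(m$exonEnds[i])
    thickS <- if (isTRUE(m$coding[i])) m$cdsStart[i] - 1L else start(genes)[i] - 1L
    thickE <- if (isTRUE(m$coding[i])) m$cdsEnd[i] else start(genes)[i] - 1L
    rows[i] <- paste(as.character(seqnames(genes)[i]), start(genes)[i] - 1L,
                     end(genes)[i], m$geneId[i], 0L,
                     as.character(strand(genes)[i]), thickS, thickE, 0L,
                     length(exS),
                     paste0(paste(exE - exS + 1L, collapse = ","), ","),
                     paste0(paste(exS - start(genes)[i], collapse = ","), ","),
                     sep = "\t")
  }
  writeLines(rows, path)
  invisible(path)
}

#' @rdname tandemUTR-io
#' @export
writeSitesBed <- function(sites, path) {
  rd <- rowData(sites)
  gr <- rowRanges(sites)
  df <- data.frame(chrom = as.character(seqnames(gr)), start = start(gr) - 1L,
                   end = start(gr), name = rd$clusterId,
                   score = rd$totalReads, strand = as.character(strand(gr)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
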