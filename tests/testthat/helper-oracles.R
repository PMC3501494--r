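suppressPackageStartupMessages({
  library(Biostrings)
  library(GenomicRanges)
  library(S4Vectors)
  library(SummarizedExperiment)
})

linkerSeq <- "TTTTCTTTTTTCTTTTTT"

# brute-force trend oracle: expand the 2xK table into one (rowScore,
# colScore) observation per read and use stats::cor on the raw pairs
bruteTrendR <- function(counts, colScores, rowScores = c(1, 2)) {
  x <- numeric(0); y <- numeric(0)
  for (i in seq_len(nrow(counts)))
    for (j in seq_len(ncol(counts))) {
      x <- c(x, rep(rowScores[i], counts[i, j]))
      y <- c(y, rep(colScores[j], counts[i, j]))
    }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

randomSwitchTable <- function(maxK = 5, maxN = 50) {
  K <- if (maxK == 2) 2L else sample(2:maxK, 1)
  n <- sample(4:maxN, 1)
  counts <- matrix(0L, 2, K)
  pick <- sample.int(2L * K, n, replace = TRUE)
  for (ix in pick) counts[ix] <- counts[ix] + 1L
  list(counts = counts, scores = sort(sample(100:5000, K)))
}

# width-1 cleavage events at given positions; alignments end (transcript
# sense) at the cleavage position with the given tail length
makeEvents <- function(chrom, positions, strand = "+", tail = 40L,
                       sample = NULL, readIds = NULL) {
  n <- length(positions)
  if (is.null(readIds)) readIds <- sprintf("r%03d", seq_len(n))
  alnStart <- if (strand == "+") positions - tail + 1L else positions
  alnEnd <- if (strand == "+") positions else positions + tail - 1L
  gr <- GRanges(chrom, IRanges(positions, positions), strand = strand,
                readId = readIds, alnStart = alnStart, alnEnd = alnEnd)
  if (!is.null(sample)) mcols(gr)$sample <- sample
  gr
}

# a gene-model GRanges row in the package's knownGenes-like layout
makeGene <- function(geneId, chrom, strand, exonStarts, exonEnds,
                     cdsStart = NA, cdsEnd = NA, coding = TRUE) {
  GRanges(chrom, IRanges(min(exonStarts), max(exonEnds)), strand = strand,
          geneId = geneId, coding = coding,
          cdsStart = cdsStart, cdsEnd = cdsEnd,
          exonStarts = paste(exonStarts, collapse = ","),
          exonEnds = paste(exonEnds, collapse = ","))
}

randomDNA <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")
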