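#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end strand granges
#' @importFrom Biostrings DNAStringSet reverseComplement subseq
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges rowData
#'   rowData<- assay assays colData
NULL

# Anchored oligo-dT linker that every genuine library read starts with.
LINKER <- "TTTTCTTTTTTCTTTTTT"

#' SapasSimulation: a synthetic 3'-end sequencing substrate
#'
#' Container for a simulated genome, its gene models, the per-gene ground
#' truth (planted tandem poly(A) sites, usage distributions in two
#' conditions, expression factors, switching and differential-expression
#' classes) and planted internal-priming decoy loci.
#'
#' @slot genome A [Biostrings::DNAStringSet] of chromosome sequences.
#' @slot genes A [GenomicRanges::GRanges] of transcript spans with metadata
#'   columns `geneId`, `coding`, `cdsStart`, `cdsEnd`, `exonStarts`,
#'   `exonEnds` (comma-separated 1-based inclusive coordinates).
#' @slot truth A `data.frame` with one row per gene carrying the planted
#'   truth (see [generateGenome()] for the columns).
#' @slot decoys A [GenomicRanges::GRanges] of width-1 internal-priming decoy
#'   cleavage positions (strand = transcript strand of the decoy read).
#' @slot params The simulation parameter list actually used.
#'
#' @seealso [generateGenome()], [generateReads()]
#' @export
setClass("SapasSimulation",
  representation(
    genome = "DNAStringSet",
    genes  = "GRanges",
    truth  = "data.frame",
    decoys = "GRanges",
    params = "list"
  )
)

setValidity("SapasSimulation", function(object) {
  msg <- character()
  tr <- object@truth
  if (nrow(tr) != length(object@genes))
    msg <- c(msg, "truth table and gene models disagree in length")
  for (i in seq_len(nrow(tr))) {
    u1 <- .splitNum(tr$usage1[i]); u2 <- .splitNum(tr$usage2[i])
    ss <- .splitNum(tr$sites[i])
    if (length(u1) != length(ss) || length(u2) != length(ss))
      msg <- c(msg, sprintf("gene %s: usage vectors and sites differ in length", tr$geneId[i]))
    if (abs(sum(u1) - 1) > 1e-8 || abs(sum(u2) - 1) > 1e-8)
      msg <- c(msg, sprintf("gene %s: usage probabilities do not sum to 1", tr$geneId[i]))
    if (tr$exprFactor1[i] <= 0 || tr$exprFactor2[i] <= 0)
      msg <- c(msg, sprintf("gene %s: expression level must be > 0", tr$geneId[i]))
    # sites inside last exon or <= 1 kb downstream in transcript sense
    lo <- tr$lastExonStart[i]; hi <- tr$lastExonEnd[i]
    bad <- if (tr$strand[i] == "+") any(ss < lo | ss > hi + 1000L)
           else any(ss > hi | ss < lo - 1000L)
    if (bad)
      msg <- c(msg, sprintf("gene %s: site outside last exon + 1 kb", tr$geneId[i]))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn SapasSimulation-class chromosome sequences
#' @param x,object A `SapasSimulation`.
#' @export
genomeSeq <- function(x) x@genome

#' @describeIn SapasSimulation-class gene models as a GRanges
#' @export
geneModels <- function(x) x@genes

#' @describeIn SapasSimulation-class the planted per-gene truth table
#' @export
truthTable <- function(x) x@truth

#' @describeIn SapasSimulation-class planted internal-priming decoy loci
#' @export
decoyLoci <- function(x) x@decoys

#' @describeIn SapasSimulation-class simulation parameters used
#' @export
simParams <- function(x) x@params

#' @export
setMethod("show", "SapasSimulation", function(object) {
  tr <- object@truth
  cat("SapasSimulation with", nrow(tr), "genes on",
      length(object@genome), "chromosome(s)\n")
  cat("  genome:", sum(lengths(object@genome)), "bp;",
      length(object@decoys), "internal-priming decoy locus/loci\n")
  cat("  switching genes:", sum(tr$switchClass != "null"),
      "| DE genes:", sum(tr$deClass != "null"),
      "| noncoding:", sum(!tr$coding), "\n")
})

#' TandemUTRSet: tandem poly(A) sites annotated on genes
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] whose rows are
#' poly(A) sites assigned as tandem sites of a gene, ordered per gene by
#' increasing tandem 3'UTR length, with a `counts` assay of reads per site
#' per sample. Row metadata carries `geneId` and `utrLength` (transcript
#' sense distance, in nt, from the 3'UTR begin to the site, inclusive).
#'
#' @export
setClass("TandemUTRSet", contains = "RangedSummarizedExperiment")

setValidity("TandemUTRSet", function(object) {
  rd <- rowData(object)
  msg <- character()
  if (!all(c("geneId", "utrLength") %in% colnames(rd)))
    return("rowData must contain geneId and utrLength")
  if (nrow(rd) > 0) {
    if (any(rd$utrLength < 1)) msg <- c(msg, "utrLength must be >= 1")
    for (g in unique(rd$geneId)) {
      len <- rd$utrLength[rd$geneId == g]
      if (any(diff(len) <= 0))
        msg <- c(msg, sprintf("gene %s: tandem UTR lengths not strictly increasing", g))
    }
  }
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "TandemUTRSet", function(object) {
  rd <- rowData(object)
  nG <- length(unique(rd$geneId))
  multi <- if (nrow(rd)) sum(table(rd$geneId) >= 2) else 0L
  cat("TandemUTRSet:", nrow(rd), "tandem site(s) in", nG, "gene(s);",
      multi, "gene(s) with a tandem 3'UTR (>= 2 sites);",
      ncol(object), "sample(s)\n")
})

# internal: comma-string <-> numeric vector used throughout truth tables
.splitNum <- function(x) as.numeric(strsplit(x, ",", fixed = TRUE)[[1]])
.joinNum <- function(x) paste(x, collapse = ",")
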