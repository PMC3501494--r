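#' Per-gene expression and fold-change differential expression calls
#'
#' Raw per-gene counts are the sums of the gene's assigned tandem-site
#' reads per sample. Counts are normalized to reads per million mapped
#' (with a pseudocount of 1 so fold changes stay defined at zero counts):
#' `cpm = (raw + 1) / librarySize * 1e6`. The fold change is case over
#' control; genes with fold >= `minFold` are `up`, fold <= 1/`minFold`
#' are `down`, others `ns`. Library sizes should be the per-sample read
#' counts surviving the internal-priming filter (the last stage of the
#' read funnel); by default the column sums of the count matrix are used.
#'
#' @param x A [TandemUTRSet-class] (counts aggregated per gene) or a
#'   gene x sample count matrix.
#' @param controlSample,caseSample Sample (column) names.
#' @param librarySizes Named per-sample library sizes; default column
#'   sums. Must be > 0.
#' @param minFold Fold-change threshold (default 3).
#' @param pseudocount Added to raw counts before normalization (default 1).
#' @return A [S4Vectors::DataFrame]: `geneId`, raw counts and CPM per
#'   sample, `fold` (case/control) and `deFlag` (up/down/ns).
#' @export
countAndNormalize <- function(x, controlSample, caseSample,
                              librarySizes = NULL, minFold = 3,
                              pseudocount = 1) {
  if (is(x, "TandemUTRSet")) {
    counts <- rowsum(assay(x, "counts"), rowData(x)$geneId)
  } else {
    counts <- as.matrix(x)
  }
  stopifnot(all(c(controlSample, caseSample) %in% colnames(counts)))
  if (is.null(librarySizes))
    librarySizes <- colSums(counts)
  if (any(librarySizes[c(controlSample, caseSample)] <= 0))
    stop("library sizes must be > 0")
  cpm <- sweep(counts + pseudocount, 2,
               librarySizes[colnames(counts)], "/") * 1e6
  fold <- unname(cpm[, caseSample] / cpm[, controlSample])
  deFlag <- ifelse(fold >= minFold, "up",
                   ifelse(fold <= 1 / minFold, "down", "ns"))
  out <- DataFrame(geneId = rownames(counts),
                   rawControl = unname(counts[, controlSample]),
                   rawCase = unname(counts[, caseSample]),
                   cpmControl = unname(cpm[, controlSample]),
                   cpmCase = unname(cpm[, caseSample]),
                   fold = fold, deFlag = deFlag)
  rownames(out) <- NULL
  out
}

#' Relative isoform abundance from qPCR Ct values
#'
#' Quantifies tandem 3'UTR isoform usage from two primer sets per gene: a
#' constitutive set (cUTR) upstream of the proximal site, shared by all
#' isoforms, and an extended set (eUTR) upstream of the distal site,
#' specific to the long isoforms. With `dCt = Ct_extended -
#' Ct_constitutive` per sample and `ddCt = dCt_case - dCt_control`, the
#' default ratio `2^-ddCt` (orientation `eutr-over-cutr`) is the relative
#' extended-isoform abundance in the case sample: ratio > 1 means
#' relatively more of the extended (long) isoform in the case, concordant
#' with a positive trend-test r. Orientation `cutr-over-eutr` reports the
#' reciprocal (the shortened-to-lengthened-region expression ratio).
#'
#' @param ctConstControl,ctExtControl,ctConstCase,ctExtCase Ct values
#'   (cycles) of the constitutive and extended primer sets in the two
#'   samples; vectors recycle across genes.
#' @param orientation `"eutr-over-cutr"` (default) or `"cutr-over-eutr"`.
#' @return Numeric ratio(s), always > 0.
#' @export
ddctRatio <- function(ctConstControl, ctExtControl, ctConstCase, ctExtCase,
                      orientation = c("eutr-over-cutr", "cutr-over-eutr")) {
  orientation <- match.arg(orientation)
  stopifnot(all(is.finite(c(ctConstControl, ctExtControl,
                            ctConstCase, ctExtCase))))
  dCtControl <- ctExtControl - ctConstControl
  dCtCase <- ctExtCase - ctConstCase
  ratio <- 2^(-(dCtCase - dCtControl))
  if (orientation == "cutr-over-eutr") ratio <- 1 / ratio
  ratio
}
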