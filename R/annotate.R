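#' Extract 3'UTR regions from gene models
#'
#' Noncoding models are skipped. For each coding model only the last exon
#' (transcript sense) is considered: the 3'UTR begins at the first base of
#' the stop codon when the stop codon lies inside the last exon, or at the
#' last exon's 5' end otherwise, and ends at the last exon's 3' end. The
#' CDS coordinates are taken to include the stop codon.
#'
#' @param genes A [GenomicRanges::GRanges] of transcript spans with
#'   metadata columns `geneId`, `coding`, `cdsStart`, `cdsEnd`,
#'   `exonStarts`, `exonEnds` (comma-separated, 1-based inclusive), as
#'   produced by [generateGenome()] or [readGeneModels()].
#' @return A [GenomicRanges::GRanges] of 3'UTR regions (one per coding
#'   gene) with metadata columns `geneId` and `stopInLastExon`.
#' @export
extractUTRRegions <- function(genes) {
  m <- mcols(genes)
  keep <- which(m$coding)
  chrom <- character(0); utrS <- integer(0); utrE <- integer(0)
  str <- character(0); gid <- character(0); inLast <- logical(0)
  for (i in keep) {
    exS <- .splitNum(m$exonStarts[i]); exE <- .splitNum(m$exonEnds[i])
    s <- as.character(strand(genes)[i])
    if (s == "+") {
      le <- which.max(exS)
      lastS <- exS[le]; lastE <- exE[le]
      if (m$cdsEnd[i] > lastE)
        stop(sprintf("gene %s: CDS end lies beyond the last exon", m$geneId[i]))
      stopIn <- (m$cdsEnd[i] - 2L) >= lastS && m$cdsEnd[i] <= lastE
      uS <- if (stopIn) m$cdsEnd[i] - 2L else lastS
      uE <- lastE
    } else {
      le <- which.min(exS)
      lastS <- exS[le]; lastE <- exE[le]
      if (m$cdsStart[i] < lastS)
        stop(sprintf("gene %s: CDS end lies beyond the last exon", m$geneId[i]))
      stopIn <- (m$cdsStart[i] + 2L) <= lastE && m$cdsStart[i] >= lastS
      uS <- lastS
      uE <- if (stopIn) m$cdsStart[i] + 2L else lastE
    }
    chrom <- c(chrom, as.character(seqnames(genes)[i]))
    utrS <- c(utrS, uS); utrE <- c(utrE, uE); str <- c(str, s)
    gid <- c(gid, m$geneId[i]); inLast <- c(inLast, stopIn)
  }
  GRanges(chrom, IRanges(utrS, utrE), strand = str,
          geneId = gid, stopInLastExon = inLast)
}

#' Assign poly(A) sites to genes as tandem sites
#'
#' A poly(A) site becomes a tandem site of a gene when one of three rules
#' holds (strand must match throughout, and "one and only one" candidate
#' region is required):
#' \enumerate{
#'   \item the 5' end (transcript sense) of the cleavage cluster lies
#'     within exactly one 3'UTR region;
#'   \item the cluster lies within 1 kb downstream (transcript sense) of
#'     exactly one 3'UTR region and contains a read whose alignment
#'     overlaps that region;
#'   \item the cluster lies within 1 kb downstream of exactly one 3'UTR
#'     region and contains a read whose alignment overlaps one of the
#'     tandem sites already assigned to that gene. Rule 3 is applied after
#'     rules 1-2, iterating proximal to distal until no further site is
#'     assigned.
#' }
#' A site whose cluster 5' end falls inside the 3'UTRs of two or more
#' genes is left unassigned and counted as ambiguous. Each assigned site
#' gets a tandem UTR length: the transcript-sense distance from the 3'UTR
#' begin to the representative position, inclusive.
#'
#' @param sites A clustering result from [clusterEvents()]; only clusters
#'   passing the read-support threshold are assigned.
#' @param utrs 3'UTR regions from [extractUTRRegions()].
#' @param events The cleavage-event GRanges that was clustered (carrying
#'   `alnStart`/`alnEnd` alignment extents).
#' @return A [TandemUTRSet-class]: the assigned sites ordered per gene by
#'   increasing `utrLength`, with the per-sample `counts` assay carried
#'   over; metadata `unassigned` and `ambiguous` give cluster counts.
#' @export
assignTandemSites <- function(sites, utrs, events) {
  pa <- polyASites(sites)
  n <- nrow(pa)
  rd <- rowData(pa)
  chrom <- as.character(seqnames(rowRanges(pa)))
  str <- as.character(strand(rowRanges(pa)))
  rep_ <- start(rowRanges(pa))

  # transcript-sense 5' end of each cluster
  five1 <- ifelse(str == "+",
                  vapply(rd$memberPositions, min, numeric(1)),
                  vapply(rd$memberPositions, max, numeric(1)))

  # per-cluster alignment reach, enough to decide read overlap with any
  # upstream interval (alignments end at the cleavage position)
  evChrom <- as.character(seqnames(events))
  evStrand <- as.character(strand(events))
  evKey <- paste(evChrom, evStrand, start(events))
  minAlnStart <- rep(NA_integer_, n); maxAlnEnd <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    mem <- rd$memberPositions[[i]]
    sel <- evKey %in% paste(chrom[i], str[i], mem)
    if (any(sel)) {
      minAlnStart[i] <- min(mcols(events)$alnStart[sel])
      maxAlnEnd[i] <- max(mcols(events)$alnEnd[sel])
    }
  }

  uChrom <- as.character(seqnames(utrs))
  uStr <- as.character(strand(utrs))
  uS <- start(utrs); uE <- end(utrs)
  uGene <- mcols(utrs)$geneId

  geneOf <- rep(NA_character_, n)
  ambiguous <- rep(FALSE, n)
  downstreamGene <- rep(NA_character_, n)   # unique 1-kb-downstream candidate

  for (i in seq_len(n)) {
    inUtr <- which(uChrom == chrom[i] & uStr == str[i] &
                     uS <= five1[i] & five1[i] <= uE)
    if (length(inUtr) == 1) { geneOf[i] <- uGene[inUtr]; next }
    if (length(inUtr) >= 2) { ambiguous[i] <- TRUE; next }
    cs <- rd$clusterStart[i]; ce <- rd$clusterEnd[i]
    down <- if (str[i] == "+")
      which(uChrom == chrom[i] & uStr == "+" & cs > uE & ce <= uE + 1000L)
    else
      which(uChrom == chrom[i] & uStr == "-" & ce < uS & cs >= uS - 1000L)
    if (length(down) != 1) next
    downstreamGene[i] <- uGene[down]
    # rule 2: a member read overlaps the 3'UTR itself
    j <- down
    overlapsUtr <- if (str[i] == "+") !is.na(minAlnStart[i]) && minAlnStart[i] <= uE[j]
                   else !is.na(maxAlnEnd[i]) && maxAlnEnd[i] >= uS[j]
    if (overlapsUtr) geneOf[i] <- uGene[j]
  }

  # rule 3: fixpoint over remaining downstream candidates, proximal first
  repeat {
    changed <- FALSE
    for (i in order(ifelse(str == "+", rep_, -rep_))) {
      if (!is.na(geneOf[i]) || is.na(downstreamGene[i])) next
      g <- downstreamGene[i]
      tpos <- rep_[!is.na(geneOf) & geneOf == g]
      if (length(tpos) == 0) next
      hit <- if (str[i] == "+") !is.na(minAlnStart[i]) && any(minAlnStart[i] <= tpos & tpos <= maxAlnEnd[i])
             else !is.na(maxAlnEnd[i]) && any(maxAlnEnd[i] >= tpos & tpos >= minAlnStart[i])
      if (hit) { geneOf[i] <- g; changed <- TRUE }
    }
    if (!changed) break
  }

  assigned <- which(!is.na(geneOf))
  utrIdx <- match(geneOf[assigned], uGene)
  utrLength <- ifelse(uStr[utrIdx] == "+",
                      rep_[assigned] - uS[utrIdx] + 1L,
                      uE[utrIdx] - rep_[assigned] + 1L)
  out <- pa[assigned, ]
  rowData(out)$geneId <- geneOf[assigned]
  rowData(out)$utrLength <- as.integer(utrLength)
  o <- order(rowData(out)$geneId, rowData(out)$utrLength)
  out <- out[o, ]
  metadata(out)$unassigned <- n - length(assigned)
  metadata(out)$ambiguous <- sum(ambiguous)
  methods::new("TandemUTRSet", out)
}

#' Which tandem 3'UTR isoforms contain a given site?
#'
#' Decides, for each tandem isoform of a gene, whether an interval given
#' in transcript-sense 3'UTR coordinates (for example an experimentally
#' validated miRNA target site) lies within the isoform: isoform i
#' contains the site iff the interval end is at most the isoform's tandem
#' UTR length (boundary inclusive).
#'
#' @param utrLengths Ascending tandem UTR lengths of the gene's isoforms.
#' @param siteStart,siteEnd The interval in UTR coordinates; `siteEnd`
#'   is the last coordinate that must still lie inside the UTR.
#' @return A logical vector along `utrLengths`.
#' @export
isoformMirnaPresence <- function(utrLengths, siteStart, siteEnd) {
  if (siteStart < 0 || siteEnd < siteStart)
    stop("negative or reversed interval")
  stats::setNames(siteEnd <= utrLengths,
                  paste0("isoform", seq_along(utrLengths)))
}
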