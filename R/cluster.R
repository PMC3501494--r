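#' Cluster cleavage events into poly(A) sites
#'
#' Greedy iterative clustering within each (chromosome, transcript strand)
#' group: the unclustered position with the highest pooled read count
#' (ties broken toward the smaller coordinate) seeds a cluster and absorbs
#' every unclustered position within `radius` nt of it; the seed position
#' becomes the cluster representative. The scheme is repeated until no
#' position remains, so a cluster never spans more than `2 * radius` nt.
#' Clusters supported by at least `minReads` pooled reads are poly(A)
#' sites; smaller clusters are kept in the returned object (flagged
#' `pass = FALSE`) so the read funnel still balances.
#'
#' Events are canonically sorted before the greedy pass, so the result does
#' not depend on input order. Sites are called on the pooled samples and
#' counts are carried per sample, so the same site coordinates serve every
#' sample.
#'
#' @param events A [GenomicRanges::GRanges] of width-1 cleavage events
#'   (strand = transcript strand). An optional metadata column `sample`
#'   assigns each event to a sample; absent, all events form one sample.
#' @param radius Clustering radius in nt (default 24).
#' @param minReads Minimum pooled reads for a cluster to be a poly(A) site
#'   (default 2).
#' @param samples Optional full set of sample identifiers (columns of the
#'   counts assay); defaults to the labels observed in `events`.
#' @return A [SummarizedExperiment::RangedSummarizedExperiment] whose rows
#'   are clusters (ranges = representative position, width 1) with rowData
#'   `clusterId`, `nMembers`, `memberPositions` (IntegerList),
#'   `clusterStart`, `clusterEnd`, `totalReads`, `pass`, an assay `counts`
#'   (clusters x samples), and metadata `radius`, `minReads`,
#'   `droppedClusters`, `droppedReads`.
#' @seealso [polyASites()]
#' @export
clusterEvents <- function(events, radius = 24L, minReads = 2L,
                          samples = NULL) {
  stopifnot(radius >= 0)
  samp <- mcols(events)$sample
  if (is.null(samp)) samp <- rep("sample1", length(events))
  samp <- as.character(samp)
  sampleIds <- if (!is.null(samples)) samples else sort(unique(samp))
  if (length(sampleIds) == 0) sampleIds <- "sample1"
  if (!all(samp %in% sampleIds))
    stop("events carry sample labels outside `samples`")

  chroms <- as.character(seqnames(events))
  strands <- as.character(strand(events))
  if (any(strands == "*"))
    stop("cleavage events must carry a transcript strand, found '*'")
  pos <- start(events)

  outChrom <- character(0); outStrand <- character(0); outRep <- integer(0)
  outMembers <- list(); outCounts <- NULL

  for (grp in unique(paste(chroms, strands))) {
    sel <- which(paste(chroms, strands) == grp)
    gchrom <- chroms[sel[1]]; gstrand <- strands[sel[1]]
    # per-position, per-sample tallies; canonical position order
    tab <- table(factor(pos[sel]), factor(samp[sel], levels = sampleIds))
    upos <- as.integer(rownames(tab))
    cnt <- matrix(as.integer(tab), nrow = nrow(tab),
                  dimnames = list(NULL, sampleIds))
    pooled <- rowSums(cnt)
    unclustered <- rep(TRUE, length(upos))
    while (any(unclustered)) {
      cand <- which(unclustered)
      seed <- cand[order(-pooled[cand], upos[cand])][1]
      take <- cand[abs(upos[cand] - upos[seed]) <= radius]
      unclustered[take] <- FALSE
      outChrom <- c(outChrom, gchrom); outStrand <- c(outStrand, gstrand)
      outRep <- c(outRep, upos[seed])
      outMembers <- c(outMembers, list(sort(upos[take])))
      cc <- colSums(cnt[take, , drop = FALSE])
      outCounts <- rbind(outCounts, cc)
    }
  }
  if (length(outRep) == 0) {
    outCounts <- matrix(0L, 0, length(sampleIds),
                        dimnames = list(NULL, sampleIds))
  }
  total <- as.integer(rowSums(outCounts))
  o <- order(outChrom, outRep)
  gr <- GRanges(outChrom[o], IRanges(outRep[o], outRep[o]),
                strand = outStrand[o])
  mcols(gr) <- DataFrame(
    clusterId = sprintf("cluster%05d", seq_along(o)),
    nMembers = lengths(outMembers[o]),
    memberPositions = IRanges::IntegerList(outMembers[o]),
    clusterStart = vapply(outMembers[o], function(x)
      if (length(x)) min(x) else NA_integer_, integer(1)),
    clusterEnd = vapply(outMembers[o], function(x)
      if (length(x)) max(x) else NA_integer_, integer(1)),
    totalReads = total[o],
    pass = total[o] >= minReads)
  counts <- outCounts[o, , drop = FALSE]
  rownames(counts) <- mcols(gr)$clusterId
  se <- SummarizedExperiment(assays = list(counts = counts), rowRanges = gr)
  metadata(se) <- list(radius = radius, minReads = minReads,
                       droppedClusters = sum(!mcols(gr)$pass),
                       droppedReads = sum(total[o][!mcols(gr)$pass]))
  se
}

#' Poly(A) sites from a clustering result
#'
#' Subsets a [clusterEvents()] result to the clusters supported by at
#' least the minimum number of reads (the poly(A) sites).
#'
#' @param clusters A RangedSummarizedExperiment from [clusterEvents()].
#' @return The subset of rows with `pass = TRUE`.
#' @export
polyASites <- function(clusters) clusters[rowData(clusters)$pass, ]
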