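#' Default parameters of the synthetic 3'-end sequencing substrate
#'
#' The defaults describe a two-condition tandem-UTR study: 1-4 tandem
#' poly(A) sites per gene, a 10% noncoding fraction, 10% of coding genes
#' with the stop codon in an earlier exon, 15% of genes carrying a distal
#' site up to 1 kb downstream of the last exon, 10% switching genes with a
#' usage shift of 0.3 between proximal and distal site, 10%
#' differentially-expressed genes at 4-fold, and internal-priming decoy
#' loci (A-rich stretches) next to 30% of genes.
#'
#' @return A named list of simulation parameters.
#' @export
simDefaults <- function() {
  list(
    chromCount        = 2L,
    sitesPerGeneProbs = c(0.25, 0.35, 0.25, 0.15),
    minSiteSpacing    = 80L,  # > 2*24 + 24, so jitter up to 24 nt cannot
                              # bleed reads into a neighbouring cluster

    fracNoncoding     = 0.10,
    fracNoStop        = 0.10,
    fracDownstream    = 0.15,
    fracSwitch        = 0.10,
    usageShift        = 0.30,
    fracDE            = 0.10,
    deFold            = 4,
    lastExonRange     = c(900L, 1400L),
    utrLenRange       = c(500L, 1150L),
    decoyFracLoci     = 0.30,
    pad               = 2500L
  )
}

# K positions in [lo, hi], ascending, pairwise spacing >= sp
.drawSpaced <- function(lo, hi, K, sp, what = "gene") {
  span <- hi - lo
  slack <- span - (K - 1L) * sp
  if (slack < 0L || K > slack + 1L)
    stop(sprintf("%s: config requests more sites (%d, spacing %d nt) than the last exon can hold (%d nt)",
                 what, K, sp, span + 1L))
  x <- sort(sample.int(slack + 1L, K) - 1L)
  lo + x + (seq_len(K) - 1L) * sp
}

# replace transcript-sense 'A' by a non-A base inside [from, to] (genomic)
.scrubNonA <- function(bases, from, to, strand) {
  idx <- max(1L, from):min(length(bases), to)
  if (strand == "+") {
    hit <- idx[bases[idx] == "A"]
    if (length(hit)) bases[hit] <- sample(c("C", "G", "T"), length(hit), replace = TRUE)
  } else {
    hit <- idx[bases[idx] == "T"]
    if (length(hit)) bases[hit] <- sample(c("A", "C", "G"), length(hit), replace = TRUE)
  }
  bases
}

# usage probabilities: Dirichlet-like with a uniform floor so every site
# keeps appreciable mass (sites are meant to be detectable at depth ~100)
.drawUsage <- function(K) {
  g <- stats::rgamma(K, shape = 2)
  0.7 * g / sum(g) + 0.3 / K
}

#' Generate a synthetic genome with planted tandem poly(A) sites
#'
#' Builds a toy multi-chromosome genome, two-exon gene models on both
#' strands, per-gene tandem poly(A) sites with usage distributions for two
#' conditions, planted switching and differential-expression classes, and
#' intergenic A-rich internal-priming decoy loci (>= 13 A in 20 nt). The
#' genomic sequence within +/- 24 nt of each planted site and in its 44 nt
#' transcript-sense downstream window is kept free of transcript-sense
#' adenines, so genuine sites trim and map to their exact coordinate and
#' always survive the internal-priming filter; decoy loci, conversely, are
#' guaranteed to be removed by it.
#'
#' Intergenic spacing is >= 2 kb on each side of every gene, so 1-kb
#' downstream windows never span two genes.
#'
#' @param nGenes Number of genes (>= 1).
#' @param seed Integer random seed; the output is byte-identical under the
#'   same seed.
#' @param config Named list overriding entries of [simDefaults()].
#' @return A [SapasSimulation-class] object. The truth table has one row
#'   per gene with columns `geneId`, `chrom`, `strand`, `txStart`, `txEnd`,
#'   `exonStarts`, `exonEnds`, `cdsStart`, `cdsEnd`, `coding`,
#'   `stopInLastExon`, `lastExonStart`, `lastExonEnd`, `utrStart`, `utrEnd`,
#'   `downstreamSite`, `sites` (comma list, proximal to distal), `usage1`,
#'   `usage2`, `exprFactor1`, `exprFactor2`, `switchClass`, `usageShift`,
#'   `exprFold`, `deClass`.
#' @export
generateGenome <- function(nGenes, seed = 1L, config = list()) {
  stopifnot(nGenes >= 1)
  p <- utils::modifyList(simDefaults(), config)
  set.seed(seed)

  maxK <- length(p$sitesPerGeneProbs)
  nNoncoding <- round(p$fracNoncoding * nGenes)
  noncoding <- rep(FALSE, nGenes)
  if (nNoncoding > 0) noncoding[sample.int(nGenes, nNoncoding)] <- TRUE
  codingIdx <- which(!noncoding)
  nNoStop <- round(p$fracNoStop * length(codingIdx))
  noStop <- rep(FALSE, nGenes)
  if (nNoStop > 0) noStop[sample(codingIdx, nNoStop)] <- TRUE

  chromOf <- rep(seq_len(p$chromCount), length.out = nGenes)
  strandOf <- sample(c("+", "-"), nGenes, replace = TRUE)
  Kof <- sample.int(maxK, nGenes, replace = TRUE, prob = p$sitesPerGeneProbs)
  downstreamOf <- rep(FALSE, nGenes)
  eligDown <- which(Kof >= 2)
  nDown <- round(p$fracDownstream * nGenes)
  if (nDown > 0 && length(eligDown) > 0)
    downstreamOf[sample(eligDown, min(nDown, length(eligDown)))] <- TRUE
  decoyOf <- stats::runif(nGenes) < p$decoyFracLoci

  tr <- data.frame(
    geneId = sprintf("gene%03d", seq_len(nGenes)),
    chrom = sprintf("chr%d", chromOf), strand = strandOf,
    txStart = NA_integer_, txEnd = NA_integer_,
    exonStarts = "", exonEnds = "",
    cdsStart = NA_integer_, cdsEnd = NA_integer_,
    coding = !noncoding, stopInLastExon = FALSE,
    lastExonStart = NA_integer_, lastExonEnd = NA_integer_,
    utrStart = NA_integer_, utrEnd = NA_integer_,
    downstreamSite = downstreamOf,
    sites = "", usage1 = "", usage2 = "",
    exprFactor1 = NA_real_, exprFactor2 = NA_real_,
    switchClass = "null", usageShift = 0, exprFold = 1,
    deClass = "null", stringsAsFactors = FALSE
  )

  cursor <- integer(p$chromCount)           # last used coordinate per chrom
  decoyPos <- integer(0); decoyStrand <- character(0); decoyChrom <- character(0)

  for (i in seq_len(nGenes)) {
    ch <- chromOf[i]; s <- strandOf[i]; K <- Kof[i]
    c0 <- cursor[ch]
    if (decoyOf[i]) {
      dpos <- c0 + 400L
      decoyPos <- c(decoyPos, dpos)
      decoyStrand <- c(decoyStrand, sample(c("+", "-"), 1))
      decoyChrom <- c(decoyChrom, sprintf("chr%d", ch))
    }
    L <- sample(p$lastExonRange[1]:p$lastExonRange[2], 1)
    txStart <- c0 + p$pad
    if (!tr$coding[i]) {
      lastExonStart <- txStart; lastExonEnd <- txStart + L - 1L
      txEnd <- lastExonEnd
      exS <- lastExonStart; exE <- lastExonEnd
      utrS <- NA_integer_; utrE <- NA_integer_
      siteLo <- lastExonStart + 150L; siteHi <- lastExonEnd - 60L
    } else if (s == "+") {
      exon1S <- txStart; exon1E <- txStart + 299L
      lastExonStart <- exon1E + 201L; lastExonEnd <- lastExonStart + L - 1L
      txEnd <- lastExonEnd
      exS <- c(exon1S, lastExonStart); exE <- c(exon1E, lastExonEnd)
      tr$cdsStart[i] <- exon1S + 30L
      if (noStop[i]) {
        tr$cdsEnd[i] <- exon1E - 10L
        utrS <- lastExonStart; utrE <- lastExonEnd
      } else {
        U <- sample(p$utrLenRange[1]:min(p$utrLenRange[2], L - 50L), 1)
        utrS <- lastExonEnd - U + 1L; utrE <- lastExonEnd
        tr$cdsEnd[i] <- utrS + 2L
        tr$stopInLastExon[i] <- TRUE
      }
      siteLo <- utrS; siteHi <- utrE - 60L
      if (is.na(utrS)) { siteLo <- lastExonStart; siteHi <- lastExonEnd - 60L }
      siteLo <- siteLo + 150L
    } else {
      lastExonStart <- txStart; lastExonEnd <- txStart + L - 1L
      exon1S <- lastExonEnd + 201L; exon1E <- exon1S + 299L
      txEnd <- exon1E
      exS <- c(lastExonStart, exon1S); exE <- c(lastExonEnd, exon1E)
      tr$cdsEnd[i] <- exon1E - 30L
      if (noStop[i]) {
        tr$cdsStart[i] <- exon1S + 10L
        utrS <- lastExonStart; utrE <- lastExonEnd
      } else {
        U <- sample(p$utrLenRange[1]:min(p$utrLenRange[2], L - 50L), 1)
        utrS <- lastExonStart; utrE <- lastExonStart + U - 1L
        tr$cdsStart[i] <- utrE - 2L
        tr$stopInLastExon[i] <- TRUE
      }
      siteLo <- utrS + 60L; siteHi <- utrE - 150L
      if (is.na(utrS)) { siteLo <- lastExonStart + 60L; siteHi <- lastExonEnd - 150L }
    }
    tr$txStart[i] <- txStart; tr$txEnd[i] <- txEnd
    tr$exonStarts[i] <- .joinNum(exS); tr$exonEnds[i] <- .joinNum(exE)
    tr$lastExonStart[i] <- lastExonStart; tr$lastExonEnd[i] <- lastExonEnd
    tr$utrStart[i] <- utrS; tr$utrEnd[i] <- utrE

    Kin <- if (downstreamOf[i]) K - 1L else K
    inPos <- .drawSpaced(siteLo, siteHi, Kin, p$minSiteSpacing, tr$geneId[i])
    # downstream sites sit 20-40 nt past the last exon: genuinely outside
    # the annotated 3'UTR, yet within the reach of a 47-57 nt trimmed read
    # so their clusters always contain a read overlapping the UTR
    if (s == "+") {
      sites <- inPos
      if (downstreamOf[i]) sites <- c(sites, lastExonEnd + sample(20:40, 1))
    } else {
      sites <- rev(inPos)                    # proximal first = highest coord
      if (downstreamOf[i]) sites <- c(sites, lastExonStart - sample(20:40, 1))
    }
    tr$sites[i] <- .joinNum(sites)
    cursor[ch] <- txEnd + p$pad
  }

  # planted classes ------------------------------------------------------
  eligSwitch <- which(tr$coding & Kof >= 2)
  nSwitch <- round(p$fracSwitch * nGenes)
  nSwitch <- min(nSwitch, length(eligSwitch))
  swIdx <- if (nSwitch > 0) sample(eligSwitch, nSwitch) else integer(0)
  half <- floor(length(swIdx) / 2)
  if (length(swIdx)) {
    tr$switchClass[swIdx] <- "shortened"
    tr$switchClass[swIdx[seq_len(length(swIdx) - half)]] <- "lengthened"
  }
  nDE <- round(p$fracDE * nGenes)
  deIdx <- if (nDE > 0) sample.int(nGenes, nDE) else integer(0)
  halfDE <- floor(length(deIdx) / 2)
  if (length(deIdx)) {
    tr$deClass[deIdx] <- "down"
    tr$deClass[deIdx[seq_len(length(deIdx) - halfDE)]] <- "up"
  }

  for (i in seq_len(nGenes)) {
    K <- Kof[i]
    u1 <- .drawUsage(K)
    u2 <- u1
    if (tr$switchClass[i] != "null") {
      shift <- p$usageShift
      donor <- if (tr$switchClass[i] == "lengthened") 1L else K
      recv  <- if (donor == 1L) K else 1L
      if (u1[donor] < shift + 0.05) {          # make the shift feasible
        u1[donor] <- shift + 0.05
        rest <- setdiff(seq_len(K), donor)
        u1[rest] <- u1[rest] / sum(u1[rest]) * (1 - u1[donor])
      }
      u2 <- u1
      u2[donor] <- u1[donor] - shift
      u2[recv]  <- u1[recv] + shift
      tr$usageShift[i] <- shift
    }
    tr$usage1[i] <- .joinNum(round(u1, 6) / sum(round(u1, 6)))
    tr$usage2[i] <- .joinNum(round(u2, 6) / sum(round(u2, 6)))
    f1 <- stats::runif(1, 0.8, 1.25)
    f2 <- switch(tr$deClass[i], up = f1 * p$deFold, down = f1 / p$deFold, f1)
    tr$exprFactor1[i] <- f1; tr$exprFactor2[i] <- f2
    tr$exprFold[i] <- switch(tr$deClass[i], up = p$deFold, down = 1 / p$deFold, 1)
  }
  # usage strings are renormalized after rounding; keep vectors exact
  for (i in seq_len(nGenes)) {
    u1 <- .splitNum(tr$usage1[i]); tr$usage1[i] <- .joinNum(u1 / sum(u1))
    u2 <- .splitNum(tr$usage2[i]); tr$usage2[i] <- .joinNum(u2 / sum(u2))
  }

  # sequence -------------------------------------------------------------
  chromLens <- cursor + 500L
  chromNames <- sprintf("chr%d", seq_len(p$chromCount))
  seqs <- vector("list", p$chromCount)
  for (ch in seq_len(p$chromCount)) {
    bases <- sample(c("A", "C", "G", "T"), chromLens[ch], replace = TRUE)
    gsel <- which(chromOf == ch)
    for (i in gsel) {
      for (pos in .splitNum(tr$sites[i])) {
        if (tr$strand[i] == "+")
          bases <- .scrubNonA(bases, pos - 24L, pos + 44L, "+")
        else
          bases <- .scrubNonA(bases, pos - 44L, pos + 24L, "-")
      }
    }
    dsel <- which(decoyChrom == chromNames[ch])
    for (j in dsel) {
      dp <- decoyPos[j]
      if (decoyStrand[j] == "+") {
        bases <- .scrubNonA(bases, dp - 24L, dp, "+")
        bases[(dp + 1L):(dp + 15L)] <- "A"
      } else {
        bases <- .scrubNonA(bases, dp, dp + 24L, "-")
        bases[(dp - 15L):(dp - 1L)] <- "T"
      }
    }
    seqs[[ch]] <- paste(bases, collapse = "")
  }
  genome <- DNAStringSet(unlist(seqs))
  names(genome) <- chromNames

  genes <- GRanges(tr$chrom, IRanges(tr$txStart, tr$txEnd), strand = tr$strand,
                   geneId = tr$geneId, coding = tr$coding,
                   cdsStart = tr$cdsStart, cdsEnd = tr$cdsEnd,
                   exonStarts = tr$exonStarts, exonEnds = tr$exonEnds,
                   seqlengths = stats::setNames(lengths(genome), chromNames))
  decoys <- GRanges(if (length(decoyPos)) decoyChrom else character(0),
                    IRanges(decoyPos, decoyPos), strand = decoyStrand,
                    decoyId = if (length(decoyPos))
                      sprintf("decoy%03d", seq_along(decoyPos)) else character(0),
                    seqlengths = stats::setNames(lengths(genome), chromNames))
  methods::new("SapasSimulation", genome = genome, genes = genes, truth = tr,
               decoys = decoys, params = c(p, list(nGenes = nGenes, seed = seed)))
}

#' Simulate a 3'-anchored read set for one condition
#'
#' Each genuine read is `readLength` nt: the 18-nt anchored oligo-dT linker,
#' an extra T-run (geometric, mean `tRunMean`, capped at `tRunMax`), then the
#' reverse complement of the transcript 3' terminus ending at a cleavage
#' position drawn from the gene's planted sites (per-condition usage
#' probabilities) with uniform jitter of up to `jitter` nt. Linker-less junk
#' reads and internal-priming reads at the planted decoy loci are
#' interleaved at the configured fractions. Per-gene read numbers are
#' Poisson with mean `depth` times the gene's expression factor for the
#' condition.
#'
#' @param sim A [SapasSimulation-class] from [generateGenome()].
#' @param condition 1 or 2.
#' @param depth Expected reads per gene at expression factor 1.
#' @param jitter Maximum cleavage-position jitter in nt; must be <= 24 or
#'   adjacent planted sites could merge during clustering.
#' @param junkFraction,decoyReadFraction Target fractions of linker-less
#'   junk reads and of decoy internal-priming reads among all reads.
#' @param tRunMean,tRunMax Mean and cap of the extra T-run after the linker.
#' @param readLength Read length in nt (75 by default).
#' @param seed Integer random seed.
#' @return A list with `reads` (a named [Biostrings::DNAStringSet]) and
#'   `truth`, a data.frame with one row per read: `readId`, `origin`
#'   (gene/decoy/junk), `geneId`, `site` (planted site), `cleavage`
#'   (jittered position actually transcribed), `hasLinker`.
#' @export
generateReads <- function(sim, condition = 1L, depth = 100, jitter = 5L,
                          junkFraction = 0.15, decoyReadFraction = 0.05,
                          tRunMean = 3, tRunMax = 10L, readLength = 75L,
                          seed = 1L) {
  stopifnot(is(sim, "SapasSimulation"), condition %in% c(1L, 2L))
  if (jitter > 24)
    stop("jitter > 24 nt would merge adjacent planted sites; refusing")
  set.seed(seed)
  tr <- truthTable(sim)
  genome <- genomeSeq(sim)
  decoys <- decoyLoci(sim)
  if (length(decoys) == 0) decoyReadFraction <- 0

  fac <- if (condition == 1L) tr$exprFactor1 else tr$exprFactor2
  nPer <- stats::rpois(nrow(tr), depth * fac)
  planned <- round(sum(depth * fac) / max(1e-9, 1 - junkFraction - decoyReadFraction))
  nJunk <- if (planned > 0) stats::rbinom(1, planned, junkFraction) else 0L
  nDecoy <- if (planned > 0 && decoyReadFraction > 0)
    stats::rbinom(1, planned, decoyReadFraction) else 0L

  linker <- LINKER
  tRunP <- 1 / (1 + tRunMean)

  mkRead <- function(chrom, strand, pos, tRun) {
    tail <- readLength - nchar(linker) - tRun
    if (strand == "+") {
      seg <- as.character(subseq(genome[[chrom]], pos - tail + 1L, pos))
      tailSeq <- as.character(reverseComplement(DNAStringSet(seg))[[1]])
    } else {
      tailSeq <- as.character(subseq(genome[[chrom]], pos, pos + tail - 1L))
    }
    paste0(linker, strrep("T", tRun), tailSeq)
  }

  nTotal <- sum(nPer) + nJunk + nDecoy
  seqV <- character(nTotal)
  originV <- character(nTotal); geneV <- character(nTotal)
  siteV <- rep(NA_real_, nTotal); cleavV <- rep(NA_real_, nTotal)
  linkV <- logical(nTotal)
  k <- 0L
  for (i in seq_len(nrow(tr))) {
    if (nPer[i] == 0) next
    sites <- .splitNum(tr$sites[i])
    usage <- .splitNum(if (condition == 1L) tr$usage1[i] else tr$usage2[i])
    pick <- sample.int(length(sites), nPer[i], replace = TRUE, prob = usage)
    jit <- if (jitter > 0) sample((-jitter):jitter, nPer[i], replace = TRUE) else
      integer(nPer[i])
    tRun <- pmin(stats::rgeom(nPer[i], tRunP), tRunMax)
    for (j in seq_len(nPer[i])) {
      k <- k + 1L
      pos <- sites[pick[j]] + if (tr$strand[i] == "+") jit[j] else -jit[j]
      seqV[k] <- mkRead(tr$chrom[i], tr$strand[i], pos, tRun[j])
      originV[k] <- "gene"; geneV[k] <- tr$geneId[i]
      siteV[k] <- sites[pick[j]]; cleavV[k] <- pos; linkV[k] <- TRUE
    }
  }
  if (nDecoy > 0) {
    pick <- sample.int(length(decoys), nDecoy, replace = TRUE)
    tRun <- pmin(stats::rgeom(nDecoy, tRunP), tRunMax)
    for (j in seq_len(nDecoy)) {
      k <- k + 1L
      d <- decoys[pick[j]]
      pos <- start(d)
      seqV[k] <- mkRead(as.character(seqnames(d)), as.character(strand(d)),
                        pos, tRun[j])
      originV[k] <- "decoy"; geneV[k] <- mcols(d)$decoyId
      cleavV[k] <- pos; linkV[k] <- TRUE
    }
  }
  if (nJunk > 0) {
    for (j in seq_len(nJunk)) {
      k <- k + 1L
      first <- sample(c("A", "C", "G"), 1)      # never starts with the linker
      rest <- paste(sample(c("A", "C", "G", "T"), readLength - 1L,
                           replace = TRUE), collapse = "")
      seqV[k] <- paste0(first, rest)
      originV[k] <- "junk"; geneV[k] <- NA_character_
    }
  }
  perm <- sample.int(k)                          # interleave read classes
  ids <- sprintf("read_c%d_%06d", condition, seq_len(k))
  truth <- data.frame(readId = ids, origin = originV[perm],
                      geneId = geneV[perm], site = siteV[perm],
                      cleavage = cleavV[perm], hasLinker = linkV[perm],
                      stringsAsFactors = FALSE)
  reads <- DNAStringSet(seqV[perm])
  names(reads) <- ids
  list(reads = reads, truth = truth)
}

#' Simulate per-gene 2xK switch tables directly at the count level
#'
#' Bypasses read simulation: for each gene, draws per-condition site counts
#' from a multinomial over the gene's usage distribution. Switching genes
#' move `usageShift` of probability mass from the proximal to the distal
#' site (lengthened) or the reverse (shortened) in condition 2. Column
#' scores are tandem UTR lengths drawn between 200 and 2000 nt.
#'
#' @param nGenes Number of genes.
#' @param readsPerSample Reads per gene per condition (multinomial size).
#' @param switchFraction Fraction of genes with a planted switch, split
#'   evenly between lengthened and shortened.
#' @param usageShift Planted usage shift between the two sites.
#' @param maxSites Maximum number of tandem sites per gene (K is uniform on
#'   2..maxSites).
#' @param seed Integer random seed.
#' @return A list with `tables` (list of 2xK count matrices, rows
#'   control/case), `utrLengths` (list of ascending column scores) and
#'   `truth` (data.frame with `geneId`, `class`).
#' @export
simulateSwitchTables <- function(nGenes = 2000, readsPerSample = 100,
                                 switchFraction = 0, usageShift = 0.3,
                                 maxSites = 4, seed = 1L) {
  set.seed(seed)
  nSw <- round(switchFraction * nGenes)
  class <- rep("null", nGenes)
  if (nSw > 0) {
    idx <- sample.int(nGenes, nSw)
    half <- floor(nSw / 2)
    class[idx] <- "shortened"
    class[idx[seq_len(nSw - half)]] <- "lengthened"
  }
  tables <- vector("list", nGenes)
  lens <- vector("list", nGenes)
  for (i in seq_len(nGenes)) {
    K <- sample(2:maxSites, 1)
    u1 <- .drawUsage(K)
    u2 <- u1
    if (class[i] != "null") {
      donor <- if (class[i] == "lengthened") 1L else K
      recv  <- if (donor == 1L) K else 1L
      if (u1[donor] < usageShift + 0.05) {
        u1[donor] <- usageShift + 0.05
        rest <- setdiff(seq_len(K), donor)
        u1[rest] <- u1[rest] / sum(u1[rest]) * (1 - u1[donor])
      }
      u2 <- u1
      u2[donor] <- u1[donor] - usageShift
      u2[recv]  <- u1[recv] + usageShift
    }
    tables[[i]] <- rbind(control = stats::rmultinom(1, readsPerSample, u1)[, 1],
                         case    = stats::rmultinom(1, readsPerSample, u2)[, 1])
    lens[[i]] <- sort(sample(200:2000, K))
  }
  list(tables = tables, utrLengths = lens,
       truth = data.frame(geneId = sprintf("gene%04d", seq_len(nGenes)),
                          class = class, stringsAsFactors = FALSE))
}

#' Simulate per-gene expression counts for two conditions
#'
#' Control counts are Poisson with mean `depth`; case counts are Poisson
#' with mean `depth` times the planted fold change (1, `fold` for
#' upregulated, `1/fold` for downregulated; the DE fraction is split evenly
#' between up and down so the two library sizes stay comparable).
#'
#' @param nGenes Number of genes.
#' @param depth Expected reads per gene per sample.
#' @param deFraction Fraction of genes with a planted expression change.
#' @param fold Planted fold change.
#' @param seed Integer random seed.
#' @return A list with `counts` (nGenes x 2 matrix, columns control/case)
#'   and `truth` (data.frame with `geneId`, `class` in up/down/null).
#' @export
simulateExpressionCounts <- function(nGenes = 2000, depth = 100,
                                     deFraction = 0.05, fold = 4, seed = 1L) {
  set.seed(seed)
  class <- rep("null", nGenes)
  nDE <- round(deFraction * nGenes)
  if (nDE > 0) {
    idx <- sample.int(nGenes, nDE)
    half <- floor(nDE / 2)
    class[idx] <- "down"
    class[idx[seq_len(nDE - half)]] <- "up"
  }
  mult <- ifelse(class == "up", fold, ifelse(class == "down", 1 / fold, 1))
  counts <- cbind(control = stats::rpois(nGenes, depth),
                  case    = stats::rpois(nGenes, depth * mult))
  rownames(counts) <- sprintf("gene%04d", seq_len(nGenes))
  list(counts = counts,
       truth = data.frame(geneId = rownames(counts), class = class,
                          stringsAsFactors = FALSE))
}
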