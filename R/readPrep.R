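#' Qualify and trim 3'-anchored reads
#'
#' A read qualifies only if it begins with the 18-nt anchored oligo-dT
#' linker 5'-TTTTCTTTTTTCTTTTTT-3'. The linker and the maximal following
#' run of T (and N) characters are removed; the run ends at the first A, C
#' or G. Reads whose trimmed remainder is shorter than `minLength` nt are
#' rejected as `too_short`; reads without the linker as `no_linker`.
#'
#' @param reads A [Biostrings::DNAStringSet] or character vector of raw
#'   reads (alphabet A, C, G, T, N).
#' @param minLength Minimum trimmed length (default 25 nt); the minimum is
#'   applied to the trimmed remainder, whose length drives mappability.
#' @return A [S4Vectors::DataFrame] with one row per read: `readId`,
#'   `status` (qualified/no_linker/too_short), `linkerFound`, `trimmed`
#'   (NA for rejected reads) and `trimmedLength`.
#' @export
qualifyAndTrim <- function(reads, minLength = 25L) {
  seqs <- as.character(reads)
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(seqs))
  hasLinker <- startsWith(seqs, LINKER)
  trimmed <- rep(NA_character_, length(seqs))
  trimmed[hasLinker] <- sub("^[TN]*", "", substring(seqs[hasLinker], nchar(LINKER) + 1L))
  tlen <- ifelse(is.na(trimmed), 0L, nchar(trimmed))
  status <- ifelse(!hasLinker, "no_linker",
                   ifelse(tlen < minLength, "too_short", "qualified"))
  trimmed[status != "qualified"] <- NA_character_
  DataFrame(readId = ids, status = status, linkerFound = hasLinker,
            trimmed = trimmed,
            trimmedLength = ifelse(status == "qualified", tlen, NA_integer_))
}

#' Place trimmed reads on a genome by exact full-length match
#'
#' An exact-match placer for synthetic genomes: each trimmed read is
#' searched on both strands of every chromosome and reported as unmapped
#' (0 hits), unique (1 hit) or multi (>= 2 hits). Only unique placements
#' are usable downstream. Reads containing any non-ACGT character are
#' unmapped (an exact matcher cannot place them). For real data, align
#' externally and import placements with [placementsFromSam()].
#'
#' @param qualified Output of [qualifyAndTrim()] (rejected rows are
#'   ignored), or a named character vector / DNAStringSet of trimmed reads.
#' @param genome A [Biostrings::DNAStringSet] of chromosomes.
#' @return A [S4Vectors::DataFrame]: `readId`, `status`
#'   (unique/multi/unmapped), and for unique placements `chrom`, `start`,
#'   `end` (1-based inclusive), `alnStrand` (genome strand matched).
#' @export
placeReads <- function(qualified, genome) {
  if (is(qualified, "DataFrame") && "trimmed" %in% colnames(qualified)) {
    keep <- qualified$status == "qualified"
    seqs <- qualified$trimmed[keep]
    ids <- qualified$readId[keep]
  } else {
    ids <- names(qualified)
    seqs <- as.character(qualified)
    if (is.null(ids)) ids <- sprintf("read%06d", seq_along(seqs))
  }
  n <- length(ids)
  res <- DataFrame(readId = ids, status = rep("unmapped", n),
                   chrom = rep(NA_character_, n), start = rep(NA_integer_, n),
                   end = rep(NA_integer_, n), alnStrand = rep(NA_character_, n))
  if (length(seqs) == 0) return(res)

  clean <- !grepl("[^ACGT]", seqs)
  uniqSeq <- unique(seqs[clean])
  if (length(uniqSeq) == 0) return(res)
  nHits <- integer(length(uniqSeq)); names(nHits) <- uniqSeq
  hitChrom <- character(length(uniqSeq)); hitStart <- integer(length(uniqSeq))
  hitEnd <- integer(length(uniqSeq)); hitStrand <- character(length(uniqSeq))

  # one variable-width dictionary, exact-matched via a constant trusted
  # band (max.mismatch = 0 verifies the remainder exactly)
  dict <- DNAStringSet(uniqSeq)
  widths <- nchar(uniqSeq)
  tbw <- min(25L, min(widths))
  pdF <- Biostrings::PDict(dict, tb.start = 1L, tb.width = tbw)
  pdR <- Biostrings::PDict(reverseComplement(dict), tb.end = -1L, tb.width = tbw)
  for (ch in names(genome)) {
    for (sgn in c("+", "-")) {
      m <- Biostrings::matchPDict(if (sgn == "+") pdF else pdR,
                                  genome[[ch]], max.mismatch = 0)
      cnt <- lengths(m)
      for (i in which(cnt > 0)) {
        nHits[i] <- nHits[i] + cnt[i]
        st <- IRanges::start(m[[i]])[1]
        hitChrom[i] <- ch; hitStart[i] <- st
        hitEnd[i] <- st + widths[i] - 1L; hitStrand[i] <- sgn
      }
    }
  }
  idx <- match(seqs, uniqSeq)            # NA for reads with non-ACGT
  mapped <- !is.na(idx)
  n <- ifelse(mapped, nHits[idx], 0L)
  res$status <- ifelse(n == 0, "unmapped", ifelse(n == 1, "unique", "multi"))
  one <- which(n == 1)
  res$chrom[one] <- hitChrom[idx[one]]
  res$start[one] <- hitStart[idx[one]]
  res$end[one] <- hitEnd[idx[one]]
  res$alnStrand[one] <- hitStrand[idx[one]]
  res
}

#' Infer transcript cleavage events from unique placements
#'
#' Trimmed 3'-anchored reads are reverse complements of transcript 3'
#' termini, so the transcript strand is the opposite of the alignment
#' strand and the cleavage position (last transcribed base) is the genomic
#' coordinate of the read's 5' base: the alignment start for reads placed
#' on the forward genome strand (transcript on the reverse strand), the
#' alignment end for reads placed on the reverse strand (transcript
#' forward).
#'
#' @param placements Output of [placeReads()] (or [placementsFromSam()]);
#'   only rows with status "unique" are used.
#' @param genome Optional [Biostrings::DNAStringSet] used to set sequence
#'   lengths on the result.
#' @return A width-1 [GenomicRanges::GRanges] of cleavage events, strand =
#'   transcript strand, with metadata columns `readId`, `alnStart`,
#'   `alnEnd`.
#' @export
inferCleavage <- function(placements, genome = NULL) {
  u <- placements[placements$status == "unique", , drop = FALSE]
  sl <- if (!is.null(genome)) stats::setNames(lengths(genome), names(genome)) else NULL
  if (nrow(u) == 0)
    return(GRanges(seqlengths = sl))
  pos <- ifelse(u$alnStrand == "+", u$start, u$end)
  txStrand <- ifelse(u$alnStrand == "+", "-", "+")
  gr <- GRanges(u$chrom, IRanges(pos, pos), strand = txStrand,
                readId = u$readId, alnStart = u$start, alnEnd = u$end)
  if (!is.null(sl)) GenomeInfoDb::seqlengths(gr) <- sl[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' Internal-priming filter on cleavage events
#'
#' Examines the genomic sequence 1 to 20 bases downstream (transcript
#' sense) of each cleavage position. The event is removed as an
#' internal-priming candidate if that window contains more than 12 A's,
#' the pattern AAAAAAAA, or matches `GA{4,}GA{3,}G`. Windows truncated at a
#' contig end are evaluated as-is against the same thresholds.
#'
#' @param events Cleavage events from [inferCleavage()].
#' @param genome A [Biostrings::DNAStringSet].
#' @return A [S4Vectors::DataFrame] with one row per event: `keep`,
#'   `reason` (NA, `a_count`, `a_run` or `ga_pattern`) and `window` (the
#'   transcript-sense downstream sequence examined).
#' @export
internalPrimingFilter <- function(events, genome) {
  n <- length(events)
  if (n == 0)
    return(DataFrame(keep = logical(0), reason = character(0), window = character(0)))
  chroms <- as.character(seqnames(events))
  bad <- setdiff(unique(chroms), names(genome))
  if (length(bad))
    stop("chromosome(s) absent from genome: ", paste(bad, collapse = ", "))
  pos <- start(events)
  str <- as.character(strand(events))
  key <- paste(chroms, str, pos)
  uk <- !duplicated(key)
  win <- character(sum(uk))
  uchr <- chroms[uk]; upos <- pos[uk]; ustr <- str[uk]
  for (i in seq_along(win)) {
    len <- length(genome[[uchr[i]]])
    if (ustr[i] == "+") {
      if (upos[i] >= len) { win[i] <- ""; next }
      win[i] <- as.character(subseq(genome[[uchr[i]]], upos[i] + 1L,
                                    min(upos[i] + 20L, len)))
    } else {
      if (upos[i] <= 1L) { win[i] <- ""; next }
      s <- subseq(genome[[uchr[i]]], max(1L, upos[i] - 20L), upos[i] - 1L)
      win[i] <- as.character(reverseComplement(s))
    }
  }
  nA <- vapply(strsplit(win, ""), function(x) sum(x == "A"), integer(1))
  aRun <- grepl("AAAAAAAA", win, fixed = TRUE)
  gaPat <- grepl("GA{4,}GA{3,}G", win)
  ureason <- ifelse(nA > 12, "a_count",
                    ifelse(aRun, "a_run", ifelse(gaPat, "ga_pattern", NA_character_)))
  idx <- match(key, key[uk])
  reason <- ureason[idx]
  DataFrame(keep = is.na(reason), reason = reason, window = win[idx])
}

#' Run the full read-qualification funnel for one sample
#'
#' Applies [qualifyAndTrim()], [placeReads()] (or externally supplied
#' placements), [inferCleavage()], an optional chromosome blocklist
#' (e.g. the mitochondrial genome) and [internalPrimingFilter()], and
#' returns the surviving cleavage events together with an exactly
#' balancing funnel report:
#' raw = qualified + no_linker + too_short;
#' qualified = unique + multi + unmapped;
#' unique = blocklisted + nuclear; nuclear = kept + ip_removed.
#'
#' @param reads Raw reads ([Biostrings::DNAStringSet] or character).
#' @param genome A [Biostrings::DNAStringSet].
#' @param placements Optional precomputed placements (e.g. from
#'   [placementsFromSam()]); when given, [placeReads()] is skipped.
#' @param blocklist Character vector of chromosomes to exclude after
#'   unique mapping (default none).
#' @param minLength Minimum trimmed read length (see [qualifyAndTrim()]).
#' @return A list with `events` (kept cleavage events, a GRanges),
#'   `funnel` (named integer vector of stage counts), `qualified` and
#'   `placements` (per-read DataFrames), and `ipFilter` (per-event filter
#'   DataFrame).
#' @export
prepReads <- function(reads, genome, placements = NULL,
                      blocklist = character(0), minLength = 25L) {
  q <- qualifyAndTrim(reads, minLength = minLength)
  if (is.null(placements)) placements <- placeReads(q, genome)
  ev <- inferCleavage(placements, genome)
  blocked <- as.character(seqnames(ev)) %in% blocklist
  evN <- ev[!blocked]
  ip <- internalPrimingFilter(evN, genome)
  kept <- evN[ip$keep]
  funnel <- c(raw = length(reads),
              no_linker = sum(q$status == "no_linker"),
              too_short = sum(q$status == "too_short"),
              qualified = sum(q$status == "qualified"),
              unmapped = sum(placements$status == "unmapped"),
              multi = sum(placements$status == "multi"),
              unique = sum(placements$status == "unique"),
              blocklisted = sum(blocked),
              nuclear = length(evN),
              ip_removed = sum(!ip$keep),
              kept = length(kept))
  list(events = kept, funnel = funnel, qualified = q,
       placements = placements, ipFilter = ip)
}

#' Import unique placements from a SAM file
#'
#' Accepts alignments computed by an external aligner in SAM format as a
#' drop-in replacement for [placeReads()]. Reads flagged unmapped get
#' status "unmapped"; reads marked secondary/supplementary, or whose MAPQ
#' is 0 (the convention common aligners use for multireads), are "multi";
#' all others are "unique". Requires the Rsamtools package.
#'
#' @param path Path to a SAM file.
#' @return A [S4Vectors::DataFrame] in the format of [placeReads()].
#' @export
placementsFromSam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("placementsFromSam() requires the Rsamtools package")
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "qwidth", "strand", "mapq"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  unmapped <- bitwAnd(b$flag, 4L) > 0L
  secondary <- bitwAnd(b$flag, 256L) > 0L | bitwAnd(b$flag, 2048L) > 0L
  multi <- !unmapped & (secondary | (!is.na(b$mapq) & b$mapq == 0L))
  status <- ifelse(unmapped, "unmapped", ifelse(multi, "multi", "unique"))
  DataFrame(readId = b$qname, status = status,
            chrom = ifelse(unmapped, NA_character_, as.character(b$rname)),
            start = ifelse(unmapped, NA_integer_, b$pos),
            end = ifelse(unmapped, NA_integer_, b$pos + b$qwidth - 1L),
            alnStrand = ifelse(unmapped, NA_character_, as.character(b$strand)))
}
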