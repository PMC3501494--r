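test_that("qualifyAndTrim removes linker and following T/N run", {
  tail30 <- paste0("AGCA", strrep("G", 26))
  q <- qualifyAndTrim(paste0(linkerSeq, "TT", tail30))
  expect_equal(q$status, "qualified")
  expect_equal(substr(q$trimmed, 1, 4), "AGCA")
  expect_equal(q$trimmed, tail30)

  # single mismatch inside the linker
  q <- qualifyAndTrim(paste0("TTTTCTTTTTTCTTTTAT", strrep("C", 40)))
  expect_equal(q$status, "no_linker")

  # 20 nt remainder < 25 nt
  q <- qualifyAndTrim(paste0(linkerSeq, "TTT", strrep("C", 20)))
  expect_equal(q$status, "too_short")

  # N inside the T run is trimmed with it
  q <- qualifyAndTrim(paste0(linkerSeq, "TNTT", "CGG", strrep("A", 25)))
  expect_equal(q$status, "qualified")
  expect_equal(substr(q$trimmed, 1, 3), "CGG")

  expect_equal(qualifyAndTrim("")$status, "no_linker")
})

test_that("trimming is idempotent and never leaves a leading T or N", {
  set.seed(1)
  sim <- generateGenome(6, seed = 1)
  rr <- generateReads(sim, 1, depth = 30, seed = 2)
  q <- qualifyAndTrim(rr$reads)
  tr <- q$trimmed[q$status == "qualified"]
  expect_false(any(substr(tr, 1, 1) %in% c("T", "N")))
  q2 <- qualifyAndTrim(paste0(linkerSeq, tr))
  expect_identical(q2$trimmed, tr)
  expect_true(all(q2$status == "qualified"))
})

test_that("exact placement distinguishes unique, multi and unmapped reads", {
  set.seed(42)
  seg <- randomDNA(40)
  chr1 <- paste0(randomDNA(500), seg, randomDNA(500))
  chr2 <- paste0(randomDNA(300), seg, randomDNA(300))
  genome <- DNAStringSet(c(chr1 = chr1, chr2 = chr2))

  probe <- substr(chr1, 101, 140)          # planted forward substring
  pl <- placeReads(c(u = probe), genome)
  expect_equal(pl$status, "unique")
  expect_equal(pl$chrom, "chr1")
  expect_equal(pl$start, 101L)
  expect_equal(pl$end, 140L)
  expect_equal(pl$alnStrand, "+")

  # same 40-mer planted on both chromosomes -> multi, discarded downstream
  pl <- placeReads(c(m = seg), genome)
  expect_equal(pl$status, "multi")

  pl <- placeReads(c(a = randomDNA(40)), genome)
  expect_equal(pl$status, "unmapped")

  # reverse-strand placement
  rc <- as.character(reverseComplement(DNAStringSet(substr(chr1, 201, 240))))
  pl <- placeReads(c(r = rc), genome)
  expect_equal(pl$status, "unique")
  expect_equal(pl$alnStrand, "-")
  expect_equal(pl$start, 201L)

  # an exact matcher cannot place reads containing N
  withN <- paste0(substr(probe, 1, 20), "N", substr(probe, 22, 40))
  pl <- placeReads(c(n = withN), genome)
  expect_equal(pl$status, "unmapped")
})

test_that("cleavage position is the read's 5' base, transcript strand flips", {
  pl <- DataFrame(readId = c("a", "b", "c", "d"),
                  status = rep("unique", 4),
                  chrom = "chr1",
                  start = c(2001L, 2001L, 2001L, 2001L),
                  end = c(2040L, 2040L, 2040L, 2040L),
                  alnStrand = c("-", "+", "-", "-"))
  ev <- inferCleavage(pl)
  # minus-strand alignment spanning [2001,2040]: 5' base at 2040, transcript +
  expect_equal(start(ev)[1], 2040L)
  expect_equal(as.character(strand(ev))[1], "+")
  # plus-strand alignment: 5' base at 2001, transcript -
  expect_equal(start(ev)[2], 2001L)
  expect_equal(as.character(strand(ev))[2], "-")
  # events are per read: identical alignments give distinct events
  expect_equal(sum(start(ev) == 2040L & as.character(strand(ev)) == "+"), 3L)
})

test_that("internal-priming filter removes A-rich downstream windows", {
  windows <- c(aRun = "AAAAAAAACGTCGTCGTCGT",
               aCount = "AACAACAAACAAAACAAAAC",
               gaPat = "GAAAAGAAAGCCCCCCCCCC",
               keep = "ACGTACGTACGTACGTACGT")
  for (w in names(windows)) {
    chr <- paste0(strrep("C", 35), windows[[w]], strrep("G", 30))
    genome <- DNAStringSet(c(chr1 = chr))
    ev <- makeEvents("chr1", 35L, strand = "+", tail = 30L)
    res <- internalPrimingFilter(ev, genome)
    expect_equal(res$window, unname(windows[[w]]))
    if (w == "keep") expect_true(res$keep) else expect_false(res$keep)
  }
  # reasons follow the rule that fired
  chr <- paste0(strrep("C", 35), windows[["aCount"]], strrep("G", 30))
  res <- internalPrimingFilter(makeEvents("chr1", 35L, tail = 30L),
                               DNAStringSet(c(chr1 = chr)))
  expect_equal(res$reason, "a_count")
})

test_that("internal-priming window is reverse-complemented for minus-strand events", {
  win <- "AAAAAAAACGTCGTCGTCGT"
  rcwin <- as.character(reverseComplement(DNAStringSet(win)))
  # transcript-sense downstream of a minus-strand event lies genomically
  # left of the cleavage position
  chr <- paste0(strrep("C", 30), rcwin, strrep("G", 40))
  genome <- DNAStringSet(c(chr1 = chr))
  ev <- makeEvents("chr1", 51L, strand = "-", tail = 30L)
  res <- internalPrimingFilter(ev, genome)
  expect_equal(res$window, win)
  expect_false(res$keep)
})

test_that("windows truncated at a contig end are evaluated as-is", {
  chr <- paste0(strrep("C", 50), "AAAAA")       # 5 A after position 50
  genome <- DNAStringSet(c(chr1 = chr))
  res <- internalPrimingFilter(makeEvents("chr1", 50L, tail = 30L), genome)
  expect_equal(res$window, "AAAAA")
  expect_true(res$keep)                          # 5 A <= 12, no pattern
  res <- internalPrimingFilter(makeEvents("chr1", 55L, tail = 30L), genome)
  expect_equal(res$window, "")
  expect_true(res$keep)
  expect_error(internalPrimingFilter(makeEvents("chrX", 10L), genome), "chrX")
})

test_that("funnel conserves reads at every stage", {
  sim <- generateGenome(8, seed = 21)
  rr <- generateReads(sim, 1, depth = 60, jitter = 3, junkFraction = 0.15,
                      decoyReadFraction = 0.05, seed = 22)
  p <- prepReads(rr$reads, genomeSeq(sim))
  f <- p$funnel
  expect_equal(f[["raw"]], length(rr$reads))
  expect_equal(f[["raw"]],
               f[["qualified"]] + f[["no_linker"]] + f[["too_short"]])
  expect_equal(f[["qualified"]],
               f[["unique"]] + f[["multi"]] + f[["unmapped"]])
  expect_equal(f[["unique"]], f[["blocklisted"]] + f[["nuclear"]])
  expect_equal(f[["nuclear"]], f[["kept"]] + f[["ip_removed"]])
  expect_equal(f[["kept"]], length(p$events))
})

test_that("decoy reads are all removed and jitter-free genuine reads all kept", {
  sim <- generateGenome(10, seed = 23)
  rr <- generateReads(sim, 1, depth = 60, jitter = 0, junkFraction = 0.1,
                      decoyReadFraction = 0.08, seed = 24)
  p <- prepReads(rr$reads, genomeSeq(sim))
  keptIds <- mcols(p$events)$readId
  genuine <- rr$truth$readId[rr$truth$origin == "gene"]
  decoy <- rr$truth$readId[rr$truth$origin == "decoy"]
  expect_length(intersect(decoy, keptIds), 0L)
  expect_setequal(keptIds, genuine)
})

test_that("chromosome blocklist removes events after unique mapping", {
  sim <- generateGenome(6, seed = 25)
  rr <- generateReads(sim, 1, depth = 40, jitter = 0, junkFraction = 0,
                      decoyReadFraction = 0, seed = 26)
  p <- prepReads(rr$reads, genomeSeq(sim), blocklist = "chr2")
  expect_false("chr2" %in% as.character(seqnames(p$events)))
  expect_equal(p$funnel[["unique"]],
               p$funnel[["blocklisted"]] + p$funnel[["nuclear"]])
  expect_gt(p$funnel[["blocklisted"]], 0)
})

test_that("events are invariant under genome reflection (strand symmetry)", {
  sim <- generateGenome(5, seed = 27)
  rr <- generateReads(sim, 1, depth = 40, jitter = 0, junkFraction = 0,
                      decoyReadFraction = 0, seed = 28)
  genome <- genomeSeq(sim)
  p1 <- prepReads(rr$reads, genome)
  p2 <- prepReads(rr$reads, reverseComplement(genome))
  L <- setNames(lengths(genome), names(genome))
  flip <- function(ev) {
    pos <- L[as.character(seqnames(ev))] - start(ev) + 1L
    paste(as.character(seqnames(ev)), pos,
          ifelse(as.character(strand(ev)) == "+", "-", "+"))
  }
  keyFwd <- paste(as.character(seqnames(p1$events)), start(p1$events),
                  as.character(strand(p1$events)))
  expect_setequal(flip(p2$events), keyFwd)
  expect_equal(p1$funnel, p2$funnel)
})
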