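test_that("3'UTR begins at the stop codon when it lies in the last exon", {
  # plus strand: last exon [5001,5600], CDS ends 5100 (stop = [5098,5100])
  g <- makeGene("gA", "chr1", "+", c(4501L, 5001L), c(4800L, 5600L),
                cdsStart = 4550L, cdsEnd = 5100L)
  u <- extractUTRRegions(g)
  expect_equal(start(u), 5098L)
  expect_equal(end(u), 5600L)
  expect_true(mcols(u)$stopInLastExon)

  # stop codon in an earlier exon: UTR = whole last exon
  g <- makeGene("gB", "chr1", "+", c(4501L, 5001L), c(4800L, 5600L),
                cdsStart = 4550L, cdsEnd = 4700L)
  u <- extractUTRRegions(g)
  expect_equal(start(u), 5001L)
  expect_equal(end(u), 5600L)
  expect_false(mcols(u)$stopInLastExon)

  # minus strand mirror: last exon is the leftmost, stop = [cdsStart, +2]
  g <- makeGene("gC", "chr1", "-", c(5001L, 5801L), c(5600L, 6100L),
                cdsStart = 5401L, cdsEnd = 6050L)
  u <- extractUTRRegions(g)
  expect_equal(start(u), 5001L)
  expect_equal(end(u), 5403L)

  # noncoding models produce no region
  g <- makeGene("gD", "chr1", "+", 5001L, 5600L, coding = FALSE)
  expect_equal(length(extractUTRRegions(g)), 0L)

  # CDS end beyond the last exon is a model defect
  g <- makeGene("gE", "chr1", "+", c(4501L, 5001L), c(4800L, 5600L),
                cdsStart = 4550L, cdsEnd = 5700L)
  expect_error(extractUTRRegions(g), "gE")
})

test_that("rule 1 assigns in-UTR sites and computes the tandem UTR length", {
  utrs <- GRanges("chr1", IRanges(5098, 5600), strand = "+",
                  geneId = "gA", stopInLastExon = TRUE)
  ev <- makeEvents("chr1", c(5301L, 5301L), tail = 40L)
  cl <- clusterEvents(ev)
  m <- assignTandemSites(cl, utrs, ev)
  expect_equal(nrow(m), 1L)
  expect_equal(rowData(m)$geneId, "gA")
  expect_equal(rowData(m)$utrLength, 204L)
})

test_that("rule 2 assigns a downstream site via a UTR-overlapping read", {
  utrs <- GRanges("chr1", IRanges(5098, 5600), strand = "+",
                  geneId = "gA", stopInLastExon = TRUE)
  # cleavage 40 nt past the UTR end; 51-nt alignments reach back to 5590
  ev <- makeEvents("chr1", c(5640L, 5640L), tail = 51L)
  cl <- clusterEvents(ev)
  m <- assignTandemSites(cl, utrs, ev)
  expect_equal(rowData(m)$geneId, "gA")
  expect_equal(rowData(m)$utrLength, 5640L - 5098L + 1L)

  # same cleavage with short alignments that do not reach the UTR or any
  # tandem site: no rule fires
  ev <- makeEvents("chr1", c(5640L, 5640L), tail = 20L)
  cl <- clusterEvents(ev)
  m <- assignTandemSites(cl, utrs, ev)
  expect_equal(nrow(m), 0L)
  expect_equal(metadata(m)$unassigned, 1L)
})

test_that("rule 3 chains through already-assigned tandem sites to a fixpoint", {
  utrs <- GRanges("chr1", IRanges(5098, 5600), strand = "+",
                  geneId = "gA", stopInLastExon = TRUE)
  ev <- c(makeEvents("chr1", c(5580L, 5580L), tail = 40L,
                     readIds = c("a1", "a2")),  # rule 1 (inside the UTR)
          makeEvents("chr1", c(5620L, 5620L), tail = 51L,
                     readIds = c("b1", "b2")),  # rule 2 (reads reach 5570)
          makeEvents("chr1", c(5660L, 5660L), tail = 45L,
                     readIds = c("c1", "c2")),  # reads reach 5616: only the
                                                # tandem site 5620 is hit
          makeEvents("chr1", c(5700L, 5700L), tail = 45L,
                     readIds = c("d1", "d2")))  # chains off 5660
  cl <- clusterEvents(ev)
  m <- assignTandemSites(cl, utrs, ev)
  expect_equal(nrow(m), 4L)
  expect_equal(rowData(m)$geneId, rep("gA", 4))
  expect_equal(rowData(m)$utrLength, c(483L, 523L, 563L, 603L))
})

test_that("a site inside two genes' UTRs is ambiguous and unassigned", {
  utrs <- GRanges("chr1", IRanges(c(5000, 5200), c(5600, 5800)),
                  strand = "+", geneId = c("gA", "gB"),
                  stopInLastExon = c(TRUE, TRUE))
  ev <- makeEvents("chr1", c(5300L, 5300L), tail = 40L)
  cl <- clusterEvents(ev)
  m <- assignTandemSites(cl, utrs, ev)
  expect_equal(nrow(m), 0L)
  expect_equal(metadata(m)$ambiguous, 1L)
})

test_that("downstream candidates require one and only one UTR within 1 kb", {
  utrs <- GRanges("chr1", IRanges(c(5000, 5500), c(5400, 5900)),
                  strand = "+", geneId = c("gA", "gB"),
                  stopInLastExon = c(TRUE, TRUE))
  # 6 nt past gB's UTR but also < 1 kb downstream of gA's: not unique
  ev <- makeEvents("chr1", c(5906L, 5906L), tail = 51L)
  cl <- clusterEvents(ev)
  m <- assignTandemSites(cl, utrs, ev)
  expect_equal(nrow(m), 0L)
})

test_that("minus-strand assignment mirrors the plus strand", {
  utrs <- GRanges("chr1", IRanges(5098, 5600), strand = "-",
                  geneId = "gA", stopInLastExon = TRUE)
  ev <- makeEvents("chr1", c(5301L, 5301L), strand = "-", tail = 40L)
  cl <- clusterEvents(ev)
  m <- assignTandemSites(cl, utrs, ev)
  expect_equal(rowData(m)$geneId, "gA")
  expect_equal(rowData(m)$utrLength, 5600L - 5301L + 1L)
})

test_that("on synthetic data every planted coding-gene site maps to its gene", {
  sim <- generateGenome(12, seed = 41)
  r1 <- generateReads(sim, 1, depth = 80, jitter = 0, junkFraction = 0,
                      decoyReadFraction = 0, seed = 42)
  r2 <- generateReads(sim, 2, depth = 80, jitter = 0, junkFraction = 0,
                      decoyReadFraction = 0, seed = 43)
  p1 <- prepReads(r1$reads, genomeSeq(sim))
  p2 <- prepReads(r2$reads, genomeSeq(sim))
  e1 <- p1$events; mcols(e1)$sample <- rep("control", length(e1))
  e2 <- p2$events; mcols(e2)$sample <- rep("case", length(e2))
  ev <- c(e1, e2)
  cl <- clusterEvents(ev)
  m <- assignTandemSites(cl, extractUTRRegions(geneModels(sim)), ev)
  rd <- rowData(m)
  tr <- truthTable(sim)
  for (i in which(tr$coding)) {
    planted <- as.numeric(strsplit(tr$sites[i], ",")[[1]])
    got <- start(rowRanges(m))[rd$geneId == tr$geneId[i]]
    expect_setequal(got, planted)
  }
  # tandem UTR lengths are strictly increasing within every gene
  for (g in unique(rd$geneId))
    expect_true(all(diff(rd$utrLength[rd$geneId == g]) > 0))
})

test_that("isoform miRNA-site presence is decided by containment", {
  expect_equal(unname(isoformMirnaPresence(c(500, 1000), 800, 822)),
               c(FALSE, TRUE))
  expect_equal(unname(isoformMirnaPresence(c(500, 1000), 10, 32)),
               c(TRUE, TRUE))
  expect_equal(unname(isoformMirnaPresence(c(500, 1000), 478, 500)),
               c(TRUE, TRUE))
  expect_error(isoformMirnaPresence(c(500, 1000), -5, 20), "interval")
  expect_error(isoformMirnaPresence(c(500, 1000), 30, 20), "interval")
})
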