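#' Default pipeline configuration
#'
#' Thresholds default to the method's standard values: clustering radius
#' 24 nt, at least 2 reads per poly(A) site, at least 30 reads per switch
#' table, FDR cutoff 0.01, minimum |r| 0.1, and a 3-fold differential
#' expression threshold.
#'
#' @return A nested list with a `simulate` block (used when no `inputs`
#'   block is supplied), an empty `inputs` block, `thresholds`, and
#'   `blocklist`.
#' @export
defaultPipelineConfig <- function() {
  list(
    simulate = list(nGenes = 40L, seed = 1L, depth = 100, jitter = 5L,
                    junkFraction = 0.15, decoyReadFraction = 0.05,
                    config = list()),
    inputs = NULL,
    thresholds = list(radius = 24L, minSiteReads = 2L, minTableReads = 30L,
                      fdr = 0.01, minR = 0.1, minFold = 3,
                      minTrimmedLength = 25L),
    blocklist = character(0)
  )
}

#' Run the tandem-3'UTR pipeline end to end
#'
#' Orchestrates all stages for a two-sample (control vs case) comparison:
#' read qualification and trimming, exact-match placement, cleavage
#' inference, internal-priming filtering, poly(A)-site clustering, tandem
#' 3'UTR annotation, the switching test with BH FDR control, and
#' fold-change differential expression. Inputs are either simulated (the
#' `simulate` block) or read from files (the `inputs` block with `genome`
#' FASTA, `genes` TSV from [writeGeneModels()], and `fastqControl` /
#' `fastqCase`). Library sizes for expression are the per-sample reads
#' surviving the internal-priming filter. The run is deterministic for a
#' fixed seed.
#'
#' @param config A configuration list; see [defaultPipelineConfig()].
#'   Supplied entries override the defaults entry-wise.
#' @param outDir Optional directory; when given, all intermediate tables
#'   (events, sites, models, switch results, expression, funnel report)
#'   are written there as TSV/BED.
#' @param quiet Suppress stage-boundary log lines.
#' @return A list: `sim` (when simulated), `prep` (per-sample funnels and
#'   events), `clusters`, `sites`, `utrs`, `models`, `switch`,
#'   `expression`, `funnel` (the stage-count report, samples as columns).
#' @export
runPipeline <- function(config = list(), outDir = NULL, quiet = FALSE) {
  cfg <- utils::modifyList(defaultPipelineConfig(), config)
  th <- cfg$thresholds
  say <- function(...) if (!quiet) message(sprintf(...))

  sim <- NULL
  if (!is.null(cfg$inputs)) {
    for (f in c("genome", "genes", "fastqControl", "fastqCase"))
      if (is.null(cfg$inputs[[f]]) || !file.exists(cfg$inputs[[f]]))
        stop("missing input path: ", f)
    genome <- readGenomeFasta(cfg$inputs$genome)
    genes <- readGeneModels(cfg$inputs$genes)
    readsControl <- readReadsFastq(cfg$inputs$fastqControl)
    readsCase <- readReadsFastq(cfg$inputs$fastqCase)
  } else {
    s <- cfg$simulate
    say("simulating %d genes (seed %d)", s$nGenes, s$seed)
    sim <- generateGenome(s$nGenes, seed = s$seed, config = s$config)
    genome <- genomeSeq(sim)
    genes <- geneModels(sim)
    r1 <- generateReads(sim, 1L, depth = s$depth, jitter = s$jitter,
                        junkFraction = s$junkFraction,
                        decoyReadFraction = s$decoyReadFraction,
                        seed = s$seed + 1L)
    r2 <- generateReads(sim, 2L, depth = s$depth, jitter = s$jitter,
                        junkFraction = s$junkFraction,
                        decoyReadFraction = s$decoyReadFraction,
                        seed = s$seed + 2L)
    readsControl <- r1$reads; readsCase <- r2$reads
    sim <- list(sim = sim, truthControl = r1$truth, truthCase = r2$truth)
  }

  prep <- list(
    control = prepReads(readsControl, genome, blocklist = cfg$blocklist,
                        minLength = th$minTrimmedLength),
    case = prepReads(readsCase, genome, blocklist = cfg$blocklist,
                     minLength = th$minTrimmedLength))
  say("prep: control %d/%d kept, case %d/%d kept",
      prep$control$funnel["kept"], prep$control$funnel["raw"],
      prep$case$funnel["kept"], prep$case$funnel["raw"])

  evC <- prep$control$events; evA <- prep$case$events
  mcols(evC)$sample <- rep("control", length(evC))
  mcols(evA)$sample <- rep("case", length(evA))
  events <- c(evC, evA)

  clusters <- clusterEvents(events, radius = th$radius,
                            minReads = th$minSiteReads,
                            samples = c("control", "case"))
  sites <- polyASites(clusters)
  say("clustering: %d cluster(s), %d poly(A) site(s)",
      nrow(clusters), nrow(sites))

  utrs <- extractUTRRegions(genes)
  models <- assignTandemSites(clusters, utrs, events)
  say("annotation: %d tandem site(s) in %d gene(s)",
      nrow(models), length(unique(rowData(models)$geneId)))

  switch <- testSwitching(models, "control", "case", fdrCut = th$fdr,
                          rCut = th$minR, minTotal = th$minTableReads)
  say("switch test: %d tested, %d called",
      sum(is.na(switch$skip)), sum(switch$class != "ns"))

  libSizes <- c(control = unname(prep$control$funnel["kept"]),
                case = unname(prep$case$funnel["kept"]))
  expr <- if (all(libSizes > 0) && nrow(models) > 0)
    countAndNormalize(models, "control", "case", librarySizes = libSizes,
                      minFold = th$minFold)
  else DataFrame(geneId = character(0), fold = numeric(0),
                 deFlag = character(0))

  cnt <- assay(models, "counts")
  funnel <- rbind(
    sapply(prep, function(p) p$funnel),
    genes_with_reads = sapply(c("control", "case"), function(sm)
      if (nrow(models)) length(unique(rowData(models)$geneId[cnt[, sm] > 0])) else 0L),
    polya_sites = rep(nrow(sites), 2),
    genes_with_sites = rep(length(unique(rowData(models)$geneId)), 2))

  out <- list(sim = sim, prep = prep, events = events, clusters = clusters,
              sites = sites, utrs = utrs, models = models, switch = switch,
              expression = expr, funnel = funnel, config = cfg)
  if (!is.null(outDir)) .writePipelineOutputs(out, outDir)
  out
}

.writePipelineOutputs <- function(out, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name)
    utils::write.table(as.data.frame(df), file.path(outDir, name),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  ev <- out$events
  wt(data.frame(chrom = as.character(seqnames(ev)), position = start(ev),
                strand = as.character(strand(ev)),
                readId = mcols(ev)$readId, sample = mcols(ev)$sample),
     "events.tsv")
  if (nrow(out$sites)) writeSitesBed(out$sites, file.path(outDir, "sites.bed"))
  rd <- rowData(out$models)
  wt(cbind(data.frame(geneId = rd$geneId, siteId = rd$clusterId,
                      position = start(rowRanges(out$models)),
                      utrLength = rd$utrLength),
           as.data.frame(assay(out$models, "counts"))), "models.tsv")
  wt(out$switch, "switch.tsv")
  wt(out$expression, "expression.tsv")
  utils::write.table(out$funnel, file.path(outDir, "funnel.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  if (!is.null(out$sim)) {
    writeGenomeFasta(genomeSeq(out$sim$sim), file.path(outDir, "genome.fa"))
    writeGeneModels(geneModels(out$sim$sim), file.path(outDir, "genes.tsv"))
    wt(truthTable(out$sim$sim), "truth_genes.tsv")
    wt(out$sim$truthControl, "truth_reads_control.tsv")
    wt(out$sim$truthCase, "truth_reads_case.tsv")
  }
  invisible(outDir)
}
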