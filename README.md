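# tandemUTR

Alternative polyadenylation (APA) among tandem poly(A) sites in a gene's
terminal exon produces mRNA isoforms that differ only in 3'UTR length —
and hence in miRNA target sites and stability. 3'-anchored sequencing
protocols (SAPAS-style) read from the poly(A) tail into the transcript's
3' terminus, so each uniquely mapped read marks one cleavage event at
single-base resolution.

**tandemUTR** is an R/Bioconductor-style package for researchers who want
to call per-gene tandem-3'UTR *lengthening or shortening* between two
conditions from such reads. It covers the whole path:

1. **Read qualification** — keep reads starting with the anchored
   oligo-dT linker `TTTTCTTTTTTCTTTTTT`, trim the linker and the
   following T-run, require ≥ 25 nt of remainder.
2. **Placement and cleavage inference** — exact-match placement on both
   strands (or external SAM); unique placements only; cleavage position =
   the read's 5' base, transcript strand = opposite of alignment strand.
3. **Internal-priming filter** — drop events whose 20-nt transcript-sense
   downstream window has > 12 A, contains `AAAAAAAA`, or matches
   `GA{4,}GA{3,}G`.
4. **Poly(A)-site clustering** — greedy highest-count-first clustering
   within 24 nt; sites need ≥ 2 pooled reads.
5. **Tandem 3'UTR annotation** — 3'UTRs from the stop codon (or last-exon
   5' end) to the last-exon 3' end; sites assigned by in-UTR position or,
   within 1 kb downstream, by UTR-/tandem-site-overlapping reads.
6. **Switching test** — for each co-expressed gene with K ≥ 2 tandem
   sites and ≥ 30 reads, the 2×K table of per-site counts (rows: control
   = 1, case = 2; column scores: tandem UTR lengths) is tested with the
   linear trend alternative to independence,

   *M² = (n − 1) r²  ~  χ²(df = 1)*,

   where *r* is the count-weighted Pearson correlation of row and column
   scores. *r* > 0 means longer 3'UTRs in the case sample. BH-FDR ≤ 0.01
   with |r| ≥ 0.1 calls a switch; multi-patient results merge into a
   union and a sign-consistent intersection.
7. **Expression** — per-gene counts, reads-per-million normalization
   (pseudocount 1), 3-fold up/down calls; plus the qPCR
   `2^-ΔΔCt` cUTR/eUTR ratio used for isoform-usage validation.

A first-class **synthetic-data generator** plants tandem sites, usage
shifts, expression fold changes, internal-priming decoys and linker-less
junk reads with machine-readable truth tables, so every stage is testable
against exact ground truth.

## Worked example

Simulate a 30-gene two-condition study (depth 100 reads/gene, 15% junk
reads, 5% internal-priming decoys) and run everything:

```r
library(tandemUTR)
res <- runPipeline(list(simulate = list(nGenes = 30L, seed = 11L,
                                        depth = 100, jitter = 0L,
                                        junkFraction = 0.15,
                                        decoyReadFraction = 0.05,
                                        config = list())))
res$funnel[, "control"]
#>              raw        no_linker        too_short        qualified
#>             3935              600                0             3335
#>         unmapped            multi           unique      blocklisted
#>                0                0             3335                0
#>          nuclear       ip_removed             kept genes_with_reads
#>             3335              184             3151               27
#>      polya_sites genes_with_sites
#>               65               27
```

The funnel balances exactly: 600 of 3,935 raw reads lack the linker
(the planted junk), 184 unique events sit over A-rich downstream windows
(the planted decoys) and are removed, and 3,151 events remain to infer
cleavage sites. The switch test then calls, among 27 genes:

```r
sw <- as.data.frame(res$switch)
head(sw[order(sw$q), c("geneId","K","n","r","M2","p","q","class")], 3)
#>     geneId K   n      r    M2        p        q      class
#> 14 gene015 3 229  0.350 27.86 1.31e-07 1.44e-06 lengthened
#> 23 gene025 2 209  0.367 28.08 1.16e-07 1.44e-06 lengthened
#> 22 gene023 2 168 -0.380 24.06 9.35e-07 6.85e-06  shortened
```

`gene015` shifted 0.3 of its usage toward the distal site in the case
condition: r = 0.35 > 0 reads as "longer 3'UTRs in the case sample", and
q ≤ 0.01 with |r| ≥ 0.1 calls it lengthened. Checking against the
planted truth, all three calls are the three planted switching genes
with the correct sign:

```r
merge(sw[sw$class != "ns", c("geneId","r","class")],
      truthTable(res$sim$sim)[, c("geneId","switchClass")], by = "geneId")
#>     geneId          r      class switchClass
#> 1 gene015  0.3495434 lengthened  lengthened
#> 2 gene023 -0.3795531  shortened   shortened
#> 3 gene025  0.3674474 lengthened  lengthened
```

Differential expression from the same run (3-fold rule on CPM):

```r
ex <- as.data.frame(res$expression)
ex[ex$deFlag != "ns", ]
#>     geneId rawControl rawCase cpmControl cpmCase fold deFlag
#> 24 gene027         98     390      31419  102787 3.27     up
```

A thin command-line wrapper lives in `inst/scripts/sapas-pipeline.R`
(`simulate` and `run-all` subcommands over a YAML config).

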