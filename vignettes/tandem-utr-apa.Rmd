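---
title: "Detecting tandem 3'UTR switching from 3'-anchored sequencing"
author: "tandemUTR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tandem 3'UTR switching from 3'-anchored sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemUTR)
```

## The problem

Most human genes carry several poly(A) cleavage sites in their terminal
exon. Alternative polyadenylation (APA) among such *tandem* sites produces
mRNA isoforms that differ only in 3'UTR length, and with it in miRNA
target-site content and stability. 3'-anchored protocols (SAPAS-style)
read outward from the poly(A) tail: every sequenced fragment starts with
an anchored oligo-dT linker and continues into the reverse complement of
the transcript's 3' terminus, so a single uniquely mapped read pins down
one cleavage event at single-nucleotide resolution. This package
implements the complete path from such raw reads to per-gene calls of
3'UTR lengthening or shortening between two conditions, together with a
synthetic-data generator that plants known switching events so every
stage can be validated against ground truth.

## The processing model

**Qualification and trimming.** A read qualifies only if it begins with
the 18-nt linker `TTTTCTTTTTTCTTTTTT`. The linker and the maximal
following run of T's is removed; the run ends at the first A, C or G,
and N's inside the run are trimmed with it (an N cannot prove the run
ended). The minimum length of 25 nt is applied to the trimmed remainder:
mappability of what is left is what the threshold is protecting, so the
remainder is the quantity that must clear it.

**Placement.** Trimmed reads are placed by exact full-length matching on
both strands of the genome; reads with zero hits are unmapped, reads with
two or more are discarded as multireads, and only unique placements
continue. Exact matching is the right tool for the synthetic genomes this
package generates (they contain no sequencing errors); for real data an
external aligner's SAM output can be supplied instead
(`placementsFromSam()`), with MAPQ 0 and secondary alignments treated as
multireads.

**Cleavage inference.** Because the protocol reads the reverse complement
of the transcript terminus, the transcript strand is the *opposite* of
the alignment strand, and the cleavage position — the last transcribed
base — is the genomic coordinate under the read's 5' base: the alignment
start for forward-strand placements, the alignment end for reverse-strand
placements. This orientation convention is exercised by a
genome-reflection test: reverse-complementing the genome must reproduce
all events at mirrored coordinates with flipped strands.

**Internal-priming filter.** Oligo-dT can anneal to genomically encoded
A-runs, faking cleavage signals. An event is removed when the 20-nt
transcript-sense window immediately downstream of its cleavage position
contains more than 12 A's, the pattern `AAAAAAAA`, or matches
`GA{4,}GA{3,}G`. Windows truncated at a contig end are evaluated as-is
against the same thresholds, which can only make the filter more
conservative (fewer A's fit in a shorter window).

**Clustering.** Cleavage positions within 24 nt are clustered iteratively:
the unclustered position with the highest pooled read count seeds a
cluster and absorbs everything within the radius, ties breaking toward
the smaller coordinate for determinism. Greedy highest-count seeding was
chosen over single-linkage because it bounds the span of any cluster at
twice the radius, whereas single-linkage chains can grow without bound
and swallow neighbouring sites. Clusters with at least 2 pooled reads
become poly(A) sites; singletons are dropped from the site list but kept
in the funnel report so reads remain conserved. Sites are called on the
pooled samples, so identical site coordinates serve both conditions.

**Tandem 3'UTR annotation.** Noncoding models are ignored and only the
last exon matters: the 3'UTR runs from the first base of the stop codon
(when the stop codon lies in the last exon) or from the last exon's 5'
end (when it does not) to the last exon's 3' end. A poly(A) site is a
tandem site of a gene when (1) its cluster's transcript-sense 5' end lies
inside exactly one 3'UTR; or it lies within 1 kb downstream of exactly
one 3'UTR and contains a read that overlaps (2) that UTR or (3) a tandem
site already assigned to that gene — rule 3 iterating proximal to distal
until a fixpoint. Requiring "exactly one" candidate throughout keeps
assignments unambiguous; a site inside two genes' UTRs is counted as
ambiguous and dropped. Each tandem site's UTR length is the
transcript-sense distance from the UTR begin to the cluster
representative, inclusive. Reading the convention literally, the UTR
begin includes the stop codon's first base; shifting that convention by
±3 nt would shift all of a gene's lengths uniformly and cannot change any
test outcome, because the trend statistic is invariant under affine
transformations of the column scores.

## The switching test

For a gene with $K \ge 2$ tandem sites, co-expressed in both samples
(at least one assigned read in each — the package's operationalisation;
no read at all is the only unambiguous notion of "not expressed"), the
per-site read counts form a $2 \times K$ table with the samples as rows
(row scores: control = 1, case = 2) and the sites as columns ordered by
increasing UTR length, the lengths serving as column scores. Tables with
fewer than 30 reads are skipped as underpowered. With $r$ the
count-weighted Pearson correlation between row and column scores over
the $n$ reads, the linear trend alternative to independence is

$$M^2 = (n - 1)\, r^2 \sim \chi^2_1 \quad \text{(large } n\text{)},$$

a 1-df test that spends all its power on the ordered alternative —
monotone redistribution of reads toward longer or shorter isoforms —
rather than on arbitrary deviations from independence as the
$(K-1)$-df Pearson test would. $r > 0$ means longer tandem 3'UTRs in the
case sample; $r < 0$, shorter. P-values are adjusted per comparison by
Benjamini-Hochberg, and a gene is called at $q \le 0.01$ and
$|r| \ge 0.1$; the $|r|$ floor screens out statistically significant but
biologically negligible shifts at very high counts. Degenerate tables
(a zero-variance margin) are defined to give $r = 0$, $p = 1$; columns
with zero marginal are kept, since the correlation handles them
naturally. Tests validate $M^2$ two ways: against brute-force Pearson
correlation on the expanded per-read observation pairs, and against the
$2 \times 2$ closed form $M^2 = \frac{n-1}{n}\chi^2_{\text{Pearson}}$.

Across patients, the union keeps every gene called in at least one
patient (discordant signs flagged and counted once), and the
intersection keeps genes called in all patients with the same sign.

**Expression.** Per-gene counts are the summed tandem-site reads. With
library sizes taken from the last funnel stage (reads surviving the
internal-priming filter), counts are normalized to reads per million
with a pseudocount of 1 — the pseudocount keeps fold changes defined at
zero counts and is negligible at the depths where calls are made. Genes
change expression at case/control fold $\ge 3$ (up) or $\le 1/3$ (down);
no second significance test is layered on top of the fold rule. The
companion qPCR quantity `ddctRatio()` computes
$2^{-\Delta\Delta C_t}$ from constitutive (cUTR) and extended (eUTR)
primer sets; in the default orientation a ratio above 1 means relatively
more extended isoform in the case sample, concordant with $r > 0$, and a
flag reports the reciprocal (cUTR/eUTR) orientation.

## What the generator emulates

`generateGenome()` lays out two-exon genes on both strands of a toy
multi-chromosome genome with at least 2 kb of intergenic space on each
side, so 1-kb downstream windows never touch two genes. Defaults, chosen
once as a realistic two-condition study:

| parameter | default | why |
|---|---|---|
| tandem sites per gene | 1–4 (probs 0.25/0.35/0.25/0.15) | mirrors the observed site-count spectrum |
| site spacing | ≥ 80 nt | keeps clusters separable at any honored jitter (≤ 24 nt) |
| noncoding genes | 10% | exercises the "neglect noncoding" rule |
| stop codon outside last exon | 10% of coding genes | exercises the whole-last-exon UTR fallback |
| downstream distal site | 15% of genes, 20–40 nt past the exon | exercises annotation rules 2–3 while staying within read reach |
| switching genes | 10%, usage shift 0.3 | detectable but not trivial at the default depth |
| DE genes | 10% at 4-fold, split up/down | clearly beyond the 3-fold rule; balanced so library sizes stay comparable |
| cleavage jitter | ±5 nt | models cluster width well inside the 24-nt radius |
| junk reads | 15% | realistic linker-less fraction for the qualification funnel |
| decoy reads | 5% at A-rich loci (≥ 13 A / 20 nt) | adversarial input for the internal-priming filter |
| extra T-run | geometric, mean 3, capped at 10 | only its trimming behaviour matters |
| base quality | constant `I` | quality is never used downstream |

Reads are 75 nt: linker, T-run, then the reverse complement of the
transcript ending at a cleavage position drawn from the gene's usage
distribution. Per-gene read numbers are Poisson around `depth` times the
gene's expression factor.

Two guarantees are engineered into the sequence so that truth is exact.
First, the transcript-sense bases within ±24 nt of every planted site are
kept non-A, so the T-run trimmer always stops exactly at the true
terminus and jitter-free reads map back to the planted coordinate.
Second, the 44 nt transcript-sense downstream of every planted site is
kept non-A, so genuine sites always survive the internal-priming filter,
while decoy loci carry a planted 15-A run and are always removed. These
guarantees are what let the round-trip tests assert *exact* site
recovery, exact counts, 100% decoy removal and 0% genuine loss.

What the generator deliberately does not model: sequencing errors,
PCR duplicates, real transcriptome composition, expression-coupled
usage, splicing within the read span, or chained/overlapping genes.
Passing the round-trip tests therefore demonstrates the correctness of
the pipeline's logic, not robustness to alignment noise — for real data
the alignment step should be an external mismatch-tolerant aligner via
SAM input.

Two lighter-weight generators bypass read simulation where only the
statistics are under test: `simulateSwitchTables()` draws per-gene
$2 \times K$ tables multinomially (null calibration and power), and
`simulateExpressionCounts()` draws Poisson gene counts (DE calling).

## Numerical and design choices

* Coordinates are 1-based inclusive throughout the R API
  (GRanges/IRanges convention); BED output is converted to 0-based
  half-open by the writers.
* The clustering tie-break (equal counts → smaller coordinate) and the
  canonical pre-sort make results independent of input order.
* FDR is computed per comparison across that comparison's tested genes.
* P-values are reported at full precision.
* The mitochondrial exclusion of real studies is an optional chromosome
  blocklist, empty by default for synthetic genomes.
* Degenerate inputs: empty read sets flow through every stage and yield
  an all-zero funnel; windows at contig ends are evaluated as-is; a
  jitter request above 24 nt is refused because adjacent planted sites
  could merge.

## Validation conditions and problem sizes

The test suite validates the trend statistic on 1,000 random
$2 \times K$ tables ($K \le 5$, $n \le 50$) against the brute-force
oracle and on 500 random $2 \times 2$ tables against the closed form
(both at $10^{-10}$); calibrates the null on 2,000 simulated genes at
100 reads per gene per sample, requiring the empirical $P(p < 0.05)$ in
$[0.03, 0.07]$ and BH discoveries at FDR 0.01 below 1%; requires 80%
signed recovery of 200 planted 0.3-usage-shift genes among 2,000 at
FDR 0.01 and $|r| \ge 0.1$ with empirical false discovery below 5%;
runs the full read pipeline on a 30-gene genome at depth 100 with 15%
junk and 5% decoy reads, asserting exact site and count recovery; and
requires 95% sensitivity with at most 5% false calls for planted 4-fold
expression changes at depth 100. `scripts/acceptance.R` recomputes all
of these quantities from scratch for any seed.

## Limitations

* The built-in placer is exact-match only; real reads need an external
  aligner.
* Only two-row (two-sample) comparisons are supported; multi-condition
  ordered tests and continuous covariates are out of scope.
* Expression calling is the fold rule only — no count-model inference —
  and poly(A)-site categorisation beyond gene assignment (intronic, CDS,
  known-site databases) is not implemented.
* The $\chi^2_1$ approximation of $M^2$ is a large-sample result; the
  30-read floor keeps tables in a regime where the null calibration
  holds empirically.
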