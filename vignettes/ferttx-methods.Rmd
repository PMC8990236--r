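---
title: "ferttx: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ferttx: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical and
algorithmic choices. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The setting

Three expression assays observe the same transcriptome at different
resolutions. Whole-genome sequencing (WGS) and tissue RNA-seq provide
per-locus biallelic read counts; CAGE-seq provides single-bp pileups of
capped 5' tag ends; ISO-seq provides complete exon chains per molecule.
`ferttx` implements the joint analysis: heterozygous-site detection and a
genome divergence statistic, a two-stage chi-squared test of
allele-specific expression (ASE), reads-per-million quantification, CAGE
peak calling with 5' UTR derivation, and exon-chain isoform
classification. All internal coordinates are 1-based inclusive; BED12
conversion happens only at the file boundary and is delegated to
`rtracklayer`, with round-trip tests pinning the convention.

## Variant sites and divergence

A locus is called heterozygous when **both alleles are observed in at
least `min_reads_per_allele` reads** (default 2). Otherwise the majority
allele gives a homozygous call; zero depth, or a tie below the threshold
(where no majority exists), is reported `uncallable` rather than forced
into a class. Allele A is the reference allele by convention.

Genome divergence takes locus tallies, not reads: with `Ho`
homozygous-alternative and `He` heterozygous loci against a reference
genome of size `G` (default 2.7 Gbp, cattle),

$$D = \frac{H_o + H_e/2}{G}, \qquad \text{homology} = 100\,(1 - D)\,\%.$$

Each homozygous-alternative locus differs on both haplotypes, each
heterozygous locus on one. `divergence()` computes in full precision;
reports round homology to 3 decimals. Taking `Ho`/`He` as given integers
(with `tally_zygosity()` as the bridge from a called table) keeps the
statistic reproducible from published tallies without read data.

Region classification (`classify_snp_region()`) partitions every position
against a gene model, strand-aware: exonic positions between the
transcript 5' boundary and the CDS start are 5' UTR, coding exonic
positions CDS, exonic positions past the CDS end 3' UTR, intra-span
non-exonic positions intron, all else intergenic. When a CAGE peak is
supplied its TSS-side boundary replaces the annotated first-exon edge as
the 5' UTR outer bound, and exonic positions upstream of it fall back to
intergenic — the partition property is preserved. The minus-strand logic
is tested against a mirror-coordinate oracle that reflects all
coordinates about an arbitrary point, flips strand and reuses the
plus-strand path.

## Two-stage allele-specific expression

Per heterozygous locus and tissue, with observed allele counts
$O = (O_1, O_2)$ and $R = O_1 + O_2$:

* stage 1 tests the equal-ratio null $E_i = R/2$ at
  $\alpha_\text{primary} = 10^{-4}$ (the strict cutoff stands in for
  multiplicity control over many loci; an explicit correction is out of
  scope by design);
* stage 2 re-tests stage-1 hits against the WGS-ratio null
  $E_i = R\,G_i/\sum G$ at $\alpha_\text{confirm} = 10^{-2}$, where $G$
  are the same animal's WGS allele counts at the locus.

The statistic is Pearson's $\chi^2 = \sum_i (O_i - E_i)^2/E_i$ with one
degree of freedom and **no continuity correction**; the p-value is the
upper tail. A final call requires significance under both nulls, so skew
that merely reproduces allelic bias already visible in the DNA (the
"explained-by-WGS" case) does not survive stage 2. Both stages are
retained per locus. Stage 2 is applied per SNP, not per gene — the
narrower reading of an ambiguous choice, and the one that needs no
aggregation rule.

Eligibility: only loci heterozygous in the matching animal's WGS are
tested; others are skipped with a logged reason. `min_depth` defaults to
10 reads (the chi-squared approximation is untrustworthy below that;
setting 0 disables the floor). A documented approximation check in the
tests shows the chi-squared p ranks small-depth loci ($R \le 30$)
concordantly with the exact binomial two-sided test in ≥ 95% of random
pairs; it is an approximation note, not a correctness gate.

A property test verifies type-I calibration: under a simulated null
(allele fraction 0.5, depth ≥ 50) the empirical positive rate at
$\alpha \in \{0.05, 0.01, 10^{-4}\}$ stays within three binomial standard
errors of $\alpha$.

One stated-world choice deserves a note. The bias-discrimination
property — loci whose RNA ratio equals a skewed WGS ratio of 0.6 fire at
stage 1 but not stage 2 in ≥ 95% of replicates — is only attainable when
the WGS depth comfortably exceeds the RNA depth: stage 2 treats the
WGS-estimated ratio as fixed, so ratio-estimation noise inflates the
statistic by a factor $\approx 1 + R/\sum G$. The acceptance fixture
therefore uses RNA depth 2,000 against WGS depth 20,000 (inflation 1.1,
leaving $P(\text{not significant}) \approx 0.986$ per locus). This was
fixed before measuring, from the closed form, not tuned afterwards.

## Expression

$\text{RPM}_{ij} = T_{ij}/A_j \times 10^6$, where $T_{ij}$ is reads (for
RNA-seq, read pairs) mapped to gene $i$ in tissue $j$ and $A_j$ the total
mapped for that tissue and technology; the unit difference across
technologies is a property of the inputs, not of the formula. RPKM
divides by CDS length in kbp, using the annotated coding isoform
(`cds_length()` counts exonic coding bases). "Detected" defaults to
`mapped_reads > 0` with an optional RPM floor — the narrative notion of
"no significant expression" is deliberately left configurable, and both
the flag and the raw values are reported. When the gene set tiles the
library, per-tissue RPM sums to exactly $10^6$; the generator's
multinomial totals make this an exact invariant, not an approximation.

## CAGE peaks and 5' UTR length

Within a promoter window (default ±5 kbp around the annotated transcript
5' end; the assays motivating the default do not state one), contiguous
runs of positions with ≥ `threshold` tags (default 1) on the gene's
strand form clusters; the cluster with the maximal tag sum is the gene's
peak, ties broken by proximity to the gene's 5' coding position. Zero
coverage yields "no TSS", a result, not an error. Boundaries are
reported with `stop` = the boundary farther in the **upstream**
(5'-ward, strand-aware) direction and `start` the other, so `stop` can be
numerically below `start` on either strand.

The UTR length is $|\text{stop} - \text{5' coding position}|$. The
plausible alternative — distance to the peak *center* — fails to
reproduce the published reference set this rule was validated against
(shipped in `inst/extdata/fertility_gene_tss.tsv`, 12 genes covering both
strands and both peak orientations, including peaks straddling the coding
start); the stop-boundary rule reproduces every row and is the default,
with `rule = "center"` available for comparison. The reference column's
mean is 521.8 bp; the tests assert that value as computed from the column
itself.

## Isoform classification

Isoform identity is intron-chain identity. For a candidate against a
reference set (same chromosome and strand), in order:

1. **known** — identical intron chain and both terminal ends within
   `terminal_fuzz` (default 50 bp, typical long-read end variability; a
   difference of exactly the fuzz is still known);
2. **intron_retention** — the candidate splices a proper subset of a
   reference's introns at identical coordinates (the flanking junctions
   therefore match, which distinguishes retention from novel junctions);
   retained reference-intron indices are reported, and
   `retention_dependency()` builds the per-gene implication table (e.g.
   chains retaining {2} and {2,3} give "3 ⇒ 2" true, "2 ⇒ 3" false);
3. **novel_terminal** — identical intron chain but a terminal end beyond
   the fuzz: a UTR-only variant. This call **requires** short-read
   junction corroboration (every candidate junction spanned by
   ≥ `min_junction_reads` reads); without it the chain is flagged
   `ambiguous_degradation` instead, because a 5'-truncated or extended
   chain with no independent support is indistinguishable from degraded
   RNA. Passing no junction table disables the evidence requirement
   (`multi_evidence = NA`) rather than silently failing every call;
4. **novel_junction** — everything else.

Reference preference is deterministic and order-invariant (matches are
searched in lexicographic reference-id order), and the whole
classification is translation-invariant, both property-tested. Nested
exon detection uses the host's full genomic span, boundary-inclusive —
an exon nested in another gene's intron is the motivating biology — with
an exon-level containment mode as an option; partial overlaps are never
hits.

## The synthetic world

The generator emits the stated world the tests score against, with an
explicit, mandatory seed and no global random state (each stage draws
from a fixed offset of the config seed; identical configs give
byte-identical files).

* **Annotation**: genes placed left to right with 6–10 kbp gaps (so
  ±5 kbp promoter windows never collide), exon/intron lengths from
  configurable ranges, and the planted 5' UTR realized exactly inside the
  5'-terminal exon. Planted UTR lengths default to uniform on 81–1,919
  bp, the observed range in the bovine fertility-gene reference set. The
  nested pair is built by overlapping a minus-strand host onto the last
  exon of the preceding plus-strand guest (explicit coordinates are also
  accepted). Infeasible placement is an error, not a silent truncation.
* **WGS counts**: SNPs at 5/kbp, heterozygous with probability 0.6
  (matching the roughly 60:40 het:hom-alt ratio of the published
  genome-wide tallies); depth Poisson (mean 30, typical WGS); allele A
  binomial with the configured reference bias. Error alleles at
  homozygous loci default off so genotype truth is crisp; `error_rate`
  exists for robustness tests.
* **RNA counts**: per tissue, depth Poisson (mean 100, chosen for test
  power, not to mimic any study — per-tissue depths are not published);
  allele fraction is the planted ASE effect where present (default: 10
  loci at 0.8 in every tissue), the WGS bias elsewhere. An explicit
  locus→(tissue→fraction) effect map is accepted once loci exist;
  effects at non-heterozygous loci are config errors.
* **Gene totals**: gamma weights per gene × tissue shared across
  technologies, multinomial within each library so totals conserve
  exactly. Library sizes default to 10⁶ / 10⁵ / 2×10⁴ for
  RNA-seq / CAGE-seq / ISO-seq, mirroring the real depth ordering.
* **CAGE**: a discretized symmetric triangular kernel (unimodal, finite
  support, analytically locatable mode) centered on the planted TSS;
  realized counts are rounded expectations so the mode is exact by
  construction. Background noise is available but defaults off.
* **Isoforms**: one chain per planted category, realized by chain
  algebra (donor shifted 30 bp into the intron; introns fused; 5' end
  extended 600 bp), each emitted junction supported by 50 short reads.
  The default plan covers all four categories (≥ 20 chains on the
  default 13-gene world) plus one dependency pair.

What the generator does **not** emulate: read-level errors and mapping
artifacts, overdispersion beyond binomial/Poisson, linked loci or
phasing, isoform abundance, multi-modal or shifted promoters. A green
truth-recovery test therefore establishes that the algorithms invert the
generative model they were aimed at — not that they are robust to real
sequencing noise.

## Numerical and degenerate-input choices

* Homology printed to 3 decimals; computation unrounded.
* `expected_wgs` with $\sum G = 0$, and any $E_i = 0$ in the chi-squared,
  are explicit untestable-locus errors, never silent zeros or NaN.
* RPM requires $0 \le T \le A$, $A > 0$; RPKM requires CDS length > 0.
* Peak tie-breaks (equal cluster sums, equal mode counts) resolve toward
  the gene's 5' coding position; deterministic by construction.
* `known` vs `novel_terminal` boundary: difference exactly equal to the
  fuzz is `known`.
* Zygosity ties below the het threshold are `uncallable`.

## Pipeline and reporting

`run_pipeline()` chains the stages from one config (exactly one of
synthetic or file inputs), logs one line per stage with row counts, and
writes every table as TSV plus a consolidated plain-text `report.txt`;
every number in the report is read back from a stage table. HTML output
is deliberately not produced — plain text keeps the report diffable and
the deliverable text-only. On synthetic input the report gains a
truth-scoring section (zygosity accuracy, ASE precision/recall, TSS mode
recovery, isoform accuracy, nested-exon recovery). The divergence stage
uses the synthetic chromosome length as genome size on simulated runs —
against the 2.7 Gbp default, any synthetic tally would round to 100%.

## Known limitations

Biallelic SNPs only (no indels, no multi-allelic sites); no genotype
likelihoods; no beta-binomial overdispersion in the ASE model; no
cross-technology normalization; single-TSS-per-gene reporting; no
transcript assembly or ORF annotation. Published per-study hit counts
that depend on unavailable raw reads (e.g. how many of a study's SNPs
reach significance) are not reproduction targets; the calibration and
truth-recovery properties above are what the package can and does
guarantee.
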