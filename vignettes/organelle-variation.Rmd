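---
title: "Methods: genome-wide intraspecific variation in organelle genomes"
author: "orgvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide intraspecific variation in organelle genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgvar)
library(dplyr)
```

## The question the package answers

Plant mitochondrial genomes present a long-standing puzzle: their genic
regions evolve slowly while their intergenic regions diverge so fast that
they can be impossible to align even between closely related species. One
way to separate the two candidate explanations — heterogeneous mutation
input versus heterogeneous selection — is to measure *intraspecific*
variation genome-wide: resequence many accessions of one species, call
variants against the organelle reference, and compare the per-site variant
density of every functional compartment of the genome. If mutation input is
uniform, the variant density of synonymous coding sites should match that of
intergenic DNA (both near-neutral), while nonsynonymous sites should fall
below the baseline in proportion to selective constraint.

`orgvar` implements that analysis as a reusable, tested pipeline:

1. **Functional partitioning** — every position of an annotated (usually
   circular) organelle genome receives exactly one label per layer:
   * *functional*: nonsynonymous site, synonymous site, rRNA, tRNA,
     pseudogene, intron, intergenic;
   * *copy*: single-copy vs repeat;
   * *structural* (plastids): LSC, SSC, IRA, IRB.
   The layers are orthogonal — each sums to the genome length on its own —
   so repeat statistics and functional statistics share one denominator
   total, as in the published summary tables this design mirrors.
2. **Codon-degeneracy site classification** — coding positions are divided
   into synonymous/nonsynonymous site classes from the degeneracy of their
   codon position.
3. **Hard filtering** of GATK-style variant calls, accession merging,
   transition/transversion and minor-allele-frequency summaries.
4. **Per-category abundance tables** (counts, per-site rates, mean MAF),
   structural stratification, and neutrality ratios against the intergenic
   baseline.
5. **Windowed depth profiling** for copy-number evidence.
6. A **synthetic-data generator** that produces every input the pipeline
   consumes, with known ground truth.

## Coordinate and representation conventions

All internal coordinates are **1-based, fully inclusive** — the GFF3, VCF
and IRanges convention. BED input (0-based half-open) is converted at the
I/O boundary. An interval whose start exceeds its end wraps the origin and
is only legal on a circular genome; tests verify that a wrapping feature
yields the same category lengths as the equivalent rotated genome.

The partition is stored as three per-position factor vectors. For organelle
genomes (0.1–0.5 Mb) this is a few megabytes and keeps every downstream
count a plain `table()`; no interval algebra can disagree with it.

## Functional partitioning

**Precedence.** Published category lengths sum exactly to the genome
length, implying every position got exactly one functional label, but no
overlap-resolution rule is ever stated in this literature. We therefore
assign by a configurable precedence, default

> CDS > rRNA > tRNA > pseudogene > intron > intergenic,

mirroring functional importance: a tRNA inside a group-II intron is counted
as tRNA, a coding position inside a repeat is still a coding position.
Assignment is canonical (features are processed in a deterministic order),
so permuting the annotation's record order cannot change the partition —
a property the tests enforce. When two genes' CDS parts overlap, the gene
first in canonical order (id, then start) keeps the position, with a
warning.

**Introns** are derived, not read: for every gene with multi-part CDS (or
exon) structure, introns are the gene span minus the union of its parts.

**Repeats** are taken from the annotation or a BED file, never detected de
novo — published repeat compartments are annotation-derived and a detection
method would add an uncontrolled degree of freedom.

**Structural regions.** The two inverted-repeat intervals are supplied by
the caller (IRs are universally reported with plastid genome accessions).
Of the two remaining arcs of the circle the longer is LSC, the shorter SSC.
Reverse-complement identity of the IRs is checked but only warned about,
since annotated IR copies occasionally differ by a few indels. IRA and IRB
are merged into a single IR stratum for reporting.

## Codon degeneracy and site classes

A codon position is *d*-fold degenerate when *d* of the three possible
single-base substitutions preserve the amino acid (0 preserved → 0-fold,
1 → 2-fold, 2 → 3-fold, 3 → 4-fold). The default genetic code is NCBI
table 1: plant organelle CDSs use the standard code.

The published tables report an *integer bipartition* of CDS length into
nonsynonymous and synonymous sites, but the exact rule behind those numbers
(4-fold only? ≥ 2-fold? rounded fractional weights?) is not recoverable
from methods sections that merely cite "degeneracy of the codons". We
therefore expose three modes and do not attempt to match any particular
published split:

* `fourfold` (default): synonymous iff 4-fold degenerate. The only
  unambiguous hard rule; it undercounts synonymous capacity at 2-fold
  sites but keeps "synonymous site" meaning *any change is silent*.
* `any_syn`: synonymous iff ≥ 2-fold. The permissive hard rule; for every
  sequence its synonymous-site count is ≥ the fourfold count (tested).
* `fractional`: Nei–Gojobori-style weights, (preserving changes)/3 per
  position; exact but non-integer.

Edge cases, chosen to keep layer sums equal to annotated CDS length: the
terminal stop codon's positions are kept and classed nonsynonymous (weight
0); codons containing N are classed nonsynonymous with a warning; internal
stops are an error in strict mode; a phase offset or non-multiple-of-3
remainder flags the gene non-canonical, classifies its complete codons, and
classes leftover positions nonsynonymous.

Minus-strand genes are reassembled in strand-aware transcription order
(parts by descending start, each part reverse-complemented) before
classification; the genomic position of every site class is retained.

## Variant filtering and summaries

The hard filter is the strict organelle criterion set
`QUAL < 60, QD < 20.0, FS > 10.0, MQ < 30.0`
(fail if **any** holds). The inequalities are strict as printed: a variant
sitting exactly on a threshold passes. Missing QD/FS/MQ annotations fail
closed by default — with hundreds of accessions an unannotated call is more
likely a caller hiccup than a confident variant — and `missing = "pass"` is
available. The filter is a pure monotone predicate: relaxing any threshold
can only admit more variants (tested by property).

The published workflow filters per accession and again after merging; we
implement one parameterised pass applied at both stages with identical
thresholds. Merging takes the union of sites, requires a consistent
reference allele, deduplicates alternates in first-seen order, and genotypes
absent accessions as reference (configurable to missing; the published
convention is unstated). Site annotations of a merged record are the means
of the per-accession values, which keeps the merge independent of input
order.

Organelle genotypes are haploid. Diploid-encoded homozygous calls collapse;
heterozygous calls (heteroplasmy or mapping noise — their handling is never
stated in this literature) resolve to the site's major allele by default,
with `first` and `missing` policies available.

**MAF** is the frequency of the second most frequent allele among
non-missing sampled accessions; the reference genome is not a sample, so a
fixed difference from the reference has MAF 0 — which reproduces the
qualitative "MAF 0.0000" pattern of published tables, though whether those
tables used this convention is unknowable. The per-category MAF column is
an arithmetic mean over the category's variant sites (median via
`maf_fun`); published tables print one MAF per category without naming the
aggregator, and the mean is the simplest consistent choice.

**Ts/Tv** counts biallelic SNPs only (multiallelic SNPs are excluded, the
standard convention); the ratio is undefined when there are no
transversions, and reports round it to 2 decimals. Multiallelic SNPs still
count once toward category SNP counts — both behaviours are fixed and
tested.

**CDS SNP classification** defaults to the *site class* of the position
(`cds_mode = "site"`), so the numerator matches the denominator's
definition and abundance stays a true per-site rate. The alternative
(`"effect"`: synonymous iff every alternate allele leaves the amino acid
unchanged) is provided because published wording is ambiguous between the
two; non-CDS rows are identical under either mode (tested). Indels are
assigned to the category of their VCF anchor position — boundary-spanning
attribution is never specified in this literature.

Report tables round per-site rates and MAFs to 4 decimals, matching
conventional table precision; full precision is retained in memory.

## Depth windowing and copy number

Depth input is the 3-column `samtools depth` contract; positions absent
from the file are zero-coverage (the producing tool omits them by default).
Windows tile the genome from position 1 at 1000 bp — the conventional
resolution for organelle copy-number profiling; the final partial window is
averaged over its own length (droppable via `drop_partial`). Window means
include zero-depth positions, so total depth is conserved exactly under
windowing (tested).

Normalisation divides by the **median** window mean — robust to the CNV
segments themselves, unlike the mean — and a simple fold-change flag marks
windows outside [0.5, 2]. No segmentation or significance machinery is
attached: the upstream evidence for organelle CNV is visual depth
heterogeneity plus ddPCR validation, and a heavier caller would claim more
than the data model supports. GC-bias correction is a known confounder of
depth-based copy number and is deliberately out of scope.

## The synthetic generator: what it emulates, what it does not

`simulate_genome()` plants valid ORFs (start codon, no internal stop, whole
codons, some split by one intron), rRNA/tRNA/pseudogene features, exact
duplicated repeat pairs and an optional reverse-complement IR pair in a
random circular sequence. `simulate_variants()` makes every position a
variant site independently with the per-site probability of its functional
category, draws alternate alleles with a transition:transversion odds,
carrier counts from the allele-frequency law, and QUAL/QD/FS/MQ so that an
expected fraction `f_fail` fails the hard filter. `simulate_depth()` draws
Poisson depth around `mean_depth × fold` with configurable fold segments.
Everything is byte-deterministic under a seed.

Defaults are fixed at the magnitudes of published organelle population
data: a 200 kb circle with 20 accessions; per-site SNP rates 4×10⁻⁴
(nonsynonymous) to 2.2×10⁻³ (introns) with intergenic = synonymous =
9×10⁻⁴ — the neutral-baseline contrast that is the analysis' headline;
indel rates 2–5×10⁻⁴ confined to non-coding categories; ts:tv odds 2:1
(plant mitogenome-like); `f_fail` 0.3 (strict criteria discard a sizeable
minority of raw calls); 50× depth with fold-2 and fold-0.5 segments of five
windows each. Carrier counts default to uniform minor-allele counts on
`1..n/2`; the `uniform` law adds reference-fixed sites (MAF 0).

Deliberate non-features, stated as limitations: variants are linkage-free
(sufficient for abundance statistics, wrong for haplotype structure);
repeat copies mutate independently (no gene-conversion homogenisation, so
the generator cannot *create* the repeat-vs-single-copy rate differences
the real data show — it can only test that rates put in are measured back);
no read-level simulation, recombination, or substoichiometric dynamics.
Passing recovery tests therefore demonstrates that the measurement
machinery is unbiased under the generative model, not that real organelle
data satisfy that model.

## Test design and problem sizes

Each operation is checked against an independent oracle where one exists:
exhaustive 9-mutant enumeration for all 61 sense codons (degeneracy); a
naive membership-mask partitioner (functional layers); brute-force
Nei–Gojobori sums (fractional weights); hand-computed toy genomes (a 100 bp
genome with one ORF, rRNA and an overlapping repeat). Published summary
statistics whose inputs are printed — transition/transversion counts,
per-category SNP counts and lengths — are recomputed through the package's
own machinery and compared at printed precision.

Stochastic checks use sizes chosen for statistical power at fixed seeds:
parameter recovery on the 200 kb / 20-accession default (each category's
abundance within 3 binomial SEs of its rate); the neutral-contrast check on
elevated rates (synonymous = intergenic = 0.02, nonsynonymous = 0.004)
because the default rates leave the ratio's sampling error wider than the
0.8–1.25 classification band at realistic synonymous-site counts; CNV
recovery as 30 replicates of a 20 kb genome with five-window fold-2 and
fold-0.5 segments, requiring the mean recovered fold within 10% of truth.

## Known limitations

* Precedence-based single labelling discards overlap information; a
  position inside both a tRNA and an intron counts once.
* The fourfold default undercounts synonymous opportunity relative to
  fractional counting; comparisons across studies must match modes.
* Indel anchoring to one position misattributes indels spanning category
  boundaries.
* Median normalisation of depth assumes CNV segments cover well under half
  the genome.
* The merge's mean-aggregation of QUAL/QD/FS/MQ is one defensible choice
  among several; re-deriving annotations from reads is out of scope.
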