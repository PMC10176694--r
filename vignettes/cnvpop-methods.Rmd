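---
title: "Population CNV analysis with cnvpop: methods and design notes"
author: "cnvpop authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population CNV analysis with cnvpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvpop)
```

## Scope

`cnvpop` implements the population-genetic half of a resequencing CNV
study in a two-population panel (cultivated accessions versus their wild
relatives): everything downstream of the per-accession CNV caller. The
caller itself (read alignment, split-read/read-pair/read-depth
evidence) is out of scope; the pipeline starts from a table of
per-accession deletion and duplication calls and ends with CNV regions
(CNVRs), their linkage disequilibrium with SNPs, copy-number
population-differentiation statistics, gene-level annotation, and a
benchmarking module for scoring any caller's output against a truth
set. A synthetic-data generator provides panels with known planted
truth, so that every stage can be validated end to end.

## Coordinate conventions

All intervals are 0-based half-open internally. GFF3 and VCF are
1-based on disk and converted at the boundary; BED passes through
unchanged. The CNV call TSV carries an explicit `#coords=` directive
(`0half` or `1incl`) so a file is never ambiguous about its dialect.

## CNVR definition

Calls shorter than 50 bp are discarded (the conventional lower bound of
the CNV size definition; the boundary is inclusive, `length >= 50`, and
configurable). Remaining calls are merged into CNVRs by deterministic
greedy clustering under *stringent reciprocal overlap*: calls are
sorted by (chrom, start, end, accession) and scanned once; a call joins
the open cluster iff its overlap with the cluster's running extent is
at least 90% of the call length *and* at least 90% of the extent
length, and the extent then grows to the union. The underlying merge
rule in the literature is ambiguous about clique versus chain
semantics; the greedy sort-ordered reading used here is one defensible
interpretation, is fully deterministic, and is pinned by an
oracle-equivalence test against an independent re-implementation.

Clusters present in fewer than 10 distinct accessions are dropped. An
accession contributing both a deletion and a duplication to one cluster
counts once, with both event flags; a CNVR is typed `loss` if all
carrier events are losses, `gain` if all are gains, `both` otherwise.

CNVR genotypes follow the published recoding: a loss carrier is `0/1`,
a gain carrier `1/1`, a non-carrier `0/0`, one VCF record per CNVR
(`SVTYPE=CNV`, class in `INFO/CNVCLASS`). Two consequences are worth
stating plainly:

* the recoding is zygosity-blind — a homozygous deletion is still
  written `0/1`, because the upstream evidence does not genotype copy
  number per allele; we follow the published convention literally;
* an accession with both events in one CNVR is emitted `1/1`
  ("gain wins") — an arbitrary but pinned tie-break.

Under this recoding the CNVR minor allele frequency counts 1 alt
allele per loss carrier and 2 per gain carrier over `2N` alleles,
folded to the minor side; CNVRs with MAF < 0.05 can be filtered to
match the SNP panel's criterion.

## LD rank classification

For each CNVR, up to 300 SNPs upstream and 300 downstream (same
chromosome, MAF >= 5%, SNPs inside the CNVR span excluded) are
selected. All SNP–SNP pairwise r² among the selected SNPs and all
CNVR–SNP r² are pooled and ranked by decreasing r² with average ranks
on ties. `N` is the number of CNVR–SNP values ranking strictly better
than the median rank of the SNP–SNP values. With 600 SNPs the
category boundaries are the published 0–200 / 200–400 / 400–600; with
fewer SNPs (chromosome ends, sparse maps) the thresholds scale to
thirds of the achieved SNP count rather than dropping the CNVR, and
`n_snps_used` is reported so such cases are visible.

Two readings of "ranking over the median" coincide when the pooled
values are tie-free: counting by rank and counting CNVR–SNP r² values
above the median SNP–SNP r². The implementation records both (`N` and
`N_value`) and a property test asserts their equality on tie-free
data; `N` (the rank reading) drives classification. r² itself is the
squared Pearson correlation of allele dosages with pairwise-complete
handling of missing genotypes (the default behaviour of the standard
PLINK `--r2` computation); missing dosages are never imputed.

## Vst

For a gene with CN vectors $x_1$ (cultivars) and $x_2$ (wild):

$$V_{st} \;=\; \frac{V_{total} - (V_1 N_1 + V_2 N_2)/N_{total}}{V_{total}}$$

where all variances use the population (denominator-$N$) estimator.
This choice is forced by internal consistency: the formula weights
group variances by group *sizes*, which only telescopes with the law
of total variance under $N$-denominator variances. A consequence is
that $V_{st}$ is structurally non-negative (the size-weighted
within-group variance can never exceed the pooled variance), so no
clamping to $[0,1]$ is ever applied — the bound holds by construction,
not by truncation. $V_{st}$ is undefined (NA) when the pooled variance
is zero (CN constant across the panel); such genes are reported but
excluded from ranking.

"Top 1%" uses the empirical type-7 quantile of the defined Vst values
with ties at the cutoff included, so gene counts are reproducible for
a given input. Per-gene group comparisons use the two-sided Wilcoxon
rank-sum test with continuity correction; a gene with identical CN
everywhere is flagged degenerate with p = 1.

The wild panel can be restricted to a subset of accessions (the
analysis situation where only the progenitor species among the wild
relatives are informative) via `vst_scan(wild_subset = ...)`.

## Annotation and feature impact

A gene is *CN-variable* when the union of CNVRs covers strictly more
than 50% of its span (plural CNVRs are unioned before the fraction is
taken; the inequality is strict at 0.5).

Feature-impact accounting unions calls per event type first
("non-overlapping CNVs") and reports, per feature class, the
percentage of bases covered by the deletion union and duplication
union. Flank size is not standardised anywhere; the default is 2 kb
and configurable. The classes exon / intron / flank-upstream /
flank-downstream / intergenic partition the genome under the pinned
precedence *gene body (exon over intron) > upstream flank > downstream
flank > intergenic*, which makes the conservation test (interval
arithmetic equals per-base scanning, exactly) well-posed; CDS,
exon and gene-body rows additionally report their own overlapping
totals.

Windowed densities assign a feature to a window by its *start*
coordinate (not bp overlap — pinned, documented); both non-overlapping
(step = window) and sliding windows are supported, and only windows
fully contained in the chromosome are emitted (a chromosome shorter
than one window yields a single clipped window). Term enrichment is a
plain one-sided Fisher exact test per term with Benjamini–Hochberg
correction — a deliberate simplification of DAG-aware GO algorithms
(topGO's `elim`), which are out of scope; with a flat term map the
Fisher tail is exactly the hypergeometric tail asserted by the test
oracle.

## Benchmarking

`match_calls` scores a call set against a truth set by greedy bipartite
matching: candidate pairs share chromosome (and type, by default) and
overlap reciprocally at >= 50% of both lengths — the matching criterion
is not standardised in the literature, so the common SV-benchmarking
default is adopted and exposed as a flag. Pairs are accepted in order
of decreasing overlap fraction (ties by input order), each truth entry
and each call matched at most once; TP/FN/FP, TPR and FDR follow.
Greedy rather than optimal assignment is used: it is deterministic,
near-optimal for interval data, and verified against an exhaustive
oracle on small instances.

## PCA

`genotype_pca` performs centred-dosage PCA of samples over any
genotype matrix (SNPs or recoded CNVRs). Monomorphic markers are
dropped, missing dosages mean-imputed per marker (equivalent to
zero-filling after centring), and an optional flag applies
allele-frequency scaling by $\sqrt{p(1-p)}$ in the style of smartpca;
plain centring is the default because the qualitative claim the module
supports (two-population separation) is robust to the normalisation.
Eigenvector signs are fixed deterministically (largest-magnitude
loading made positive) so scores are stable across runs.

## The synthetic world

The generator emulates the statistical structure the analysis assumes,
not sequencing reads:

* **Genome**: equal-length chromosomes; genes placed uniformly without
  overlap (spans 1–5 kb, 1–5 exons each); TEs placed independently at
  a target bp density. Default panel sizes mirror a 289-cultivar /
  57-wild design.
* **CNV loci**: lengths log-uniform between 100 bp and 50 kb (the true
  length distribution beyond published histogram bins is unknown; this
  is a modelling choice, not a data fact). The DEL:DUP ratio defaults
  to 10:1, mirroring the strong deletion excess in published call
  sets. Carriers are independent Bernoulli draws at per-population
  locus frequencies; each carrier's call takes truncated Gaussian
  breakpoint jitter constrained to keep >= 90% reciprocal overlap with
  the planted locus and length >= `min_len`, so planted truth is
  consistent with the merge criterion and recovery tests are
  well-posed. Loci are placed with a guard gap (0.2 × max length, and
  at least 8 jitter SDs) so distinct loci cannot chain into one CNVR.
* **SNPs**: founder-mosaic haplotypes (default 20 founders,
  recombination breakpoints ~ every 50 kb) rather than a coalescent —
  the LD module only needs tunable block-wise r², not realistic
  genealogies. Emitted SNPs satisfy the MAF floor; candidates are
  redrawn a bounded number of times, then the generator errors.
* **CN matrix**: baseline 2.0; −1 per planted deletion and +1 per
  planted duplication for carriers of loci overlapping the gene;
  additive Gaussian noise (default SD 0.2 CN units, a realistic
  depth-estimation error at moderate coverage); clipped at 0.

All randomness flows from one explicit integer seed per operation and
the global RNG state is restored afterwards; identical seeds give
bit-identical output.

What a green test on this world does *not* establish: robustness to
depth-dependent caller sensitivity, breakpoint errors beyond the 90%
reciprocal-overlap envelope, reference bias, or population structure
more complex than two labelled groups. Published headline numbers from
real panels (counts of CNVRs, genome fractions, LD proportions)
depend on terabytes of reads and specific callers and are not
reproduced here; the package's claims are property-based.

## Numerical choices and degenerate inputs

* Vst hand-fixtures are asserted to 1e-12; PCA orthogonality and
  reconstruction to 1e-8.
* r² is NA (not 0) when either vector is constant after
  pairwise-complete filtering; such pairs are dropped from LD pools.
* A CNVR with zero eligible flanking SNPs is flagged unclassifiable
  rather than silently dropped.
* Merging tie-break: sort key (chrom, start, end, accession); equal
  calls always cluster identically.
* The infeasible-packing guard in the genome simulator errors rather
  than looping when requested gene spans cannot fit.

## Known limitations

* The LD scan computes up to C(600, 2) SNP–SNP r² per CNVR; a
  `max_pairs` subsampling option (pinned seed) exists for large scans.
* One CN value per gene per accession is assumed; window-level CN
  averaging upstream of the matrix is the caller's concern.
* The enrichment module treats terms as flat sets; no ontology DAG.
* `read_gff_genes` expects the conventional gene/mRNA/exon/CDS
  hierarchy; exotic GFF3 layouts (multiple mRNAs are fine, orphan
  features are not) are not normalised.
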