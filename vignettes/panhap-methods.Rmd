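---
title: "Methods and design of the panhap analysis stack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the panhap analysis stack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panhap)
```

panhap implements the downstream analysis layer of a multi-genome crop
pan-genome study: it consumes orthogroup tables, VCFs, GFF3 gene models
and phenotype tables, and produces pan-genome composition and growth
curves, a functional variant catalogue, a merged SV catalogue, and
haplotype–phenotype calls. This vignette records the models, the
tunable parameters, the numerical choices, and what the synthetic-data
generators do and do not emulate.

## Pan-genome classification and rarefaction

A presence/absence matrix (`pa_matrix`) holds F gene families over N
genomes. `classify_families()` partitions families by occupancy o:
core (o = N), softcore (softcore_min ≤ o ≤ N−1; default
softcore_min = N−1), dispensable (2 ≤ o < softcore_min) and private
(o = 1). The classes are mutually exclusive — the published composition
tables this reproduces total 100%, which forces exclusivity — and the
reported percentages use largest-remainder rounding at 2 decimals, the
convention under which a composition column sums to exactly 100.00
rather than 99.99 or 100.01. (Plain per-entry rounding of a 50.9044%
share prints 50.90; composition tables print 50.91 because the missing
hundredth goes to the largest remainder.)

`rarefy()` draws, for each subset size k = 1..N, `reps = 1000`
independent uniform k-subsets of genomes and records pan (families in
at least one subset genome) and core (families in all of them). When
`choose(N, k) <= reps` the subsets are enumerated exhaustively once
each instead — so small designs are exact, and the sampled path can be
validated against the exhaustive one. Replicate subsets are drawn
independently (the same subset may recur), which is standard
rarefaction practice; per-replicate nested monotonicity (pan
non-decreasing, core non-increasing as genomes accumulate) holds by
construction of union and intersection.

`fit_growth_models()` fits the conventional pan power law
\(P(k) = A_p k^{B_p} + C_p\) and core exponential decay
\(C(k) = A_c e^{-B_c k} + C_c\) to the median curves with
`minpack.lm::nlsLM`. Starting values are deterministic — amplitude from
the median range, pan exponent from the log–log slope of the
increments, core rate 0.5, offset from the last median — followed by a
fixed ladder of 10 jittered restarts (scale factors 1, 0.5, 2, …), the
best RSS winning; the fit is therefore reproducible without a seed. A
constant curve short-circuits to the exact degenerate solution
(amplitude 0, offset the constant) rather than asking the optimizer to
identify an unidentifiable rate. If no restart converges the fit is
returned flagged with the best attempt's RSS. Note the power-law
parameterization is not unique (negative A with negative B plus a large
offset can fit a saturating curve equally well); the reported RSS, the
fitted curve and the plateau are invariant to this.

`detect_plateau()` returns the smallest k ≥ 2 such that *every*
subsequent step grows the median pan size by less than
`rel_threshold = 0.005` (0.5%). Requiring all subsequent steps — not
just the first — prevents a noisy early dip from being read as a
plateau. On the default synthetic matrix the plateau lands at 12
genomes; the real-data value depends on the real occupancy profile,
which only the deposited data can supply.

## The synthetic-data generators

All generators are pure functions of `(spec, seed)`: they seed a local
RNG stream derived from the global seed and a stage label
(`derive_seed`), leave the caller's RNG untouched, and emit truth
labels alongside every artefact.

* `generate_pangenome_matrix()` defaults to the published 17-genome
  composition (17,483 / 2,656 / 13,986 / 220 over 34,345 families).
  Dispensable occupancies follow an exact largest-remainder partition
  of a 1/o weight profile over o = 2..N−2 — the decreasing occupancy
  histogram typical of crop pan-genomes; no occupancy histogram is
  published for the real matrix, so the profile is a package choice,
  made once. Softcore
  families drop one uniformly chosen genome; private families are
  assigned round-robin.
* `generate_annotated_genome()` packs 1–4-exon genes on both strands
  with ≥ 200 bp intergenic margins; CDSs start ATG, end with a stop,
  contain no internal stop, and satisfy the mod-3 rule. Introns are
  60–200 bp so that splice windows never collide.
* `generate_variants()` plants SNPs and small InDels whose class is
  decided by construction: non-coding sites are drawn from compartments
  that exclude splice windows (so each site has one unambiguous label),
  and coding labels come from full-CDS re-translation of the mutated
  sequence — a protein-level oracle independent of the codon-local
  classifier it is later used to test. Requested class histograms are
  realized exactly or the call errors.
* `generate_sv_callsets()` spaces cluster centroids 10 kb apart and
  rejects jitter above half the inter-cluster gap, so merge correctness
  is decidable against the planted clusters.
* `generate_haplotype_dataset()` plants additive haplotype effects with
  homoscedastic Gaussian noise — the simplest generative structure
  under which Duncan grouping is well-posed. Defaults: 200 accessions,
  6 SNPs, two haplotypes with means 29.84 g and 14.66 g (the published
  extremes for a superior/inferior haplotype pair of a 100-seed-weight
  gene, used here as planted effects) and noise sd 3 g, a realistic
  within-haplotype spread for 100-seed weight; het and missing calls
  are injected per cell at rate 0.02.

What the generators do **not** emulate: linkage disequilibrium,
coalescent population structure, sequencing error profiles, repeat
content, or realistic gene density. Passing tests therefore demonstrate
algorithmic correctness on data whose ground truth is known — not
robustness to every artefact of real resequencing data.

## Variant filtering and effect classification

`filter_variants()` retains records with QUAL ≥ 20 and site depth ≥ 50,
boundaries inclusive; a missing value fails its rule. Site depth is
INFO/DP when present, else the summed per-sample DP.

`classify_variant_effects()` assigns region by exon membership first
(exonic includes UTR positions, because the published exonic subclass
percentages include UTR variants), then intron membership, else
intergenic. Coding SNPs are translated codon-locally and strand-aware;
the amino-acid label (`Leu90Trp`) numbers codons from the translation
start after phase adjustment. CDS InDels are frameshift iff the allele
length difference is not a multiple of 3. Splice annotation: donor and
acceptor are the 2 intronic bases at the transcription-wise start and
end of an intron; splice_region covers ≤ 8 intronic or ≤ 3 exonic bases
from a junction — a common annotation convention, since the class names
come without a published window. A variant under several genes takes
the most severe consequence (nonsense > frameshift > missense >
splice donor/acceptor > synonymous > UTR > splice_region > intronic),
ties to the smaller gene id; InDels spanning an exon–intron boundary
are classed by their leftmost affected base and flagged. Only the
standard nuclear code is used. A ref allele disagreeing with the genome
is an error naming the position, not a silent skip.

Size classes split at the published 50 bp boundary: SNP, InDel
(< 50 bp), SV (≥ 50 bp). Multi-allelic VCF records are split into
biallelic records (splitting keeps every downstream operation
biallelic), `./.` genotypes are missing, never
reference, and external formats keep their native 1-based closed
coordinates with conversion at the package boundary only.

## SV merging

`merge_svs()` reimplements the SURVIVOR-style merge semantics: records
below `min_len = 50` bp are dropped; remaining records cluster by
single linkage, linking two records iff same chromosome, same type
(`require_type`), same strand pair (`require_strand`), and both
breakpoints within `max_dist = 1000` bp. The published analysis names
the tool, the 50 bp floor and strand awareness but not the distance;
1 kb is that tool's conventional default and is exposed as an argument.
Insertions compare insertion point and inserted length (an insertion's
end coordinate carries no information). Single linkage means chains can
exceed `max_dist` end-to-end; that is the same behaviour as the
reference tool and is documented rather than "fixed", because the
planted-cluster tests rely on reproducing it. The cluster
representative is the medoid (minimum summed breakpoint distance, ties
to the first in canonical coordinate order), which makes the merge
idempotent and invariant to sample and record order.

## Duncan's multiple range test and superior haplotypes

`duncan_mrt()` computes the one-way ANOVA mean-square error and error
df, sorts group means descending, and tests spans of p consecutive
ordered means against the least significant range
\(R_p = q_{(1-\alpha)^{p-1}}(p, \nu)\sqrt{MSE/n_h}\), where the
studentized-range quantile is evaluated numerically by
`stats::qtukey` (no tabulated critical values) and \(n_h\) is the
harmonic mean of all group sizes (standard practice for unequal n).
Spans are tested widest first; a non-significant span protects all its
sub-spans. The non-significant spans are then intervals of the sorted
means, and the maximal intervals yield the letter display, so two
groups share no letter exactly when the procedure separates them. Under
the null with g groups, the probability of *any* separation equals the
widest-span level \(1-(1-\alpha)^{g-1}\) (protection blocks everything
below a non-significant widest span); with g = 5 and α = 0.05 that is
18.55%, which the Monte-Carlo calibration in the test suite and
acceptance script reproduces. Zero within-group variance everywhere
leaves the range statistic undefined and is an error.

`call_superior_haplotype()` keeps haplotypes with at least `min_n = 5`
phenotyped carriers (the published analysis reports haplotype
frequencies but no threshold; 5 is the package default, exposed as an
argument), runs the range test, and calls the maximum-mean haplotype
superior only when its letter set is disjoint from the minimum-mean
qualifying haplotype's — a formalization of "highest trait mean in a
distinct significance group". Haplotype enumeration uses the gene body
with no flank by default (flanks unstated in the source analyses), and
excludes accessions with any heterozygous call (reason `het`, taking
precedence) or any missing call (reason `missing`).

## KASP scoring

Calls are matrix-local A/B codes plus H and missing. A marker is
polymorphic iff some non-donor cultivar's homozygous call differs from
the donor's homozygous call; H and NA never enter the comparison but
are counted. Superior-allele carriage is conservative: heterozygous
calls never count, matching assays reported as homozygous
(e.g. 'C/C') alleles.

## Problem sizes and determinism

The shipped analyses and checks use: the full 34,345 × 17 matrix with
1000 rarefaction replicates; 500 planted variants over 24 genes for the
classifier-vs-oracle comparison; 50 random SV call-set specs; 2000
Monte-Carlo replicates (5 groups × n = 10) for the Duncan null
calibration; and 200 planted-effect haplotype datasets for
superior-haplotype recovery. All stages derive their RNG streams from
one global seed, and byte-identical outputs for identical
(inputs, configuration, seed) is an enforced invariant — each analysis
driver writes a manifest of its resolved configuration next to its
outputs.

## Known limitations

* The real-data quantities that need the deposited accessions (the
  actual occupancy matrix and its ~11-genome plateau, the real SNP/SV
  catalogues, the 3,171-accession haplotype means) are represented by
  planted-truth synthetic equivalents; agreement there validates the
  algorithms, not the biology.
* The haplotype stack assumes biallelic SNPs and hom-only haplotypes
  (a direct consequence of the het-exclusion rule), so no phasing is
  attempted.
* Gene counts are per primary transcript; `read_gene_models()` can
  return all transcripts, but the pipeline uses the first listed
  transcript per gene.
* TRA (translocation) records merge on their two breakpoints like any
  two-locus record; no cross-chromosome second-locus bookkeeping beyond
  that is attempted.
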