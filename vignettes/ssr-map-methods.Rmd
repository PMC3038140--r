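---
title: "Methods: SSR mining, pedigree QC and annotated map statistics"
author: "ssrmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SSR mining, pedigree QC and annotated map statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrmap)
```

ssrmap implements the analysis stages of an SSR-based genetic mapping
project in an outbred conifer: mining microsatellites from sequence,
choosing primer pairs, measuring locus diversity in a reference panel,
quality-controlling full-sib segregation data, summarising the resulting
linkage map, and curating redundant and paralogous markers. This vignette
explains each model, its assumptions, the tunable parameters, and the
numerical and design choices where conventions were genuinely open.

## Perfect-SSR mining

A locus is a *maximal perfect run* of a 2–6 bp unit: `find_perfect_ssrs()`
reports a run only when it meets the class minimum length in bp
(`ssr_criteria()`: dinucleotides 12, trinucleotides 15, tetranucleotides
16, pentanucleotides 20, hexanucleotides 24 — the classical marker-panel
criteria, i.e. at least 6/5/4/4/4 whole units). Only uninterrupted repeats
count: a compound stretch such as (TC)₈(TA)₆ is two loci, and an
interrupted stretch such as (TA)₂₁G(AT)₆ is two loci of one motif class.
Mononucleotide runs are never reported.

Three conventions make the output well defined:

* **Canonical motifs.** A repeat can be written 2 × k ways (k rotations on
  each strand). `canonical_motif()` returns the lexicographic minimum over
  all cyclic rotations of the unit and of its reverse complement, so the
  (AAT) class absorbs (ATA), (TAA), (ATT), (TAT) and (TTA). Scanning is
  therefore forward-strand only; a reverse-strand pass would double-count.
* **Period minimality.** An (AT)n run is simultaneously an (ATAT)n and an
  (ATATAT)n run; `is_period_minimal()` restricts reporting to units that
  are not repetitions of shorter units, so each physical repeat appears in
  exactly one motif class.
* **Maximality and trimming.** The scanner locates maximal runs with a
  vectorised lag-k self-comparison; a run's `repeat_count` is
  `floor(run_bp / unit_len)` (trailing partial units are excluded), its
  start is the leftmost phase, and no reported locus can be extended by a
  full unit on either side. Coordinates are 1-based inclusive. Sequence is
  uppercased on ingest and any non-ACGT character (N, ambiguity codes)
  terminates a run — an SSR straddling a masked base is split, not dropped.
  Ties in reporting order are resolved by (start, unit length).

Two maximal runs of *different* minimal periods may overlap (each class
that independently meets its threshold is reported). The test suite checks
the scanner against an independent brute-force enumeration (greedy
lookahead runs from every position, filtered to left-maximal starts) on
repeat-rich random sequences, where such corner cases arise naturally.

## Primer-pair selection

`select_primer_pair()` encodes the size-distributed selection strategy
that spreads amplicon sizes across multiplexed genotyping panels. Pairs
not flanking the target SSR are discarded first; `pair_quality` is a
Primer3-convention *penalty*, so "best quality" means the smallest value.
For dinucleotide targets the best-quality pair with an amplicon of
100–299 bp wins, else the shortest amplicon above 299 bp. For longer
motifs the preference inverts: best quality above 299 bp, else the longest
at or below 299 bp.

Two boundary readings were open and are fixed as follows: "from 100 bp to
299 bp" is inclusive of 299, and for longer motifs "less than 299 bp" is
read as ≤ 299 so that a 299 bp candidate is never unselectable. Quality
ties break by shorter amplicon, then by pair identity, making selection a
pure function of the candidate set (and so permutation-invariant, which is
property-tested). The full design-engine parameter set (primer size
18/20/24 nt, GC 20–80%, Tm 56/60/64 °C, complementarity 3/8 nt, amplicon
100–500 bp) travels as metadata in `primer_design_config()`; running the
design engine itself is out of scope.

## Gene diversity

`unbiased_gene_diversity()` is Nei's small-sample corrected expected
heterozygosity \((2n/(2n-1))(1-\sum_i p_i^2)\) with *n* the diploid count
of scored individuals; allele frequencies come from copy counts over the
2n chromosomes, and missing calls drop the individual at that locus only
(n varies by locus). The correction inflates the plain gene diversity by
exactly \(1/(2n-1)\), vanishing as n grows. Monomorphic loci have
diversity exactly zero and are excluded from class means (but flagged, not
discarded — monomorphic transcribed SSRs remain useful cross-species
candidates).

`compare_diversity()` contrasts class means with a pooled-variance
(Student) t test — df = nₐ + n_b − 2, not Welch — because published class
comparisons of this kind pool; the 95% interval is the standard pooled CI
for the mean difference and always contains it.

## Segregation QC in CP pedigrees

Outbred cross-pollination (CP) markers segregate by configuration:
ab×cd and ef×eg give four classes at ¼ each, hk×hk gives ¼:½:¼, and the
testcross forms lm×ll and nn×np give two classes at ½ each
(`cp_expected_ratios()`). `distortion_test()` is a Pearson χ² of observed
class counts among non-missing progeny against those expectations,
df = classes − 1, computed directly from (O−E)²/E with no continuity
correction so textbook values reproduce exactly (an 80:20 split of 100
testcross progeny gives χ² = 36). A marker is *distorted* at P < 0.005,
deliberately without multiple-testing adjustment: markers within that
limit can still be mapped with confidence, and the type-I rate of the flag
is itself property-tested (≈0.5% under true ratios).

The exclusion thresholds are arguments with the study defaults: distortion
P < 0.005, marker missingness > 70%, sample missingness > 40%
(`filter_samples()`, which is idempotent). Null-allele segregation is a
pass-through annotation flag — detecting nulls needs parental data outside
this package's scope, as do order-consistency and group-inflation
exclusions, which require re-running linkage software. Sample identity
across genotyping cohorts is verified by multi-locus concordance
(`match_samples()`): a pair is the same individual only at concordance
exactly 1 over at least 5 compared loci (configurable).

## Map statistics

With groups' observed spans \(l_i\) and marker counts \(m_i\),
`estimate_genome_length()` applies the Chakravarti method-4 moment
correction \(\hat L = \sum_i l_i (m_i+1)/(m_i-1)\), which accounts for
chromosome ends beyond the terminal markers and approaches the observed
length as markers are added. Coverage uses the random-placement model
\(c = 1 - e^{-2dm/L}\) (`coverage_probability()`), monotone in each
argument in the expected directions. `marker_interval()` reports both the
concatenated-map average (total span / total markers) and the mean of
per-group averages, which differ slightly by construction.

Because both estimators assume randomly placed markers,
`interval_count_test()` checks that assumption: each group is parsed from
its first marker into half-open 10 cM intervals — the final partial
interval is kept, a choice that conserves every marker — and the counts of
intervals holding x markers are compared with \(N\,\mu^x e^{-\mu}/x!\).
The two-population Kolmogorov–Smirnov comparison admits two sample
constructions, and the choice is exposed as a flag: the default
(`method = "counts"`) compares the observed and expected counts-per-x
vectors indexed by x; the alternative (`method = "intervals"`) compares
the N per-interval counts against an equal-size sample of Poisson
quantiles (a one-sample K-S against a discrete law would misbehave under
ties). Co-segregating markers at one position count individually.

## Marker curation

Two mapped markers share *gene-identity evidence* when they derive from
the same cDNA clone (code **B**), share a UniGene cluster ID (**A**), or
align at ≥99% nucleotide identity over more than 185 bp (**C**) — the
alignment criterion applying only when one member is a non-focal-species
EST or a genomic sequence, since two focal-species ESTs of one gene would
already share a cluster. When several codes apply the strongest (B > A >
C) is reported. An evidence-positive pair mapped within 3 cM on one
linkage group is *redundant* (one locus assayed twice); mapped farther
apart or to different groups it is a tentative *paralog* pair. The 3 cM
threshold is configurable; it reflects how far genotyping error can
displace markers of a single locus. The classification is symmetric and
exhaustive: every evidence-positive mapped pair is exactly one of the two.
`group_paralogs()` merges paralog edges into families by connected
components. Of a redundant pair, the member with the larger χ²
contribution to its ordered group is excluded
(`choose_redundant_drop()`; ties break lexicographically and are flagged).

Annotation acceptance mirrors curation practice: a UniGene assignment
needs identity strictly above 85% spanning at least 220 nt (span is read
as alignment length, the natural BLAST report field); a reference-protein
assignment needs amino acid identity strictly above 45% covering more
than 45% of the translated marker length. One GO term is carried per
marker; `go_level_summary()` tabulates level-3 lineage categories as
provided (no GO DAG traversal — consuming standardized lineages avoids
ontology-version drift), excluding `"molecular_function"` stub
assignments from functional percentages.

## What the simulators emulate — and what they do not

Every stage has a seeded generator returning inputs plus an exact truth
table:

* `sim_ssr_sequences()` plants perfect, compound or imperfect repeats
  (units from the classical enrichment panel: AC, AAC, AAG, AAT, ACC,
  ACG, AGG, ATC, AAAC, AAAT, AGAT) into uniform-ACGT backgrounds that are
  rejection-sampled to be repeat-free, so the truth is exhaustive. Insert
  junctions are constrained — and each planted sequence verified against
  an internal lookahead repeat scan, regenerating on collision — so a
  correct scanner must recover exactly the truth rows.
* `sim_genotype_panel()` draws Hardy–Weinberg genotypes for a
  14-individual panel at 94 + 8 EST-SSR and 83 genomic-SSR loci. Per-locus
  allele profiles (one major allele plus equifrequent minors) are solved
  so the generating gene diversity equals a uniform draw centred on the
  class target (0.43 transcribed, 0.72 genomic); the grand polymorphic
  mean is then (94·0.43 + 83·0.72)/177 ≈ 0.57 in expectation.
* `sim_pedigree()` samples CP genotype classes at their Mendelian (or
  shifted) probabilities, plants exact-fraction high-missing samples and
  optional relabelled duplicate cohorts.
* `sim_genetic_map()` apportions 429 markers over 12 groups totalling
  1,429 cM by largest remainder. Group sizes are a fixed realistic
  gradient (142 down to 89 cM); placement is "anchored" by default (first
  and last markers at the group ends, matching how map tables report
  spans) or fully uniform for null-distribution studies. Under the
  anchored default the Chakravarti estimate is ≈1,511 cM — any
  proportional span/count allocation at these totals lands within ~0.5%
  of 1,515 cM, so the genome-length reproduction does not depend on the
  unknown per-group breakdown.
* `sim_marker_annotations()` plants 28 redundant pairs (evidence mix
  A/B/C with backing alignment rows for C), 21 paralog families totalling
  58 markers (members forced >3 cM apart or cross-group), independent
  markers, and weighted GO level-3 categories (catalytic activity +
  binding = 46% of functional assignments).

These generators reproduce the *statistical structure* each method
assumes — HWE, Mendelian segregation, Poisson marker placement, clean
evidence links. Real data violate them in ways the simulations do not:
null alleles and scoring error distort panels and pedigrees jointly,
linkage maps inherit ordering error from the mapping software, annotation
evidence is incomplete and sometimes wrong. Passing the planted-truth
tests therefore demonstrates correctness of the implementations, not
robustness of the upstream study design.

## Numerical choices, problem sizes and limitations

Degenerate inputs error early and informatively: loci with fewer than two
scored individuals, groups with fewer than two markers, zero pooled
variance, unknown cross types or genotype codes, unmapped members of a
classified pair. Frequencies must sum to 1 within 1e-9. The test suite
sizes its simulations to run in seconds to a couple of minutes in total:
scanner–oracle equivalence on 1,000 repeat-rich sequences up to 2 kb,
10,000 null markers for the distortion type-I rate, 200 replicate null
maps for the interval test, and panel/pedigree/curation stages at the
study's own dimensions.

Out of scope by design: linkage grouping, ordering and Kosambi map
construction (a linkage package's job — maps are consumed in TSV or
chart-input form); primer design and BLAST execution (candidate lists and
alignment summaries are consumed); allele binning and other lab-side
steps; F-statistics, HWE exact tests and null-allele frequency
estimation; alternative genome-length estimators (pairwise
maximum-likelihood, LOD method-of-moments) that the moment estimator was
preferred over.
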