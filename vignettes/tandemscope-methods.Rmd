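---
title: "tandemscope: models, statistics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tandemscope: models, statistics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemscope)
```

## The problem

Giant linear extrachromosomal elements ("Borgs", 0.6--1.1 Mbp) associated
with *Methanoperedens* archaea are riddled with *perfect* tandem direct
repeats: head-to-tail copies of a nucleotide unit with zero mismatches
between copies. These repeats occur both between genes and inside ORFs;
in-ORF repeats have unit lengths divisible by three and therefore introduce
perfect amino-acid tandem repeats (aaTRs) into proteins, typically creating
intrinsically disordered regions. tandemscope implements the computational
side of that analysis as a tested pipeline: detection, flanking-partial and
phase characterization, context classification, composition statistics,
codon usage, aaTR clustering, replichore prediction, and within-population
unit-number variation -- together with a synthetic-genome generator that
plants all of these signals with machine-readable truth.

## Repeat model and canonicalization

A tandem-repeat region is a maximal periodic stretch: an interval on which
`s[i] == s[i + m]` holds for a period `m`, reported when it contains at
least `min_copies` (default 3) full copies and spans at least
`min_region_len_nt` (default 50) nt, with no mismatch tolerated. Three
conventions make the report well defined:

* **Primitive units.** The reported unit is never itself a repetition of a
  shorter string; copies are counted against the primitive unit
  (`primitive_root()`).
* **Canonical placement.** A maximal periodic stretch of length `L` admits
  `L mod m + 1` placements of the `floor(L/m) * m` window ("phases"), each
  pairing a start with a rotation of the unit. We report the leftmost
  placement. Consequently a reported region always has `left_partial = 0`
  and carries the entire partial flank on its right; `enumerate_phases()`
  exposes all alternatives, and `flanking_partials()` computes maximal
  partial matches for *any* placement, so phase-shifted descriptions
  remain first-class.
* **Overlap policy.** Each periodic stretch is reported once, at its
  primitive period; overlapping arrays with genuinely different units are
  all reported.

The scanner works per period: a byte-level comparison of the sequence with
its `m`-shift, run-length encoded. A configurable cap `max_unit_len_nt`
(default 100, far above any observed unit) keeps the genome scan linear in
`m_max * n`. The same machinery runs on proteins with aa thresholds
(region >= 16 aa, unit >= 3 aa, >= 3 copies); N and X break runs and can
never occur inside a region. The normative definition of correctness is
not the algorithm but the brute-force enumeration oracle in the test
suite, which the scanner must match exactly on random and adversarial
inputs.

## ORF context and the divisible-by-three rule

A region fully inside an ORF is *genic* (nested ORFs resolve to the
smallest container), partially overlapping is *boundary*, otherwise
*intergenic*. For two-way reporting, a boundary region counts as genic
when at least half of it lies inside the ORF (configurable). Genic regions
whose unit length is divisible by three are translated: if the region does
not start on a codon boundary, leading bases are dropped to the next
boundary (possibly costing one copy) and the amino-acid unit is the
translation of the correspondingly rotated nucleotide unit; reverse-strand
ORFs are mapped through the reverse complement. Because a primitive
nucleotide unit can translate to a repetitive amino-acid string, the aa
unit is reduced to its primitive root with copies rescaled. An in-frame
stop inside a repeat is flagged as anomalous rather than fatal -- in the
data this pipeline models, it never occurs.

## Statistics

**Composition contrast.** The genome is split into repeat and non-repeat
segments; each segment is cut into non-overlapping 50 bp substrings
(remainders dropped), and each substring contributes a count vector
`[N_A, N_T, N_C, N_G]`. Per nucleotide, a Kruskal--Wallis rank test (two
groups, tie-corrected, chi-square approximation with df = 1) compares
repeat against non-repeat counts; the four p-values form one
Benjamini--Yekutieli family. BY is the step-up rule
`adj_(i) = min_{j>=i} p_(j) * m * c(m) / j` with `c(m)` the harmonic
number, valid under arbitrary dependence. Both statistics are implemented
in this package and cross-checked in the tests against independent
reference implementations. Two calibration notes: type-I error is
assessed on the raw per-nucleotide p-value (the BY adjustment is
deliberately conservative and cannot sit at alpha), and the degenerate
all-identical case is defined as H = 0, p = 1. Windows with no G or C get
GC skew 0 rather than NA so cumulative skew stays defined on A/T-rich
stretches.

**Codon usage.** Codons of supplied coding sequences are split into aaTR
codons and all others; the headline quantity is the frequency ratio
(0 marks codons absent from aaTRs, the "absent codon" signature).
Per-codon enrichment uses a two-sided Fisher exact test on the 2x2 count
table with BY correction across all 64 codons -- the source analysis
reports corrected per-codon p-values without naming its test, and an
exact count-based test is the defensible default.

**Amino-acid enrichment** is the residue frequency in concatenated aaTR
regions divided by the proteome frequency, presented in order of the
TOP-IDP disorder-propensity scale (a named constant, overridable), so
depletion of order-promoting and enrichment of disorder-promoting
residues is visible at a glance.

## aaTR clustering

Units are tripled (the minimum unit length is 3 aa, so tripling gives
alignable strings and downweights rotational phase) and compared by
global-alignment identity with match = 1, mismatch/indel = 0. Under that
scoring the aligned identities equal the longest common subsequence, so
`d(a, b) = 1 - LCS / (|a| + |b| - LCS)`: symmetric, in [0, 1], zero iff
identical. This deliberately clusters by composition-and-order similarity
rather than substitution-matrix similarity, because the clusters being
modeled group units of near-identical residue composition. Average-linkage
trees are cut at 0.6 (the honest tunable; the source procedure's
tree-cutting rule is not documented); flat groups with >= 3 members become
clusters, the rest are `n.c.`. Cluster ids derive from sorted member
units, so the whole procedure is a pure function of the unit multiset.
Names pool residue counts over member units and list every residue at
>= 10% of the pool in descending frequency, alphabetical on ties -- the
slash notation seen in some published cluster names encodes an
undocumented distinction and is not reproduced.

## Population variation from reads

Because the repeats are perfect, alignment is unnecessary: a read spans a
region iff it contains the 15 bp anchors flanking the extended repeat
interval, each exactly once, and the sequence between them is the region's
periodic string with a whole number of units (known partial flanks
tolerated; both orientations tried). Reads containing the unit without
both anchors are non-spanning. A region is called variable when two or
more distinct unit counts each have >= 2 supporting reads; regions with no
spanning reads leave the denominator. Anchors that are not unique in the
genome flag the region un-assessable.

## The synthetic world

The generator's defaults state the simulated world: 1 Mbp linear genome;
background base composition A/T/G/C = 38.4/28.8/20.3/12.5% on the coding
strand; repeat units drawn at 48.4/23.7/17.1/10.8% (the A-enrichment of
real repeat units); ORFs with ATG starts, stop-free bodies, forward strand
on the left replichore and reverse on the right; a G/C excess that flips
at the midpoint so cumulative skew recovers the replichore structure;
intergenic units of 7--36 nt and genic units of 3--8 aa (unit length
divisible by three, codon-aligned, reverse-translated avoiding the stop
codons and the codons empirically absent from aaTRs); 3--8 copies, raised
per-unit so every region reaches the 50 nt floor; partial flanks planted
with probability 0.5 per side; and a variant table planting the 14-of-18
G-to-A tally inside repeats against a 462/494/101 split outside.

Choices the sources do not fix, made once: ORF lengths 900--3000 nt; ORF
codons sampled from base frequencies pre-compensated so that the
non-stop-conditional marginal matches the background target; planted
boundaries are forced non-extendable at the nucleotide level on both
sides, and for genic repeats also at the amino-acid level (a synonymous
boundary codon would otherwise create a protein-side partial flank that
shifts the canonical aa placement off the planted interval); every planted
stretch is pre-screened in isolation so it contains no second array at
detection thresholds; and after assembly the whole genome is re-scanned,
with accidental arrays resampled (codon-aligned inside ORFs), until
detection reports exactly the planted truth. Truth rows store the
*canonicalized* form of each planted region and are re-validated against
the emitted sequence by direct string comparison before being returned.

What a green planted-recovery test establishes, and what it does not: the
generator certifies a repeat-free background, so 100% sensitivity and
precision are a fair bar for the detector; but synthetic genomes have no
sequencing error, no assembly collapse, and iid background rather than
real genomic structure, so the tests validate the algorithms, not
performance on raw reads or uncurated assemblies.

Reads are sampled uniformly; molecules covering a variable region draw
their unit count from the planted mixture (default: one unit fewer with
probability 0.4), which mirrors the one-unit-difference pattern seen in
real read pilings. No error model or paired-end structure is simulated.

## Summary report

The per-genome summary computes its derived columns by explicit formulas:
percent of genome in repeats (2 decimals), repeat units per bp
(7 decimals), percent of proteins with aaTRs (2 decimals), and two
integer-rounded ratio columns. The column reported as the ORF/intergenic
split is implemented as `100 * (TRs in ORFs) / (all TRs)` -- that formula,
not the literal ratio a label of the form "ORF/intergenic" suggests,
reproduces every printed row of the published per-genome table
(e.g. 23/56 -> 41, 12/20 -> 60), and the discrepancy is deliberately
resolved in favor of arithmetic consistency.

## Numerical conventions and degenerate inputs

* Coordinates are 0-based half-open everywhere internally; GFF3 (1-based
  inclusive) and the variant TSV convert at the I/O boundary; BED shares
  the internal convention.
* Ties in replichore prediction resolve leftmost; a flat skew profile is
  `NA` ("undetermined").
* `div3_fraction()` and the ratio columns return `NA` on empty classes;
  frequency ratios return `Inf`/0 sentinels for one-sided absence and `NA`
  for 0/0.
* All randomness flows from explicit seeds; identical inputs give
  byte-identical outputs.

## Known limitations

Only perfect repeats are detected (mismatched or reverse-complement
arrays are out of scope by design); gene prediction is not performed (ORFs
are inputs); protein-side aaTRs lacking a nucleotide source are reported
by the protein scanner but not linked; and the clustering cutoff, while
stable on planted families, is a tunable that real analyses should sweep.
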