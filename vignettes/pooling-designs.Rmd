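---
title: "Label-free pooling designs and genotype-based demultiplexing: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free pooling designs and genotype-based demultiplexing: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairpool)
```

## The problem

Pooling several samples into one 10x reaction cuts reagent cost and removes
between-reaction batch effects, but every pooled cell must afterwards be
traced back to its sample of origin. Genotype-based demultiplexing separates
cells of genetically distinct donors without any added label, yet it only
recovers *anonymous* genotype clusters: something must still connect each
cluster to a named sample. When the experiment consists of matched pairs —
one skin and one PBMC sample per donor — the pairing itself can carry that
information. `pairpool` formalizes the idea as a decoding problem: place
samples into reactions so that the observables available after sequencing
(which clusters share a genotype across reactions, and optionally which
clusters are male) admit exactly one assignment of identities.

## Pooling layouts

**Dual layout** (`design_strategy1()`, two samples per reaction). Donors are
partitioned into chains of three (the last chain absorbs a remainder, up to
five). A chain of donors $d_1,\dots,d_m$ produces $m-1$ reactions that
alternate tissue — $\{ \mathrm{skin}\,d_1, \mathrm{skin}\,d_2 \}$,
$\{\mathrm{pbmc}\,d_2, \mathrm{pbmc}\,d_3\}$, … — so every interior donor's
matched pair spans two consecutive reactions. The samples left over (the
first donor's PBMC, the last donor's remaining tissue) are paired
tissue-by-tissue into closing reactions; odd counts meet in one mixed-tissue
closing tube. The layout uses exactly N reactions for N donors and is
uniquely decodable from genotype-sharing alone, which the generator verifies
after construction.

**Triplet layout** (`design_strategy2()`, three samples per reaction,
requires known sexes, N divisible by 3, N ≥ 6). N/3 anchor donors each span
a dual reaction pair (a *block*): the anchor's PBMC sits in the block's
"skin" tube and its skin in the "PBMC" tube, so within each block exactly
one genotype is shared. Every reaction is filled with two samples from
*filler* donors of different sexes; filler $k$'s skin goes to block $k$ and
its PBMC to block $k-1$ (cyclically), so no filler pair ever sits inside one
block. Anchor choice is forced up to ordering: with $K = N/3$ blocks the
roster must contain between $K$ and $2K$ donors of each sex, the surplus
over $K$ per sex becomes anchors, and donors are taken in lexicographic
order so designs are byte-reproducible. Decodability here *requires* the
sex observable: without it the two same-tissue fillers of every block are
interchangeable and the checker reports exactly $2^{N/3}$ consistent
assignments.

## The identifiability checker

`check_identifiability()` builds the noise-free observables a design would
generate — the partition of (reaction, cluster) slots into same-donor
classes, plus per-slot sex labels when requested — and counts *every*
slot-to-sample assignment consistent with them by backtracking enumeration
with forward pruning (injectivity per reaction; one donor per class;
distinct donors across classes; sex agreement). The count is exact; a design
is identifiable iff it equals one. The same solver backs
`resolve_identities()`, where the class partition comes from the empirical
match graph instead of ground truth, with two relaxations: components
containing a *conflicted* node (one matching two clusters in a single other
reaction) contribute no constraints, and the distinct-donor rule applies
only to reaction pairs whose locus overlap met `min_shared_loci` — a missing
match on a poorly covered pair is missing data, not evidence. The resolver
returns the unique mapping, the explicit ambiguity set (all consistent
assignments up to 100, beyond that the count plus the interchangeable slot
groups), or an inconsistency with the constraint class implicated by
re-solving under progressive relaxation. It never guesses.

One redundancy property surfaced by the solver is worth knowing: in the
triplet layout each block is *doubly* determined. Even if the anchor's match
edge is lost (say, too few co-called loci), the fillers' own cross-block
matches plus injectivity still pin the anchor by elimination, so a single
missed match usually costs nothing. Ambiguity appears only when several
observables fail together, and is then reported as such.

## The demultiplexer stand-in

`fit_genotype_clusters()` is a deliberately small souporcell-style core,
suitable for the desk scale this package targets and for validating the
design logic: binomial-mixture EM on per-cell ref/alt counts with uniform
mixing weights, no read remapping and no ambient-RNA term. Real souporcell
outputs (cluster table TSV, cluster-genotype VCF) can be ingested through
`read_souporcell_clusters()` / `read_cluster_genotypes_vcf()` and feed the
identical downstream types.

Numerical choices: cluster allele fractions are clipped to
$[\varepsilon, 1-\varepsilon]$ (default $\varepsilon = 0.01$, matching the
simulated sequencing error) so log-likelihoods stay finite; convergence is
declared when the total log-likelihood improves by less than `tol = 1e-4`;
the first of 5 restarts is seeded k-means++-style on per-cell alt-fraction
vectors (missing loci mean-imputed), the rest from random cells, ties
breaking to the earlier restart; cells with zero covered loci are
`unassigned` and excluded from the likelihood. The per-iteration
log-likelihood trace is retained and is non-decreasing. K is always the pool
size given by the design, never estimated.

Doublets: a cell is called a cross-genotype doublet when the best
two-cluster average profile beats the best single profile by more than
`doublet_margin = 2` nats — at the default simulated depth this keeps false
calls rare while recall rises quickly with coverage (≥ 0.8 at mean depth 5).
Consensus calls discretize $q$ with `hom_threshold = 0.1` and
`het_band = 0.15` (no-call between the bands, and wherever a cluster's
aggregate coverage at a locus is below `min_reads = 3`).

## Matching and sex inference

Cross-reaction concordance is the fraction of identical discretized calls on
co-called loci; `tau_match = 0.9` declares a shared donor, comfortably above
the ≈ 0.5 expected for unrelated donors under Hardy–Weinberg at the
simulated allele frequencies (the exact expectation
$\sum_g P(g)^2 = 0.375$ at allele frequency 0.5). Scores within 0.05 below
threshold are flagged `borderline` for review rather than decided. A
continuous correlation of allele fractions is computed only as a diagnostic
and never drives matching.

Sex is inferred from `y_pct`, the percentage of a cluster's singlet-cell
UMIs mapping to the nine-gene Y panel; doublets are excluded because their
mixed origin blurs the signal. The threshold `tau_male = 0.02` (percent) was
fixed once against the simulation defaults, where male clusters sit near
0.45% and female leakage near 0.004% — a >10x margin on either side — and is
exposed as a parameter; `plot_sex_calls()` shows the per-cluster separation
so the threshold can be audited on real data, where ambient contamination
and panel dropout will move both ends.

## What the simulator does and does not emulate

`sim_config()` defaults describe a shallow desk-scale experiment: 300 SNPs
with alt-allele frequencies uniform on [0.1, 0.5], Hardy–Weinberg genotypes,
200 cells per pooled sample, Poisson(2) reads per cell per locus, 1%
sequencing error, 5% doublets formed by summing two independently drawn
member cells, Y-gene UMIs Poisson(0.5) per gene per male cell versus
Poisson(0.005) leakage per female cell, and 100 background genes with
per-gene rates Gamma(2, 0.2) (≈ 1000 UMIs per cell, so the Y-share proxy
lands in a realistic sub-percent range). All randomness flows from one seed;
reaction streams are derived from the seed and the reaction's position, so
reactions can be simulated in any order.

Not modeled: ambient RNA, inter-reaction contamination, expression doublets
with non-additive profiles, dropout beyond Poisson sampling, batch effects,
or any transcriptome structure — the background genes exist to give the
Y-share a denominator and the QC filters something to act on. Passing the
end-to-end tests therefore shows that the *decoding logic* is correct under
the stated noise model, not that the EM stand-in matches a production
demultiplexer on real reads; for real data the intended path is ingesting
the external demultiplexer's outputs. Because a simulated transcriptome has
~109 genes, pipeline runs on synthetic data should set `min_genes_per_cell`
to a simulation-scale value (the tests use 10–20); the defaults (200/4000/3,
normalize to 10,000 then log1p) are the standard real-data values.

QC order follows the stated contract: cell filters (boundaries kept: exactly
200 or exactly 4000 detected genes survive) before gene filters, counted
against surviving cells; cross-genotype doublet removal keeps unassigned
cells. Cell-then-gene filtering is idempotent on realistic matrices but not
in adversarial corner cases where removing a gene drops a cell below the
detection floor; the filter is applied once, as in standard practice.

## Problem sizes and test design

Tests enumerate designs for N = 3–15 donors (dual) and N = 6, 9, 12, 15
(triplet); the exhaustive checker handles the 12-reaction, 3-slot triplet
instances in well under a second thanks to pruning. End-to-end recovery runs
the 9-donor triplet design at the simulation defaults (3,600 cells across 6
reactions). EM correctness is additionally pinned to a brute-force
enumeration of all hard assignments on instances of ≤ 8 cells, 2 clusters
and 4 loci, and the genotype and concordance models to their closed-form
Hardy–Weinberg expectations.

## Limitations

- Pools of more than three samples, and optimizing for anything beyond
  identifiability and reaction count, are out of scope.
- Sex inference uses Y genes only (no XIST/X-dosage route); sex-chromosome
  aneuploidies and related edge cases are not handled beyond the threshold
  rule.
- Genotype matching detects identity, not relatedness; close relatives may
  exceed `tau_match` at shallow coverage and would surface as conflicts.
- The triplet design requires every donor's sex to be known and a sex
  composition between N/3 and 2N/3 of each sex; other rosters are rejected
  with the limiting sex named rather than silently re-balanced.
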