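---
title: "Methods: haplowebs, fields for recombination, and Robertsonian karyotype models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplowebs, fields for recombination, and Robertsonian karyotype models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haploweb)
```

This vignette is the package's own account of the science it
implements: the data model, the phasing and delimitation procedures,
every tunable parameter with its default and rationale, what the
synthetic-data generator emulates (and does not), and the design
decisions taken where the method left room.

## The data and its assumptions

The input is the standard product of direct Sanger sequencing of
diploids at a few nuclear loci: one aligned consensus sequence per
specimen per locus, in which a site where two peaks are reproducibly
superimposed in the chromatograms is recorded as a two-base IUPAC
ambiguity code (`R Y S W K M`). Three-peak sites are rejected as
invalid input. `N` marks chromatogram dropouts and is excluded from
every distance and phasing computation at that site (pairwise
deletion); `-` marks alignment gaps. Haploid loci (mitochondrial
*cytb*) may not contain ambiguity codes. Protein-coding loci may be
declared codon-framed, which only enforces an aligned length divisible
by three.

The delimitation procedure presumes a specific population-genetic
regime, and everything downstream is honest only within it:

* **Divergence exceeds diversity.** Species-level allele pools are
  separated by several (≥ 3) *fixed* substitutions, while within-pool
  polymorphism is shallow — a star of rare variants around a common
  central haplotype. This is the regime in which a heterozygote's pool
  membership is diagnosable at all.
* **Homozygotes expose haplotypes.** Every allele pool of interest is
  observed directly in at least some homozygous individuals.

## Short deletions as shared derived states

Non-extended deletions (a parameter, `max_fill_len = 5` columns;
longer gaps are an error because the recoding is not defensible for
them) are replaced column-by-column with a nucleotide drawn from the
bases *not observed* at that column in any ungapped sequence. The same
fill base is used in every gapped sequence at a column, so a shared
k-nt deletion becomes exactly k diagnostic substitutions shared by its
carriers. The draw is seeded and every fill decision is written to the
provenance output. If all four bases are already present at a gapped
column the operation fails loudly — there is no absent state to use.

Two details are deliberate: filling is per *column* (not one base per
gap run), and the fill base is shared across sequences. Per-run
single-base filling would make a 3-nt deletion count as three
identical-base columns, which changes nothing downstream; per-sequence
random fills would fabricate spurious polymorphism inside the deletion.

## Phasing by homozygote subtraction

For a genotype `g` with `k` heterozygous sites there are `2^k` raw
decompositions into unordered haplotype pairs. The procedure anchors
the decomposition in observed homozygotes: every pool haplotype `r`
that matches `g` at all homozygous sites and carries one member of
every ambiguity pair is a candidate reference, and forces its
complement (at a heterozygous site with pair {x, y} and r carrying x,
the complement carries y). Candidates are then filtered by two
preferences, in order:

1. **locality** — references whose homozygote carriers include a
   specimen from the focal specimen's sampling locality (surrounding
   populations are the best guide to which allele combinations
   actually segregate there);
2. **frequency** — references with the highest global carrier count.

If exactly one (reference, complement) pair survives, the genotype is
phased; otherwise it is left `unresolved`. Ties are never broken
arbitrarily: a fabricated phase would silently contaminate the
networks. When the locality and frequency preferences would resolve to
*different* unique pairs, the locality choice wins and the conflict is
recorded in the output's `note` column. Complements not present in the
pool are emitted as `deduced` haplotypes and carry a `*` suffix in
their identifiers, so every downstream table and figure distinguishes
observed from hypothesised alleles.

The test suite checks two invariants exhaustively: site-wise
recombination of every returned pair reproduces the input genotype
exactly, and for `k ≤ 8` the result agrees with brute-force
enumeration of all `2^k` decompositions under the same preference
rules.

## The haploweb and fields for recombination

Haplotype nodes are connected by the epsilon-0 minimum-spanning
network: all edges that occur in *some* minimum spanning tree under
the mutational-step distance (an edge (u, v, w) qualifies exactly when
u and v are disconnected by edges of weight < w). All tied
alternatives are retained and no inferred median vectors are added —
the simplest structure whose branch lengths are proportional to
mutation counts. Arcs (curves in the figures) join the two haplotypes
of every heterozygous individual, weighted by carrier count.

A **field for recombination (FFR)** is a pool of alleles linked
together by heterozygotes — connected components of the arc graph;
mutational edges never merge pools. Two refinements make the concept
operational when hybrids are present:

* An arc spanning at most `max_arc_steps = 2` mutational steps is
  ordinary within-pool linkage. The default matches the assumed
  regime: in a star-shaped pool two variants are at most two steps
  apart, while distinct pools are ≥ 3 steps apart. Longer arcs connect
  alleles of different pools.
* A pool is *anchored* if it contains at least one haplotype observed
  in a homozygote. A long arc between two anchored pools does **not**
  merge them; its carriers are flagged as FFR-bridging heterozygotes
  (the hybrid pattern) and listed as members of both fields. A long
  arc whose far side is unanchored (typically a deduced complement
  carrying private mutations) cannot indicate a field of its own; that
  side is absorbed into the mutationally nearest anchored pool.

Without these rules the strict components definition would let a
single F1 collapse both parental species into one FFR, and the flag
"specimen with alleles in two FFRs" could never fire. The cost is a
threshold: a genuine pool separated by ≤ 2 steps cannot be
distinguished from within-pool variation, and an intraspecific lineage
whose homozygotes were never sampled will be absorbed rather than
delimited. Both limits are inherent to delimitation from Sanger-scale
data, not artifacts of the implementation.

A haploid mitochondrial locus has no heterozygotes; for multilocus
work its "pools" are MSN components after cutting edges longer than
`mt_step_threshold = 5` steps. The default separates sibling-species
clades (tens of substitutions apart in *cytb*) while tolerating
within-clade variation; it is configurable because it is a stand-in
for a tree-based clade definition, not part of the FFR concept.

## Multilocus consensus and classification

The conspecificity matrix counts, for each specimen pair, the loci at
which the pair shares at least one FFR; the diagonal holds the number
of loci scored (a specimen missing at a locus leaves that locus
unscored for its pairs). Pairs conspecific at `ceiling(L/2)` of their
L mutually scored loci (majority — the weakest defensible default,
configurable) are linked, and consensus clusters are single-linkage
components with deterministic, sorted-id numbering.

Per-locus calls compare the FFRs of a specimen's two alleles with the
specimen's *a-priori* species label, which comes from metadata
(karyotype, morphology) and never from the locus being called — the
same non-circularity the original field practice maintains. FFRs are
labelled by the majority a-priori label of their members; ties leave
the FFR unlabelled and its calls `unresolved`. The rule table is:

| alleles fall in | vs a-priori label | call |
|---|---|---|
| one FFR, same species | match | `pure_<species>` |
| one FFR (or two same-species FFRs), other species | mismatch | `heterospecific_homozygote` |
| FFRs of two species | — | `heterospecific_heterozygote` |
| two FFRs, both own species | match | `intraspecific_lineage_heterozygote` |

The per-specimen summary applies, in order: any heterospecific
heterozygote → *interspecific hybrid candidate*; else any
heterospecific homozygote → *introgression/ancestral-polymorphism
candidate*; else a mitochondrial clade label disagreeing with the
majority nuclear label → *mito-nuclear discordant*; else *concordant*.
The order makes the table total and gives precedence to the strongest
genetic evidence. The introgression-versus-ancestral-polymorphism
distinction is deliberately **not** decided computationally: both
hypotheses explain the same single-specimen pattern, and separating
them needs demographic inference outside this package's scope.

## Robertsonian karyotype model

A Robertsonian fusion joins two acrocentric autosomes into one
metacentric; each fused *copy* reduces the diploid number by one and
leaves the fundamental number (arm count) unchanged. A karyotype is a
base complement (`base_2n = 54`, the all-acrocentric complement of the
subgenus; `NF = 56` stored, never computed) plus a list of fusions
with zygosity 1 or 2, written `2Rb(2.11),1Rb(3.10)`. Each arm may
participate in at most one fusion. Somatic mosaics are supported as
zygosity ranges (`1-2Rb(3.10)` → 2n = 50–51), and the consistency
checker compares stated against computed 2n, requiring the stated
range to be covered. F1 prediction is defined only for parents
homozygous for all their fusions — each then contributes exactly one
copy of each fusion, so the F1 zygosity is the number of parents
carrying it; heterozygous parents produce non-deterministic gametes
(chains and dicentrics at meiosis) and are rejected rather than
modelled. Arm numbering is taken at face value; when comparing across
species whose same-numbered fusions are known to be non-homologous,
use distinct arm ids per lineage.

## The synthetic cohort generator

`make_cohort()` emulates exactly the stated regime, with truth tables
for every stage:

* **Pool structure.** Per nuclear locus: a random ancestral sequence
  is the centre of the species-A pool (W); species B (T) differs at
  `max(3, Poisson(3))` fixed positions; a second conspecific lineage
  (E) differs from W the same way and, at the 970-bp locus, carries a
  3-nt deletion near the start. The floor of 3 enforces the "pools
  separated by at least three fixed substitutions" premise — a
  realisation with fewer fixed differences would be a world in which
  the method is not claimed to work. The mitochondrial locus uses
  Poisson(20) (~2% of 1143 bp, sibling-species scale).
* **Within-pool polymorphism.** Each sampled allele copy is the pool
  centre plus a Poisson(`mut_per_allele = 0.1`) number of private
  mutations at non-diagnostic positions (infinite-sites). Variants are
  therefore singletons, as in the near-monomorphic empirical loci, and
  never occur spuriously as homozygotes — which a
  population-frequency allele model would produce at Hardy–Weinberg
  rates and real shallow samples essentially never show.
* **Specimen classes.** Pure A (two W), pure B (two T), pure A of the
  E lineage (two E), F1 (W + T, species-A label, contact locality),
  introgressed (two T under a species-A label), intraspecific W/E
  heterozygote, and optional mitochondrially discordant pure-A
  specimens. Localities place species A in 1–3, species B in 4–6, and
  all mixed classes at the contact locality 3. Metadata karyotypes
  match the class (2Rb(2.11) homozygote, fusion-free, or the 2n = 53
  F1 heterozygote).
* **Encoding.** Genotypes are IUPAC-encoded from the allele pairs. The
  E-lineage deletion is recoded to an absent base at the pool level
  *before* encoding (a heterozygous indel has no single-sequence IUPAC
  representation), so emitted FASTA is gap-free; the raw gapped
  alleles stay in the truth table, and the fill convention itself is
  exercised on the raw pools by the tests.

What the generator does **not** emulate: recombination within loci,
coalescent genealogy shape, backcross pedigrees beyond F1,
sequencing error, and alignment error. A green test therefore
establishes that the pipeline recovers truth *in the stated regime*;
it says nothing about loci whose divergence is comparable to their
diversity, where the method's own premises fail.

## Numerical and determinism choices

* All randomness (generator, gap filling) flows from explicit seeds;
  the pipeline writes an MD5-checksummed manifest and two runs with
  the same configuration are byte-identical.
* Haplotype ids are assigned in pool-frequency order, FFR and cluster
  ids by sorted first member, and single-linkage ties broken by sorted
  specimen id, so outputs are stable across platforms.
* p-distances are reported to three decimals in summaries; undefined
  distances (no comparable sites) are `NA`, never zero.
* Degenerate inputs fail loudly at the boundary: ragged alignments,
  disallowed symbols (with position), ambiguity codes in haploid loci,
  gap columns with all four bases observed, arm reuse in karyotype
  formulas, heterozygous parents in F1 prediction.

## Known limitations

* FFR delimitation needs homozygote-anchored pools; lineages sampled
  only in heterozygotes are absorbed into their nearest pool.
* The `max_arc_steps` threshold trades within-pool tolerance against
  pool resolution; pools closer than 3 steps are not separable.
* Mitochondrial "clades" are distance components, not tree clades;
  with rate heterogeneity the two can disagree.
* The phasing preferences can be defeated by private mutations on a
  hybrid's alleles: the locality-preferred reference then yields a
  chimeric complement. The complement is still a valid decomposition
  of the genotype (conservation always holds) and is absorbed into the
  correct pool by proximity, but the reported haplotype sequence may
  differ from the true allele by those private sites.
* With more than two species, the "other species" attribution of a
  heterospecific homozygote in the summary report is ambiguous; the
  report assumes the two-species setting.
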