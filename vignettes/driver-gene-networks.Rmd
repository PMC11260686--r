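---
title: "Driver-gene mutation networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Driver-gene mutation networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diwann)
```

This vignette is the package's account of the science it implements:
the models and their assumptions, the parameters that matter, the
numerical and design choices made where the design was genuinely open,
and what the synthetic cohorts do and do not show about real data.

## The problem

Tumor genomes carry orders of magnitude more passenger than driver
mutations. Recurrence across independent donors is among the most
reliable marks of driver status, so the pipeline first reduces a
MAF-style somatic mutation table to its recurrent, likely-functional
fraction, then studies the survivors with two complementary network
views: a sequence-similarity network over per-tumor mutation profiles,
and bipartite networks linking tissues or samples to mutated genes.

## Data reduction

Filtering is a composition of three subset operations, each idempotent
and permutation-invariant:

1. **Variant-class exclusion.** Non-coding classes — intergenic (IGR),
   intron, 5'Flank and lincRNA calls — are removed. Class strings are
   compared after whitespace trimming and an optional synonym map
   absorbs dialect spellings.
2. **Census-gene recurrence.** For genes in a driver census, a mutation
   identity `(gene, position, ref, alt)` survives only if carried by at
   least 2 *distinct* donors. Donor-distinctness is a deliberate
   reading of "recurrent": duplicate calls inside one tumor are not
   evidence of independent recurrence.
3. **Non-census top frequency.** For every cancer type independently,
   distinct non-census gene–mutation pairs are ranked by distinct-donor
   count and the top `ceiling(0.04 * P_t)` pairs are kept (`P_t` =
   number of distinct pairs in tissue `t`), with all ties at the cutoff
   count kept so the result cannot depend on row order. A record
   survives if its pair is kept in *any* tissue. The ranking unit is
   the gene–mutation pair, not the gene: a gene with one dominant
   hotspot and many singletons contributes each pair separately.

A consequence of the tie rule worth knowing: in a tissue where the
cutoff count is 1, *every* singleton pair ties with the cut and
survives. That is the intended semantics (permutation invariance is
non-negotiable), and on sparse cohorts it makes the 4 % rule lenient.

## The transformed reference

Concatenating the full cDNA of every kept gene would give a reference
of hundreds of kilobases whose pairwise edit distances are dominated by
identical wild-type stretches. Instead, the reference keeps exactly one
base per distinct surviving locus, ordered by gene (lexicographic by
default) and position. Since every sample uses the same locus order,
the order itself cannot affect distances between samples; lexicographic
is chosen purely for reproducibility.

Each donor's sequence starts from the reference and applies that
donor's mutations: a substitution replaces its tracked base, a deletion
removes every tracked locus its span covers, and an insertion adds its
bases immediately after its tracked locus. Internally this is
implemented as mark-and-build (per-locus keep/replace flags plus
insert-after strings) rather than sequential splicing in descending
offset order; the two are equivalent, but mark-and-build has no
index-shift corner cases when one donor carries adjacent indels.
Resolution rules for degenerate input: at most one edit applies per
tracked locus per donor; two substitutions with different alternates at
one locus are an error (the data contradict themselves); a locus both
substituted and deleted resolves to deleted; insertions after a deleted
locus are still emitted. Indel semantics produce the expected length
variation of per-sample sequences around the reference length.

Samples with identical strings collapse into one weighted node carrying
the occurrence count, per-tissue counts, the dominant tissue (maximal
count, ties broken lexicographically for determinism), the union of
causative genes and the donor list. A wild-type node holding the
unmutated reference is added before network construction — the only
node allowed an occurrence count of zero — and serves as the pivot of
the DiWANN search. The node table labels it explicitly, so node counts
with or without it are both recoverable.

## The DiWANN network

Every node gets directed edges to *all* of its nearest neighbors under
unit-cost edit distance; the shared minimum distance is the edge
weight. The graph is sparse (out-degree equals the number of ties at
the minimum, usually 1–2) yet has no singleton nodes, unlike a
threshold network.

The construction contract is exactness, not a particular pruning
schedule: `build_diwann()` must produce the same edge set as
`brute_force_ann()`, which computes the full distance matrix through an
independent implementation (`utils::adist`). The prunings used are all
admissible bounds:

* the length bound `|len(a) − len(b)| ≤ d(a, b)`;
* the triangle bound `|d(p, a) − d(p, b)| ≤ d(a, b)`, with `p` the
  wild-type pivot whose full distance row is computed first;
* each node's current best is initialized to its pivot distance, so the
  banded dynamic program can abandon any candidate as soon as the
  distance provably exceeds it. The band at half-width `k` treats cells
  with `|i − j| > k` as infinite; any true distance `≤ k` is still
  returned exactly, which is what makes the abandon sound.

Instrumentation (`n_computed`, `n_pruned`, `n_abandoned`, `n_avoided`)
reports how much of the all-pairs work was skipped. On cohort-shaped
data (many distance-1 neighbors) most pairs are pruned; on uniformly
random sequences the bounds bite less — correctness is unchanged
either way, as the randomized equivalence tests check across sizes up
to 300 nodes.

Sequences are restricted to the alphabet `{A, C, G, T}`; ambiguity
codes are rejected at ingestion because edit-distance semantics over
them are undefined here.

## Community detection and enrichment

Louvain modularity optimization runs on the undirected collapsed view.
Edit distances encode *dissimilarity* while modularity expects
affinity, so edges are re-weighted as `1/d` before clustering: the
transform preserves the "closer = stronger" rank order and leaves the
dominant weight-1 edges at unit weight. Whether to use weights at all
was an open choice; `1/d` was selected once as the least-committal
monotone transform. Reciprocal edge pairs collapse to a single
undirected edge (their distances are equal by symmetry). The heuristic
is seeded for determinism, and an edgeless graph short-circuits to
singleton clusters. Cluster ids are re-labelled contiguously from 0.

Enrichment asks, per cluster and per annotation term (cancer types and
causative genes), whether the term is over-represented among the
cluster's nodes relative to *all* network nodes as background — the
standard one-sided Fisher construction; the p-value is computed as the
hypergeometric upper tail (`phyper`), which is identical to
`fisher.test(alternative = "greater")` and is cross-checked in the
tests against both that and a direct binomial-coefficient enumeration.
Benjamini–Hochberg correction is applied within each term type at
`alpha = 0.05`; no correction procedure was mandated by the problem, so
the field default was chosen. Both the raw count of enriched terms and
the testable-term denominator are recoverable from the result table,
since which denominator to report was left open.

Cluster profiles expand collapsed nodes back into samples (a node
counts once per occurrence), tally samples per cancer type, report the
genes mutated in the most member samples, and the mean mutational load
(filtered mutations per member sample).

## Bipartite networks and projections

Bipartite edges are presence/absence: a gene mutated five times in one
tissue still yields one edge, because the projection weight definition
counts *distinct shared neighbors*, not call multiplicities. The
one-mode projection onto either side weights each pair by the size of
its shared-neighbor set; per-cancer-type gene projections restrict the
records to one tissue first, so their weights are within-tissue
co-occurrence counts and sum exactly to the global projection weights
(tissues partition samples). Weight-cutoff subgraphs drop light edges
and then orphaned nodes. Default reporting cutoffs (tissue projection
≥ 6, gene projection ≥ 7, sample–gene projection ≥ 9, per-type > 2)
are parameters, not semantics.

## The synthetic cohort generator

The generator emulates the statistical structure the pipeline assumes,
at desk scale, with one fixed default condition:

* **200 donors** over **25 cancer types** with geometrically skewed
  proportions (ratio 0.82, one pancreatic-like dominant type) — real
  pan-cancer callsets are dominated by a few large projects.
* **Variant-class mix** 75 % excluded classes, IGR the single largest —
  mirroring callsets where intergenic calls dominate — and a coding
  remainder across missense/nonsense/silent/splice/frameshift.
* **8 census genes**, each with **3 planted recurrent sites** shared by
  `2 + Poisson(1)` distinct donors with identical identity; 5 % of
  planted sites become 1–3 bp indels, which is what makes per-sample
  sequence lengths vary around the reference length.
* **30 non-census genes** with one hotspot each, carrier counts
  following a geometric gradient (`8 × 0.85^rank`) concentrated in a
  per-gene home tissue — giving the per-tissue top-4 % rule genuine
  structure to rank.
* **Passenger noise**: `Poisson(2)` private SNVs per donor at uniform
  positions over genes of 400–1200 nt, donor-private with probability
  approaching 1 as the position space grows.

Variant classes are drawn per *site* for planted and hotspot mutations
(so a recurrent site passes or fails the class filter as a unit, and
recurrence survives filtering by construction) and per *record* for
passengers. The generator never emits two mutations at the same
(donor, gene, position), so donor-level substitution conflicts cannot
arise from random collisions; the conflict check in
`apply_mutations()` remains active for external data. Every operation
draws from its own RNG stream derived from `(seed, operation name)`,
so adding an operation can never perturb existing outputs.

**What passing tests show and do not show.** The generator reproduces
the *combinatorial* structure the pipeline's contracts depend on
(recurrence, gradients, skew, privacy of passengers, indel length
variation). It does not emulate mutational signatures, trinucleotide
context, copy number, genome coordinates, or realistic gene lengths;
green tests therefore validate the algorithms' correctness and
determinism, not biological conclusions about any real cohort. The
published headline numbers for the real pan-cancer dataset (hundreds of
unique sequence nodes, a ~2.2 kb reference) come from access-restricted
data and are not reproduced at this scale; what is reproduced exactly
are the analytic identities relating those numbers (mean degree
`2m/n`, bipartite node-count sums) and every algorithmic property.

## Numerical choices and degenerate inputs

* Edit distances, counts and weights are integers throughout; no
  floating-point tolerances enter any graph construction.
* Ties: all-nearest-neighbor ties all receive edges; top-frequency ties
  at the cutoff are all kept; dominant-tissue ties break
  lexicographically; top-weight tables sort by weight then names.
* Degenerate inputs: an empty filter output halts the pipeline with a
  manifest rather than an error; a zero-locus reference yields empty
  strings (network construction then refuses, as all sequences
  coincide); graphs with no connected triple report transitivity 0
  rather than NaN, keeping the documented [0, 1] range.
* Problem sizes in the shipped tests (up to 300-node networks, 200-donor
  cohorts, 1,000 metric triples, exhaustive 2×2 sweeps with margins
  ≤ 12) were chosen so the whole suite validates every contract in
  about a minute on a single CPU.

## Known limitations

* The per-tissue top-4 % rule is lenient on sparse cohorts (singleton
  ties), by design; users wanting a strict cut can lower `fraction` or
  post-filter.
* Louvain is a heuristic: cluster counts are deterministic only per
  seed, and monotonicity in resolution holds empirically, not
  provably.
* Indel placement semantics on the reduced reference are a modelling
  choice (tracked-locus granularity); codon-aware or coordinate-level
  semantics are out of scope.
* Projection weights are raw co-occurrence counts; no null-model
  significance (hypergeometric backbone) is attached to them.
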