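---
title: "Methods: repertoire statistics and Dollo reconstruction of the calcium-signaling toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repertoire statistics and Dollo reconstruction of the calcium-signaling toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catoolkit)
library(tibble)
```

## The problem

Intracellular calcium signaling is carried by a toolkit of multidomain
proteins: channels that let calcium into the cytosol (influx), pumps and
exchangers that remove it (efflux), sensors that decode the calcium
signature, and kinases and other effectors that relay the decoded signal.
These proteins are built from a limited set of structural domains —
evolutionary units classified into SCOP superfamilies — and the *domain
architecture* of a protein is the ordered N→C sequence of those
superfamilies. catoolkit analyses the evolution of this toolkit at the
architecture level: which architectures exist in which genomes, how
abundant and diverse the calcium-binding part of a proteome is, which
functional components the architectures serve, and where in a species tree
each architecture was gained and lost.

Architectures are serialized as comma-separated superfamily ids with the
literal `_gap_` marker for unannotated stretches, e.g.
`47473,_gap_,50729,56112,_gap_` (an EF-hand followed by a kinase unit, with
unassigned regions). Two strings are the same architecture only if they
agree token for token, gaps included: `47473` and `47473,_gap_` are
distinct. This is deliberate — architecture counting throughout the
package is at exact string level, so parsing is strict: any token that is
not a positive integer or `_gap_` is an error rather than a silent gap,
which protects downstream counts from annotation-dialect drift.

The calcium-binding registry shipped with the package
(`ca_builtin_registry()`) is a curated set of calcium-binding SCOP
superfamilies: 31 entries of which 30 are distinct (one superfamily, the
TSP type-3 repeat, appears twice in the curation; both rows are kept, and
membership uses the deduplicated id set so the duplication is harmless). An
architecture is *calcium-binding* iff it contains at least one registry
superfamily.

## Repertoire statistics

For each genome the package counts annotated proteins and distinct
architectures, overall and restricted to calcium-binding architectures.
Three derived quantities summarize a proteome:

- **Diversity fraction** `n_ca_archs / n_archs_total`: the share of a
  proteome's distinct architectures that bind calcium.
- **Redundancy ratio**
  `(n_ca_proteins / n_ca_archs) / (n_proteins_total / n_archs_total)`:
  proteins-per-architecture among calcium-binding architectures relative to
  the proteome-wide rate. A value of 1 means calcium-binding architectures
  are duplicated at the background rate; under uniform duplication the
  ratio is exactly 1 by construction.
- **Abundance–diversity correlation**: the Pearson correlation, across
  genomes, of calcium-binding protein counts against distinct
  calcium-binding architecture counts, one point per proteome. A high
  correlation indicates that repertoire expansion was accompanied by domain
  shuffling (new architectures) rather than duplication alone, which would
  grow abundance without diversity.

The genome × superfamily occurrence matrix counts *proteins*, not domain
copies: a protein with two EF-hands contributes 1 to the EF-hand column.
This matches the interpretation of per-genome domain occurrence as "how
many proteins carry this domain" and keeps columns comparable between
domains that do and do not occur in tandem repeats.

Genomes that fail a metric's precondition (no architectures; no
calcium-binding architectures for the redundancy ratio) are reported with
`NA`, warned about, and excluded from cross-genome statistics rather than
imputed.

Proteins with no structural annotation are simply absent from the proteome
tables; all totals are over annotated proteins. A separate metadata table
can carry each genome's taxon label and total gene count for plotting
against genome size; genomes missing from it default to taxon `"unknown"`
and a gene count equal to the annotated count.

## Functional components and the conserved core

The component catalog is data, not code: a table of component ids (e.g.
`decoding-CDPK`, `relay-muscle-contraction`), their category (influx,
efflux, decoding, relay, other) and a `binds_calcium` flag. The shipped
example catalog covers the component names attested in the worked examples
and is explicitly user-replaceable, because any real component mapping is a
curation product that users will want to supply themselves.

`build_annotation_map()` implements the labeling procedure: each labeled
protein is resolved to its architecture, and labels accrue to the
architecture (globally — the same architecture in different genomes gets
the union of labels). Labels from a `binds_calcium` component are
restricted to architectures that actually contain a registry domain;
violating pairs are dropped with a warning. This restriction is the reason
the flag exists: downstream relay components (kinases acting after the
calcium sensor) legitimately label architectures without any
calcium-binding domain, while a "calcium sensor" label on such an
architecture is a curation error.

An architecture with ≥ 2 components is *multipurpose* (the ≥ 3 subset is
reported separately, as the highly multipurpose tail). The *conserved
core* at coverage threshold *t* is the set of components for which at
least a fraction *t* of genomes contain ≥ 1 annotated architecture;
`t = 1` is the minimal toolkit. The core is antitone in *t*, and comparing
the core at 1.0 and 0.9 probes its robustness: on data where every core
component is universally present the two sets coincide.

## Ancestral reconstruction: Dollo parsimony

The species tree is a rooted newick tree (polytomies allowed and handled
natively; no arbitrary binarization) whose leaves are genome ids. Unnamed
internal nodes receive deterministic preorder labels `N1, N2, …` so that
all outputs are addressable and reproducible; named nodes (such as a
`LECA` label at the eukaryote root) are preserved.

Ancestral architecture content is reconstructed under **Dollo parsimony**:
each architecture originates exactly once and may be lost repeatedly;
losses are minimized. Dollo is the natural model for multidomain
architecture content because the independent re-creation of the same
ordered multidomain arrangement is improbable, and it yields a
deterministic, testable reconstruction. It is a modeling choice of this
package — resources that distribute precomputed ancestral genome contents
do not publish an algorithm to reproduce, so no claim of numerical identity
with any external reconstruction is made, and the package's guarantees are
stated (and tested) against an exhaustive in-package oracle instead.

For one architecture with possessing leaf set *L*:

1. the **gain node** is the most recent common ancestor of *L*;
2. a node is **present** iff it is the gain node or a descendant of it
   *and* its subtree contains at least one leaf of *L*;
3. a branch parent→child with parent present and child absent is a
   **loss**; the single **gain** sits on the branch into the gain node
   (the root's incoming branch when the gain is at the root).

This assignment attains the minimum loss count among all single-gain
histories consistent with the leaves: any single-gain history must be a
connected presence set containing *L*, the gain cannot be below the MRCA,
and pruning any present subtree with no possessing leaves never increases
losses. The test suite does not take the argument on faith: it enumerates
*every* single-gain assignment on every rooted bifurcating shape with up to
6 leaves and every nonempty leaf pattern (511 shape × pattern cases) and
checks that the reconstruction matches the brute-force minimum exactly.

Branch events, lineage trajectories (per-node repertoires along a
root-to-leaf path) and treemap tables (per-node multipurpose percentage
and per-component single-purpose percentages, the latter summing to 100
where any single-purpose architecture is present) are all derived from the
reconstructed state matrix, so the event/state parity identity holds on
every path by construction and is re-checked property-style in the tests.

The model deliberately ignores horizontal transfer. Content evolution in
prokaryote-heavy trees is dominated by transfer, which violates the
single-origin assumption; the reconstruction will run on such trees but
its output should then be read as a lower bound on origins, not history.

## The synthetic-data generator

Because the package's real-world inputs are large curated databases it
cannot ship, every pipeline stage is exercised against a simulator with
recorded ground truth (`sim_config()`, `simulate_toolkit()`,
`emit_dataset()`). The generator emulates the statistical structure of the
analysis inputs: a rooted bifurcating species tree (uniform branch
attachment), architectures gained once at a sampled node, propagated with
independent per-branch loss draws, materialized as 1 or more protein
copies per possessing genome, and labeled with functional components drawn
consistently with the registry restriction.

Standing defaults (the package's study conditions, used by the tests and
the acceptance script): 20 leaves, 200 architectures, 80 % of them
calcium-binding, gains uniform over internal nodes, per-branch loss
probability 0.1, copy numbers 1 + Poisson(1), component counts
1 + Poisson(0.4). These sizes keep the whole simulated analysis in
seconds while leaving every distribution non-degenerate: ~1/3 of
architectures become multipurpose and a ~5 % tail carries three or more
components, copy numbers average 2 with real spread, and 20 proteomes give
the cross-genome statistics enough points to be meaningful. Randomness is
organized as one deterministic sub-stream per architecture index, so
output is byte-identical under a fixed seed and independent of evaluation
order.

Two generator regimes matter for testing:

- **Unrestricted losses** (default): reconstruction cannot always recover
  the truth — a clade can lose an architecture entirely, hiding a deeper
  origin — but Dollo's loss count is provably conservative (never more
  losses than the true history for any single-gain simulation), and the
  tests check exactly that bound.
- **Terminal losses only** (`terminal_losses_only = TRUE`): the regime
  used as the exact-recovery oracle. Loss draws are restricted to terminal
  branches, and the loss pattern is additionally rejection-sampled until
  the history is *identifiable* — the survivors' MRCA equals the gain node
  and every present node keeps a surviving possessor in its subtree.
  Without this conditioning, exact recovery would fail whenever a terminal
  loss emptied a whole child subtree of the gain node (for instance a leaf
  child of the gain); with it, node-for-node equality of reconstruction
  and truth is a theorem, and the suite verifies it at the full study
  conditions.

Architectures whose simulated history strands no surviving leaf are
redrawn; at the default loss rate this conditioning is rare and its bias
on the empirical per-branch loss frequency is far below the binomial
standard error at the simulated counts (a property the tests check
directly).

What the generator does *not* emulate — and hence what passing tests do
not show about real data: sequence evolution and annotation error
(architecture strings are exact); horizontal transfer; correlated losses
(draws are independent per branch); realistic copy-number skew (no
Pyrococcus-style genome-wide duplication bursts); biased taxon sampling;
and the ~30 % of real eukaryote proteins with no structural annotation,
which the package represents only as absence from the tables.

## Numerical and design choices

- **Determinism everywhere**: architectures and output rows are sorted
  lexicographically, internal node ids are preorder-deterministic, and the
  pipeline manifest records an MD5 per output; identical inputs give
  identical bytes.
- **Degenerate inputs** fail loudly with typed errors: empty architecture
  strings, all-gap architectures, empty registries, duplicate protein ids,
  unrooted trees, unknown leaf labels, empty presence sets, empty
  annotation results.
- **Ties**: Dollo as specified has no ties to break (the MRCA rule is
  unique); where several optimal single-gain histories exist in the
  brute-force sense they differ only in never-observable present nodes
  with no surviving descendants, which the MRCA rule excludes.
- **Thresholds**: the multipurpose threshold defaults to 2 components with
  the ≥ 3 count reported separately; core-toolkit coverage defaults to the
  sweep {1.0, 0.9}. Both are arguments, not constants.
- **Problem sizes in the shipped tests**: oracle equivalence on all shapes
  ≤ 6 leaves (511 cases), simulation recovery at 20 leaves × 200
  architectures, 1,000 randomized coverage trials for the core toolkit.
  These sizes were chosen so the full suite and the acceptance script each
  run in a couple of minutes on one CPU while exhausting the small-case
  space completely.

## Limitations

The package analyses architecture *content*, not sequences: it cannot
detect convergent architectures (excluded by the Dollo assumption), does
not model gene counts at ancestral nodes (presence/absence only), and
treats each proteome row as one protein, leaving isoform collapsing to
data preparation. The shipped component catalog is an editable example,
not a completed curation; conclusions about specific components are only
as good as the user-supplied mapping.
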