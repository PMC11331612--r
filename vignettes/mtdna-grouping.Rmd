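---
title: "Phylogenetically informed grouping of human mtDNA haplogroups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetically informed grouping of human mtDNA haplogroups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtgrouper)
```

## The problem

Human mtDNA haplogroup names record the history of their discovery, not the
nested structure of the mitochondrial tree: the deepest-splitting African
lineages carry two-character designations (L0–L7) while shallow,
Eurasian-biased branches own most single letters, and all non-L haplogroups
nest within L3. When studies collapse haplogroups into "macro-haplogroups" by
name prefixes, the result is often polyphyletic (an "L" group that is not a
clade) and systematically under-resolves African variation. This package
implements both the nomenclature-based groupings (to reproduce and audit
common practice) and a phylogeny-driven alternative: max-clade clustering of
a tree at one or several distance thresholds, with cluster levels translated
back into traditional nomenclature through MRCA lookup, and a hierarchical
dotted "mtHg-address" that names every haplotype uniquely and monophyletically.

## The name grammar and its irregularities

The cladistic notation for mitochondrial clusters assumes a name is one
capital letter followed by digit blocks and single lowercase letters in
alternation (`C1d1`). On the core name (the label up to the first `+`, `@`
or `*`, which begin mutation annotations rather than clade identity) we use
the regular expression

```
^[A-Z]([0-9]+([a-z][0-9]+)*[a-z]?)?$
```

which permits ending on either a digit block or a lowercase letter. Four
irregularity classes are flagged: consecutive uppercase letters (nested-clade
shorthand, `JT`), consecutive lowercase letters (`H3ag1`), any of the
modifier symbols `*()@+"` in the raw label, and apostrophe merges of sibling
clades (`M9a'b`). A name counts as *strictly cladistic* only when the core
matches the grammar **and** no irregularity flag is set; a symbol-bearing
label such as `D5a2a1+@16172` therefore is not strict even though its core
`D5a2a1` matches the grammar, which is how such names are usually tallied.
Percentages in the classification summary are rounded half-up to one decimal,
the precision at which these statistics tend to be quoted. Names are
case-sensitive; surrounding whitespace, internal whitespace, and digit-group
commas (`@16,172`) are removed before parsing.

Two deliberate edges: SCL refuses the bare name `L` (there is no haplogroup
L — only L0–L7 exist, and grouping by the letter alone is precisely the
practice being audited), and apostrophe names are kept whole and resolved in
hierarchies by exact label match, with no splitting heuristic.

## Max-clade clustering

Given a rooted tree with branch lengths (substitutions/site) and a threshold
`t`, the max-clade partition is the unique decomposition of the leaves into
*maximal* clades whose within-clade leaf-pair path-distance maximum is at
most `t`. Two passes over the edge list give it in linear time:

1. **postorder:** for every node keep the deepest leaf distance through each
   child; the clade diameter is the larger of the childrens' diameters and
   the sum of the two deepest leaf paths through distinct children;
2. **top-down:** emit a cluster at every highest node whose diameter passes;
   descendants of emitted nodes are covered, leaves are always valid, so the
   assignment is total and singletons get real cluster ids (a total
   assignment is required for addresses).

Numerical choices: the comparison is inclusive (`≤ t`) with an absolute
tolerance of 1e-12 to absorb branch-length summation noise, so zero-length
cherries co-cluster at `t = 0`. Cluster ids are assigned in ascending order
of each cluster's smallest tip index, making runs deterministic across
platforms. Trees must be rooted (ape's convention: a basal polytomy counts
as unrooted) because clades are undefined otherwise; branch support values
and internal labels are ignored, and no support-based collapsing is done.
The exhaustive oracle used in the tests enumerates every clade, filters by
the diameter bound computed from the full distance matrix, and keeps the
clades with no valid ancestor; the fast algorithm must match it exactly on
hundreds of random trees.

## mtHg-addresses and level naming

Running the partition over a strictly decreasing ladder (default
`0.008, 0.007, …, 0.001, 0`) stacks, for each sample, one cluster id per
level into a dotted address. Because the max-clade constraint is monotone in
`t` and clades are nested or disjoint, finer partitions refine coarser ones;
hence equal components at one position force equality at all coarser
positions (prefix consistency), and with a final threshold of 0 two samples
share a complete address exactly when their tree distance is zero — the
testable content of "no pseudo-haplogroups". Component ids are per level,
not cumulative, matching the dotted-number rendering where the same digit
recurs across levels. `finest_shared_threshold()` returns the threshold at
the end of the longest shared prefix, i.e. the finest level at which two
samples are still congrouped.

Cluster levels are translated into nomenclature by naming each cluster with
the MRCA haplogroup of its members' (modifier-stripped) labels; a cluster
whose members all carry one haplogroup is named by it directly, which also
avoids spurious lookup failures against partial hierarchies. The default
macro/meso/micro thresholds 0.006/0.005/0.004 sit in the range where the
grouping transitions from a handful of deep groups to tens of fine ones on
trees of diameter ~0.01; they are explicitly illustrative defaults, not a
proposed standard — suitable thresholds must be chosen per phylogeny.

## Sequence distances

The packaged mask removes the poly-C tracts 303–315 and 16183–16194 (rCRS
coordinates) that disrupt alignment; the rCRS 3107 spacer and RSRS 523–524
spacers are expected to be resolved upstream as indels. Reference-space
coordinates are counted over the reference row's non-gap characters, and a
column where the reference is gapped inherits the coordinate of the last
preceding base, so insertions inside a masked tract are masked with it.
Original coordinates are carried along on the masked object, which makes
masking idempotent. Distances are raw mismatch proportions (p-distance) or
counts under pairwise deletion — sites where either sequence is a gap or not
an unambiguous base are excluded for that pair, and ambiguity codes are
conservatively treated as missing. No model correction is applied: the
downstream uses (MDS, within-group violins) are rank-driven, and on mtDNA
scales multiple hits are rare. A pair with no comparable sites is an error,
never a silent zero.

## Ordination conventions

Correspondence analysis is computed from the SVD of the standardized
residual matrix `S = D_r^{-1/2} (P − r cᵀ) D_c^{-1/2}`; reported coordinates
are principal (mass-rescaled singular vectors scaled by singular values), so
the total inertia equals χ²/n — an identity the tests enforce to 1e-10.
All-zero rows/columns are pruned with a message since masses must be
positive; axis signs are arbitrary, and tests compare up to sign. CA is
scale-invariant, so feeding counts or relative frequencies is equivalent.
Classical MDS double-centers the squared distances and embeds with the
non-negative eigenpairs; negative eigenvalues — expected for tree metrics,
which are additive but generally not Euclidean — are reported and never used
for coordinates, and no additive-constant correction is applied.

## What the simulators emulate — and what they do not

The fixture bundle mirrors the shape of a population survey: a rooted tree
(Yule or Kingman topology) rescaled to diameter 0.01 so the 0.001–0.008
ladder is informative; a haplogroup hierarchy grown from the tree itself with
strict-grammar names (so labels are clade-consistent by construction);
seven populations whose group profiles are Dirichlet draws; and sequences
evolved along the tree under the one-parameter equal-rates substitution
model, whose cherry expectation `(3/4)(1 − e^{−4ℓ/3})` calibrates the
generator in the tests. Irregularity injection rewrites a recorded label —
apostrophe merges are synthesized as a sibling-level composite node inserted
under the original name's parent (so injected names still resolve and the
clade-MRCA invariant holds), and `+@pos` suffixes resolve via modifier
stripping — with every injection bookkept, so classifier recovery can be
asserted exactly.

Deliberately *not* simulated: indels and alignment error (alignment is an
upstream concern; masking is tested on hand-built toys), realistic mtDNA
mutation spectra, hotspots, heteroplasmy, and rate heterogeneity. Passing
tests therefore demonstrate algorithmic correctness on clean, tree-true
data, not robustness to alignment artefacts or model misspecification on
real sequence data.

## Problem sizes and determinism

The test suite works at sizes chosen to exercise the algorithms well past
their corner cases while staying quick on one core: exhaustive-oracle
equivalence on 200 random trees of up to 12 leaves with thresholds sampled
across the full diameter; refinement, prefix-consistency and the
within-group distance bound on 100-leaf trees over the eight-value ladder;
CA/MDS identities on dozens of random tables and configurations; generator
calibration at 10,000 sites. All stochastic tests fix their seeds, and every
generator is seed-deterministic end to end (a bundle reproduces
byte-identically from its seed).

## Known limitations

* Hierarchies must label every node uniquely; the packaged schematic
  hierarchy is a compact teaching fixture, not a full reference phylogeny.
* Rooting is the caller's responsibility (an outgroup such as the RSRS);
  trees with a basal polytomy are rejected for clustering.
* Only the max-clade criterion is implemented; other tree-clustering
  criteria (single-linkage, sum-length) are out of scope, as are haplogroup
  calling, alignment, and tree inference themselves.
* The CLI keeps to plain TSV/JSON; figures are left to the caller, with all
  plot-ready numbers available as tidy tables.
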