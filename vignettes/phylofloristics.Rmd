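---
title: "Phylofloristic structure and beta diversity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylofloristic structure and beta diversity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloflora)
```

## The problem

Regional floristic checklists record which species occur in which region,
but treat all species as exchangeable. Placing the checklist on a
time-calibrated phylogeny lets two further questions be asked. Within a
region: are the co-occurring taxa more closely related than a random draw
from the species pool (phylogenetic clustering, the signature of rapid
in-situ diversification or strong environmental filtering), or less
(overdispersion, the signature of a contact zone where distantly related
lineages meet)? Between regions: how much evolutionary history do two
floras share, beyond the species they have in common?

`phyloflora` implements this workflow end to end: grafting checklist taxa
onto a backbone megatree, deriving family/genus/species analysis trees,
computing the within-flora indices NRI and NTI and the between-flora
measures PhyloSor and S.E.S. Dnn under tip-shuffle null models, and
partitioning all of it by geographical distribution elements (pantropic,
north temperate, and so on).

## Building the analysis tree

Backbone megatrees never contain every checklist species. A species absent
from the backbone is bound into the smallest containing clade that is
resolvable: its genus if any congener is a tip, otherwise its family. Three
scenarios are offered:

* **S1 (polytomy)** — attach at the crown node of the containing clade,
  with pendant length equal to the crown age. Deterministic, and the
  default: it adds no unwarranted resolution.
* **S2 (random)** — attach at a uniformly chosen point inside the clade
  (an internal node, or the midpoint of a pendant edge), seeded.
* **S3 (BLADJ)** — attach as S1, then re-date every node created by
  grafting by even age interpolation, holding the backbone's original node
  ages fixed.

When the containing clade is a single tip the crown is undefined; a new
node is inserted at half the tip's pendant edge and the newcomer attached
there. This half-edge convention is what the Phylomatic lineage of tools
does; it preserves ultrametricity and adds the new split at the midpoint
of the only age interval the tree constrains. Grafting never changes the
patristic distance between any two pre-existing tips, and an ultrametric
backbone stays ultrametric to within 1e-6 relative tolerance — both
properties are enforced by tests.

BLADJ-style dating spaces undated nodes evenly: along a path between two
dated nodes with k undated nodes in between, the age interval is divided
into k+1 equal steps. When a node has several dated descendants, the
nearest one by node count constrains it (ties resolved toward the oldest,
which keeps ages monotone). Calibrations that date a node older than its
ancestor are rejected outright.

Rank-level trees keep one exemplar tip per genus or family — the
lexicographically first species, a deterministic and reproducible choice —
and relabel it with the rank name. Because the trees are ultrametric, any
congeneric exemplar gives identical between-group distances; lexicographic
choice simply pins the within-group pruning.

## The indices

With patristic distance d(i, j) (the sum of branch lengths on the
tip-to-tip path, in Myr):

* **MPD** — mean of d over all unordered pairs of a community.
* **MNTD** — mean over members of the distance to the nearest other
  member.
* **NRI / NTI** — sign-flipped standardized effect sizes,
  `-(obs - mean(null)) / sd(null)`, of MPD and MNTD respectively: positive
  means co-occurring taxa are *closer* than expected (clustering),
  negative means overdispersion.
* **PhyloSor** — `BL_shared / (0.5 * (BL_A + BL_B))`, where each `BL` is
  the branch length of the rooted spanning subtree of a community and
  `BL_shared` the length of edges common to both subtrees. The spanning
  subtree includes the path to the root: this root-inclusive convention is
  used everywhere in the package, and is the one under which the 4-tip
  worked example in the README gives 0.8.
* **Dnn** — mean distance from each taxon of one community to its nearest
  relative in the other. The definition is directional; the package
  reports the mean of the two directions by default (`direction =
  "mean"`), with both one-way variants available. **S.E.S. Dnn** is its
  sign-flipped standardized effect size: positive means the two floras are
  phylogenetically closer than expected.

## The null model

Null distributions come from shuffling the tip labels of the pool-pruned
phylogeny: community membership sizes — and, for region pairs, the size of
their overlap — are held fixed while the phylogenetic positions are
randomized. The pool is the union of all regional floras (configurable);
element-group analyses shuffle within the element's taxa only, so the null
asks "is this element's flora structured, given the element's own
phylogenetic spread?". Within one permutation the same shuffle is shared
by every region and region pair, preserving cross-community correlation
structure.

Each analysis uses 999 permutations by default. One-sided p-values
oriented toward clustering use the rank formula `(#{null <= obs} + 1) /
(n + 1)`; a two-sided flag at |SES| > 1.96 is reported alongside, since
sidedness conventions differ between studies. When the null distribution
has zero spread (for instance a community equal to the entire pool, or two
identical regions, whose Dnn is 0 under every shuffle) the SES is
undefined and is reported as missing with a `degenerate` flag — never as
±infinity.

A single master seed is expanded into per-stage integer streams
(`seed_streams()`), so the whole pipeline is bit-reproducible: identical
config plus seed gives byte-identical output CSVs.

## Geographical elements

Distribution-element codes operate at genus and family rank; requesting an
element analysis at species rank is an error by design. The genus
vocabulary ships the 15 codes standard in Chinese floristic work, grouped
into tropical (PT, TATAD, OWT, TATA, TATAF, TA) and temperate (NT, EANAD,
OWTE, TEA, MWACA, CA, EA, EC) super-groups, with cosmopolitan (COSM)
outside both and the legacy code ESHD retained inert. Family-level
typologies vary between floras, so the family vocabulary is a documented
synthetic placeholder (the 13 broadest codes) intended to be overridden
from CSV. Taxa whose element is unknown are excluded from every element
group — mirroring standard practice of dropping taxa with unclear
distribution patterns — but always count in `ALL TAXA`.

## The synthetic-data generator

The generator exists so that every stage has inputs with *known*
statistical structure. It emulates, at desk scale, a three-region flora on
a dated tree:

* trees are constant-rate Yule or birth–death trees conditioned on the tip
  count (`ape::rphylo`), default 200 tips — large enough for stable null
  distributions, small enough that a 999-permutation analysis runs in
  under a second;
* taxonomies cut the tree into monophyletic family clades and, within
  them, genus clades, so rank collapse and grafting are exercised against
  a known truth;
* communities of 30 taxa per region by default: `clustered` draws from
  the smallest clade holding the requested size; `overdispersed` uses
  greedy maximum-dispersion selection — each step adds the taxon with the
  largest summed distance to those already selected, directly pushing up
  MPD. Exact max-MPD subset selection is NP-hard; plain farthest-point
  (max-min) greedy was evaluated and rejected because it optimizes the
  minimum spacing rather than the mean and, on 200-tip pools, leaves MPD
  too close to the random expectation to register as significant
  overdispersion. `strength` interpolates toward uniform sampling, with
  `strength = 0` identical to `random`;
* element codes are assigned per genus (all congeners share a code) with
  proportions 0.5 tropical / 0.45 temperate / 0.05 unknown — a small
  unknown fraction keeps the exclusion path exercised.

What the generator does *not* emulate: real floras have thousands of
species, log-series-like richness imbalance across clades, spatially
autocorrelated ranges, and non-random element–clade associations. Passing
tests therefore demonstrate that the estimators and null models behave
correctly on trees with known structure — not that any particular
empirical flora is clustered or overdispersed.

## Calibration and recovery checks

The test suite (and `scripts/acceptance.R`) recomputes:

* **oracle equivalence** — MPD, MNTD, Dnn, rooted PD and PhyloSor against
  independent brute-force implementations (ancestor-walk path sums,
  edge-set enumeration) to 1e-9, on random trees up to 30 tips and
  exhaustively over all community pairs of an 8-tip tree;
* **null calibration** — 200 uniformly random 20-taxon communities from a
  100-tip Yule pool, 999 shuffles each: mean NRI and NTI fall within
  ±0.15 and the |SES| > 1.96 rejection rate within 2–10%;
* **parameter recovery** — clustered (strength 1) communities recover
  NRI > 0 with p < 0.05, and overdispersed NRI < 0, in at least 90% of 100
  replicates at 200 tips / 30 taxa / 999 shuffles; random communities are
  flagged in at most 10%. The same harness shows S.E.S. Dnn > 0 for region
  pairs nested in one clade and < 0 for pairs in disjoint clades;
* **tree-surgery guarantees** — grafting preserves ultrametricity and
  pre-existing distances; BLADJ chain fixtures match the closed-form even
  spacing exactly;
* **determinism** — rerunning the pipeline with the same master seed
  yields byte-identical CSVs.

These problem sizes were chosen as the smallest at which the Monte-Carlo
tolerances above are comfortably stable.

## Numerical choices and limitations

* Ultrametricity is asserted with a relative tolerance of 1e-6 on
  root-to-tip sums; metric comparisons in tests use 1e-9.
* Edge lengths produced by dating are clamped at zero if they come out
  negative by less than 1e-9 (floating-point dust); anything worse is an
  error.
* Polytomies are preserved, never randomly resolved: all metrics are
  distance-based and polytomy-safe.
* Taxa present in no region are dropped from matrices (they cannot affect
  any metric); species that can be placed nowhere on the tree (family
  absent from both backbone and checklist overlap) are logged and
  excluded.
* Abundance-weighted variants, UniFrac-style metrics and the pairwise
  between-community distance D_pw are deliberately out of scope; the
  analyses are presence/absence only.
* PhyloSor is reported raw, without a null model, and SES p-values are
  reported uncorrected for multiple testing; users comparing many element
  groups should apply their own correction.
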