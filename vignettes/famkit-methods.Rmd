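---
title: "Species-tree-aware gene family analysis with famkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species-tree-aware gene family analysis with famkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famkit)
```

## Scope and model

`famkit` implements the bespoke computational stages of a
species-tree-aware gene-family pipeline: the statistical heavy lifting
(posterior sampling of gene trees, probabilistic reconciliation,
multispecies-coalescent re-estimation) is done by external tools whose
standard output files — rooted newick trees, NEXUS tree samples — this
package consumes. `famkit` then answers four questions:

1. which nodes of the family tree are duplications (species-overlap
   classification), and which of them should split the family into
   ortholog sets (paralog-generating nodes);
2. how far the family tree sits from the species tree once duplications
   are accounted for (duplication-aware average normalized
   Robinson–Foulds distance);
3. which duplications and losses the family history implies on each
   species branch (LCA reconciliation);
4. which sampled tree best summarizes a posterior sample (maximum clade
   credibility selection).

A fifth component, the simulator, exists so that all of the above can be
exercised against a known ground truth.

All trees are `ape::phylo` objects and are treated as **rooted**
throughout; the only place an unrooted interpretation is used is inside
the Robinson–Foulds computation, where it is the standard definition.
Multifurcations are allowed everywhere and each operation states its
multifurcation rule. Unary nodes are suppressed on read, with branch
lengths summed along suppressed paths; an absent branch length means "no
information" and is never coerced to zero.

## Species-overlap classification and splitting

For an internal node with child subtrees carrying species sets
$S_1, \dots, S_k$, the overlap set is the set of species present in at
least two of the $S_i$ (for a binary node, simply $S_1 \cap S_2$), and
the overlap score is

$$\mathrm{score} = \frac{|\text{overlap}|}{|S_1 \cup \dots \cup S_k|} \in [0, 1].$$

A node is a **duplication** when its score exceeds the threshold; at the
default threshold 0.0 any non-empty overlap is a duplication (strict
inequality is used at non-zero thresholds, which reproduces the behaviour
of the ETE implementation that popularized the algorithm). The
generalization to multifurcations — species in at least two children —
was chosen over resolving multifurcations to binary, because any
resolution order would make the classification depend on an arbitrary
choice.

A node is **paralog-generating** when its child subtrees share at least
`min_common` species (default 2). The rationale for not splitting at
every duplication: most nodes with exactly one shared species are
species-specific (terminal-branch) duplications, and splitting there
would shred the family into many near-singleton sets; requiring two
shared species both controls the number of ortholog sets and keeps
obvious in-paralogs together. With `min_common = 1` the criterion
degenerates to plain SO duplication detection, which the package exposes
but does not default to.

Splitting dissolves each flagged node: its child subtrees become
independent trees and the flagged node disappears, so the resulting
forest always partitions the leaf set. Flagged nodes are processed
root-first and released subtrees are re-scanned, which makes the result
deterministic for nested flags. Note that dissolving a *non-root* node
produces its children **and** the residual tree, so $k$ flagged binary
nodes yield $k + 1$ sets only when the flagged nodes sit along a single
root-ward chain; in general the count follows from the positions of the
flagged nodes, and the partition property is what the package guarantees
(and tests).

## The duplication-aware distance

The family-level statistic is computed by a fixed pipeline:

1. split the family tree into ortholog trees at its paralog-generating
   nodes (`min_common = 2`);
2. decompose each ortholog tree at every remaining SO duplication
   (threshold 0.0) into subtrees with at most one gene per species, and
   relabel leaves to species names;
3. compare each subtree to the species tree by normalized RF restricted
   to their common species, with $\mathrm{nRF} = \mathrm{RF} / (|B_1| +
   |B_2|)$ (the normalization used by ETE, equal to $2(n-3)$ for two
   binary trees on $n$ shared leaves);
4. average over subtrees within each ortholog tree, then take the
   unweighted mean of the per-ortholog means.

Two choices here were genuinely open. First, subtrees sharing fewer than
four species with the species tree are **skipped** — RF is degenerate
below four leaves (both trees always agree) — and the skip counts are
reported rather than silently folded into the average as zeros. Second,
the overall value is the unweighted mean of per-ortholog means, which
follows the sequential description of the procedure ("for each ortholog
tree the average was estimated, then the overall average was obtained");
the pooled mean over all subtrees is also reported as a secondary field
for users who prefer weighting by subtree count. These two conventions
matter only for families with many small paralog clades; for families
dominated by a few large ortholog sets the two means are close.

## LCA reconciliation

Each gene node maps to the species-tree LCA of its descendants' species;
a node $v$ is a duplication iff $M(v) = M(c)$ for one of its children
$c$. Losses on the gene edge $v \to c$ follow the standard path
convention

$$\mathrm{losses}(v \to c) = d\big(M(v), M(c)\big) - \mathbb{1}[v\ \text{is a speciation}],$$

with $d$ the number of species-tree edges between the images. Each loss
is assigned to the species branch where the lineage disappears: walking
down the image path, every traversed species node sheds one loss per
off-path child branch (for multifurcating species nodes this counts one
loss per off-path child, the natural extension of the binary
convention). Duplications are counted on the branch of $M(v)$.

Species present in the species tree but absent from the family are a
modelling decision, not a computation: the package assumes a single
ancestral copy at the species root and reports the implied losses along
the stem from the species root to the image of the gene root in a
separate `absence_losses` table, never mixed into the path-based loss
counts. This keeps "the gene was never there" distinguishable from "the
gene was there and was lost", which the data alone cannot resolve.

SO and LCA classifications disagree by design (SO is more conservative
on sparse overlaps), but one containment always holds and is asserted in
the tests: every SO duplication with non-empty overlap is also an LCA
duplication, because a shared species forces the node and its child to
share their species-tree image.

## Posterior summarization

Clades are **rooted** (TreeAnnotator semantics) — a clade is the leaf
set below an internal node — and frequencies are counted over the
post-burn-in trees. Burn-in is a fraction of trees, not of generations,
because tree sample files carry trees, not timestamps; the first
$\lfloor b N \rfloor$ trees are excluded. The MCC tree is the *sampled*
tree maximizing the sum of log clade frequencies — never a consensus
construction — with ties broken by the earliest sample index. Mean clade
heights are reported only when every post-burn-in tree is ultrametric,
matching the common "mean heights" summary without promising time
calibration for samples that are not dated.

## The simulator

`simulate_family()` runs a Gillespie process per gene lineage along a
dated species tree, root to tips: waiting times are exponential with
rate $\lambda_d + \lambda_l + \lambda_t$; a duplication splits the
lineage in place, a loss terminates it, a transfer copies it onto a
branch chosen **uniformly** among the branches co-existing at that
moment (the donor excluded — a deliberate simplification of rate-weighted
transfer flows, sufficient for generating test fixtures and stated
explicitly here). At species-tree nodes every surviving lineage
bifurcates into both daughters. Ancestral copies start at the root node
itself, not on a stem branch. The full tree (including extinct lineages)
is kept alongside the observable tree, the event log records every
event's type, time, branch and lineage, and the node labels of the
returned trees record the generating event of every internal node
("D"/"S"/"T"), which is what lets the tests match detected
paralog-generating nodes against the truth after pruning.

What the simulator emulates: duplication-loss-transfer histories with
correct timing along a dated species tree. What it does not emulate:
sequence evolution and reconstruction error (gene trees are exact),
incomplete lineage sorting, rate variation across branches or families,
and rate-weighted transfer preferences. Tests passing on simulations
therefore validate the *combinatorial* machinery — they say nothing
about robustness to phylogenetic reconstruction error, which in a real
pipeline is handled upstream by the samplers.

### Fixture conditions

The fixture species tree (`example_dated_species_tree()`) has eight
species, crown age 4, two old crown radiations (stem length 2) and
recent sister-species splits (terminal branches 0.6). The shape was
chosen to resemble a vertebrate-style family tree — most lineage-time on
internal branches, congeneric species pairs at the tips — so that a
reasonable fraction of simulated duplications is ancient enough to leave
two or more species on both sides, the signature the paralog-generating
criterion detects. The default rates ($\lambda_d = 0.1$,
$\lambda_l = 0.05$, $\lambda_t = 0$ per lineage per unit time) give
families averaging roughly 1.5 duplications, occasional extinctions, and
no transfers, matching the regime under which duplication recovery is
evaluated.

```{r fixture}
st <- example_dated_species_tree()
plot(st)
ape::axisPhylo()
```

## Numerical and degenerate-input choices

* **Single-leaf trees** are valid everywhere (a split can release a
  singleton ortholog set); they serialize as `label;`.
* **Bipartition keys** join sorted labels with `|`; leaf labels
  containing `|` would collide and are the user's responsibility (gene
  and species identifiers in practice never contain it).
* **Branch-length precision** in `write_newick()` is decimal places,
  with trailing zeros trimmed; the round-trip tests hold to the stated
  precision.
* **RF with no shared splits possible**: when both pruned trees are
  stars, `max_rf = 0` and nRF is defined as 0 (identical unresolved
  topologies).
* **Ties in MCC selection** go to the earliest sampled tree, making the
  selection deterministic; the score itself is order-invariant, which is
  asserted under permutation.
* **Reproducibility**: `simulate_family()` seeds R's RNG from its `seed`
  argument, so identical inputs give bit-identical event logs and trees.

## Verification strategy and problem sizes

The test suite checks every operation against an independent oracle:
brute-force split enumeration (path-edge disjointness over all leaf
subsets) for RF on every unrooted 5- and 6-leaf topology pair; an
independent set-arithmetic recomputation of species-overlap events on
every rooted gene-tree shape up to 7 leaves over 4 species (11,463
shapes); `phangorn::RF.dist` as a cross-check; an exhaustive per-tree
scorer for MCC selection on 50-tree samples; the analytic expectation
$\sum_b N_b(e^{\lambda L_b} - 1)$ for duplication counts under pure
duplication (800 replicates, three standard errors); and the simulator's
event log for duplication recovery (500 replicates at the default
rates: no flagged node may sit on a non-duplication, and more than half
of all simulated duplications must be recovered). The all-rates-zero
null pipeline is required to be *exact*: overall nRF identically 0, no
events, one ortholog set per family, over 100 replicates. These sizes
keep the full suite comfortably fast while leaving each property
checked either exhaustively or at scales where sampling error is
negligible.

## Known limitations

* The ortholog-set splitter is the species-overlap criterion, not a
  reconciliation-based one; `dl_events()` provides the LCA alternative
  for users who want all putative duplications, but it does not drive
  the splitting.
* The distance module implements the literal split–decompose–average
  procedure; it is *similar to* TreeKO's speciation distance but is not
  TreeKO's all-pairs formulation, and no duplication-penalty variant is
  provided.
* Branch-length-aware distances (weighted RF, KC) are out of scope.
* Transfer-aware reconciliation is out of scope; transfers exist only in
  the simulator's event vocabulary.
* The CLI consumes files produced by external samplers; it never invokes
  them.
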