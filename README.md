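# famkit

Species-tree-aware analysis of gene family trees in R.

## The problem

A gene family tree relates all homologous genes of a family across a set of
species. It disagrees with the species tree whenever the family duplicated,
lost copies, or (rarely, in animals) transferred between genomes. Telling
orthologs (diverged by speciation) from paralogs (diverged by duplication),
quantifying how far a reconstructed family tree sits from the species
phylogeny, and mapping duplications and losses onto species branches are the
recurring computational steps of any species-tree-aware pipeline built
around samplers such as BEAST, reconciliation tools such as ALE, and
multispecies-coalescent re-estimation of ortholog trees. `famkit`
implements those bespoke steps:

* **Species-overlap (SO) classification** — an internal node of a rooted
  gene tree is a *duplication* when its child subtrees share species. The
  overlap score of a node is |shared species| / |union of species|; with
  the threshold at 0.0, any non-empty overlap is a duplication.
* **Paralog-generating nodes and ortholog sets** — a node whose child
  subtrees share at least `min_common = 2` species is *paralog-generating*;
  splitting the family tree at those nodes yields ortholog sets (leaving
  species-specific duplications, overlap of a single species, alone).
  Re-estimated ortholog trees can be grafted back into the family tree.
* **Duplication-aware average normalized Robinson–Foulds distance** — the
  family tree is split into ortholog trees, each ortholog tree is
  decomposed at its remaining SO duplications into single-copy subtrees,
  each subtree is compared with the species tree by
  nRF = RF / (|B1| + |B2|) restricted to shared species, and per-ortholog
  means are averaged into one family-level statistic.
* **LCA reconciliation** — each gene node maps to the species-tree LCA of
  its descendants' species; a node is a duplication iff it maps to the same
  species node as one of its children, and losses are counted per species
  branch by the standard path convention.
* **MCC summarization** — the maximum clade credibility tree of a posterior
  sample (the sampled tree maximizing the sum of log clade frequencies),
  with posterior supports annotated.
* **Simulation** — a Gillespie duplication–loss–transfer process along a
  dated species tree with a ground-truth event log, so every step above is
  testable without downloads.

## Worked example

```r
library(famkit)

species_tree <- example_dated_species_tree()   # 8 species, crown age 4
sim <- simulate_family(species_tree,
                       sim_params(dup_rate = 0.08, loss_rate = 0.05),
                       seed = 27)
sim
#> Simulated gene family: 12 extant gene(s); 2 duplication(s), 1 loss(es), 0 transfer(s)

gene_tree <- sim$observable_tree
map <- sim$species_map                          # regex "^g[0-9]+_(.+)$"

# duplication nodes and paralog-generating nodes
ev <- so_events(gene_tree, map)
table(ev$event)
#> duplication  speciation
#>           2           9
flagged <- find_paralog_generating(gene_tree, map, min_common = 2)
flagged[, c("node", "overlap_size", "overlap_score")]
#>   node overlap_size overlap_score
#> 2   14            4             1

# split into ortholog sets at the one paralog-generating node
sets <- extract_ortholog_sets(gene_tree, map)
sapply(sets, `[[`, "size")
#> [1] 4 5 3

# duplication-aware distance from the species tree
family_nrf(gene_tree, species_tree, map)
#> Family vs species tree, duplication-aware normalized RF
#>   ortholog trees: 3  decomposed subtrees: 5  skipped: 4
#>   ortholog 1 (4 members): mean nRF = 0.0000 over 1 subtree(s)
#>   ortholog 2 (5 members): mean nRF = NA over 0 subtree(s)
#>   ortholog 3 (3 members): mean nRF = NA over 0 subtree(s)
#>   overall nRF = 0.0000 (pooled 0.0000)

# duplications and losses on species branches
events <- dl_events(gene_tree, species_tree, map)
events
#> Reconciliation events: 2 duplication(s), 1 loss(es); 0 stem/absence loss(es)
head(events_by_branch(events, species_tree), 4)
#>   species_node parent label dup_count loss_count absence_loss_count
#> 1            1     11    s1         0          0                  0
#> 2            2     11    s2         0          0                  0
#> 3            3     12    s3         0          0                  0
#> 4            4     12    s4         1          0                  0
```

This family carries one ancient duplication (the paralog-generating node,
whose child subtrees share four species) and one species-specific
duplication on the branch of `s4`. The tree evolved without topological
distortion, so every decomposed single-copy subtree that shares at least
four species with the species tree matches it exactly (overall nRF 0);
subtrees with fewer than four shared species are skipped and counted.
Losses and transfers move nRF away from 0.

The same operations are available from the shell through the installed
script (`inst/scripts/famkit`):

```sh
famkit split     --tree fam.nwk --species-map map.tsv --out-prefix fam
famkit compare   --family fam.nwk --species-tree sp.nwk \
                 --species-map 'regex:^g[0-9]+_(.+)$' --out-prefix cmp
famkit reconcile --gene-tree fam.nwk --species-tree sp.nwk \
                 --species-map map.tsv --out-prefix rec
famkit mcc       --sample posterior.trees --burnin 0.1 --out mcc.nwk
famkit simulate  --species-tree sp.nwk --dup 0.1 --loss 0.05 --seed 42 \
                 --replicates 100 --out-dir sims/
```

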