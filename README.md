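# catoolkit

Comparative-genomic analysis of the calcium-signaling toolkit at the level
of protein **domain architectures**.

Intracellular calcium signaling is carried by multidomain proteins that
generate a cytosolic calcium signal (influx), remove it (efflux), decode
it, and relay it to effectors. Each protein is described by its domain
architecture: the ordered N→C sequence of SCOP superfamily domains,
serialized as a string such as `47473,_gap_,50729,56112,_gap_` (EF-hand,
unannotated stretch, kinase units). catoolkit takes per-genome tables of
such architectures, a curated registry of calcium-binding superfamilies, a
functional-component catalog, and a rooted species tree, and computes:

- **Repertoire metrics** per genome — calcium-binding protein and
  architecture counts, the *diversity fraction*
  `n_ca_archs / n_archs_total`, the *redundancy ratio*
  `(n_ca_proteins / n_ca_archs) / (n_proteins_total / n_archs_total)`, the
  genome × superfamily occurrence matrix, and the cross-genome Pearson
  correlation between calcium-binding abundance and architecture diversity.
- **Functional annotation** — component labels inferred from proteins onto
  architectures (labels from calcium-binding components are restricted to
  architectures containing a registry domain), single- vs multipurpose
  classification, and the *conserved core*: components present in every
  genome (or any coverage fraction, with a sensitivity sweep).
- **Ancestral reconstruction** — Dollo parsimony (each architecture gained
  exactly once at the MRCA of its possessing leaves; losses minimized)
  over a rooted species tree with polytomies, yielding per-node presence
  states, per-branch gain/loss events, root-to-leaf lineage trajectories,
  and per-node treemap tables.
- **Synthetic data** — a generator that evolves architecture repertoires
  along a simulated tree with recorded ground truth (states, events, copy
  numbers, component map), so the whole pipeline is testable end to end
  without external databases.

Everything is tibble-first and pipe-friendly; reconstruction objects
support `tidy()`, `glance()` and `autoplot()`, and `plot_*()` helpers
cover the main result types.

## Worked example

```r
library(catoolkit)

sim  <- simulate_toolkit(sim_config(n_leaves = 20, n_architectures = 200, seed = 7))
summ <- summarize_genomes(sim$genomes, sim$registry)
head(summ, 4)
#> # A tibble: 4 × 7
#>   genome_id taxon_group total_gene_count n_proteins_total n_archs_total
#> 1 G0001     unknown                   46               46            25
#> 2 G0002     unknown                  101              101            47
#> 3 G0003     unknown                   29               29            14
#> 4 G0004     unknown                   94               94            39
#> # with n_ca_proteins, n_ca_archs

abundance_diversity_correlation(summ)
#> [1] 0.9060105
mean(diversity_fraction(summ))
#> [1] 0.7918767
mean(redundancy_ratio(summ))
#> [1] 0.9938812
```

The correlation of ~0.91 says that across these 20 proteomes,
calcium-binding abundance and architectural diversity grow together —
expansion by shuffling, not just duplication. The mean diversity fraction
~0.79 reflects the simulated 80 % calcium-binding share, and a redundancy
ratio near 1 means calcium-binding architectures are duplicated at the
proteome-average rate.

```r
ann <- build_annotation_map(sim$protein_components, sim$genomes,
                            sim$catalog, sim$registry)
count_multipurpose(ann, 2); count_multipurpose(ann, 3)
#> [1] 81
#> [1] 11
core_toolkit(ann, sim$genomes, 1.0)
#> [1] "decoding-annexin"  "decoding-calmodulin" "decoding-CDPK" ...

rec <- dollo_reconstruct(sim$tree, presence_from_genomes(sim$genomes, sim$registry))
glance(rec)
#> # A tibble: 1 × 6
#>   n_architectures n_leaves n_nodes n_gains n_losses n_root_architectures
#> 1             160       20      39     160       83                    4
head(branch_events(rec), 2)
#> # A tibble: 2 × 4
#>   parent child event architecture
#> 1 <NA>   N1    gain  18073,56436,65310,82934
#> 2 <NA>   N1    gain  56784
```

Here 160 of the 200 simulated architectures are calcium-binding and
reach at least one leaf; each gets exactly one gain (the Dollo
assumption), 83 losses are inferred in total, and 4 architectures are
reconstructed back to the root. Events with parent `<NA>` sit on the
root's incoming branch.

A file-based run of the same analysis:

```r
emit_dataset(sim, "demo")
config <- ca_run_config(tree = "demo/tree.nwk", proteomes = "demo/proteomes",
                        registry = "demo/registry.csv", catalog = "demo/catalog.tsv",
                        components = "demo/protein_components.tsv",
                        metadata = "demo/metadata.tsv", out = "demo/out")
run_all(config)   # summaries, occurrence matrix, annotation map, core sweep,
                  # ancestral states, branch events, treemaps, manifest.json
```

A thin CLI over the same functions lives at `inst/cli/catoolkit.R`
(subcommands `simulate`, `metrics`, `components`, `ancestral`, `all`).

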