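# tcrnet

Similarity-network analysis of T-cell receptor (TCRβ) CDR3 repertoires.

High-throughput TCR sequencing yields, per individual, tens of thousands
of unique CDR3β amino-acid sequences (clonotypes) at varying abundances.
`tcrnet` is for immunologists and computational biologists who want to
ask structural questions of such repertoires: do the abundant clonotypes
sit in dense neighborhoods of sequence space? Are the well-connected
sequences the *public* ones — shared across individuals, or even across
species? How does an immune challenge reshape that structure?

The core objects and statistics:

* **Similarity network** — undirected graph over unique CDR3 amino-acid
  sequences with an edge wherever the Levenshtein distance
  (one substitution, insertion or deletion) is exactly 1. A *cluster* is
  a connected component of ≥ 2 nodes. Construction uses a
  deletion-variant index (O(n·L) candidates instead of O(n²) pairs) with
  exact verification; it is tested for edge-set equality against an
  independent all-pairs dynamic-programming oracle.
* **Sharing level** `s(x) ∈ {0, …, N}` — the number of individuals in a
  reference cohort whose repertoire contains sequence `x`; 1 = private,
  N = public, with thresholded categories (e.g. CS-public = public in
  both a mouse and a human reference cohort).
* **Gini coefficient** `G = Σᵢ (2i − n − 1) x₍ᵢ₎ / (n Σ x)` of clone
  abundances — 0 for a perfectly even repertoire, 1 − 1/n for a single
  dominant clone.
* **Convergent recombination** — mean number of distinct nucleotide
  variants encoding an amino-acid clonotype, profiled by sharing level.
* **VDJ simulator** — a generative null model (weighted segment choice,
  geometric junctional trimming and insertion, productive rejection
  sampling, power-law clone sizes) that produces single- or two-species
  cohorts in which sharing, convergent recombination and network density
  emerge from generation probability alone.

Exact Fisher (2×2) and paired Wilcoxon signed-rank tests, annotation
linkage (identical / distance-1 / unlinked, with self vs non-self
enrichment), GraphML/SIF export with node-attribute CSVs, and
figure-level pipelines (`run_figure1/2/5`) are included.

## Worked example

Simulate a 12-mouse cohort (30,000 rearrangements each), build the
network of one individual's 1000 most frequent clonotypes, and relate
connectivity to publicness:

```r
library(tcrnet)

cohort_m <- generate_cohort(default_mouse_config(), n_individuals = 12,
                            n_clonotypes = 30000, seed = 42)
sharing <- sharing_levels(cohort_m)

rep1 <- cohort_m$repertoires[[1]]
top  <- top_clonotypes(rep1, 1000)
net  <- build_network(top)
net
#> <tcr_network> 1000 nodes, 533 edges, 388 clustered nodes in 46 clusters
#>   provenance: repertoire sim_mouse_01 (1000 clonotypes)

accumulated_frequency(top)           # the top-1000 hold 41.0% of all reads
rnd <- random_clonotypes(rep1, 1000, seed = 1)
build_network(rnd)                   # random-1000: 110 clustered, 67 edges

degree_sharing_correlation(net, sharing, method = "spearman")
#> rho = 0.77, p = 4.0e-195            connectivity tracks publicness
abundance_degree_r2(net)
#> 0.003                               ...but not abundance

repertoire_gini(top)
#> 0.527                               evenness of the top of the repertoire

convergent_recombination(rep1, sharing)
#> mean nt variants per AA clonotype rises from 1.01 (private, s = 1)
#> to 3.10 (public, s = 12)
```

The interpretation mirrors the biology the package targets: the abundant
and the public clonotypes form dense distance-1 clusters (388 clustered
nodes vs 110 for a random selection of the same size), node degree
correlates with sharing level but essentially not with abundance, and
public clonotypes are convergently recombined (many nucleotide spellings
of the same amino-acid sequence).

Real data enter as plain TSV (`cdr3_aa`, `count`, `v_gene`, `j_gene`,
optional `cdr3_nt`) or AIRR Rearrangement TSV (`junction_aa`,
`duplicate_count`, `v_call`, `j_call`, `junction`) via
`read_repertoire()` / `read_cohort()`.

A command-line interface covers the common runs:

```sh
Rscript -e 'tcrnet::tcrnet_cli()' build-net --input rep.tsv \
    --select top:1000 --export graphml --out net
Rscript -e 'tcrnet::tcrnet_cli()' simulate --individuals 12 \
    --size 30000 --seed 42 --out sim/
```

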