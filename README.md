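# pangevo

Pangenome-evolution analysis for bacterial genome sets, built for studies
like the comparative genomics of *Pseudoalteromonas*: how large is the gene
repertoire of a genus, is it still growing as genomes are added, what did
the last common ancestor carry, and how much of the variation rides on
mobile genetic elements?

`pangevo` takes per-genome protein sets (FASTA) and, optionally, a rooted
phylogeny and reference protein databases, and provides:

- **Ortholog families** by pairwise bidirectional best hits (BBH) with a
  built-in Smith–Waterman/BLOSUM62 backend (or precomputed BLAST tabular
  hits), families being connected components of the BBH graph.
- **Core / accessory / unique partitioning** of the family presence/absence
  matrix: a family in every genome is core, in exactly one genome unique,
  otherwise accessory.
- **Rarefaction and openness.** Random combinations of *N* genomes (10
  replicates per *N*) give pangenome, core and new-gene curves, fitted by
  nonlinear least squares to

  - Heap's law `N(pan) = k·N^γ`,
  - the new-gene decay `N(new) = k·N^(−α)`,
  - the core double exponential
    `N(core) = k₁·exp(−N/τ₁) + k₂·exp(−N/τ₂) + Θ`,

  where `γ > 0` means the pangenome has no asymptote — it is *open* — and
  `Θ` estimates the asymptotic core genome.
- **Gene gain/loss reconstruction** on a rooted tree by weighted (Sankoff)
  maximum parsimony with gains twice as costly as losses, yielding
  per-branch gain/loss counts and ancestral genome sizes, including the
  LCA's.
- **First-best-hit annotation screens** (mobilome, cold adaptation,
  resistance, transport) with the strict thresholds e-value < 1e-20,
  coverage > 30%, similarity > 60% (the CAP preset uses e < 1e-30 only),
  panmobilome partitioning, Jaccard/average-linkage clustering of
  presence profiles, and bipartition comparison against a phylogeny.
- **A synthetic genome-set generator** — gene-family birth/death along a
  known tree with sequence evolution — so the whole pipeline is testable
  against ground truth without downloading genomes.

The published summary tables of the 38-strain *Pseudoalteromonas* dataset
(genome statistics, per-strain mobilome counts, partition counts) ship as
plain-text data under `inst/extdata/` for the worked examples and checks.

## Worked example

Simulate six genomes with known family history, recover the families by
BBH clustering, partition and rarefy the pangenome, and reconstruct gains
and losses on the true tree:

```r
library(pangevo)

tree     <- simulate_tree(6, seed = 7)
cfg      <- sim_config(seed = 11)
truth    <- simulate_families(tree, cfg)
genomes  <- sim_sequences(truth, cfg)

clustering <- cluster_genomes(genomes)       # BBH families + matrix
pangenome_partition(clustering$matrix)
#> Pangenome partition over 6 genomes: 80 families
#>   core          40 (50%)
#>   accessory     10 (13%)
#>   unique        30 (38%)

tab  <- rarefy(clustering$matrix, seed = 3)  # 10 random combinations per N
heap <- fit_heap(tab)
heap
#> heap_pangenome fit (50 points, RSS = 1279)
#>         k     gamma
#> 44.781800  0.321792
classify_openness(heap)
#> $status
#> [1] "open"

reconstruct_gain_loss(clustering$matrix, tree)
#> Gain/loss reconstruction: 80 families, 6 genomes, total cost 81.0
#>   LCA (root) genome size: 44 families
#>   total gains 36, total losses 9
```

The partition recovers the 40 simulated core families exactly; the fitted
`γ ≈ 0.32 > 0.05` calls the simulated pangenome open (gain events keep
introducing new families along the tree); and the reconstruction places
most inferred gains on terminal branches, as expected when unique families
arise from recent events. On this configuration the BBH families match the
simulated ground truth with adjusted Rand index 1.0.

`run_pipeline(pipeline_config(...))` chains all stages over a directory of
FASTA files and writes TSV outputs plus a run manifest;
`inst/scripts/pangevo.R` wraps `simulate` and `run` for shell use.

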