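---
title: "Pangenome openness, gene gain/loss and mobilome screens with pangevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pangenome openness, gene gain/loss and mobilome screens with pangevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pangevo)
```

## The analysis

`pangevo` implements a complete bacterial pangenome-evolution workflow over
per-genome protein sets:

1. **Orthology.** Gene families are built by pairwise *bidirectional best
   hits* (BBH): for every cross-genome gene pair the package computes a
   Smith–Waterman local alignment, and two genes form a BBH pair when each
   is the other's best hit in the partner genome. Families are the
   connected components of the BBH graph; genes with no reciprocal edge
   become singleton families.
2. **Partition.** Over a genome group, a family present in every genome is
   *core*, in exactly one genome *unique*, otherwise *accessory*.
3. **Rarefaction and curve fits.** Random combinations of N genomes (10
   replicates per N by default) yield pangenome size, core size and
   new-gene counts as functions of N. Three models are fitted by nonlinear
   least squares: Heap's law `k·N^γ` for the pangenome, the power-law decay
   `k·N^(−α)` for new genes, and the double exponential
   `k₁·exp(−N/τ₁) + k₂·exp(−N/τ₂) + Θ` for the core genome, with Θ the
   asymptotic core estimate. A fitted `γ > 0` means the pangenome keeps
   growing as genomes are added — an *open* pangenome.
4. **Gain/loss reconstruction.** Presence/absence patterns are mapped onto
   a rooted phylogeny by weighted (Sankoff) maximum parsimony, with a gain
   twice as costly as a loss (the cost dual of "losses twice as probable as
   gains"). The root row of the resulting node table is the inferred gene
   repertoire of the last common ancestor (LCA).
5. **Annotation screens.** Genes are assigned to reference categories
   (plasmid/virus/prophage for the mobilome; cold-adaptation, resistance
   and transport sets use the same machinery) by *first best hit* under
   strict thresholds, and mobile families are partitioned into a
   core/accessory/unique *panmobilome*. Strain-by-feature presence profiles
   are clustered hierarchically and compared against the phylogeny by
   shared bipartitions.

A synthetic genome-set generator with known ground truth makes every stage
testable end to end without downloading genomes.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| BBH hit cutoff | e ≤ 1e-5 | significance floor for best-hit orthology |
| rarefaction replicates | 10 | random combinations per N |
| screen e-value | < 1e-20 | strict; CAP preset tightens to < 1e-30 |
| screen coverage | > 30% | strict, computed on the query |
| screen similarity | > 60% | strict; positive-scoring aligned positions |
| gain : loss cost | 2 : 1 | weighted-parsimony event costs |
| core-fit initial guesses | 1, 1, 0.1, 0.1, 1500 | `(k₁, k₂, τ₁, τ₂, Θ)` |
| openness threshold ε | 0.05 | `γ > ε` is called open |

All screen thresholds are strict inequalities, so a hit at exactly 60%
similarity (or exactly 1e-20, or exactly 30% coverage) is rejected. The
CAP (cold-adaptation protein) preset applies only the tightened e-value,
with no coverage or similarity floor.

The openness rule "any γ > 0 is open" is exact in ideal arithmetic, but a
fitted exponent carries noise; ε = 0.05 separates fitted noise from real
growth and is configurable in `classify_openness()`.

## The alignment backend

The built-in backend is Smith–Waterman over BLOSUM62 with affine gaps
(open 11, extend 1) via `Biostrings::pairwiseAlignment`, scored into bits
and an e-value with the standard gapped BLOSUM62 Karlin–Altschul constants
(λ = 0.267, K = 0.041). *Similarity* is the percentage of aligned positions
with a positive substitution score, *identity* the percentage of exact
matches, both over the alignment length including gap columns; *coverage*
is always computed on the query, since reference databases mix protein
lengths. Precomputed 12-column BLAST tabular hits are accepted as an
alternative backend and take precedence when supplied; that dialect has no
similarity column, so identity stands in for similarity with a warning
(a 13th column supplies similarity when available).

The BBH stage reports only hits with e ≤ 1e-5. Without a significance
floor, a gene whose true ortholog is missing from the partner genome picks
up an arbitrary weak best hit there, and two such genes can form a spurious
reciprocal pair; the floor removes these while leaving genuine homologs
(typically e ≪ 1e-20) untouched.

## Numerical choices in the curve fits

Fits run on the full (N, replicate) point cloud by default; per-N means
are available behind `use_means = TRUE`. Optimization is
Levenberg–Marquardt through `minpack.lm::nls.lm`.

The double-exponential fit records the conventional initial guesses
`(1, 1, 0.1, 0.1, 1500)` and starts there, but that point is numerically
degenerate: with τ₁ = τ₂ = 0.1, `exp(−N/0.1)` underflows for every N ≥ 2,
the Jacobian with respect to k₁, k₂, τ₁, τ₂ is effectively zero, and any
pure descent method stalls with only Θ updated (the model-formula interface
`nlsLM()` refuses the start outright as rank-deficient). `fit_core_decay()`
therefore also restarts from a small deterministic set of data-scaled time
constants (τ on the order of 1 to the largest N, amplitudes on the data
range) and keeps the lowest-RSS solution. On noiseless model data this
recovers generating parameters to machine precision, including the
degenerate start's intended optimum. The two exponential terms are
exchangeable, so (k₁, τ₁) and (k₂, τ₂) are reported in whichever order the
optimizer lands on; tests accept the label swap. Time constants are bounded
below at 1e-8 and a fit driven to that bound is flagged rather than
accepted silently. Heap and decay fits use data-scaled starts (k from the
smallest-N sizes, exponent 0.5), which avoids divergence on arbitrary
scales.

Percentages everywhere are integers rounded half-up; on the genus partition
counts (1571, 2901, 18058) this reproduces the printed 7/13/80 split
exactly.

## Parsimony details

The Sankoff recursion runs over all families simultaneously (cost matrices
indexed family × node), with per-edge transition costs and no root prior.
Among minimum-cost assignments, ties are broken first by the fewest total
events and then by preferring absence, which makes the reconstruction
deterministic and resolves single-genome families as recent gains on
terminal branches rather than ancestral presence with repeated loss — the
conservative choice for ancestral genome content. Multifurcating trees are
handled by the same recursion; branch lengths are ignored (costs are per
event). With asymmetric costs (gains at 2, losses at 1), a family confined
to one root-adjacent clade is explained by a single loss in the sibling
clade rather than a gain, so inferred ancestral repertoires lean large;
this is a property of the cost scheme, not of the implementation, and the
suite verifies the dynamic program against exhaustive enumeration of all
internal-state assignments on small trees.

## What the synthetic generator does and does not emulate

`sim_config()` defaults describe a small open pangenome: 6 genomes on a
random coalescent-like tree (exponential branch lengths, mean 0.1), 40
core families, gain events at rate 25 per unit branch length (one family
per event by default), per-family loss intensity 2, and proteins of 100
residues substituting at 0.3 per site per unit branch length — roughly
75–90% within-family identity at the leaves, a realistic range for
congeneric strains. Core families are never lost, so the simulated core is
core by construction; gained families are lost independently per branch
with probability `1 − exp(−loss_rate · length)`. A configurable fraction
(default 10%) of families is labeled mobile and drives the screen-stage
ground truth.

The generator reproduces the statistical structure the analysis assumes —
binary family presence generated by birth/death along a known tree, family
sequences divergent but recognizable, singletons arising on terminal
branches — and deliberately omits much of real data: no paralogs within a
genome, no indels or rate heterogeneity across sites or lineages, no
horizontal transfer of an existing family between lineages (a new gain is
always a new family), no nucleotide-level evolution, and uniform random
ancestral proteins rather than real domain structure. Tests passing on
simulated data therefore validate the pipeline's logic and bookkeeping,
not its behaviour on biological idiosyncrasies like promiscuous domains or
low-complexity sequence.

Every stochastic step is seeded; one master seed fans out to per-stage
derived seeds, so a configuration and seed reproduce byte-identical trees,
matrices and FASTA output.

## Degenerate inputs

- Identical genomes: rarefaction is flat, `new_genes = 0` for N ≥ 2, and
  the decay fit returns a degenerate flag with k = 0 instead of failing.
- A constant presence/absence matrix gives all-zero Jaccard distances; the
  clustering returns a star dendrogram with a warning.
- Rarefaction with more replicates than distinct combinations (always the
  case at N equal to the genome count) recurs combinations and says so.
- Empty FASTA files are skipped with a warning; duplicate gene ids within
  a genome are an error naming the file and id.
- N = 1 rarefaction rows are emitted (flagged by the `extended` column)
  but excluded from curve fits, which use N ≥ 2 as in the published
  sampling scheme.

## Problem sizes in the test suite

The suite validates parsimony against exhaustive enumeration on 20 random
trees of 3–6 leaves with 100 random patterns each; curve-model recovery on
noiseless data over N = 2..38 with 10 replicates per N; end-to-end family
recovery on a 6-genome simulated set (~80 families, ~300 genes); and
rarefaction/openness properties over 10 seeds. These sizes keep the whole
suite to a few minutes on one CPU while exercising every code path; the
pipeline itself scales to dozens of genomes, with the all-vs-all alignment
stage dominating run time (quadratic in total gene count).

## Known limitations

- The Karlin–Altschul e-value uses fixed gapped-BLOSUM62 constants and raw
  sequence lengths, not composition-adjusted effective lengths; e-values
  are comparable within a run but not identical to BLAST's.
- Connected-component closure is the simplest consistent reading of
  pairwise BBH clustering; it can chain families through promiscuous genes
  on real data (no Markov-clustering refinement is attempted).
- Weighted parsimony yields point reconstructions, not posterior
  probabilities; no birth–death rate estimation is attempted.
- The mobilome screen assigns one category per gene from its first best
  hit, as in the published workflow; genes with genuinely mixed homology
  are not split.
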