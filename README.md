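# kpnet

Bow-tie hierarchy decomposition and null-model statistics for directed
signalling networks, built around the yeast kinase–phosphatase network
(KP-Net) use case.

## The problem

Kinases and phosphatases (KPs) form a directed, signed network of
phosphorylation (P) and dephosphorylation (D) interactions. Such networks
are typically not trees and not flat: they organize into a **bow tie** — a
small strongly connected **core** that integrates signals, an upstream
**top** layer that feeds it, and a downstream **bottom** layer it drives,
with remaining enzymes peripheral and non-enzyme substrates below. `kpnet`
is for systems biologists who have such an edge list and want to:

- quantify how hierarchical the network is (**global reaching centrality**,
  GRC),
- sort enzymes into top/core/bottom layers with the **vertex sort**
  algorithm (SCC condensation + leaf removal on the DAG and its transpose,
  yielding a level interval per node),
- test observed statistics (motif counts, GRC, layer property means) against
  five **degree-constrained randomization null models** (DPR, SDPR, IDPR,
  ODPR, DNPR) plus Erdős–Rényi graphs,
- check layer **robustness** to added/removed edges (Jaccard stability and
  hypergeometric overlap),
- fit discrete **power laws** to degree sequences, and
- predict kinase–substrate edges from **consensus phosphorylation motifs**
  matched to dynamic phosphosites, gated by a gold-standard network.

## The statistics in brief

Local reaching centrality of node *i* is
`C_R(i) = |descendants(i)| / (N − 1)`; the network's hierarchy is
`GRC = Σ_i (max_j C_R(j) − C_R(i)) / (N − 1)` ∈ [0, 1]
(1 = out-star autocracy, 0 = cycle democracy). Vertex sort assigns each
node a bottom-up leaf-removal index `b` on the condensation and `t` on its
transpose; with `D = max b` levels, the reported top-first span is
`[t, D − b + 1]`. The core layer is the largest SCC; top = its ancestors,
bottom = its descendants (path semantics; a direct-arc mode is available).
Layer comparisons use a pooled permutation test (RT) for mean differences
and the hypergeometric tail (HT) for enrichment/depletion and set overlap.

## Worked example

```r
library(kpnet)

bt <- gen_planted_bowtie(planted_spec(10, 6, 10, 2, 25), seed = 42)
bt$network
#> kpnet_network: 53 nodes (22 kinases, 6 phosphatases, 25 other), 120 signed edges

sn <- sort_network(bt$network)
sn$partition
#> kpnet_partition: top=10, core=6, bottom=10, peripheral=2, substrates=25
sn$D
#> [1] 3

grc(bt$network)
#> GRC = 0.5314 over 53 nodes (max C_R = 0.7500)

count_motifs(bt$network)
#> motifs: ffl=17, fbl2=1, bifan=39

empirical_pvalue(bt$network, function(x) grc(x)$grc, "ER",
                 n_reps = 200, seed = 1)
#> empirical p (ER, 200 reps, tail ge): observed=0.5314, null 0.165 +- 0.0646, p=0

layer_regulation_counts(bt$network, sn$partition)
#>    top   core bottom
#>     22     26     18
```

The sort recovered the planted 10/6/10 bow tie exactly (the generator
returns the ground truth in `bt$truth`). The planted network's GRC (0.53)
is far above every one of 200 size-matched Erdős–Rényi graphs (null mean
0.17), hence the empirical p of 0: the network is genuinely hierarchical.
The core, though smallest, regulates the most proteins (26) — the bow-tie
signature. Robustness:

```r
rb <- robustness_suite(bt$network, ks = c(10, 30), reps = 10, seed = 7)
subset(rb$summary, layer == "core")
#>      mode  k layer   jaccard    p_overlap
#> 2     add 10  core 0.7275824 9.768492e-04
#> 5     add 30  core 0.4306385 2.024714e-02
#> 8  delete 10  core 0.8833333 3.204972e-04
#> 11 delete 30  core 0.5666667 2.034704e-01
```

Layer stability (mean Jaccard vs the unperturbed layers) decays as more
edges are perturbed, and deleting edges is gentler than adding them at
matched k — the behaviour expected of a bow tie assembled from
high-confidence interactions.

## Command line

```sh
Rscript -e 'kpnet::kpnet_cli()' sort --edges edges.tsv --nodes nodes.tsv \
    --layers-out layers.tsv --out summary.json
```

Subcommands: `sort`, `grc`, `motifs`, `randomize`, `stats rt|ht|profile`,
`robustness`, `predict`, `simulate bowtie|powerlaw`. The same entry point is
installed as `exec/kpnet`.

## Further reading

The methods vignette (`vignettes/kpnet-methods.Rmd`) documents the model,
the null-model constraint matrix, numerical choices, tie-breaking rules,
what the synthetic generators do and do not emulate, and known limitations.
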