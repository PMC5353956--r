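---
title: "Methods: bow-tie decomposition, null models and layer statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bow-tie decomposition, null models and layer statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kpnet)
```

This vignette is the package's own account of what it computes, the choices
made where the design was genuinely open, and what a green test does and
does not establish. No empirical claim here goes beyond what the test suite
and the acceptance script themselves compute.

## The data model

A network is a set of typed nodes (`kinase`, `phosphatase`, `other`) and a
set of unique signed directed edges `(source, target, itype)`, `itype` being
`P` (phosphorylation) or `D` (dephosphorylation). Sources must be enzymes
in curated inputs; randomized networks relax this deliberately. All
topological computation happens on a *topology view*: unique ordered arcs,
with P/D parallels collapsed to one arc and self-loops dropped. Both choices
are substantive:

- **Sign collapse.** The hierarchy concerns who regulates whom, not how;
  a pair connected by both P and D edges is one regulatory arrow. The sign
  stays available on the owning network for reporting.
- **Self-loop drop.** An autophosphorylation loop would make its node a
  strongly connected component on its own terms and distort the cyclic/
  acyclic distinction the sort depends on; inter-enzyme regulation is what
  the layers describe.

Identifiers are opaque case-sensitive strings; no gene-name normalization is
attempted. Everything iterates in sorted identifier order, so every output
is bit-for-bit reproducible at a fixed seed.

## Vertex sort and layers

The sort condenses each strongly connected component (SCC) into a super
node, then runs leaf removal on the acyclic condensation and on its
transpose. Leaf removal deletes zero-out-degree nodes in rounds; a node's
round index `b` is its bottom-up level and the transpose index `t` its
top-down level. With `D = max(b)` levels, spans are reported top-first
(level 1 = apex): `level_min = t`, `level_max = D − b + 1`. A node whose
span covers several levels is one the data genuinely do not pin down; all
members of one SCC share a span.

Layers: the **core** is the largest SCC. Ties are broken by internal arc
count, then smallest member id — arbitrary but deterministic, and flagged
with a warning when the "largest" SCC is a single node (degenerate bow
tie). **Top** is the core's ancestor set, **bottom** its descendant set,
both under path semantics by default: whether "regulates the core" means a
direct arc or any directed path is ambiguous in the field's usage; path
semantics matches the transcription-network tradition this decomposition
descends from, and `mode = "direct"` is exposed for comparison. The
remaining sorted enzymes are **peripheral**; enzymes with no arcs in the
enzyme subgraph (isolated enzymes) join the non-enzyme nodes in the
**substrates** layer and never enter the sort.

Global reaching centrality is computed on the full network (enzymes plus
substrates, self-loops dropped) by default, with
`C_R(i) = |descendants(i)|/(N−1)` and
`GRC = Σ(max C_R − C_R)/(N−1)`. The enzyme subgraph variant is one call
away (`grc(enzyme_subgraph(net))`); defaulting to the full network reflects
that hierarchy is a whole-network property, measured before the enzyme-only
sort is introduced.

## Null models

Five randomization schemes plus Erdős–Rényi, with a fixed constraint
matrix that the suite checks on every generated replicate:

| scheme | in-degrees | out-degrees | arc count | node set |
|--------|-----------|-------------|-----------|----------|
| DPR    | exact     | exact       | exact     | same     |
| SDPR   | ±1        | ±1          | ± n_nodes | same     |
| IDPR   | exact     | free        | exact     | same     |
| ODPR   | free      | exact       | exact     | same     |
| DNPR   | free      | free        | exact     | same     |
| ER     | free      | free        | exact     | same     |

No generated network contains self-loops or duplicate arcs.

**DPR** exchanges the ends of two random arcs, `n_swaps` (default 10,000)
accepted times. A proposal that would create a self-loop or duplicate arc is
*rejected* rather than patched afterwards: the observable contract is
identical, the implementation is simpler, and rejection keeps the chain
closer to uniform on the constraint set. The swap budget is read as
accepted swaps, exposed as a parameter.

**SDPR** draws each node's target in- and out-degree uniformly from
`{d, d+1, max(d−1, 0)}`, nudges the drawn in-sequence until the stub totals
balance (each entry staying within ±1 of the original), then pairs stubs
with selection probability proportional to the *square* of each node's
remaining stubs; dead-end pairings restart the pairing phase, and the
result is DPR-switched. Realized degrees equal the drawn ones, hence within
±1 everywhere.

**IDPR/ODPR** keep one column of the edge table and resample the other with
replacement — sources from the enzyme set (the source column of a
phosphorylation edge list *is* an enzyme list), targets from all nodes.
Duplicates and self-loops created by resampling are resolved by end
exchanges with random partner arcs, which leave both column multisets
intact, and the result is DPR-switched. Both pools are arguments.

**DNPR/ER** ignore degrees entirely; DNPR resamples endpoints with
replacement until the arc count is met, ER draws the arc set uniformly
without replacement. Sources are unrestricted by default (`sources =`
restores enzyme-only realism).

Empirical p-values are plain fractions,
`p = #{null ≥ observed}/n_reps` (or ≤), with the null mean, SD and central
quantiles reported alongside; replicate seeds derive deterministically from
the base seed.

## Layer statistics

The **randomization test** (RT) pools two groups, redraws groups of the
original sizes without replacement, and counts resampled mean differences
at least as extreme as the observed one. The default alternative follows
the *direction of the observed difference* and is recorded in the output:
layer claims in this literature are directional, but the direction is not
known before looking. Pools whose split count is at most 5,000 are
enumerated exhaustively (exact permutation p); missing values are dropped
per test, and a group emptied by missingness is an error naming the group.

The **hypergeometric test** (HT) is the exact tail,
`P(X ≥ k)` for enrichment and `P(X ≤ k)` for depletion. The enrichment
universe is the caller's choice (the natural default in the bow-tie setting
is the sorted enzymes: top ∪ core ∪ bottom). No multiple-testing correction
is applied anywhere — single raw p-values are what the downstream
interpretation consumes; correct externally if you run families of tests.

**Layer profiles** randomize the network under a scheme, re-sort each
replicate, and average a property per layer, reporting the across-replicate
mean with a percentile 95% CI next to the observed layer means. Degree-type
properties (`"in_degree"`, `"out_degree"`) follow the replicate's own
topology; biological properties follow the node id. A flat DNPR profile is
the signature of a property the sorting algorithm itself does not impose —
the device used to argue that layer differences in biological properties
are not sorting artefacts.

**Robustness** perturbs the signed edge list (delete k rows uniformly; add
k arcs with enzyme sources and any-node targets, no duplicates or
self-loops), re-sorts, and scores each layer by Jaccard similarity plus an
HT overlap p whose universe is the sorted enzymes present in both
partitions (restricting both layer sets to that universe keeps the HT
configuration feasible by construction). Deletion draws from the signed
edge list, not the collapsed arcs, matching the scale on which perturbation
sizes are stated for such data.

## Power-law fitting

Degrees are fitted by the Clauset-style recipe: exact discrete (zeta)
maximum likelihood for the exponent — the Hurwitz zeta evaluated by a
2,000-term sum with an Euler–Maclaurin tail, optimized numerically on
(1.01, 8) — with the lower cut-off chosen by KS-distance minimization over
candidate cut-offs retaining at least 5 tail points and at most the 99th
percentile. `gof_p` is a semi-parametric KS bootstrap (tail from the fitted
law, head resampled from the data below the cut-off, refit per replicate).

A measured limitation: with the cut-off free, the bootstrap has essentially
no power against geometric (exponential-tail) data — the KS search retreats
into a late tail window that a power law fits locally, and `gof_p` lands
anywhere between 0.3 and 0.8 for samples of 800–2,000. The suite therefore
demonstrates rejection of a geometric sample with the cut-off pinned at 1;
treat a high `gof_p` at a large fitted cut-off with corresponding caution.
The default bootstrap size (100; 200 in the test) trades precision for
runtime and is a parameter.

## Motif prediction

Consensus motifs are position-specific allowed-residue sets parsed from
dash notation (`R-x-x-S/T`); `x` positions impose no constraint, and the
acceptor (offset 0) is the *first* token whose residues all lie in
{S, T, Y}. Offsets that fall outside the protein sequence fail the match
(boundary-fail convention — a site too close to a terminus cannot exhibit
the motif). A kinase with several motifs matches if any does. Predictions
are the motif hits on dynamic phosphosites intersected with the
gold-standard network's arcs, so predicted edges are a subset of the gold
network by construction.

## Synthetic generators: what they emulate

`gen_planted_bowtie()` builds a known-truth bow tie: the core on a directed
Hamiltonian cycle (strong connectivity guaranteed) with random extra
internal arcs; deterministic base attachments (top *i* → core
`((i−1) mod n_core)+1`, and symmetrically for bottom and peripheral) plus
probabilistic extras. With all probabilities zero the construction is fully
deterministic. Defaults (10/6/10 enzymes + 2 peripheral + 25 substrates,
block densities 0.10–0.30) give networks of roughly 50 nodes and 120 edges
— dense enough that layers are identifiable, sparse enough that
perturbation tests have room to destabilize them, and the same order of
sparsity as curated signalling networks. The generator does *not* emulate a
real network's joint degree distribution, its sign composition, or its
incompleteness; a recovered planted partition therefore establishes
correctness of the classification logic, not power on real data.

`gen_powerlaw_network()` draws out-degrees from a zeta law (truncated at
n−1) with uniform targets — a degree-sequence testbed, not a growth model.
`gen_layer_properties()` draws Gaussian per-layer values with a missingness
mask. Real biological properties are skewed; the RT is distribution-free
under exchangeability, which is exactly what the uniformity test checks, so
Gaussianity is a convenience, not an assumption being validated.

## Numerical and degenerate-input conventions

- Ties at the hub/bottleneck cut (`select_top_fraction`, size
  `⌊fraction·n⌋`) break by smaller id; all-equal scores select the first
  `⌊fraction·n⌋` ids.
- Permutation p-values compare with a relative `1e−12` epsilon so float
  noise in tied differences cannot flip a count.
- Leaf removal on cyclic input, empty networks, empty reachability seeds,
  infeasible hypergeometric configurations, constant degree sequences and
  negative SDs are errors with typed condition classes
  (`kpnet_*_error`), not silent results.
- An empty layer in a stability comparison records Jaccard 0 with a
  warning rather than erroring, so robustness sweeps survive degenerate
  replicates; replicates whose re-sort fails entirely score 0 across
  layers.
- RNG discipline: every stochastic function takes a `seed` and restores the
  caller's RNG state; replicate seeds derive as
  `(seed·48271 + index·8191) mod (2^31 − 61)`, keeping all derived seeds in
  32-bit integer range.

## Known limitations

- The published KP-Net numbers (1,087 edges / 616 proteins, 9 levels,
  19/38/36 layers, GRC 0.61, regulation counts 235/276/148) are asserted by
  the acceptance tests but require the originally published supplementary
  interaction table, which cannot be shipped; those five tests fail with an
  explanatory message until the table is exported to
  `inst/extdata/kpnet_edges.tsv` / `kpnet_nodes.tsv`.
- Edge-swap randomization uses a fixed swap budget with no mixing
  diagnostics; for very sparse or rigid graphs the rejection rate is the
  only signal (a budget overrun raises `kpnet_rigid_error`).
- The gof bootstrap's low power against exponential tails at a free
  cut-off, above.
- Motif matching is boolean; no position weight matrices, no scoring.
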