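---
title: "Methods: interactome community topology, bridgeness and disease separation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interactome community topology, bridgeness and disease separation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bridgenet)
```

## The analysis in one paragraph

Given a bait protein's interactor list and curated protein–protein
interaction (PPI) data, `bridgenet` builds the induced network over the
list, keeps its largest connected component (LCC), partitions it into
communities with several published algorithms, and asks three questions of
the topology: *which proteins bridge between complexes* (bootstrap
community memberships → bridgeness → influence regions), *what each
complex does* (per-community hypergeometric enrichment with a permutation
strength test), and *how disease gene sets are arranged on the network*
(the separation statistic $S_{AB}$ with a randomized null). A final module
compares two interactomes of the same bait obtained in different
biological contexts.

## Network construction

Interaction records are filtered to a user-supplied allow-list of
interaction-type tokens before the network is built. The shipped default,
`direct_physical_types()`, accepts PSI-MI `MI:0407` (direct interaction)
and `MI:0915` (physical association) and excludes `MI:0914` (association),
which also covers co-complex inference. This is an informed curation
choice, not a community standard — interactome papers invoke the concept
of "direct and physical" without enumerating terms, and different term
sets will change the edge count, so the list is a visible, overridable
parameter rather than a constant buried in code.

Gene symbols are uppercased on ingest and compared case-insensitively;
cross-species merging by symbol (mouse/human) is deliberately left to the
caller via their own mapping, keeping the core species-agnostic.
Self-loops are dropped, duplicate unordered pairs collapsed (first source
retained, count reported), and listed proteins without any retained
interaction remain as isolated nodes until the LCC reduction removes them.
Ties in LCC size are broken toward the component containing the
lexicographically smallest symbol, so the reduction is deterministic. All
distances everywhere in the package are unweighted hop counts.

## Semi-local centrality

For a node $w$, $N(w)$ counts the nodes within graph distance 2
(neighbours and next-to-nearest neighbours). Then

$$Q(u) = \sum_{w \in \Gamma(u)} N(w), \qquad
  Cl(v) = \sum_{u \in \Gamma(v)} Q(u),$$

a two-level aggregation that rewards nodes whose neighbourhood is itself
well-connected, at a fraction of the cost of betweenness. Raw values are
unity-normalized, $(Cl - \min)/(\max - \min)$. On a vertex-transitive graph
(every node equivalent, e.g. a star's leaves plus hub all score 16) the
normalization is undefined; we assign 0.5 everywhere rather than 0 or 1,
so that a degenerate graph does not force all nodes into an extreme
influence quadrant. The implementation is two sparse matrix–vector
products; the test suite checks it against a brute-force BFS oracle on 100
random graphs.

## Bootstrap memberships and bridgeness

Hard partitions come from igraph's walktrap, spinglass, leading-eigenvector
("spectral") and infomap implementations — published algorithms are
delegated, not re-implemented. A mixed-membership stochastic blockmodel
backend is recognized by name but reported unavailable (no R
implementation exists in the supported dependency set); averaging simply
runs over the remaining algorithms.

The membership probability $u_{jv}$ of node $v$ in community $j$ is
estimated by a bootstrap: the reference partition is detected once, then
each replicate resamples the edge multiset with replacement (duplicates
collapsed — on average ~63% of edges survive), keeps the LCC of the
perturbed graph, re-detects communities, aligns the replicate's labels to
the reference by greedy maximum-overlap matching (largest intersection
first, ties toward the smaller reference id, unmatched communities get
fresh ids), and increments per-node counts. Rows are normalized by the
number of replicates in which the node survived. Two readings of
"bootstrap" are defensible here; the alternative — keep the graph fixed
and only reseed the stochastic algorithm (`resample = FALSE`) — is also
exposed, and with a deterministic algorithm it degenerates to the one-hot
reference rows, which is the documented behaviour rather than an error.
Edge resampling is the default because it perturbs the data, not merely
the optimizer, and therefore also yields non-trivial memberships for
deterministic algorithms. It is aggressive on small graphs: modularity
optimizers occasionally split a clique that has lost a third of its edges,
so membership rows from walktrap/spinglass on toy graphs are slightly
diffuse (~0.9 max entry) where infomap's are clean; on the planted
benchmarks below, all algorithms rank planted bridges correctly.

Per-algorithm bridgeness is

$$Ba(v) = 1 - \sqrt{\frac{c}{c-1} \sum_{j=1}^{c}
  \left(u_{jv} - \frac{1}{c}\right)^2},$$

the complement of the scaled Euclidean distance of the membership row from
the uniform vector: 0 for a one-hot row, 1 for a perfectly shared node.
The square root is part of the definition — it is the only reading under
which the uniform row attains exactly 1 with the $c/(c-1)$ normalizing
constant (sources typesetting this formula often lose the radical); a
`sqrt = FALSE` switch reproduces the radical-free variant for comparison.
The consensus score $Br(v)$ is the arithmetic mean of $Ba(v)$ over the
configured algorithm set (default: spinglass, spectral, infomap; walktrap
participates in clustering and the consensus partition but not in the
$Br$ average, whose reference set is the stochastic algorithms).

### Influence regions

The $(Cl, Br)$ unit square is split at $Cl = 0.5$ and $Br = 0.5$, with a
secondary line at $Br = 0.1$:

| Region | Bounds | Reading |
|---|---|---|
| R1 | $Cl < 0.5,\ Br \ge 0.5$ | global bridges (bottleneck / kinless) |
| R2 | $Cl \ge 0.5,\ Br \ge 0.5$ | mixed global + local influence |
| R3 | $Cl < 0.5,\ 0.1 \le Br < 0.5$ | hubs within one or two communities |
| R4 | remainder | locally confined influence |

Published descriptions of these quadrants use closed intervals that
overlap at the boundaries; we resolve every boundary half-open with the
point going to the high side, and assign low-$Cl$ nodes with $Br < 0.1$ to
R4 (they are described as having bridgeness "too small to have any
effect"). The classification is therefore total and disjoint — a property
test sweeps the unit square. "Bridging proteins" are R1 ∪ R2.

## Consensus partition

The consensus of several hard partitions links every node pair
co-classified in a strict majority (frequency > 0.5) of the inputs and
takes connected components of that majority graph. Strict inequality
matters: with an even number of partitions, a 50/50 pair would otherwise
chain-merge unrelated communities through tie edges.

## Enrichment and the permutation strength test

Over-representation of a term annotating $M$ of $N$ background genes, in a
community of $n$ genes containing $k$ annotated ones, is the
hypergeometric upper tail

$$p = 1 - \sum_{i=0}^{k-1}
  \frac{\binom{M}{i}\binom{N-M}{n-i}}{\binom{N}{n}},$$

evaluated through the log-space tail of `phyper`, so magnitudes like
$10^{-22}$ are computed exactly rather than through a subtraction from 1.
The Bonferroni family is all (community, term) pairs with $k \ge 1$ tested
in the call — the family is a reporting choice and is stated here because
published tables rarely state theirs. Benjamini–Yekutieli values are
reported alongside; stars follow Bonferroni at 0.05/0.01/0.001.

The strength-of-significance test re-draws the term's $M$ labels uniformly
over the background (a label permutation restricted to the tested term),
recomputes $p$, and reports the percentage of permuted p-values $\le$ the
observed one, ties inclusive; values below 1% are the conventional call.
Because label permutation *is* the hypergeometric null, the strength
converges to $100 \cdot p$ — the suite exploits this as an exact oracle at
2000 permutations. Permutation over the full background is the default;
`within =` restricts the shuffle to network nodes for the stricter
conditional null.

## Disease-module separation

For disease gene sets $A, B$ mapped onto the LCC (unmapped genes dropped
with a count; sets with fewer than two mapped genes skipped with a
warning):

- $d_{AA}$ — mean distance of each gene of $A$ to its nearest *other*
  gene of $A$;
- $d_{AB}$ — mean, over all $|A|+|B|$ genes, of the distance to the
  nearest gene of the other set (shared genes contribute 0);
- $S_{AB} = d_{AB} - (d_{AA} + d_{BB})/2$.

Identical sets give $S_{AB} = -d_{AA} < 0$; $|S_{AB}|$ is bounded by the
network diameter (asserted per pair). The one-line verbal definition of
$d_{AB}$ admits several readings; the symmetric nearest-neighbour mean
implemented here is the form of the network-medicine separation measure
this statistic descends from. The null model redraws both sets uniformly
without replacement from the network nodes (same sizes), 1000 iterations
by default; the z-score uses the null sample's mean and SD, the p-value is
two-sided normal, and pairs with $S_{AB} < -3$ or $S_{AB} > 0.1$ are
flagged "of interest" (these published thresholds are asymmetric by
construction: large negative separations mean nested/duplicated disease
annotations, while even small positive ones are unusual on a dense LCC).

## Interactome comparison

The shared-gene test treats one list as the annotation ($M$), the other as
the draw ($n$), over a genome-size background — exactly symmetric in the
two lists. At the published margins (lists of 373 and 351, overlap 39,
genome 24,402) the package computes $P = 3.0 \times 10^{-22}$; the
corresponding published figure is $2.68 \times 10^{-22}$, the same
magnitude — the printed value is not exactly recoverable from the printed
margins, and order-of-magnitude agreement is the acceptance standard.
Community-pair overlap between two partitions uses the same tail with the
background defaulting to the union of the two node sets; that default is a
self-contained choice, so published per-pair p-values obtained against
undisclosed backgrounds are not promised reproductions.

## Synthetic benchmarks: what they establish

The generators state a fixed world mirroring the scale of a bait
interactome analysis: planted-partition graphs of $n = 60$ nodes in 3
blocks with $p_{in} = 0.5$, $p_{out} = 0.01$ (within-block degree ~10,
sparse between-block noise — chosen so that block recovery is achievable
but not trivial, and small enough that 10–20 seeded replicates run in
seconds); bridge nodes wired with 5 edges into each of 2 communities;
annotation terms covering 80% of their target community and 5% of the rest
of a 150-gene background; disease sets of 8–10 genes per community. Real
PPI LCCs differ in ways the benchmarks do not emulate: heavy-tailed degree
distributions, disassortative mixing, community sizes spanning two orders
of magnitude, and annotation terms correlated with degree. A green
recovery suite therefore establishes that the estimators recover planted
structure under clean modular topology — not that any particular biological
claim is correct.

## Numerical conventions

- PageRank damping 0.85; betweenness unnormalized pair counts; closeness
  normalized to $(0,1]$; all igraph defaults otherwise.
- Degenerate unity normalization (all equal) → 0.5 for every node.
- Membership rows sum to 1 within $10^{-9}$; bridgeness clamps tiny
  negative radicands from floating-point noise to $[0,1]$.
- TSV outputs carry 6 significant digits; the network JSON (sorted nodes,
  sorted edge pairs) is byte-stable across reruns and is the
  reproducibility anchor.
- Every stochastic stage takes an explicit seed; `run_pipeline()` refuses
  to run without one and logs all seeds, versions and parameters.

## Known limitations

- No mixed-membership SBM backend; the algorithm set is the four igraph
  implementations.
- Plain flat-GMT hypergeometric enrichment only: no ontology DAG
  traversal, no topology-aware elimination variants, no live database
  queries.
- Symbol-level matching only when comparing interactomes; orthology is out
  of scope.
- The bootstrap membership procedure is one defensible reading of a
  sparsely documented practice; both it and the reseed-only variant are
  exposed precisely because the choice affects absolute $Br$ values
  (ranking is robust across the two in the benchmarks).
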