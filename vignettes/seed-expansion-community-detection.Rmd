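---
title: "Seed-expanding community detection with personalized random walks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-expanding community detection with personalized random walks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwacd)
```

## The problem

Communities are subsets of nodes more densely linked internally than to
the rest of the network. Two topological grades are useful: a community
is **strong** when every member has more neighbors inside it than inside
any other single community, and **weak** when its total internal degree
exceeds its edge count to each other community. A network whose
ground-truth communities are all strong has a *clear* structure; when some
are merely weak the structure is *ambiguous*, and modularity-driven
detectors often absorb or split those weak communities. `rwacd`
implements a seed-and-grow detector built for that regime, together with
the benchmark generators and metrics needed to validate it without any
external data.

## The model

### Structural similarity and the walk

All randomness of the walk is driven by a structural node similarity.
With `G[x]` the *closed* neighborhood of `x` (the node plus its
neighbors), the default is the closed Jaccard index

$$\mathrm{Similar}(u, v) \;=\; \frac{|\,\Gamma[u] \cap \Gamma[v]\,|}
                                    {|\,\Gamma[u] \cup \Gamma[v]\,|},$$

and a closed-cosine variant
$|\Gamma[u]\cap\Gamma[v]|/\sqrt{|\Gamma[u]||\Gamma[v]|}$ is selectable via
`similarity_config("closed_cosine")`. The body of the similarity formula
is typographically lost in the method's source description; only "the
neighborhood of $v_i$ ($v_j$)" and set cardinality survive. We therefore
use closed neighborhoods — under which adjacent nodes always have
positive similarity, so the walk can move along every edge — and document
the default as our choice rather than assert it as the original one.

Over an ordered node set $V = \{v_1,\dots,v_m\}$ the transition matrix
$M$ row-normalizes the off-diagonal similarities; the diagonal is zero
(self-transitions would only slow convergence), and a row with no
positive off-diagonal similarity falls back to the uniform distribution
over the other indices so $M$ stays stochastic (no absorbing dead
states).

A personalized walk with teleport probability $\alpha$ and restart
distribution $d$ iterates

$$s_{t+1} = (1-\alpha)\, M^{\mathsf T} s_t + \alpha\, d$$

to its stationary distribution $\pi = (1-\alpha) M^{\mathsf T}\pi +
\alpha d$. The map contracts at rate $1-\alpha$ in $L^1$, so the fixed
point is unique and independent of the start $s_0$; `rwacd` exposes the
iterative operation (`stationary_distribution()`, with an explicit error
if `max_iter` is exhausted) and uses the algebraically identical direct
solve $\pi = \alpha (I - (1-\alpha) M^{\mathsf T})^{-1} d$ on the
expansion hot path, where one factorization serves all $q$ restart
vectors. The test suite asserts the two routes agree to $10^{-8}$ on
random instances.

### Seeding

Hubs are *local maximal degree nodes*. Two readings are implemented:

* `strict_max` — degree at least that of every neighbor (ties admit the
  node);
* `neighborhood_mean` — degree at least the mean degree of the
  neighbors.

Both agree on the canonical examples (a star's center, the middle of a
3-path, all corners of a triangle). On graphs with broad degree
distributions, however, the strict rule starves the pipeline: a single
higher-degree node in an *adjacent* community disqualifies every local
candidate, and measured on LFR benchmarks (ours and the reference
generator's) it leaves most planted communities without any hub — no
hub-seeded method could then recover them. The pipeline therefore
defaults to `neighborhood_mean` (`seed_params()`); the strict variant
remains available and is the default of the standalone
`local_maximal_degree_nodes()` operation.

Around each hub `n1`, the partner `n2` is its highest-degree neighbor
that closes at least one triangle with it, and every common neighbor `n3`
yields a candidate triple. Requiring the triangle matters: the raw
highest-degree neighbor of a bridge endpoint is the *other* bridge
endpoint, which shares no neighbor and would silently discard the
community's own triples. For `Z > 3` the triple is grown greedily by the
common neighbor adding the most internal edges (ties lexicographic).

Raw triples are heavily redundant — one per common neighbor — so
`consolidate_seeds()` unions them per anchor and admits the resulting
blobs in decreasing hub-degree order only when node-disjoint from all
previously admitted seeds. This keeps at most one seed per dense region
(and at most one per hub, matching the method's stated seed count bound)
while guaranteeing that disjoint regions keep their own seed. Components
without any triangle fall back to their top-degree node plus its top
`Z − 1` neighbors, so every component is seeded. We experimented with
consolidating triples by the ξ overlap rule instead; cascaded merging of
3-node sets creeps across planted communities through occasional
cross-community triangles and was rejected on measurement.

### Expansion by total probability

With current communities $Y_1,\dots,Y_q$ and their pooled member set $V$,
a frontier node $u$ (unassigned, adjacent to at least one community) is
scored by $q$ hypothesis walks. Under hypothesis $k$ the walker restarts
uniformly on $Y_k$ — the construction of the per-hypothesis graph is
garbled in the source; walking always on $V$ with the hypothesis entering
only through the restart vector is the minimal reading that
differentiates the $q$ runs, and it is what `rwacd` implements
(documented as a decision, not as the original authors' code). The
stationary distribution is averaged over each community's members,

$$PC(k, j) = \operatorname{avg}_{v \in Y_j} \pi^{(k)}_v,$$

rows normalized to sum to one ($PC$ is $q \times q$; the source's
bookkeeping declares it $m \times q$ but then multiplies it against the
length-$q$ prior, which only makes sense for $q \times q$). The prior

$$PP(k) \propto \operatorname{avg}_{v \in Y_k} \mathrm{Similar}(u, v)$$

normalizes to one (uniform fallback when all similarities vanish), and

$$p(u \to Y_j) = \sum_k PC(k, j)\, PP(k).$$

Each expansion iteration commits the single globally largest
$p(u \to Y_j)$ over all frontier nodes; ties break by larger tightness,
then node label, then lower community index, making the whole pipeline
deterministic. Since $PC$ depends only on $(V, M, Y)$ and not on $u$, it
is computed once per iteration and shared across the frontier.

### Refinement

* `assign_leftovers()` — nodes the expansion never reached (no edge into
  any community) join the community maximizing the tightness
  $T(u, Y_k) = \text{(members adjacent to } u)/|Y_k|$, processed in
  increasing degree order; a node with zero tightness everywhere starts
  its own singleton community (disconnected fragments are legitimate
  communities, not errors).
* `merge_communities()` — while any pair satisfies
  $|C_i \cap C_j| / \min(|C_i|, |C_j|) \ge \xi$ (default $\xi = 0.5$:
  most members of the smaller community already sit in the larger), the
  pair with the largest coefficient merges; the count strictly decreases,
  so the loop terminates and is idempotent at its fixpoint. The
  left-hand side of the original merge inequality is unreadable in the
  source; the overlap coefficient is the form matching its gloss.
* `finalize_partition()` — any node still shared keeps the community it
  is tightest to (computed without the node itself; ties to the lowest
  index); indices are renumbered contiguously.

Order of refinement steps: leftovers, then merging, then overlap
resolution. The source is ambiguous between its two optimization
paragraphs; merging after leftover assignment consolidates duplicate
seed-grown communities regardless of where the leftovers landed, and the
alternative order is exposed as `run_rwa(merge_before_leftovers = TRUE)`.

## Parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| `alpha` | teleport probability per step | 0.15 | customary restart rate; the stated value |
| `Z` | seed size (complete subgraph) | 3 | stated optimum; `Z < 3` carries no community signal |
| `xi` | merge threshold on the overlap coefficient | 0.5 | stated value ("most members") |
| `tol` | $L^1$ convergence threshold of the walk | 1e-10 | contraction at $0.85$ reaches it in ~140 iterations |
| `max_iter` | iteration cap | 1000 | ample for the method's target sizes (hundreds of nodes) |
| similarity | closed Jaccard / closed cosine | Jaccard | see above |
| hub rule | strict max / neighborhood mean | mean (pipeline) | see above |

## The synthetic benchmarks

`generate_gn()` builds the classic four-group planted partition: 128
nodes randomly split into four groups of 32, expected degree 16. The
stated construction gives each within-community pair an edge with
probability $P_{in}$, but read literally that contradicts the fixed
average degree for $P_{in} > 0.52$ (expected internal degree $31 P_{in}$
alone would exceed 16). `rwacd` therefore treats $P_{in}$ as the
expected *fraction* of a node's 16 edges that stay internal —
$p_\text{within} = 16 P_{in}/31$, $p_\text{between} = 16(1-P_{in})/96$ —
which preserves mean degree 16 for every $P_{in}$ and reproduces the
known detectability behavior (structure undetectable below
$P_{in} \approx 0.4$, all-strong communities at $P_{in} \ge 0.8$). The
literal reading is available via `gn_spec(semantics = "probability")`.

`generate_lfr()` draws degrees from a truncated continuous power law
(exponent 2 by default) calibrated so the mean matches `d`, community
sizes from a truncated power law (exponent 1) tiled exactly to `N`, and
wires `round((1-mu)·k)` internal and the remaining external stubs by
repeated stub matching that rejects loops, duplicate edges and
same-community external pairs. One feasibility condition is enforced: a
node with $\mathrm{round}((1-\mu)k) > Maxc - 1$ could not place its
internal edges inside any admissible community, so the degree support is
truncated at $(Maxc - 0.5)/(1-\mu)$ *before* calibration. The reference
LFR implementation enforces the same constraint by rejection (at the
parameters used throughout — $N = 200$, $Maxd = 50$, $Maxc = 20$,
$\mu = 0.2$ — it aborts for most seeds, and its successful draws top out
at degree ≈ 24). Without the truncation roughly a tenth of the nodes
carry an unrealizable mixing target and double as community-spanning
mega-hubs, which no hub-seeded detector can interpret.

What the generators do *not* emulate: degree correlations, weighted or
overlapping communities, hierarchical structure, and the exact discrete
degree sampling of the reference LFR code (we sample a continuous law
and round). Realized LFR degrees are bounded above by the drawn sequence
(stub rejection can only lose stubs), so `Maxd` is always respected, and
the realized mixing is within a few hundredths of `mu` — both asserted
in the suite. A green benchmark test therefore establishes recovery on
*idealized* planted partitions, not on real-world networks; the bundled
karate-club fixture provides the one real-data check (its two observed
factions classify as 0 strong / 2 weak communities).

## Numerical choices and degenerate inputs

* Walk vectors are validated to be probability vectors within $10^{-9}$;
  the direct solve clamps round-off negatives at zero and renormalizes.
* All node ordering uses byte-wise (`radix`) sorting, so results are
  locale-independent; all tie-breaks are documented and deterministic.
* Probability ties during expansion use a $10^{-12}$ tolerance before the
  tightness / label / index cascade.
* A single-node network is its own partition; a single-node walk matrix
  is rejected (no off-diagonal mass); empty graphs and empty communities
  raise errors rather than guessing.
* Disconnected graphs are handled end to end: every component gets at
  least a fallback seed, and unreachable leftovers become singleton
  communities.

## Evaluation machinery

`nmi()` is the confusion-matrix normalized mutual information
($-2\sum_{ij} X_{ij}\log\frac{X_{ij}N}{X_{i.}X_{.j}}$ over the marginal
entropies); the source calls $X$ a $2\times 2$ matrix, which cannot hold
for its own four- and twelve-community benchmarks, so the general
$R \times F$ form is used. "Completely opposite" partitions are
operationalized as zero mutual information — e.g. the all-in-one
partition — the only reading under which the printed value 0 is
attainable. `f1_report()` matches each reference community to the found
community maximizing $F1 = 2pr/(p+r)$ and averages unweighted over
reference communities (the aggregation is unstated in the source; the
unweighted mean is the simplest symmetric choice).
`classify_communities()` offers the per-rest-community strong/weak
definitions quoted above (default) and the classical inside-vs-outside
variant, under which strong provably implies weak.

## Known limitations

* Dense matrices throughout: the expansion solves an $m \times m$ system
  per committed node, so the practical range is a few thousand nodes;
  million-node scalability is out of scope.
* Exactly one node is committed per expansion iteration and the whole
  frontier is re-scored afterwards; batching would be faster but changes
  results.
* The final partition is disjoint by construction; overlapping output is
  not supported.
* On benchmarks in the ambiguous regime (GN $0.4 \le P_{in} < 0.8$,
  LFR $\mu \ge 0.3$) recovery degrades gracefully but seeds may fragment
  or fuse; only the clear-structure regimes are covered by acceptance
  tests.
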