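# rwacd — seed-expanding community detection via personalized random walks

`rwacd` detects communities in undirected simple networks, and is aimed in
particular at networks with *ambiguous* community structure: networks in
which some ground-truth communities are only **weak** (their total internal
degree exceeds their edge count to each other community) rather than
**strong** (every member has more neighbors inside its community than in
any other single community). Modularity-style methods tend to miss weak
communities; growing communities outward from dense hub-centered seeds
with restart random walks recovers them more reliably.

## The method

Given a graph `G = (V, E)`:

1. **Seeding.** Local maximal degree nodes (hubs) are located; around each
   hub `n1`, a dense triple `{n1, n2, n3}` is formed with its top
   triangle-forming neighbor `n2` and each common neighbor `n3`
   (seeds of size `Z > 3` are grown greedily; the default `Z = 3`).
   Triples are consolidated into at most one disjoint seed per dense
   region.
2. **Expansion.** For a candidate node `u` adjacent to the current
   communities `Y_1 … Y_q`, one personalized random walk per hypothesis
   "`u` belongs to `Y_k`" is run over the pooled member set `V` with
   transition matrix `M` (row-normalized structural similarity, default
   Jaccard over closed neighborhoods) and restart vector `d_k` uniform on
   `Y_k`:

   `s_{t+1} = (1 − α) Mᵀ s_t + α d_k`,  α = 0.15.

   The stationary distribution π is averaged per community into the
   conditional matrix `PC(k, j) = p(u → Y_j | u ∈ G_k)`; a
   similarity-based prior `PP(k) = p(u ∈ G_k)` combines the hypotheses by
   total probability, `p(u → Y_j) = Σ_k PC(k, j) · PP(k)`. The single
   globally best `(u, Y_j)` pair is committed per iteration.
3. **Refinement.** Leftover low-degree nodes join the community with the
   largest *tightness* (fraction of members adjacent to the node);
   communities whose overlap coefficient `|C_i ∩ C_j| / min(|C_i|, |C_j|)`
   reaches `ξ = 0.5` are merged; remaining overlaps resolve by tightness
   into a total disjoint partition.

The package also ships the two standard planted-partition benchmark
generators used to validate such detectors — the 128-node / four-community
GN benchmark (average degree 16, internal-edge fraction `P_in`) and an LFR
generator (power-law degrees and community sizes, mixing parameter `μ`) —
plus the evaluation stack: confusion-matrix NMI, best-match
precision/recall/F1, and a strong/weak community classifier.

## Worked example

```r
library(rwacd)

## two 4-cliques joined by a single edge
cl  <- function(p, n) t(combn(paste0(p, seq_len(n)), 2))
net <- network(rbind(cl("a", 4), cl("b", 4), c("a1", "b1")))
run_rwa(net)
#> a1 a2 a3 a4 b1 b2 b3 b4
#>  1  1  1  1  2  2  2  2

## GN benchmark with a clear structure (P_in = 0.9)
gn    <- generate_gn(gn_spec(p_in = 0.9, rng_seed = 1))
found <- run_rwa(gn$network)
table(found)
#>  1  2  3  4
#> 32 33 31 32
nmi(gn$partition, found)
#> [1] 0.9748319
f1_report(gn$partition, found)$overall_f1
#> [1] 0.9921856
classify_communities(gn$network, found)
#>        1        2        3        4
#> "strong"   "weak" "strong" "strong"
```

The pipeline recovers the four planted groups of 32 almost exactly (one
node misassigned; NMI 0.975, mean best-match F1 0.992), and the
strong/weak classifier labels the recovered communities.

## Command line

```sh
Rscript -e 'rwacd::rwa_main()' generate  --benchmark gn --p-in 0.9 --seed 1 --output bench
Rscript -e 'rwacd::rwa_main()' detect    --input bench.edgelist --output run
Rscript -e 'rwacd::rwa_main()' evaluate  --input bench.edgelist \
    --reference bench.membership.tsv --found run.membership.tsv --output metrics.json
Rscript -e 'rwacd::rwa_main()' benchmark --benchmark lfr --mu 0.2 --reps 30 --output results.csv
```

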