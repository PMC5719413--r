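# recallnet

Simulation tools for studying how people reconstruct a small signed social
network — who is tied to whom, and whether each tie is liking or
disliking — from memory.

People do not memorise a social network tie by tie. They appear to store a
small set of ties exactly and regenerate the rest with *compression
heuristics*: schemata such as triadic closure ("my friends' friends are
probably connected") and structural balance ("I like those my friends
like"). `recallnet` implements a mechanistic model of this process for the
classic laboratory setting in which participants study a vignette
describing 15 characters joined by 23 signed ties, split over two
disconnected components, and later reconstruct the network from memory.

## The model

Let the target network have `n` nodes, `|E|` edges, `T` connected triplets
(2-paths) and `T_closed` closed connected triplets. A recall replicate:

1. **Seeding.** All ties incident to a chosen set of seed characters are
   recalled exactly.
2. **Structural pass.** Every still-unconnected pair of characters is
   visited once in random order. A pair that would close at least one
   triangle in the current recalled graph gains a tie with probability

   `P_triangle = T_closed / T`

   (the target's global clustering coefficient under the default census);
   any other pair gains a tie with the density-derived background
   probability

   `P = (|E| - T_closed) / ((n(n-1)/2) * T)`.

   Both probabilities use the *target* network's census throughout.
3. **Affective pass.** Seed ties take their true valences, except that a
   fraction `x` (default 0.30) is remembered with a random valence.
   Each heuristically added tie takes the sign of the mean sign product of
   the open triplets it closes (structural balance), or `+1` if it closes
   none (positivity bias).

Recalled networks are scored against the target by **precision** (correct
ties / recalled ties), **coverage** (correct ties / target ties) and
**quality** (correct valences / correctly recalled ties); model and
experimental summaries are compared with the standardised deviation
`delta = |mean_model - mean_exp| / sd_exp`.

The package also ships a constrained generator for the stimulus network
itself (exact hub degrees, non-adjacency of the catalogued seed
characters, two components, balanced or imbalanced valence
configurations), the 35-row catalogue of tested seed sets, and
reproducible Monte Carlo sweep drivers over seed sets, closure mis-recall
(`T_closed` override) and the valence-corruption fraction `x`.

## Worked example

```r
library(recallnet)

net <- canonical_fixture("balanced")
net
#> Signed network: 15 nodes, 23 edges (15 positive, 8 negative)
#> Density 0.219; 2 component(s)

triplet_census(net)
#> Triplet census (triplets mode): T = 61 connected, T_closed = 30 closed (10 triangles)

rec <- simulate_recall(net, c("Lewis", "Alyssa"), rng_seed = 7)
rec
#> Recalled network: 13 edges (9 seed, 4 heuristic) over 15 nodes
#> Seeds: Lewis, Alyssa; p_triangle = 0.4918, p_background = 0.000000; valences assigned

score_structure(net, rec)
#> Recall score: precision 0.769, coverage 0.435 (13 recalled, 10 correct)
score_quality(net, rec)
#> [1] 0.8
```

Seeding on Lewis and Alyssa — the high-degree character of each
component — recalls their 9 incident ties exactly, and the closure
heuristic then reconstructs 4 more; in this replicate 10 of the 13
recalled ties are real (precision 0.77), covering 43% of the target, and
8 of the 10 correctly recalled ties carry the right valence.

Sweeps aggregate this over many replicates and seed sets:

```r
cfg <- sweep_config(net, seed_sets = canonical_seed_sets()[c(1, 22), ],
                    replicates = 200, master_seed = 1)
run_seed_sweep(cfg)[, c("seed_set", "n_seed_ties", "precision_mean",
                        "coverage_mean", "quality_mean")]
#>       seed_set n_seed_ties precision_mean coverage_mean quality_mean
#> 1     Isabelle           2          0.840         0.087        0.750
#> 2 Lewis+Alyssa           9          0.741         0.543        0.795
```

A two-tie seed (Isabelle) leaves most of the network unrecoverable
(coverage 0.09), while one hub per component (Lewis+Alyssa, 9 ties)
recovers over half of it — the advantage of anchoring recall on popular
individuals.

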