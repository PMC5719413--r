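---
title: "A mechanistic model of recall of signed social networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanistic model of recall of signed social networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recallnet)
```

## The problem

When a person learns a small social network — say, fifteen characters in a
story, joined by twenty-three ties each marked as liking or disliking —
they do not store every dyad. Behaviour in recall experiments is
consistent with storing a handful of ties exactly and regenerating the
rest from *compression heuristics*: triadic closure for structure, and
structural balance plus a positivity bias for affect. `recallnet`
implements that generative account as a seeded stochastic simulator, so
that its output distribution can be compared against experimentally
observed recall.

## The recall model

A replicate is parameterised by a target network, a set of seed
characters, structural parameters and affect parameters.

**Seeding.** Every target tie incident to a seed character enters the
recalled graph and is flagged. Seeds model the few dyads a person is
certain about; the model assumes those are recalled perfectly, and that
all characters (nodes) are recalled.

**Structural pass.** All node pairs unconnected after seeding are visited
exactly once, in a uniformly random order per replicate. A visited pair
with at least one common neighbour in the *current* recalled graph gains
a tie with probability $P_{triangle} = T_{closed}/T$, where $T$ is the
target's connected-triplet (2-path) count and $T_{closed}$ its closed
count; any other pair gains a tie with the background probability
$P = (|E|-T_{closed}) / (\tfrac{n(n-1)}{2}\,T)$. One Bernoulli draw per
pair; a pair rejected under the closure rule does not get a second draw
under the background rule. Both probabilities are computed from the
target network — the assumption is that people carry a reasonably
accurate impression of how clustered and how dense the network is, not of
which particular dyads exist.

**Affective pass.** Seed ties start from their true valences, but a
fraction `x` of them (default 0.30) is re-drawn uniformly from
$\{+1,-1\}$ — "randomly chosen", not "flipped", so about half of the
corrupted ties remain accidentally correct. Each heuristically added tie
takes the sign of the mean sign product of the open triplets it closes at
the moment of addition; with no triadic context it takes $+1$. Valences
are assigned in the same visit order and graph state as the structural
pass (implemented by replaying the recorded addition order and closure
witnesses, which is equivalent to a single interleaved pass).

**Scoring.** `score_structure()` returns precision (correct ties /
recalled ties) and coverage (correct ties / target ties);
`score_quality()` returns correct valences / correctly recalled ties,
ignoring spurious ties entirely. `delta()` standardises a model-minus-
experiment gap by the experimental SD; experimental summaries are user
inputs, not package constants.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `x` | 0.30 | fraction of seed ties with randomly drawn valence |
| `census_mode` | `"triplets"` | closed count is $3\times$ triangles (ratio = global clustering coefficient); `"triangles"` uses the raw triangle count |
| `background_mode` | `"literal"` | denominator $\frac{n(n-1)}{2}T$; `"subtractive"` uses $\frac{n(n-1)}{2}-T$ |
| `closure_against` | `"recalled"` | closure tested against the evolving recalled graph; `"seed_only"` freezes it at the seed graph |
| `t_closed_override` | none | substitute closed-triplet count, for mis-recall robustness sweeps; bounded by $[0, T]$ |
| `zero_tiebreak` | `"positive"` | valence when closed triplets' sign products average exactly zero |

The two mode switches exist because the closure/background formulas admit
two readings each ("triplets" vs. "triangles" in the closed count; product
vs. difference in the background denominator) and no printed numeric value
of $P$ fixes either. The defaults take the triplet reading (so
$P_{triangle}$ is the familiar global clustering coefficient) and the
literal product denominator.

A consequence worth knowing: on the canonical stimulus the triplet census
gives $T_{closed} = 30 > |E| = 23$, so the literal background numerator is
negative and $P$ clamps to 0 (with a one-time warning per sweep cell).
Any stimulus satisfying the printed constraints has at least nine
triangles, so this is a property of the formula reading, not of one
unlucky instance. Under the clamped default, spurious ties arise only
through triadic closure and cross-component intrusions never occur; users
wanting a strictly positive background probability can set
`census_mode = "triangles"` or `background_mode = "subtractive"`.

## The stimulus generator

`default_fixture_spec()` encodes everything the vignette stimulus pins
down: 15 characters; 23 undirected ties, 15 positive and 8 negative; two
disconnected components; exact degrees for the seven catalogued seed
characters (Isabelle 2, Victoria 3, James 3, Alyssa 4, Catherine 4,
Lewis 5, Peter 5); mutual non-adjacency of all characters co-listed in
the 35-row seed-set catalogue (making catalogued tie counts additive);
Lewis and Alyssa in different components; and the partially recoverable
motif in which Anne–Henry, Henry–Elizabeth, James–Henry and
James–Elizabeth are ties while Anne–Elizabeth is not, so
⟨James, Henry, Elizabeth⟩ is a closed triplet and
⟨Anne, Henry, Elizabeth⟩ an open one.

Choices the source material leaves open, fixed here once:

* **Component sizes 8 + 7**, with Lewis in the larger component: the
  closest-to-even split of 15, and sizes did not vary by condition.
* **Five filler names** (Oliver, Sophia, Marcus, Nora, Felix) for the
  unnamed characters, so fixtures are deterministic.
* **Component membership**: Lewis, Peter, Catherine, Isabelle and
  Victoria share the larger component with three fillers; Alyssa, James,
  Henry, Elizabeth and Anne the smaller with two. Non-adjacency plus the
  degree budget force Lewis–Peter–Catherine into one component and
  Alyssa–James together; the Isabelle–Victoria block could sit on either
  side and is placed with Lewis.
* **Balanced condition**: a two-faction arrangement per component
  (negative ties exactly between factions) found by local search on the
  faction cut until it equals 8; this guarantees every triangle an even
  number of negative ties, i.e. a positive sign product.
* **Imbalanced condition**: a uniformly random arrangement of the same
  15 positive and 8 negative valences over the identical structure,
  rejected in the rare case that no triangle comes out imbalanced. A
  random arrangement (rather than a minimal one-triangle perturbation)
  better emulates a substantively imbalanced stimulus.
* **Packaged seed 1101**: the canonical fixtures in
  `inst/extdata/stimulus_{balanced,imbalanced}.tsv` are the generator's
  frozen output for that seed; `canonical_fixture()` loads them and the
  test suite verifies they regenerate exactly.

The generator is randomised constraint satisfaction with bounded
restarts; `validate_fixture()` re-checks every constraint independently
and is run on every generated network.

What the fixture does *not* claim: the true stimulus topology beyond the
printed constraints (the generated instance is a constraint-equivalent
stand-in, not a replica), reading/study behaviour, and the kin/non-kin
wording manipulation, which is carried only as an optional edge-label map
with no structural effect.

## Numerical and reproducibility choices

* **Rounding**: the corrupted-seed count is `round_half_up(x * n_seed)`,
  so `x = 0.30` with 9 seed ties corrupts exactly 3.
* **Clamping**: the background probability is clamped into $[0,1]$ after
  formula evaluation, with a warning.
* **Degenerate inputs**: a target with no connected triplets has no
  closure probability (error); empty recall yields precision `NA` (not
  zero), and zero correctly recalled ties yield quality `NA`; sweep
  aggregation excludes `NA`s and reports how many were excluded.
* **RNG policy**: sweeps derive one child seed per (cell, replicate)
  through an integer congruential mix that is exact in doubles, so a
  1000-replicate run and two 500-replicate batches pool identically, and
  every output is a pure function of (fixture, configuration, master
  seed).
* **Problem sizes**: the packaged tests exercise the census oracle on 200
  random graphs of up to 12 nodes and the monotonicity suites at 500
  replicates per cell; sweep defaults are 1000 replicates per cell, with
  smaller runs used in examples.

## What passing tests do and do not show

The test suite establishes internal correctness (census equals brute-force
enumeration; seed ties are never lost; degenerate parameter settings
close the process exactly; balance propagation with uncorrupted seeds
never mislabels a tie whose closure context consists of correctly
recalled true ties) and the model's qualitative behaviour on the
canonical stimulus (recalled volume grows with the background probability
and with the closed-triplet override; affect quality falls as `x` grows
on the balanced stimulus and is less sensitive to `x` on the imbalanced
one). None of this certifies the model against human data: experimental
means and SDs are inputs to `delta()`, and conclusions about real recall
require supplying them.

## Limitations

The model ignores forgetting over time, study-time and working-memory
covariates, directed or graded affect, and any kinship-specific priors.
Visit order, the single-pass rule and the one-draw-per-pair rule are
modelling choices exposed as configuration where ambiguous. The simulator
is aimed at vignette-scale networks (tens of nodes); the implementation
is dense-matrix based and not intended for large graphs.
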