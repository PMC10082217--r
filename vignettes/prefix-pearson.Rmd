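---
title: "Prefix-Pearson multi-source localization: models, conventions, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prefix-Pearson multi-source localization: models, conventions, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sourceloc)
```

# The problem

A message spreads over a known undirected network from an unknown set of
source nodes. We observe the *informed time* — the first arrival of the
message — at a subset of monitored nodes (observers), and nothing else: not
the dynamics family, not its parameters, not the number of sources. The task
is to rank every node by how likely it is to be a source.

The statistical handle is simple: informed times grow, on average, with hop
distance from the source that delivered the message. For a single source the
relation is close to affine; with several sources each source's relation
holds only *locally*, inside its own infection region, which is what the
prefix construction below exploits.

# Propagation models

**Diffusion.** Each edge carries an independent delay drawn from
`N(u, sigma^2)` and shared by both directions. A newly informed node
forwards to all neighbors; a neighbor's candidate arrival is the sender's
time plus the edge delay. Iterating this local rule to convergence gives
earliest-arrival semantics: the informed time of `v` is the minimum over
sources `s` of `t_s` plus the delay-weighted shortest-path length from `s`
to `v`, which is how `simulate_diffusion()` computes it (all delays are
positive, so Dijkstra applies). Draws with non-positive delay are resampled:
time must advance along a path, and for the default `sigma/u` ratios the
truncation is a negligible correction (at `u = 2, sigma = 0.25` the
probability mass below zero is ~`1e-15`; only at `sigma = 1.5` does it reach
~9%, raising the effective mean delay to ~2.27).

**SI.** Discrete synchronous steps; an uninformed node with `c` neighbors
informed at the start of a step becomes informed during the step with
probability `1 - (1 - lambda)^c`. A node stays informed forever. The general
per-node-rate form exists in the literature; every experiment here uses a
uniform `lambda`, which is what `si_params()` models.

**Source initial times.** A source's informed time is *defined* as its
initial time. In staggered-start experiments a later source is inert until
its activation step (SI) and its recorded time is clamped to its initial
time (diffusion) even if another source's wavefront arrives earlier; this
keeps the identity `informed_time(s) = t_s` that the observer model relies
on. Offsets are parameterized as `delta`: consecutive sources start
`delta * u` apart under diffusion and `delta` steps apart under SI, so
`delta` counts *expected hops* of head start in both models.

# The locator

For candidate `v_k`, sort its hop distances to the `r` observers ascending
and order the observer times the same way. For each prefix `h = 2..r`
compute the Pearson correlation of the first `h` distance/time pairs, then
sum: `f_k = sum_{h=2}^{r} rho_k^h`.

Conventions that the definition leaves open, and what this package does:

* **Threshold range.** The sum starts at `h = 2`: a one-point correlation
  is undefined, and no information is lost because every candidate loses
  the same term. The upper end includes `h = r` even when the farthest
  observers were informed by other sources — those terms are small for true
  sources and small-or-negative for non-sources, so they sharpen rather
  than blur the ranking.
* **Zero-variance prefixes** (all tied distances, or all equal times, as
  integer SI times readily produce) contribute 0 — neutral and sign-free.
  Mapping them to 1 would reward candidates equidistant from everything
  (hubs); mapping to -1 would punish them; 0 takes no position.
* **Distance ties** are broken by observer record position, never by
  informed time. Breaking by time would sort each tied block into perfect
  agreement with the time order and bias every candidate's correlation
  upward.
* **Ranking** is by descending `f` (larger `f` = more source-like), with
  identifier-order tie-breaks, and tie groups flagged so that evaluation
  can treat them honestly.
* Prefix correlations are computed from cumulative sums in O(r) per
  candidate with a relative `1e-12` guard on the variance terms, and
  distances are computed once per network and shared by all candidates.

# Evaluation

The ROC curve sweeps a prefix through the ranked list; `TPR(l)` is the
fraction of true sources in the top `l`, `FPR(l)` the fraction of
non-sources. The area is computed tie-aware: a group of tied scores is
swept as one block contributing a diagonal segment, which makes the area
identical (to machine precision; the suite checks `1e-12`) to the
Mann–Whitney form — the probability that a random source outranks a random
non-source, with half credit for ties. Without this convention the AUC of a
heavily tied ranking would depend on the arbitrary tie order.

# Locatability and observer selection

With identical edge delays, Pearson centrality cannot distinguish nodes
`u, v` whose observer-distance vectors satisfy `d^v = k d^u + c` with
`k > 0`: correlation is invariant under positive affine maps. The package
checks this relation *exactly* (anchor two coordinates with distinct `d^u`,
fit `k, c`, verify all coordinates to `1e-9`) rather than thresholding a
floating-point correlation near 1 — distances are integers, so exactness
costs nothing and removes a tolerance to tune. Degenerate cases follow from
the definition: two constant vectors are related (any `k` works), a
constant against a non-constant is not, and with a single observer every
pair is related (scalars always fit an affine map), so one observer can
never distinguish anything.

The locatability index `x` counts distinguishable unordered node pairs over
*all* nodes (observers included — sources are drawn from all nodes, so all
pairs matter). The quality index `q = 1 - (2/(n(n-1))) sum_{i<j}
cor(d_i, d_j)` rewards dissimilar distance signatures; pairs involving a
zero-variance signature fall back to the affine predicate (1 if related,
else 0), on which the formula is silent. Larger `q` means more varied
signatures; we treat larger as better because that is what the algebra of
the definition rewards.

**Greedy selection.** Finding a minimum observer set that distinguishes all
pairs is combinatorial (NP-hard in general), so `greedy_observer_sequence()`
is greedy: start empty; at each step add the node maximizing `x` of the
extended matrix, breaking ties by larger `q`, then by identifier (at size 1
`q` is undefined, so the first pick falls through to identifier order among
the all-tied candidates); once `x` saturates at `n(n-1)/2`, keep adding the
node maximizing `q` alone. Because appending a row can only break affine
relations, `x` is non-decreasing along the sequence, so any prefix of the
returned ordering is usable as an observer set of that size — which is how
the strategy-versus-random comparisons sweep the observer budget. The
implementation tracks, per still-indistinguishable pair, the affine
coefficients pinned down so far, so each candidate evaluation touches only
the surviving pairs.

# Synthetic data and experiment design

The generators are first-class, seeded, and define the study conditions:

* `generate_er(n, avg_degree, seed)` — G(n, p) with `p = <k>/(n-1)`,
  redrawn (up to 100 attempts) until connected, because the dynamics assume
  every node is eventually informed. At the default `n = 100, <k> = 4`
  roughly one draw in six is connected, so the cap is effectively never hit.
* `generate_ba(n, links_per_node, seed)` — preferential attachment grown
  from a complete clique on `links_per_node + 1` nodes, giving the
  deterministic edge count `C(m+1, 2) + (n-m-1)m`; the clique-seed
  convention is stated because the growth rule alone does not fix it.
* `degree_preserving_rewire()` — double-edge swaps rejecting loops and
  multi-edges and rolling back swaps that disconnect the graph: the null
  model keeps the degree sequence and connectivity, nothing else.
* Fixtures: `path7`, `fig1-like` (7 nodes, one hub), and `locatable10`, an
  asymmetric 10-node tree whose full-observer distance signatures are
  pairwise non-affinely-related — all 45 pairs distinguishable — so
  noiseless single-source runs on it are perfectly identifiable (AUC 1),
  which the suite uses as an end-to-end sanity anchor.

Default experiment conditions mirror the headline protocol: ER/BA networks
with `n = 100`, `<k> = 4`; diffusion `u = 2, sigma = 0.25`; SI
`lambda = 0.5`; two sources at time 0; observers drawn uniformly;
repetitions default to 50 for interactive use while the headline accuracy
numbers are computed at 200 repetitions (the acceptance script and the
acceptance tests use 200). Observer-strategy comparisons run on `n = 50`,
`<k> = 4` networks with observer budgets r in {5, 10, 15, 20, 25} and 40
repetitions per strategy — large enough that the greedy-versus-random
ordering is stable, small enough to keep the full suite fast. Every
repetition derives its own seed as `(seed + 48271 * i) mod (2^31 - 1)` and
draws networks, sources, observers and dynamics from that stream alone, so
single repetitions are reproducible in isolation and repetitions are
independent.

What the synthetic conditions do *not* emulate: real contact networks'
clustering, degree correlations and community structure (ER/BA have
essentially none of the first two in the relevant regime); reporting noise
in observer times; dynamics outside diffusion/SI (no recovery states, no
continuous-time chains). Passing tests therefore demonstrate correctness of
the method under its stated model, not performance on any particular
empirical network.

# Known limitations

* Accuracy *declines* with delay noise in this implementation: with 10%
  observers the mean AUC over 200 repetitions falls from ~0.89 at
  `sigma = 0.25` to ~0.77 at `sigma = 1.5` (the acceptance script computes
  the full sigma sweep). Earliest
  arrival takes a minimum over many paths, and at high `sigma` that minimum
  decouples informed times from hop distance faster than a single-path
  model would; the effect is intrinsic to the semantics, not a tolerance
  issue.
* The greedy observer sequence is a heuristic: it is optimal on small
  graphs where exhaustive search is feasible (the suite checks a path), but
  carries no approximation guarantee in general.
* Locatability analysis assumes identical edge delays (the "ideal state");
  under noisy delays the affine condition is necessary-but-not-sufficient
  folklore, and the package makes no claim there.
* The number of sources is never estimated — the output is a ranking, and
  AUC evaluates it against a known source set. Partitioning nodes into
  per-source infection regions is out of scope.
* SI at small `lambda` produces heavily tied, coarse integer times; the
  zero-variance convention keeps scores defined, but localization is
  genuinely harder there (lower AUC with fewer observers), consistent with
  the ordering experiments in the suite.
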