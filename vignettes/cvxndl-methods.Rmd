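---
title: "Interpretable online network dictionary learning: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpretable online network dictionary learning: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Droplet-based multiway chromatin assays report *multiway* physical contacts:
each sequenced complex links two or more genomic loci at once, so the natural
data structure is a hypergraph whose nodes are fixed-width genomic bins
(500 b by default, fragments assigned by their midpoints) and whose
hyperedges are the observed complexes. Classical dictionary learning on such
data has two problems. First, the learned elements are abstract latent
matrices: nothing ties an entry of an element back to a real, observed
contact between two genomic loci. Second, offline factorizations do not
scale to the millions of subnetwork samples a large contact map can supply.

`cvxndl` addresses both at once. The hypergraph is *clique-expanded* into an
ordinary undirected network (every hyperedge becomes a complete subgraph; an
expansion that is faithful when large hyperedges are rare). Subnetworks of a
fixed size are sampled from this network, and a small dictionary of k × k
interaction patterns is fit *online*, one sample at a time, under a
convexity constraint: each element must be a convex combination of a small
set of **representatives** — real sampled subnetworks kept verbatim. Every
element therefore maps back to genomic coordinates through the node tuples
of its representatives.

## Sampling model

A template motif `F` on `k` nodes (a k-path throughout; paths suit contact
networks, whose measurements are dominated by near-linear proximity) is
mapped into the network by *homomorphisms*: ordered node tuples `x` such
that every template edge lands on a network edge. Homomorphisms need not be
injective — a walk may backtrack — and the induced k × k adjacency
(the **patch**) is the learner's data sample after column-major flattening
(`d = k²`).

Sampling is by a pivot MCMC chain. Given the current tuple, a neighbour `v`
of the first node `u` is proposed uniformly and accepted with probability

β = min{ [Σ_c A^{k−1}(v,c) / Σ_c A^{k−1}(u,c)] · [deg(u) / deg(v)], 1 },

after which the remaining `k − 1` nodes are redrawn as a uniform directed
random walk. This is a Metropolis–Hastings correction whose target draws the
first node proportionally to its count of outgoing length-(k−1) walks; on
regular graphs β ≡ 1. The walk-count row sums are computed once per network
by repeated sparse matrix–vector products, never by dense matrix powers.
The test suite verifies the chain against exhaustive enumeration of the
homomorphism set on small graphs (total-variation distance of the patch
distribution < 0.05 at 10⁵ steps).

Practical choices: burn-in defaults to 1,000 steps; no thinning (the online
learner tolerates correlated samples); walks may backtrack, since the
homomorphism definition does not exclude it and a non-backtracking walk
would target a different distribution. Pools may be drawn as several
independent chains (`n_chains`): on networks made of dense communities
joined by sparse linkers a single chain mixes slowly across communities,
and restarting from fresh uniform starts restores coverage.

## The learner

With data samples `x_t` and dictionary `D` (d × K), each step solves the
nonnegative lasso `min_{Λ ≥ 0} ‖x_t − DΛ‖² + λ‖Λ‖₁` (cyclic coordinate
descent). Codes are constrained nonnegative: the method is NMF-like, and
nonnegative codes keep elements interpretable as additive parts. λ defaults
to 1.0 (the method is not sensitive to moderate λ on binary patches; λ = 0
removes the penalty entirely).

The dictionary update minimizes the aggregated quadratic surrogate
`Tr(D A_t Dᵀ) − 2 Tr(D B_t)` where `A_t = (1−w_t)A_{t−1} + w_t Λ_tΛ_tᵀ` and
`B_t = (1−w_t)B_{t−1} + w_t Λ_t x_tᵀ`, with `w_t = 1/t`. Two update rules
are provided:

* **Convex (online cvxNDL, the default).** The new sample is assigned to
  the element with the nearest column (Euclidean distance, ties to the
  smaller index) and appended to its representative set; then, for each of
  the `N_j + 1` leave-one-out subsets, the optimal simplex weights are
  re-solved and the subset with the smallest column-restricted surrogate is
  kept, so exactly one representative is removed. If the removed candidate
  is the newcomer itself the element is unchanged. Since "reject the
  newcomer" is always available, the realized objective never exceeds the
  incumbent's — a property the suite asserts step by step. Only the assigned
  element's column is re-optimized per step; the columns are coupled only
  through `A_t`, and re-solving untouched columns at every step would
  multiply the cost for no measurable benefit at these scales.
* **Unconstrained (online NDL baseline).** Block coordinate descent on the
  surrogate over columns, clipped to [0, 1], no representative sets. Used
  as the non-interpretable reference in the reconstruction comparisons.

The simplex-constrained quadratic programs are solved by a primal
active-set method (exact equality-subproblem solves with a pseudo-inverse
fallback for the singular faces that duplicate representatives create),
warm-started from the current weights; termination is on the simplex KKT
residual (10⁻⁸ by default, stricter than the 10⁻⁶ documented contract).
A function-value safeguard stops cycling on degenerate faces where several
supports attain identical objectives.

**Initialization.** A pool of patches (20·K by default, following the ratio
of 500 initialization samples to K = 25 used at full scale) is partitioned
by k-means on flattened patches, rebalanced so each group has between
`min_reps` (10) and `N_max` (2·min_reps) members; each element starts as
the uniform-weight mean of its group. The aggregated history `A_0`, `B_0`
is then seeded by coding the initialization samples themselves and the step
counter starts at the pool size. This matters: with a cold history the
first online steps carry weight `w_t ≈ 1`, and a single sample can erase
the initialization structure; counting the initialization samples in the
average removes that pathology while leaving the surrogate an average over
everything observed.

**Convergence.** The running surrogate loss is averaged over a 500-step
window; the fit stops when the relative change between consecutive windows
drops below `tol` (10⁻⁴). Exhausting the stream (or `max_iters`, default
10⁶) without convergence is reported as a failure via a warning — never
silently.

**Summaries.** Element importance is `γ(i) = A[i,i]² / Σ_j A[j,j]²`
(a usage distribution summing to 1); density is the mean of an element's
k² entries; and, when bin metadata is available, the median genomic
distance between adjacent path nodes over all of an element's
representatives localizes it on the proximal-to-distal axis.

## Reconstruction and evaluation

A trained dictionary is evaluated by local approximation: patches are
sampled from the target network (10·n/k by default), coded against the
dictionary, the approximations `DΛ` clipped to [0, 1], and each
approximated entry accumulated onto its visited node pair; the final score
of a pair is its accumulated value divided by its visit count. Ranking the
visited pairs by score against the true adjacency yields an average
precision. Unvisited pairs are excluded, and the diagonal is ignored (no
self-contacts). Reconstruction coding reuses the training λ by default,
with an override for λ = 0 coding.

## Synthetic generators and what they do (not) show

* `sbm_network()` draws independent-edge stochastic block models, restricted
  to the largest component. Defaults — three blocks of 100 nodes,
  within-block edge probability 0.3, between-block 0.02 — give a sparse,
  clearly blocked graph in which length-8 paths mostly stay within blocks.
  The desk-scale validation (k = 8, K = 9, 5,000 online samples, scaled
  from the full-scale k = 21, K = 25, 20,000 samples) runs end to end in
  well under ten minutes on one CPU.
* `planted_motif_network()` places disjoint copies of given subnetworks and
  joins them with sparse random linker edges (a random chain guarantees
  connectivity; labels are kept). The parameter-recovery harness in the
  test suite plants three *concentration communities* — complete graphs,
  complete bipartite graphs, and high-girth affine-plane incidence graphs —
  in which path walks induce, respectively, the full k-clique patch, the
  alternating (complete-bipartite) patch, and the pure k-path patch almost
  deterministically (collision probability ~1/degree). On literal k-node
  motif copies this concentration is impossible: with backtracking walks
  the probability that the third node revisits the first is 1/deg ≥ 1/4,
  so induced patches are intrinsically multimodal and no learner could
  match the planted adjacency to ±0.1 per entry. Community sizes are
  balanced so the chain's stationary mass (~degree^(k−1) × nodes) is
  comparable across families. A learner with K = 3 recovers all three
  planted patches to within 0.1 per entry, up to greedy matching.
* `random_dictionary()` builds elements as uniform convex combinations of
  randomly drawn pool patches. Note it is a *structured* baseline — every
  patch still contains the path topology — so its reconstruction scores sit
  far above those of an arbitrary random matrix; the meaningful comparison,
  asserted over paired seeds, is that it scores strictly below the trained
  dictionary.

What passing these tests does **not** show: real multiway contact data have
heavy-tailed hyperedge sizes, genomic-distance-dependent contact decay, and
mappability artifacts that neither generator emulates; enrichment filtering
of hyperedges is assumed to have happened upstream. Chromosome-scale
accuracy figures therefore cannot be reproduced from synthetic data, and the
package makes no claim that they are.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open; fragment midpoints are
  `floor((start + end)/2)`, so a midpoint on a bin boundary belongs to the
  upper bin.
* The node universe is the set of bins observed in at least one hyperedge;
  disconnected clique expansions are restricted to the largest component
  (with the dropped share reported) because the samplers require
  connectivity.
* Ties in nearest-element assignment and in removal candidates resolve to
  the smallest index; identical-patch pools fall back to a round-robin
  initial split (k-means cannot seed more centers than distinct points).
* Hyperedges above `--max-hyperedge-size` can be dropped at read time
  (default unlimited): very large hyperedges distort clique expansion, but
  filtering is left to the caller's judgement.
* All randomness flows through R's global RNG; every entry point takes a
  seed and records it, and equal seeds give bit-identical outputs.

## Known limitations

* Only path templates have a pivot-chain sampler; other motifs (small
  stars) are supported for enumeration and rejection sampling in tests
  only.
* One sample per online step; there is no mini-batch variant.
* The removal search is exhaustive over `N_j + 1` candidates per step,
  which is exact but quadratic in the representative budget; budgets much
  beyond a few dozen representatives per element would call for a
  screening heuristic.
* Convergence of the online objective on real data has no guarantee; the
  failure path (warning plus `converged = FALSE`) is the supported way to
  detect and restart.
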