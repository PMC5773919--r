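---
title: "Multi-network clustering for protein complex detection: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-network clustering for protein complex detection: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnclust)
```

## The problem

A protein complex is a set of proteins that assemble to perform a
function. In a protein–protein interaction (PPI) network, complexes tend
to appear as dense, possibly overlapping subgraphs — but high-throughput
PPI data are noisy enough that single-network clustering often misses
complexes whose internal edges were simply not observed. Protein
interactions are mediated physically by domains, so a domain–domain
interaction (DDI) network carries independent evidence about which
proteins *should* interact. The two networks live on different node sets
(N₁ proteins, N₂ domains) related many-to-many by domain composition,
which rules out standard multi-view clustering; `mnclust` couples them
through the association matrix `F` instead.

## Generative model

Both layers share one nonnegative membership matrix `H` (N₁ × K). The
protein layer uses `H` directly; the domain layer uses the derived
memberships `F H`, so a domain inherits the cluster profile of the
proteins containing it — the layers cannot drift apart. Each observed
edge is a Bernoulli draw with the exponential co-cluster link

$$W_{ij} = 1 - \exp\Big(-\sum_k H_{ik} H_{jk}\Big),$$

implemented in `co_cluster_affinity()`. The likelihood of a layer
(`network_log_likelihood()`) sums `A_ij log W_ij + (1 - A_ij)(-S_ij)` over
**ordered** pairs `i ≠ j`, so each undirected edge contributes twice.
Self-pairs are excluded throughout: adjacency diagonals are zero, a
self-interaction probability has no meaning in this model, and including
the diagonal of the quadratic term would add a hidden ridge penalty
`Σ_ik H_ik²` that punishes every node for its own membership mass.

Priors select the model order. Column `k` of `H` gets i.i.d. half-normal
entries with variance `λ_k`; each `λ_k` gets an inverse-gamma(a, b) prior.
When a column is not needed to explain edges, its posterior `λ_k`
collapses, the column is shrunk toward zero, and thresholding later
removes it — automatic relevance determination. `K` at initialization is
therefore an upper bound, not a model choice.

The MAP objective (`mnc_objective()`) is the negative log joint:

$$
-\log P(A^{(1)}|H) - \log P(A^{(2)}|F,H)
+ \sum_{ik} \frac{H_{ik}^2}{2\lambda_k}
+ \Big(\frac{N_1}{2} + a + 1\Big)\sum_k \log\lambda_k
+ \sum_k \frac{b}{\lambda_k}.
$$

## Parameters that matter

| parameter | default | role |
|---|---|---|
| `a` | 2 | inverse-gamma shape; its influence is dominated by N₁, so it is fixed |
| `b` | `N₁/4` (via `b_scale = 0.25`) | inverse-gamma scale; larger `b` keeps more columns alive, the N₁-proportional default balances the likelihood, whose magnitude also grows with N₁ |
| `tau` | 0.3 | membership cutoff turning `Ĥ` into discrete complexes; boundary included (`≥`) |
| `omega` | 0.25 | overlap-score threshold declaring a predicted/reference pair matched |
| `tol` | 1e-3 | relative objective-change stopping rule |
| `max_iter` | 500 | iteration cap (the optimizer typically converges in tens of sweeps at the default `tol`) |
| `perturb` | 0.01 | magnitude of the positive perturbation at initialization, and the range of random initial entries |
| `eps` | 1e-10 | floor inside `log(1 − exp(−s))` and in update denominators |

All are set in one place, `mnc_hyperparams()`.

## Optimization

`mnc_fit()` alternates two updates until the relative objective change
drops below `tol` (computed with a 1e-12 floor on the denominator):

1. **Relevance:** `λ_k ← (2b + Σ_i H_ik²)/(N₁ + 2a + 2)`, the exact
   minimizer of the objective in `λ_k` given `H` (`update_lambda()`).
2. **Membership:** the damped multiplicative rule
   `H_ik ← H_ik/2 + (H_ik/2)·num/den` (`update_H()`), where the numerator
   collects `Σ_{j≠i} A_ij H_jk / W_ij` from both layers and the
   denominator collects `Σ_{j≠i} H_jk` (plus the domain-layer analogue
   `Σ_{x≠y} F_{xi} (FH)_{yk}`) and the prior term `H_ik/(2λ_k)`.

λ is updated before H within a sweep; the order is a convention, since
the λ step is exact either way. A subtlety resolved during development:
the multiplicative denominator must exclude self-pairs to be consistent
with the self-pair-excluded objective. With the self-terms left in, the
iteration minimizes a *different* objective (the one with the hidden ridge
term), the recorded trace is non-monotone, and the stopping rule can fire
at a false plateau far from stationarity. With the consistent form used
here, the trace decreases monotonically on every fixture we generate, and
at convergence the `num/den` ratio equals 1 wherever the gradient
vanishes — entries converging to the `H = 0` boundary instead show
ratio < 1, the correct KKT behaviour. `mnc_multiplier_ratio()` exposes
the ratio matrix as a stationarity diagnostic.

Zero entries are fixed points of the multiplicative rule, which is why
initialization adds a strictly positive perturbation everywhere: nothing
starts absorbed. Columns whose maximum falls below 1e-8 are frozen rather
than dropped, keeping column indices stable until postprocessing.
Degenerate fits (a column collapsing entirely) emit a warning; a
non-finite objective aborts with the offending term named.

### Initialization

The model is non-convex, so the result depends on the start.
`initialize_from_clustering()` converts any seed clustering into a binary
indicator matrix — one column per seed group plus one singleton column per
unclustered protein, `K = K̂ + N₁ − N̂` — and perturbs all entries with
i.i.d. Uniform(0, 0.01]. The perturbation is deliberately small: large
enough to free zero entries, far too small to disturb the indicator
structure. Seed clusterings can come from a file (so output of any
external partitioner can be used), from the built-in `markov_cluster()` —
an expansion/inflation flow clustering (inflation 2.0, up to 100 rounds,
support threshold 1e-6, clusters = connected components of the limit
support) — or `initialize_random()` draws all entries on (0, `perturb`]
with a user-chosen `K`. Flow clustering hard-partitions, so planted
complexes bridged by shared proteins may arrive merged in the seed; the
ARD fit can still match every reference complex from such a start (see the
README example), but a finer seed clustering gives a finer catalog. The
CLI exposes `--restarts`, which reruns the fit with consecutive seeds and
keeps the lowest final objective.

## From memberships to complexes

`threshold_memberships()` assigns protein `i` to complex `k` when
`Ĥ_ik ≥ τ`; the boundary is included, and a protein may pass in several
columns, so overlap is preserved. `filter_and_dedup()` then drops
complexes with fewer than three members — matching how reference catalogs
are conventionally filtered — and collapses exact duplicate member sets
(ARD frequently leaves near-identical surviving columns that threshold to
the same set). Near-identical but unequal sets are *not* merged; that is
deliberate, since partial overlap may be real substructure.

## Evaluation metrics

For benchmark complexes `b_i` and predictions `q_j`, with
`T_ij = |b_i ∩ q_j|`:

- `accuracy_metrics()`: `Sn = Σ_i max_j T_ij / Σ_i |b_i|`,
  `PPV = Σ_j max_i T_ij / Σ_j |q_j ∩ U|` (U = union of benchmark members),
  `Acc = √(Sn·PPV)`.
- `overlap_score()`: `OS = |b ∩ q|² / (|b||q|)`; `frac_matched()` is the
  fraction of benchmark complexes with some `OS ≥ ω`.
- `prf()`: TP = predictions matched by any benchmark complex, FN =
  benchmark complexes matched by nothing, FP = predictions − TP. Because
  real reference sets are incomplete, unmatched predictions may be novel
  complexes; precision and F should be read with that caveat.
- `enrichment_pvalue()`: the upper-tail hypergeometric probability
  `P(X ≥ z)` of seeing `z` or more annotated proteins in a complex of size
  `C` against a background of `N`. The naive textbook form
  `1 − Σ_{l=1}^{z−1}(...)` mis-normalizes (it omits the `l = 0` mass and
  would not return 1 at `z = 0`); we use the standard tail starting the
  subtracted sum at `l = 0`, computed via `stats::phyper`. The background
  `N` defaults to the distinct proteins seen, and should normally be set
  to the size of the analyzed network; a Bonferroni factor over terms is
  available but off by default, with the raw minimum always reported.

## The synthetic generator

`sample_instance()` forward-samples the generative model itself: a block
membership matrix with planted complexes (entries equal to
`membership_strength`), a Bernoulli association map, and both layers drawn
edge-by-edge from `1 − exp(−(HHᵀ)_ij)`, with a `background_edge_noise`
chance of flipping each non-edge. Defaults define the package's standard
study conditions: 100 proteins, 40 domains, 5 complexes, strength 2
(within-complex edge probability `1 − e⁻⁴ ≈ 0.98`), 10% of proteins in
two complexes, 2 expected domains per protein, 1% spurious edges. They
were chosen once so that planted structure is strong but recovery is not
trivial: at 1% noise a 100-node network gains ~40 spurious edges, about
4% of the true edge count. What the generator does *not* emulate: the
heavy-tailed degree distributions, correlated false negatives, and
study-bias of real interactome data, and annotation terms richer than the
planted complexes themselves. Passing the recovery tests therefore shows
the estimator works where the model is correct — it does not certify
performance on real screens, where the likelihood is misspecified.

## Numerical choices

- `log(1 − exp(−s))` is evaluated as `log(−expm1(−s))` with `s` floored at
  `eps = 1e-10`, so observed edges with (numerically) zero affinity
  contribute a large finite penalty instead of `−Inf`. For `s ≥ 1e-6` the
  stable form agrees with the naive expression to well below 1e-9.
- Update denominators are floored at `eps` before division.
- Thresholding uses `≥` at both `τ` and `ω` boundaries.
- Stopping compares `|obj_t − obj_{t−1}| / max(|obj_{t−1}|, 1e-12)` with
  `tol`; `max_iter` defaults to 500, a cap the default tolerance rarely
  approaches.
- Duplicate collapse keeps the first occurrence; all catalog operations
  are order-stable so runs are byte-reproducible under a fixed seed.

## Problem sizes used in the test suite

Unit oracle checks run on instances up to 10 proteins × 6 domains × 3
clusters against scalar-loop re-implementations; stationarity fixtures use
24 proteins with the tolerance tightened to 1e-12 so that boundary-bound
entries fully decay; recovery and ablation runs use the standard
100-protein design over five seeds. These sizes make the full suite run in
well under a minute while leaving the recovery problem non-trivial.
Dense-matrix algebra is used throughout, which is comfortable to a few
thousand nodes; genuinely sparse, much larger networks would want a sparse
backend, which is out of scope here.

## Known limitations

- Binary undirected networks only: weighted or directed evidence must be
  binarized (done with a warning), discarding confidence scores.
- Exactly two layers; the shared-membership construction generalizes, but
  the implementation does not.
- No merging of highly-overlapping non-identical complexes and no density
  post-filter; catalogs can contain nested near-duplicates.
- MAP point estimation: no uncertainty on memberships or on the number of
  complexes.
- The built-in flow clustering is a seeding heuristic, not a full MCL
  replacement; supply an external clustering file when a specific seed
  partition is wanted.
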