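---
title: "Estimating the accuracy of multimeric protein models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the accuracy of multimeric protein models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`meqa` predicts the quality of individual multi-chain protein structure
models — an overall-fold score and an interface score, both in (0,1) —
from the model's geometry alone, and evaluates rankings of competing
models with CASP-style metrics. This vignette is the package's account of
the underlying models, the choices that were genuinely open, and what the
shipped synthetic data can and cannot establish.

## From structure to graph

A model is reduced to one node per residue. The representative position
is the CB atom, except glycine, which uses CA; when CB is absent (always
for glycine when orientation features are needed) a virtual CB is placed
from N, CA, C with the standard fixed linear combination of the local
backbone frame (≈1.53 Å bond, ≈110° angles, L-chirality). Edges connect
residue pairs with representative-atom distance ≤ 8 Å — ties at exactly
8 Å are included — and the same cutoff defines interface residues:
residues within 8 Å of any residue of another chain, i.e. nodes with a
cross-chain edge. Neighbour search uses cubic cell binning with side
equal to the cutoff, which the test suite checks against an all-pairs
scan.

Parsing keeps the first model of a PDB file, altloc 'A' or blank, maps
common non-standard residues to their parents (MSE→MET, SEP→SER, ...),
excludes waters and other hetero species, and drops residues missing any
of N, CA, C with a warning. How the original CASP pipelines handled
missing CB atoms or exotic residues is not documented anywhere we could
rely on; the rules above are this package's own and are stated so results
are reproducible.

## Feature layout

Nodes carry 83 features in six fixed blocks. Only the total (83) and the
six types are externally fixed; the per-block widths are a design choice
of this package, chosen as the natural widths where one exists (20 for
one-hot, 20 for a PSSM) with the remainder split to honour the total:
energy terms 20, secondary-structure/solvent agreement 5, sinusoidal
positional encoding 12 (indexed over the concatenated multi-chain
sequence, 0-based), statistical potentials 6. The widths are visible
constants (`node_feature_layout()`), so a user with real provider tools
can re-balance them — at the cost of retraining.

Edges carry ten features from five types: the CB–CB distance; the
inter-residue angle α, realised as the angle between the two CA→CB
vectors (the one reading that reaches ten values with five types); the
dihedral ω over (CAᵢ, CBᵢ, CBⱼ, CAⱼ); the dihedrals θᵢⱼ, θⱼᵢ over
(N, CA, CB, CBⱼ) in each direction; the planar angles φᵢⱼ, φⱼᵢ at each
CB; and a contact-dependent and two solvent-accessibility potentials
that are populated only on cross-chain (interface) edges and zero
otherwise. Angles are in radians; dihedrals are signed by the right-hand
rule in (−π, π], planar angles in [0, π]; degenerate frames produce 0
with a warning. All geometric features are invariant under rigid motion
of the whole complex, which the tests verify to 10⁻⁶.

External tools (PSSM generation, energy scoring, secondary-structure
agreement, statistical potentials, learned sequence embeddings) are
abstracted behind a provider contract: a provider returns a fixed-width
per-residue matrix (or per-pair value), deterministically for a given
structure and seed. The shipped defaults are hash-seeded synthetic
stand-ins. They preserve the plumbing — widths, gating, determinism — but
carry no biophysical signal; conclusions about real predictive power
require real providers.

## Graph backbones

Two regression backbones produce a global embedding X and a score
σ(MLP(X)):

* **Transformer.** Multi-head attention over contact neighbourhoods.
  Edge features are projected into both keys and values; a root weight
  carries each node's own features, so an isolated node depends only on
  itself. Each layer is followed by ReLU and TopK pooling: a learned
  projection scores nodes, the top ⌈ratio·n⌉ are kept (ties resolved
  toward lower node index, keeping the pipeline deterministic), and
  retained features are gated by tanh(score). Gating applies even at
  ratio 1.
* **MetaLayer.** Separate fully connected edge, node and global update
  networks: edges update from (source, destination, edge, global), nodes
  from (node, mean incoming edge, global), the global state from the
  means of both. Mean aggregation over an empty edge set is defined as
  zero.

Both variants end in global attention pooling (softmax over a learned
per-node gate, weighted sum of transformed features) and are permutation
invariant end to end — exactly for the MetaLayer, and for the transformer
whenever TopK scores are tie-free (the tie-break is index-based, so
pathological all-equal scores can break invariance; real feature matrices
do not produce them).

Training minimises a weighted L1 loss. The weights are the inverse
frequency of the true score over ten equal bins of (0,1), normalised to
mean one — the standard correction for the skew of quality-score
distributions, adopted here as our choice since no more specific weighting
was available to follow. One backbone is trained per score type (fold
vs interface), mirroring how the two categories are assessed separately.
Optimisation is Adam (lr 10⁻³ default) with AutoClip: the gradient norm
is clipped to the 10th percentile (default) of the full norm history,
computed with R's default linear-interpolation quantile; the first step
is never clipped. A single integer seed controls initialisation, data
order and dropout.

Layer counts, hidden sizes and pooling ratios of the originally deployed
models are not public; the defaults here (2 layers, hidden 16, 2 heads,
ratio 0.8) are desk-scale and config-overridable.

## Energy-based regression in logit space

The energy net f(X, y) takes the concatenated (embedding, logit) pair
through fully connected layers with dropout, ReLU, optional LayerNorm,
and skip connections that re-concatenate the input logit before each of
the first `skip_depth` hidden layers. Its scalar output is an energy:
lower means more compatible. Scores live in (0,1); all sampling and
density evaluation happen after mapping through the logit (with scores
clamped to [ε, 1−ε], ε = 10⁻⁶, so the transform is finite and the
sigmoid/logit round trip is exact to 10⁻⁹ inside the clamp). The
governing convention — densities in logit space — is stated here because
the transformation alone does not pin it down.

Training is noise-contrastive: for example i with true score yᵢ, the
noised true target is logit(yᵢ) + ν, ν ~ N(0, β σ²), and M−1 adversarial
logits are drawn from N(logit(yᵢ), σ²). The loss is the negative log
probability of identifying the true column under the density-corrected
softmax over all M samples, computed with log-sum-exp. The objective is
written on f = −E so minimising it pushes the true target's energy down;
inference returns the minimum-energy score over a grid of `grid_n`
evenly spaced values (k−½)/grid_n, ties resolved toward the smaller
score.

The proposal width σ *slides* with the true score:
σ = (logit(μ+γ) − logit(μ)) / z if μ+γ < 1, else the mirrored lower
branch, where z is the standard-normal third quartile. We compute z with
`qnorm(0.75)` ≈ 0.6745 rather than hard-coding the rounded 0.675; both
are accepted by the tests to three decimals. This keeps the proposal's
quartiles approximately ±γ around μ after mapping back to (0,1),
compensating for the logit's asymptotes. σ is evaluated after clamping
μ±γ, so it is finite and positive everywhere in (0,1).

Defaults — M = 65 (64 adversarial), β = 0.05, γ = 0.1, grid_n = 1000,
skip depth 2, hidden 32+32 — are not prescribed anywhere authoritative;
they follow common practice in energy-based regression and were fixed
once, before any benchmarking, as the package's study conditions. K (the
number of proposal mixture components) is fixed at 1. One published
inconsistency deserves note: the contrastive sum is written elsewhere
both over M and over M+1 terms; this package defines M as the *total*
number of samples including the noised true target, which is the reading
consistent with "M−1 adversarial samples" and with the constant-input
identity J = ln M.

## Ranking metrics

The ranking loss for a target is S(best) − S(predictor's top), on true
scores. A predictor's top pick is accepted only when its top *predicted*
score is unique among its predictions for that target; otherwise the
loss is recorded as the sentinel 0.1 ("not less than 0.1") with a flag.
Because the aggregation used by published leaderboards is not fully
specified, summaries expose both the mean-with-sentinels and the count
of targets with loss below the sentinel.

NDCG@3 uses relevance rᵢ = 1 − (S(M) − S(mᵢ))², zeroed when mᵢ's true
score is not unique, discounted by 1/log₂(i+1) over the top three, and
normalised by the true ranking's DCG@3. We read the reference model M as
the model with the highest *true* score of the target — the only reading
under which the true ranking attains exactly 1 — and flag this as an
interpretation. Ties (in true or predicted scores) are broken by model
id; targets with fewer than three models sum over the available
positions with the normalisation unchanged; a target whose scores are
all duplicated has an undefined NDCG and is reported as missing (NA),
counted as 0 in leaderboard sums.

## Synthetic data: what it emulates, what it does not

The generator builds parallel ideal helices (100°/residue, 1.5 Å rise)
placed in contact, perturbs them per chain with bounded rigid motions
plus Gaussian jitter, and labels decoys with two stand-ins: a TM-style
fold score (Kabsch superposition on CA with *fixed* residue
correspondence, d₀ = 1.24(L−15)^⅓ − 1.8 floored at 0.5 Å) and a Jaccard
overlap of cross-chain contact sets for interfaces. These are
deliberately named `fold_label` / `interface_label`, not TM-score or
QS-score: they preserve the (0,1) scale, the invariances (rigid motion;
exact 1 for an unperturbed copy) and the monotone degradation with
perturbation magnitude that training and evaluation code need, but they
perform no alignment search and no biologically calibrated interface
weighting. Perturbation magnitudes (defaults: ≤10° rotation, ≤2 Å
translation, 0.2 Å jitter, graded by a uniform scale per decoy) are the
package's own realistic-deformation choices; published decoy-generation
magnitudes are not available.

Passing tests on this data therefore demonstrate that the machinery is
correct — shapes, invariances, gradients, metric algebra, trainability —
not that the method reaches any particular accuracy on real CASP models,
which would require real structures, real feature providers and
GPU-scale training.

Two recovery datasets make trainability measurable at desk scale. The
embedding dataset draws X ~ N(0, I₁₆) and sets
score = σ(w·x) (noise-free by default); an energy net trained with the
contrastive objective on n = 2000 examples reaches held-out
grid-inference MAE < 0.05 in well under a minute. The graph dataset
labels toy dimers with their interface-residue fraction — spread across
(0,1) by varying chain separation — and a small transformer backbone
reaches validation L1 < 0.1 within a few minutes. These sizes (2000
embeddings; 100 graphs of ~24 residues; 10–15 epochs) are the package's
chosen study conditions for its acceptance checks.

## Numerical choices and degenerate inputs

* Scores clamped to [10⁻⁶, 1−10⁻⁶] before any logit; log-sum-exp for the
  contrastive loss; segment softmax in attention shifted by per-node
  maxima.
* Zero-length geometric vectors yield 0-valued features with a warning
  rather than NaN; empty neighbourhoods aggregate to zero; TopK always
  retains at least one node.
* The L1 subgradient at zero residual is taken as 0.
* Checkpoints embed their config and width metadata; scoring refuses
  mismatched feature widths or embedding dimensions rather than
  silently recycling.

## Known limitations

Single-model scoring only (no consensus mode); PDB input only (no
mmCIF), first model, protein chains only; synthetic providers carry no
real evolutionary or energetic signal; the brute-force grid bounds
inference precision by 1/(2·grid_n); and the transformer's permutation
invariance assumes tie-free pooling scores. Gradient-based (Langevin)
inference and K > 1 proposal mixtures are deliberately out of scope.
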