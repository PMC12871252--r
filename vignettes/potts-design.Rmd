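---
title: "Learning Potts energy models from protein backbones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning Potts energy models from protein backbones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pottsfold)
```

## The model

Inverse protein folding asks for sequences `s` compatible with a fixed
backbone `f`. Most sequence-design networks learn only per-site amino-acid
distributions and are judged by native sequence recovery (NSR): the
fraction of positions at which a design matches the native sequence. That
objective is blind to the pairwise physics — hydrogen bonds, packing, salt
bridges — through which stability actually arises. `pottsfold` instead
trains a graph network to emit an explicit *Potts model* over the backbone:

$$H(s) = \sum_i h_i(s[i]) + \sum_{(i,j) \in E} J_{ij}(s[i], s[j]),$$

with one 20-vector of self-energies per residue and one 20×20 pair-energy
table per edge of a k-nearest-neighbour residue graph. `H` is a
log-compatibility score (`softmax(H)` over sequences is a probability;
higher is better — negate for a physical energy). Everything downstream —
conditionals, ΔΔG predictions, local optimization — is a difference or a
softmax of `H`, and therefore invariant to the per-site gauge freedom of
Potts parameterizations; for that reason no gauge fixing is applied
anywhere.

### Architecture

The backbone is featurized as a directed k-NN graph (default `k = 48`,
CA-distance ordered, ties to the lower residue index). Each directed edge
carries 16 Gaussian radial basis activations (centers evenly spaced on
2–22 Å, width = spacing) for all 25 ordered atom pairs among
N, CA, C, O and a *virtual C-beta* placed from ideal tetrahedral geometry
— a fixed linear combination of the N–CA and C–CA bond vectors and their
cross product, so glycine is treated like every other residue — plus a
±32-clipped signed sequence-offset one-hot and a same-chain bit. Node
features start as null vectors.

A three-layer message-passing encoder (hidden width 128, dropout 10% in
training) updates nodes and edges; self-edges (i → i) ride along with the
neighbour edges. A single shared linear layer then maps every final edge
embedding to a flattened 20×20 table: the two directed tables of a pair
are averaged (one transposed) into the symmetric `J_ij` — the minimal
symmetric reduction, pinned by tests — and the diagonal of each self-edge
table supplies `h_i`. A three-layer autoregressive decoder produces
per-site logits whose causal structure follows a fixed, seeded random
decoding order per protein (keyed by global seed and protein identifier,
so every variant and replicate sees the same order).

Because no automatic-differentiation framework is available to R here,
the package includes a small reverse-mode tape (`R/autodiff.R`) over dense
matrix primitives; its gradients are finite-difference-checked in the test
suite, end to end through the encoder, decoder, Potts head and losses.

### Losses

Four objectives are implemented:

* **Node NLL** `L_V`: −(1/2000) Σ log P(s[i] | f, s[≺i]) over teacher-forced
  decoder logits. The 1/2000 constant is kept verbatim from the published
  objective even though it makes `L_V` scale with protein length while
  `L_E` does not — that asymmetry is part of the objective, not a bug.
* **Edge composite pseudo-likelihood** `L_E`: −(1/n_edges) Σ over
  undirected edges of the log-probability of the native pair under the
  400-way conditional given native residues at all other sites.
* **Single-site Potts NLL** `L_{E,ss}`: the 20-way conditional from the
  Potts model (self-energy plus pair terms to native neighbours, never
  conditioning on the site itself), −(1/2000)-summed.
* **MSA-averaged loss**: the mean of the variant's components over
  homologous sequences, each teacher-forced *with itself* (the conditioning
  prefix is the homolog, not the native sequence) and gap-masked.

Model variants gate components: `full` = `L_V + L_E` equally weighted,
`potts_only` = `L_E`, `potts_single` = `L_{E,ss}`, `node_only` = `L_V`.
Variants without a decoder carry no decoder parameters at all.

**Gap masking.** A gapped alignment position removes itself from the node
loss and every incident edge from the edge loss, and contributes nothing
to any conditional's conditioning sum. Under masking `L_E` is normalized
by the number of edges actually summed (keeping it a mean of its terms);
normalizing by the structural edge count is available as an option since
the published edge loss predates gap masking.

### Training recipe

Adam (β₁ = 0.9, β₂ = 0.98, ε = 1e-9) under the warm-up schedule
`lr = d^{-1/2} · min(step^{-1/2}, step · warmup^{-3/2})` with 4000 warm-up
steps at full scale; batches pack proteins until the 10,000-token budget
is crossed (the crossing protein is included — "until the total exceeds");
in MSA mode each batch is one protein with alignment rows subsampled
without replacement under the same budget. Gaussian coordinate noise
(σ in Å, fresh i.i.d. draw per backbone atom per axis per example per
step) is applied on the training path only; virtual C-betas are placed
after noising; validation always sees clean coordinates. Validation runs
per epoch and the best-validation checkpoint is returned. A cluster table
(`cluster_id → members`) can be supplied to re-draw one member per cluster
every two epochs, mirroring sequence-cluster resampling at PDB scale.

## Sequence generation and local optimization

Sampling draws residues site by site in the fixed decoding order from
`softmax(logits / T)` (default `T = 0.1`; `T ≤ 1e-6` is treated as the
argmax limit, which makes the greedy mode independent of the RNG even
under floating-point near-ties). Potts-guided local optimization then
revisits sites in the same order; at each site all 20 candidates are
scored by the single-site conditional — which by construction excludes
the incumbent's own terms ("current identity masked") — and the best is
installed before moving on. Ties keep the incumbent, and non-incumbent
ties resolve alphabetically; together with strict improvement this makes
convergence-mode termination a theorem (the score is bounded and strictly
increases per change), which the suite exercises on 500 random instances.
A single-site-scored variant re-evaluates the decoder per candidate (the
expensive alternative, retained for comparison).

## ΔΔG prediction

`ddg_potts()` scores a point mutation incrementally,
`h_i(mut) − h_i(wt) + Σ_{j∈N(i)} [J_ij(mut, s_j) − J_ij(wt, s_j)]`, which
equals the full `H(mut) − H(wt)` to 1e-9 (a two-path identity the tests
assert). The node scorer compares summed teacher-forced log-probabilities
of mutant and wild type under the same decoding order. Predictions are
positive-stabilizing; a sign flag accommodates datasets with the opposite
experimental convention. Reports carry both pooled Pearson r and mean
per-protein r (computed only where ≥ 3 scored mutations exist), since
dataset-level correlation can be read either way.

Inference-time neighbour ablation (`ablate_neighbors()`) retains each
site's m nearest or furthest partners by CA distance; a pair survives if
either endpoint retains it (so "each residue keeps its m nearest
neighbours" holds literally; dropping orphaned pairs is available behind
the `orphan` flag).

## MSA handling

A3M parsing records lowercase insertions per row (fraction over the
pre-removal row length) and strips them; every retained row then has the
query length. Filtering defaults to the empirically best thresholds: 50%
minimum identity, 20% maximum insertions, 20% maximum gaps. Identity is
computed in the query frame after insertion removal, with query length as
denominator and gaps counted as mismatches — the strictest common
convention; the query itself is always retained. Filtering is idempotent
and monotone in the identity threshold (property-tested). Subsampling
takes a uniform random subset capped at `floor(budget / query_length)`
rows.

## What the synthetic generators emulate — and what they do not

`make_synthetic_backbone()` builds ideal-geometry poly-alanine chains from
internal coordinates (standard bond lengths and angles, trans peptide
bonds), with helix, strand, or hairpin dihedrals; the hairpin's
two-residue turn was chosen so the strands pair at ~5 Å without steric
overlap. A seeded ±8° phi/psi jitter makes fixtures structurally distinct
while consecutive CA–CA distances stay at 3.80 ± 0.1 Å. `make_toy_msa()`
produces alignments whose expected identity, gap and insertion rates are
exact by construction. These fixtures give the tests analytic ground
truth; they do *not* contain side-chain packing, loop irregularity,
missing density, or the evolutionary covariation of real MSAs, so passing
tests certify the machinery (featurization, losses, gradients,
optimization), not biological accuracy of a trained model — which at
published scale requires GPU training on structure databases and external
structure-prediction/physics pipelines that are out of scope here
(designs are exported as FASTA for such tools).

## Desk-scale study conditions

The heavier checks run at sizes chosen so the whole suite fits on one CPU
core in minutes, stated here as the package's own configuration:

* **Pseudo-likelihood recovery**: an 8-site, 4-letter, fully connected
  Potts model (h ~ N(0, 0.5²), J ~ N(0, 0.3²)), 10,000 Gibbs samples
  (10 chains, 100-sweep burn-in, thinning 3), free (h, J) tables fitted by
  300 full-batch Adam iterations at lr 0.05 with analytic gradients, and
  the fitted vs true total energies compared over all 4⁸ = 65,536
  sequences. Fitted energies match the true landscape up to gauge
  (Pearson r ≈ 0.99 at this sample size).
* **Tiny overfit**: five 30-residue synthetic folds (two helices, one
  strand, two hairpins) with random native sequences, trained with the
  `full` variant at hidden width 64, k = 16, feed-forward multiplier 2,
  ReLU activations, and 100 warm-up steps (≈20% of the step budget, the
  same proportion the full recipe uses), 350 steps clean and 100 steps at
  σ = 0.2. The clean run memorizes its training set (greedy NSR 100%,
  > 99.9% loss drop); the noisy run's final training loss exceeds its
  clean-coordinate validation loss, the signature that noise perturbs only
  the training inputs.

## Numerical choices and degenerate inputs

Softmaxes subtract the row maximum before exponentiation. Layer
normalization uses ε = 1e-5. Distances of residue pairs with any missing
atom are set to 0 before RBF expansion and the edge is masked out of
aggregation and losses; invalid residues stay in the chain (preserving
author numbering) but never enter neighbour lists or NSR denominators.
Altloc records resolve to the highest occupancy, first on a tie.
`k_eff = min(k, n_valid − 1)`, so three-residue chains simply get two
neighbours each. An all-gap MSA row contributes nothing and is counted in
the report; zero unmasked edges define `L_E = 0` with a warning. Potts
containers and checkpoints are single-file RDS archives with a format tag,
version, and the frozen alphabet (alphabetical one-letter order) in the
header; loading verifies all three.

## Known limitations

* Training at published scale (hundreds of epochs over tens of thousands
  of chains) is out of reach of a pure-R tape on one CPU; the package
  reproduces the objectives, recipe and inference exactly, at desk scale.
* Sequence-structure self-consistency scoring (structure prediction,
  threading + relax) is external by design; only FASTA export is provided.
* MSA construction itself (profile searches) and homolog reweighting are
  out of scope; parsers expect A3M/aligned FASTA.
* The k-NN graph is the only coupling topology; couplings beyond it, and
  triplet terms, are deliberately not representable.
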