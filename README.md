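# pottsfold

Protein sequence design that learns an explicit energy function, not just
per-site residue preferences. `pottsfold` trains a k-nearest-neighbour
graph neural network to read a protein backbone and emit a **Potts
model** —

```
H(s) = Σ_i h_i(s[i]) + Σ_(i,j)∈E J_ij(s[i], s[j])
```

— one self-energy 20-vector per residue and one symmetric 20×20
pair-energy table per edge of the residue graph, extracted from the final
edge embeddings (self-edges included) by a single shared linear layer. An
autoregressive decoder on the same encoder produces per-site amino-acid
distributions for sequence generation. Training combines the node
negative log-likelihood `L_V` with the edge **composite pseudo-likelihood**
`L_E` (the probability of each native residue pair under the 400-way
conditional given the native residues elsewhere), equally weighted, with
optional Gaussian coordinate noise and optional averaging over filtered
multiple sequence alignments. The Potts output drives local sequence
optimization and ΔΔG stability prediction
(`ΔΔG_pred = H(s_mut) − H(s_wt)`, positive = predicted stabilizing).

The package is aimed at structural bioinformaticians who want an
energy-based view of inverse folding on a plain CPU: every operation —
featurization with virtual C-beta atoms, the message-passing network (on
a built-in reverse-mode autodiff tape), the four losses with gap masking,
MSA filtering, autoregressive sampling, Potts-guided optimization,
mutation scoring — is exposed as a documented R function with
oracle-backed tests.

## Worked example

Train the full variant on one synthetic 30-residue beta-hairpin until it
memorizes its native sequence, then design, optimize and score mutations:

```r
library(pottsfold)

bb <- make_synthetic_backbone(30, "hairpin", seed = 1)
g  <- build_knn_graph(bb, k = 16)
native <- int_to_aa(pottsfold:::with_seed(101, sample(20, 30, replace = TRUE)))
ds  <- list(list(id = bb$id, structure = bb, sequence = native))

cfg  <- model_config(hidden_dim = 64, k = 16, ff_mult = 2, activation = "relu")
tcfg <- train_config(warmup_steps = 50, epochs = 80, seed = 1, validate_every = 10)
run  <- fit(init_model_params(cfg, seed = 0), cfg, ds, ds, tcfg)
tail(run$log[, c("epoch", "train_LV", "train_LE", "train_total", "val_total")], 1)
#>    epoch train_LV train_LE train_total val_total
#> 80    80 0.000669  9.1e-06    0.000678  0.000363

d <- sample_sequence(run$params_best, cfg, g, temperature = 0, seed = 1)
native_sequence_recovery(d$sequence, native)
#> [1] 1
```

The per-epoch log shows both components of the composite loss: `train_LV`
is the decoder's negative log-likelihood of the native residues
(−(1/2000)·Σ log P, so 0.00067 means near-certainty at every site) and
`train_LE` the edge pseudo-likelihood (ln 400 ≈ 5.99 for an untrained
model, here ≈ 0). Greedy decoding recovers the native sequence exactly
(NSR = 1).

```r
pm  <- extract_potts(encode(g, run$params_best, cfg), cfg)
pm
#> <potts_model: 30 sites, 279 undirected edges>
opt <- local_optimize(pm, d, mode = "to_convergence")
c(opt$sweeps, opt$potts_score_final - opt$potts_score_initial)
#> [1] 1 0
```

Local optimization sweeps the sites in the decoding order, scoring all 20
candidates per site by the Potts conditional; here it confirms in one
sweep that the design is already a local optimum (no favourable
substitution, score unchanged at 336.05).

```r
mr <- parse_mutation("D5A")
score_mutations(pm, native, list(mr), scorer = "potts")$predictions
#>   protein_id mutation position predicted ddG_expt
#> 1       <NA>      D5A        5 -16.00781       NA
```

The memorized energy landscape predicts mutating the native aspartate at
position 5 to alanine is strongly destabilizing (score difference −16.0;
the sign convention is positive-stabilizing).

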