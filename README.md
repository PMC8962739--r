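# pocketgen

Pocket-conditioned generative modeling of drug-like molecules in R.

Given the atoms lining a ligand binding site, `pocketgen` learns the
conditional distribution **P(molecule | pocket)** and samples candidate
binders for a target pocket. It is aimed at computational chemists and
method developers who want a transparent, fully testable implementation of
the encoder-decoder approach to structure-conditioned molecule generation:
every component — featurization, the graph encoder, the sequence decoder,
the token grammar, training and the evaluation protocol — is plain R,
deterministic under seeds, and covered by oracle-backed tests.

## The model

A pocket (PDB `ATOM`/`HETATM` records) becomes a graph: nodes are
non-hydrogen atoms, edges connect pairs within 4.5 Å. Node *i* carries
features *x_i* = (hydrophobicity, charge, binding propensity, SASA,
sequence entropy, x, y, z) with coordinates normalized to principal axes;
the edge attribute *e_ij* is the bond multiplicity for covalent pairs, 0
for contacts.

The encoder applies K layers of edge-conditioned, multi-channel message
passing

> x_i^(k) = h_θ ( concat_c ( (1 + ε_c) · x_i^(k−1) + Σ_{j∈N(i)} h_ωc(e_ij) · x_j^(k−1) ) )

with per-channel trainable ε_c and a two-layer edge network h_ωc,
jumping-knowledge concatenation across layers, and a Set2Set attention
readout giving a fixed-size, node-order-invariant embedding.

The decoder is a GRU over SELFIES tokens modeling

> P(molecule | pocket) = P(s_0 | pocket) · Π_t P(s_t | pocket, s_0 … s_{t−1})

where s_n is `<eos>`; the projected graph embedding is the step-0 input.
Training minimizes the negative log-likelihood L = −Σ_t log P(s_t)
end-to-end through both halves. The token grammar is total: *any* token
sequence — even uniformly random — decodes to a valid molecule, so the
model cannot emit broken strings.

Sampled molecules are canonicalized, ranked by sampling frequency, and
scored against label ligands by the Tanimoto coefficient over ECFP4
fingerprints, with hit rates at TC ≥ 0.7/0.8/0.9/1.0 and Fisher-Pitman
permutation tests for group comparisons.

## Worked example

Build a planted 8-pocket fixture, train a small model, and inspect what it
generates:

```r
library(pocketgen)

ds <- make_planted_dataset(k = 8, seed = 7)     # 8 pockets, 8 distinct ligands
enc <- encoder_config(num_layers = 2, num_channels = 4, hidden_dim = 16)
model <- fit_model(ds, enc, epochs = 150, lr = 5e-3, batch_size = 4,
                   seed = 11, target_recovery = 1)

greedy_recovery(model, ds)$rate
#> [1] 1

s <- sample_batch(ds$pairs[[2]]$graph, model, n_total = 20480,
                  batch_size = 2048, seed = 3)
attr(s, "n_batches")
#> [1] 10
head(frequency_rank(s), 3)
#>   rank   smiles frequency
#> 1    1  CC(=O)O     19983
#> 2    2 CN1CC1=O       206
#> 3    3  CC(=O)N        51

max_tc_score(s, ds$pairs[[2]]$smiles)$best_tc
#> [1] 1
```

The recovery rate of 1 means greedy decoding returns the exact label
ligand (canonical match, TC = 1.0) for all 8 pockets — the model has
learned the planted pocket→ligand mapping through the encoder, not just a
marginal distribution over molecules (an unconditional baseline trained
with a constant embedding decodes one string for every pocket and cannot
exceed 1/8). The frequency table shows the conditional distribution
concentrating on the true binder of pocket 2 (acetic acid, sampled 19,983
times out of 20,480) with a thin tail of related molecules.

A thin CLI over the same functions lives at `inst/cli/pocketgen.R`
(`featurize`, `make-fixtures`, `train`, `sample`, `evaluate`).

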