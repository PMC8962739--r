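---
title: "Pocket-conditioned molecular generation: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pocket-conditioned molecular generation: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Given the atoms lining a small-molecule binding site, which molecules are
likely to bind there? `pocketgen` treats this as conditional sequence
modeling: it learns `P(molecule | pocket)` from pocket/ligand pairs and
samples candidate binders for new pockets. The architecture follows the
encoder-decoder pattern familiar from image captioning:

1. **Featurization.** A pocket (PDB `ATOM`/`HETATM` records) becomes a graph
   whose nodes are its non-hydrogen atoms and whose edges connect atom pairs
   within 4.5 Å. Each node carries eight features: Kyte-Doolittle
   hydrophobicity, formal side-chain charge, a binding-site propensity,
   Shrake-Rupley solvent-accessible surface area, per-residue sequence
   entropy, and the three coordinates after centering at the origin and
   rotating onto the principal axes. The edge attribute is the bond
   multiplicity for covalently bonded pairs and 0 for non-covalent contacts.
2. **Encoder.** K layers of edge-conditioned multi-channel message passing:
   per channel c, node i updates to
   `(1 + eps_c) x_i + sum_{j in N(i)} h_wc(e_ij) x_j`, where `eps_c` is a
   trainable scalar (initialized at 0) and `h_wc` is a two-layer network
   mapping the scalar edge attribute to a neighbor weight. Channels are
   concatenated and transformed by an update network `h_theta`. The
   per-layer outputs are concatenated (jumping-knowledge aggregation) and
   read out by Set2Set attention into a fixed-size embedding of length
   `2 * K * H`, invariant to node order.
3. **Decoder.** A GRU over SELFIES tokens. The graph embedding, linearly
   projected to the token-embedding width, is the input of step 0 (the
   hidden state starts at zero); later steps consume the embedded previous
   token. Training minimizes the negative log-likelihood
   `L = -sum_t log P(s_t)` of the label ligand under teacher forcing, where
   the final token `s_n` is `<eos>`; batches reduce by the mean of
   per-sequence sums. Inference samples autoregressively until `<eos>`.

Both halves are trained jointly: gradients of the sequence loss reach every
encoder parameter (this is asserted by the test suite).

## Tokenization

Molecules are interconverted between SMILES and a SELFIES-family token
grammar implemented in the package. Decoding is *total*: branch and ring
constructs that cannot apply in context are skipped, and bond orders are
capped by the remaining valence of the atoms involved, so every token
sequence - including uniformly random ones - derives a chemically valid
molecule. This is the property that makes the grammar attractive for
generative models: the model cannot produce syntactically broken strings.
The grammar covers neutral molecules over C, N, O, S, P, F, Cl, Br and I
with standard valences; charges, isotopes and stereochemistry are out of
scope (the built-in ligand library respects these limits). Aromatic input
is kekulized through OpenBabel before encoding, and canonical molecule
identity - used for deduplication, frequency ranking and label-recovery
checks - is OpenBabel's canonical SMILES, fixed once for the whole package.

There is no start-of-sequence token: the projected graph embedding occupies
the first input slot, so the alphabet needs only `<eos>` (index 1) and
`<pad>` (index 0). The per-step distribution masks `<pad>` to probability
zero everywhere (teacher forcing and sampling alike); with that convention
the probabilities of all terminated sequences plus the truncation mass sum
exactly to one, which the test suite verifies by exhaustive enumeration on
a tiny decoder.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| contact cutoff | 4.5 Å | pocket graph edge distance |
| covalent threshold | 1.9 Å (2.1 Å with S) | contact pairs classified covalent |
| SASA probe / points | 1.4 Å / 960 | Shrake-Rupley water probe, sphere sampling |
| K, C, H | 4, 8, 64 | encoder depth, channels, width |
| Set2Set steps | 3 | readout iterations |
| GRU hidden / token embedding | 512 / 128 | decoder capacity |
| max sequence length | 140 tokens | covers drug-like molecules |
| learning rate / clip | 1e-3 / 5 | Adam step size, global-norm clip |
| test fraction | 0.10 | random held-out split |
| SA window | (1, 6) open | synthetic-accessibility filter |
| fingerprint | ECFP4 (OpenBabel) | Tanimoto similarity bits |

Defaults are sized for desk-scale experiments and are configuration, not
claims about any reference system. The residue property table ships as an
editable TSV (20 standard amino acids plus an explicit `UNK` row, all
zeros, to which unknown residue types resolve); sequence entropy defaults
to zero when no alignment profile is supplied, since an entropy column
requires a multiple-sequence alignment the tool cannot fabricate.

## The synthetic fixtures and what they show

`make_planted_dataset()` builds `k` pockets with 50-90 heavy atoms
(compact random clusters with 1.2-2 Å nearest-neighbor spacing, residue
labels from the 20 standard codes) and pairs pocket i injectively with
ligand i from a built-in library of 23 drug-like molecules spanning 3-30
heavy atoms. The planted signal is the residue composition: with signal
strength 1 (the default study condition) every residue of pocket i takes a
pocket-specific residue type, so the residue-level feature channels
separate the pockets cleanly; with strength 0 all pockets draw from one
uniform distribution and are statistically indistinguishable - the null
control. The signal lives only in features the encoder can see, never in
identifiers.

The overfit-recovery experiment is the desk-scale stand-in for large-scale
hit-rate benchmarking: a small model (K = 2, C = 4, H = 16, GRU hidden 128,
embedding 32, Adam at 5e-3, batches of 4) trained for up to 150 epochs on
the planted 8-pocket fixture must greedily decode the exact label ligand
(canonical match, Tanimoto coefficient 1.0) for at least 7 of 8 pockets,
while an unconditional baseline - the graph embedding replaced by a
constant - collapses to a single output and cannot exceed 1 of k distinct
labels. Passing shows that the model learns `P(molecule | pocket)` through
the encoder rather than just `P(molecule)`. It does *not* show that the
same architecture attains any particular hit rate on real, curated
pocket libraries: real pockets have correlated geometry and chemistry,
labels are not unique per pocket, and generalization (rather than
memorization) is the quantity of interest there.

A frozen-encoder ablation was considered and rejected: with a frozen
randomly initialized encoder the pocket embeddings are still distinct
constants, and the decoder's trainable input projection can memorize a
mapping from distinct constants just as well, so failure of that ablation
is not a property of the architecture. The null-control dataset
(signal 0) and the constant-embedding baseline are the informative
controls.

## Evaluation protocol

For each pocket, molecules are sampled in batches (default 2,048 per
batch; 20,480 total is ten batches), decoded, canonicalized and
deduplicated; truncated (non-terminated) samples are excluded from
ranking but counted. Candidates are ranked by sampling frequency with
deterministic lexicographic tie-breaking, and the top 100 retained.
Similarity to the label ligand uses the Tanimoto coefficient over binary
ECFP4 fingerprints (radius-2 circular, as produced by OpenBabel; the
fingerprint name is configurable). Hit rates report the percentage of
pockets whose best sampled TC reaches 0.7 / 0.8 / 0.9 / 1.0. Group
comparisons use the Fisher-Pitman permutation test on the mean
difference: exhaustive over label assignments when their number fits the
permutation budget, Monte-Carlo with the +1/+1-corrected estimator (so
p > 0) otherwise. Pocket-size/ligand-size structure is summarized by
quartiles (type-7 linear interpolation) of ligand heavy-atom counts within
pocket-size bins <100, 100-160, 161-220 and >220 atoms.

## Numerical choices

* All computation is double precision; reported tolerances (1e-6 for the
  dense message-passing oracle, 1e-5 for permutation invariance, 1e-9 for
  centering) reflect accumulation order, not precision limits.
* The principal-axis rotation resolves its sign ambiguity by forcing the
  largest-magnitude coordinate along each axis positive; degenerate clouds
  (< 3 atoms or rank-deficient spread) fall back to centering only and are
  flagged.
* SASA uses a deterministic golden-spiral point lattice, so results are
  reproducible to the bit; the one-sphere closed form 4*pi*(r+probe)^2 is
  met to sampling resolution (< 2%).
* Parameter initialization is Glorot-scaled Gaussian under recorded seeds;
  `eps_c` starts at 0 so the first forward pass is an unweighted
  self-plus-neighbors aggregation. Checkpoints store configs, every
  parameter, the vocabulary, the feature scaler and all seeds; reloading
  reproduces losses bit-exactly on CPU.
* Node features are standardized (per-column mean/sd over the training
  graphs) before entering the encoder; the scaler is part of the model.
* Training aborts with a diagnostic if the loss becomes non-finite;
  gradient norms are clipped at 5.
* Sequence sampling is vectorized across a batch; the per-step categorical
  draw uses a row-wise inverse-CDF so a single seed reproduces the full
  multiset.

## Problem sizes used by the test and acceptance runs

Unit tests run on 12-40-atom pockets and 2-6-layer toy models. The
acceptance suite trains the 8-pocket recovery experiment (~1 minute),
checks grammar totality on 10,000 random sequences, calibrates the
permutation test on 1,000 null replicates, and exercises the 20,480-sample
protocol (ten 2,048-molecule batches) on a small trained model. These
sizes were chosen so the entire suite completes comfortably on one CPU
while still exercising every code path at the sizes the method's protocol
prescribes.

## Known limitations

* The SELFIES dialect is a self-contained subset (no charges, isotopes,
  stereocenters, or aromatic tokens; rings close with single or double
  bonds). Molecules outside it are rejected at encoding time with explicit
  errors.
* Synthetic pockets are geometrically plausible clusters, not physical
  protein sites; SASA, contacts and features are computed faithfully on
  them, but no claim about docking-quality realism is made.
* The bundled SA estimator is a crude size/topology heuristic; supply your
  own scores for serious filtering.
* Absolute Tanimoto values depend on the fingerprint; a different
  fingerprint choice shifts hit rates systematically.
* Training is plain R on CPU and sized for small corpora; the package
  favors transparency and testability over throughput.
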