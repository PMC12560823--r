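---
title: "Substructure-aligned multimodal pretraining: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Substructure-aligned multimodal pretraining: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A small molecule carries the same chemistry in three encodings: the 1D
SMILES string, the 2D bonded graph, and the 3D conformer. Self-supervised
pretraining can exploit all three, but when the three views are corrupted
independently the *same* region of the molecule tends to be hidden in
several views at once, so the model can trivially copy information across
modalities instead of learning complementary structure. `molfuse`
implements a pretraining scheme built around one idea: corrupt
*substructures*, and never the same substructure in two modalities.

The unit of corruption is a substructure fragment from a frequency-learned
vocabulary. Because every fragment is aligned to an explicit set of atom
indices, "mask this substructure" has a concrete meaning in all three
views: mask its token (1D), mask its atoms' feature rows (2D), or jitter
its atoms' coordinates (3D). Bond-level alignment is deliberately avoided
— single bonds are usually implicit in SMILES, so atoms are the only
reliable join key between the string, the graph and the conformer.

# Tokenization and alignment

The vocabulary is learned by byte-pair encoding over *atom-level units* of
canonical SMILES: one unit per atom token, with bond symbols, ring-closure
digits and parentheses attached to the preceding atom's unit so that units
concatenate back to the exact input string. Adjacent units are repeatedly
merged, most frequent pair first (ties: higher frequency, then the
byte-order-smaller merged string, making the build independent of corpus
order), subject to a minimum pair frequency (`minFrequency`, default 2)
and a vocabulary cap (`maxSize`, default 2048).

Tokenization replays the merges in learned order, so each fragment's atom
set is the union of its units' atoms. The resulting atom sets are pairwise
disjoint and cover every heavy atom — the invariant all perturbation and
pooling code relies on. SMILES are canonicalized (OpenBabel) once at
record construction; canonicalization is idempotent, so stored records
tokenize in their stored atom order.

On tiny corpora BPE merges run away: a 64-molecule corpus will happily
merge whole molecules into single fragments, leaving nothing to perturb.
The shipped demonstrations therefore cap the vocabulary at `maxSize = 30`
(about ten merges over ~18 base units), which keeps the median fragment
count per molecule around 4–6. This is a property of desk-scale corpora,
not of the method; with millions of molecules the frequency structure
caps fragment growth naturally.

# Non-overlapping perturbation

Given fragment count `e` and per-modality ratios `(r1d, r2d, r3d)`, the
planner selects `floor(r * e)` fragments per modality, uniformly without
replacement, in the order 1D → 2D → 3D, with each later modality drawing
only from fragments not yet selected. Counts are truncated by pool
availability, and `floor` means small molecules may receive no
perturbation in some modality — accepted, rather than over-perturbing
3-atom molecules.

The default ratio is 0.25 per modality. The natural-looking 0.15 of
masked-language-modelling practice refers to *tokens*; here the unit is a
multi-atom substructure, so 0.25 of substructures corresponds to roughly
10–15% of atoms at desk-scale fragment counts — and `floor(0.15 * e)` is
0 for nearly every desk-scale molecule, which would silence two of the
three objectives entirely.

Per-molecule randomness is derived by hashing `(global seed, molecule id,
step)`, so batch composition and ordering cannot change which views a
molecule sees — a requirement for the bitwise-reproducibility contract.

The three perturbations are strictly local: token ids at selected
positions are replaced by the mask id; feature rows of covered atoms are
replaced by a *learned* mask embedding (zeros would collide with
legitimate feature encodings); covered atoms' coordinates receive i.i.d.
Gaussian noise with `sigma = 0.1` Å per axis (small against ~1.5 Å bond
lengths). Everything not selected is bit-identical to the clean view.

# Encoders, fusion, decoders

All trainable components run on a small reverse-mode autodiff tape
written for this package (no automatic-differentiation library is
available in the target environment); every layer's gradient is validated
against central finite differences in the test suite.

* **1D** — token + learned positional embeddings into a pre-norm
  transformer encoder (default 2 layers, 4 heads).
* **2D** — GIN-style message passing with edge-feature injection
  (3 layers); permutation-equivariant by construction.
* **3D** — directional message passing: messages live on directed edges
  within a 5 Å cutoff, carry a Gaussian radial basis (8 functions) over
  distances, and are updated from incident edge pairs weighted by a
  cosine angular basis (4 functions) at the shared atom. Using only
  distances and angles makes the encoder exactly invariant to rigid
  motions. Atoms with no neighbour inside the cutoff fall back to a
  self-feature embedding, with a warning.
* **Fusion** — each modality's rows receive a learned length-`d`
  modality-identity offset (the only shape-consistent reading of
  per-modality identity parameters when `e` and `n` vary per molecule),
  are concatenated `[1D, 2D, 3D]`, and pass through a pre-norm fusion
  transformer (2 blocks). No positional table is used in fusion: order
  information enters only through the 1D encoder's positions, so fused
  atom rows stay permutation-consistent. The output is decomposed by
  slicing the same row ranges.
* **Decoders** — 1D: dense + nonlinearity + normalization + vocabulary
  projection; 2D and 3D: one light message-passing layer plus a linear
  head (to `d` and to 3 coordinates respectively).

Pre-norm blocks have an exact residual path: with the attention output
projection and the second feed-forward layer zeroed, a block is the
identity. The tests use this closed form to pin the fusion wiring.

# Objectives

Per molecule: the 1D loss is cross-entropy summed over masked positions;
the 2D loss is the structural contrastive embedding penalty
`sum (1 - cos(h_i, h_target_i))^gamma` over masked atoms with `gamma = 2`;
the 3D loss combines mean squared error and a cosine term over *all* n
atoms (the denoiser must also keep clean atoms in place), weighted by
`lambdaL2 = lambdaCos = 1`. The total is the plain sum of the three —
never a mean of means — and molecules in a batch contribute the average
of their totals.

The 2D target embedding is the input-layer feature embedding of the clean
graph under current parameters, gradient-stopped: it is the simplest
target that makes the cosine reconstruction well-posed without a second
(momentum) network, and it keeps the objective self-contained. This is a
design choice of this package, stated here because other definitions of
the target are possible.

Empty masks contribute zero loss (with a warning outside training); the
epsilon guard in cosine denominators fires only for zero-norm rows.

# Training, determinism, batching

Adam (lr `3e-3`, betas 0.9/0.999) over seeded random batches; the
learning rate is sized so a 64-molecule corpus approaches convergence
within a few hundred CPU steps. Molecules in a batch are processed on
separate tapes and their gradients averaged — mathematically identical to
padded batching with masked losses and pooling, without pad bookkeeping.
A fresh perturbation is drawn per molecule per step, so augmentation
varies across epochs. Two runs with the same seed, corpus and
configuration produce bit-identical loss trajectories and parameters;
checkpoints (parameters + config + vocabulary fingerprint) round-trip
exactly, and loading verifies the fingerprint.

The backbone default is `d = 64`: at desk scale this keeps the
200-step demonstration runs in the minutes range on one CPU core while
preserving every architectural element; all widths and depths are
configuration.

# Fine-tuning and attention export

Fine-tuning re-uses encoders and fusion from a checkpoint. The pooled
representation is `sum_i alpha_i h_i` with
`alpha_i = softmax_i(w' tanh(h_i))` over **all** fused rows — `e` token
rows, `n` atom rows, and optionally `n` 3D rows (`k = e + n (+ n)`), so
the 3D branch can be switched off without changing the head. A 2-layer
perceptron (`d → d/2 → 1`, tanh) produces the prediction; classification
outputs pass through a sigmoid, and training uses binary cross-entropy or
absolute error. By default all parameters are fine-tuned; a freeze switch
restricts updates to the head. Requesting the 3D branch for a record
without a conformer is an explicit error, never a silent fallback.

`exportSubstructureAttention()` returns the exact pooling weights of a
clean forward pass, one per fused row, labelled by modality and fragment
string or atom symbol — the raw material for substructure-level
interpretation.

# The synthetic generator — what it does and does not emulate

`generateFixtureSet()` draws from compositional templates (alkanes and
branched alkanes, ethers, alcohols, amines, amides/esters/ketones via
carbonyl insertion, halogenated variants, benzene/pyridine/phenol/
naphthalene systems) spanning 3–20 heavy atoms, with deterministic
conformers from a seeded spring relaxation (bonded pairs pulled to
type-specific lengths, non-bonded pairs repelled below 2.2 Å) and two
labels: `halogenated` (F/Cl/Br/I present) and `size`. The heteroatom
interleaving is deliberate: it mirrors drug-like corpora and prevents BPE
from collapsing homopolymer-like chains into single fragments.

What passing tests on these fixtures shows: the perturbation algebra, the
encoder symmetries, gradient correctness, end-to-end trainability, and
that the pipeline can memorize and separate at overfit scale. What it
does not show: chemical realism of conformer ensembles (one idealized
geometry per molecule, no rotamers), real label noise, assay class
imbalance, or transfer from large-corpus pretraining — the synthetic
corpus stands in for that corpus at desk scale only.

# Numerical choices and degenerate inputs

Layer normalization uses eps `1e-5`; cosine guards use `1e-8`; softmax and
log-sum-exp are max-shifted. Single-atom molecules have no edges (the GIN
layers reduce to their MLPs) and no 3D pairs (self-feature fallback).
Multi-component (dot-separated) SMILES are rejected. Scaffold keys for
acyclic molecules are the molecule's own canonical SMILES (the
Bemis-Murcko framework is empty there; grouping by canonical SMILES keeps
every molecule in a well-defined group). Scaffold groups are assigned
greedily, largest first, to the part furthest below target, with
content-based tie-breaks unless a shuffle seed is given. SDF input keeps
coordinates in block order and recovers the canonical-SMILES atom order
by a deterministic smallest-index graph match; for molecules with
non-trivial automorphisms the match may assign coordinates to a
symmetry-equivalent atom, which leaves all distances and the graph
unchanged.

# Demonstration problem sizes

The shipped tests and the acceptance script use: a 64-molecule corpus
(vocabulary capped at 30) for the 200-step descent run at batch 16; an
8-molecule, 500-step overfit run for masked-token recovery; 20 labelled
molecules (10 halogenated, 10 not) for the separability fine-tune with
the 3D branch both off and on; and 10 single-scaffold molecules for the
8/1/1 split check. These sizes are the package's desk-scale study
conditions.

# Known limitations

* The SMILES scanner covers the organic subset, bracket atoms, ring
  closures and branches; stereo descriptors are parsed but ignored.
* One conformer per molecule; no ensembles, no conformer resampling.
* The 3D denoising target is the absolute clean coordinate frame; since
  the encoder is rigid-motion invariant, the decoder can only resolve
  coordinates up to the per-molecule frame it memorizes — adequate for
  the reconstruction objective, not a generative geometry model.
* Binary classification and single-task regression heads only.
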