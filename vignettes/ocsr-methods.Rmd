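---
title: "Methods: models, parameters and design choices in ocsr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in ocsr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Optical chemical structure recognition (OCSR) turns a 2D drawing of a
molecule into a machine-readable representation. `ocsr` implements a
desk-scale version of the show-and-tell approach: render molecules to
bitmaps, encode the target structure as a linear string (SMILES,
DeepSMILES or SELFIES), and train an attention-based encoder--decoder to
translate image features into the token sequence of that string. Model
quality is scored with Tanimoto similarity over substructure-key
fingerprints, the field's standard graded measure: it rewards partial
structural recovery instead of only exact hits, and with a low-degeneracy
fingerprint a Tanimoto of 1.0 is nearly equivalent to graph isomorphism.

Everything here runs from synthetic data on one CPU. Full-scale training of
this architecture (millions of images, GPU-weeks) is explicitly out of
scope; the package's claim is that every stage is implemented faithfully
and verifiably, not that it reaches literature-scale accuracy.

## Corpus curation

Training corpora drawn from public databases are filtered with nine
structural rules before depiction. A molecule must: weigh under 1500 Da
(average atomic masses, implicit hydrogens included), be a single fragment
(no counter ions), contain only C, H, O, N, P, S, F, Cl, Br, I, Se and B,
carry no isotope labels (this covers D/T), have 5--40 bonds (graph edges; a
double bond counts once), carry no formal charges, use implicit hydrogens
only, and have a canonical SMILES shorter than 40 characters.

Two rules required interpretation:

* *"only implicit hydrogens, except in functional groups"* is
  operationalized as: reject molecules whose graph contains hydrogen as an
  explicit node (`[H]`, `[2H]`); bracket-atom implicit hydrogen counts such
  as `[nH]` are allowed. The exception clause has no mechanical reading; this
  is the closest testable one.
* the 40-character limit is measured on **this package's canonical SMILES**,
  not the input spelling, because input dialects vary and the canonical form
  is reproducible.

Parse failures are counted separately and never abort a stream: curation
over a large corpus must be total.

## Chemistry core

No cheminformatics toolkit exists in the target R environment, so the
package carries its own: a SMILES parser (organic subset, bracket atoms,
rings, branches, aromatic forms), implicit-hydrogen assignment by the
lowest-covering standard valence (aromatic atoms never promote to a higher
valence), pragmatic Hueckel aromaticity perception on the smallest ring
through each bond (sizes 5--7, lone-pair heteroatoms contribute two
electrons, exocyclic carbonyls zero), backtracking kekulization, and a
canonical writer based on iterative Morgan-style invariant refinement with
deterministic tie-breaking. The canonicalizer was validated during
development against an independent toolkit on randomized respellings of a
diverse molecule panel; the shipped tests assert spelling-invariance and
idempotence directly. Refinement-based canonical labelling has known
pathological counterexamples (highly regular graphs); none arise in the
package's chemical space.

## String representations

DeepSMILES removes open parentheses (a k-atom branch closes with k `)`
symbols, each popping one atom from the derivation path) and replaces
paired ring-closure digits with a single ring-size number at the closing
atom. The decoder rebuilds the molecular graph from this derivation and
therefore detects dangling ring sizes and over-popped paths -- exactly the
failure modes a sequence model produces, which evaluation counts as
invalid predictions. Encoding assumes ring closures bond to ancestors on
the derivation path, which is guaranteed for the package's canonical
SMILES (ring bonds are DFS back edges).

SELFIES is implemented with the v2 conventions: a 16-symbol index
alphabet, `[BranchN]`/`[RingN]` with N index symbols, branch length Q+1,
ring partner Q+1 atoms back in derivation order, and valence-capped
derivation that makes decoding total: bond orders are clamped to remaining
capacities, unrealizable atoms are dropped, out-of-range ring indices are
clamped, and unknown symbols are skipped. Aromatic systems are kekulized
before encoding because the grammar has no aromatic symbols. The
robustness property -- a shuffled symbol sequence still decodes to some
molecule -- is exercised in the tests with 100 random shuffles.

The tokenizer uses longest-match rules (bracket atoms, `Cl`/`Br`, `%nn`
one token each; SELFIES split at bracket boundaries). The vocabulary fixes
`<pad>` at index 0 so padded positions are zero in index space (the masked
loss depends on this), with `<start>`, `<end>`, `<unk>` following and
corpus tokens sorted lexicographically -- deterministic and
permutation-invariant.

## Depiction

Each curated molecule is drawn once, with one random rotation per molecule
and no other augmentation (no noise, no blur -- deliberately, matching the
pipeline being modelled). Layout is a ring-aware deterministic procedure:
zig-zag chains with 120-degree branching for acyclic molecules, and
Kamada--Kawai coordinates (igraph, seeded circular start) for cyclic ones.
The rotation angle is a deterministic uniform draw over [0, 2*pi) from a
per-molecule seed, `base_seed + hash(molecule_id)`, applied to the layout
coordinates about their centroid *before* rasterization, so no
interpolation artifacts arise; scaling is radius-based so rotation can
never clip the drawing. Bonds are drawn as 2 px black lines (parallel
strokes for multiplicity, an inner tick for aromatic bonds), heteroatoms
as bitmap-font labels on a cleared patch; carbon vertices are unlabeled,
as in standard skeletal formulas. The canvas is 299x299 RGB to match the
input contract of common CNN backbones. Images are written as PNG
(lossless) through the package's own writer (plain-C zlib bindings),
giving bit-exact reproducibility, which the tests assert byte for byte.

These depictions are simpler than literature figures: no font
anti-aliasing, no wedge/hash stereo bonds, no abbreviated groups, no page
noise. A green rendering test therefore establishes determinism and
geometric fidelity of this generator -- not robustness to real scanned
drawings.

## Featurizer

The image featurizer is a *contract*: any deterministic map from a bitmap
to a fixed L x D feature grid is admissible, so a large pretrained CNN can
plug in unchanged at full scale. The built-in default used by all tests is
a frozen, seeded random-projection patch encoder: grayscale, area-pool to
64x64, cut into an 8x8 grid of patches (L = 64), and map each flattened
patch through a fixed random affine layer with tanh (D = 64). Random but
frozen filters preserve enough spatial structure for desk-scale
experiments while keeping the repository free of pretrained weights.

## Network

The decoder follows the show-and-tell pattern: a single fully connected
layer with ReLU projects each feature row to the embedding width; additive
(Bahdanau) attention scores `e_i = v' tanh(W1 h_i + W2 s)` produce simplex
weights and a convex-combination context; a GRU consumes
`[token embedding ; context]`; two fully connected layers map the GRU
state to vocabulary logits. Training is teacher-forced with masked sparse
categorical cross-entropy (PAD positions contribute exactly zero and are
excluded from the denominator) and Adam. Reference defaults mirror the
full-scale recipe -- batch 640, embedding 600, learning rate 5e-4,
25 epochs -- with desk tests overriding them downward. The decoder hidden
width (512) and the widths of the two output layers (= units) are not
fixed by the source method and are config parameters.

Everything is implemented in base R linear algebra with hand-derived
backpropagation; a finite-difference gradient check (1e-4 relative) guards
every parameter block. Decoding is greedy argmax (lowest index wins ties)
for deterministic evaluation; the inference cap is the training max length
plus two sentinel positions. Checkpoints embed the config and a vocabulary
hash, and decoding refuses a mismatched vocabulary.

Two measurement conventions deserve note:

* the per-epoch **loss trace is the exact full-training-set loss evaluated
  after the epoch's updates** (token-mass weighted across batches), not a
  running average of pre-update batch losses. The trace then measures the
  model state and is comparable across batch sizes.
* `model_config(lr_decay=)` applies an optional per-epoch multiplicative
  step decay (default 1, i.e. constant, as in the full-scale recipe). The
  overfit sanity oracle in the acceptance suite uses full-batch Adam with
  `lr_decay = 0.98`: a constant-step Adam zig-zags along valleys and at
  the optimum, so its loss trace cannot decrease strictly; with a decayed
  step the trajectory approaches a smooth descent and the 300-step trace
  is strictly decreasing while still reaching 100% exact recovery of the
  32 memorized pairs. The sanity configuration (learning rate 5.5e-3,
  decay 0.98, full batch) was chosen for stable monotone convergence and
  is asserted, not tuned per run: the whole run is a deterministic
  function of its seeds.

## Synthetic data

The fixture generator stands in for a large public structure corpus. It
grows a carbon-anchored chain of 6--16 atoms over a weighted atom pool
(C5 N1 O2 S1 by default), separates heteroatoms by at least one carbon,
adds an occasional C=C (p = 0.15 per eligible bond), at most one ring
(p = 0.3, size 5--6) and at most one short branch (p = 0.4, length 1--2,
F/Cl allowed as terminators), then filters through the curation rules and
deduplicates canonical SMILES until the requested count is reached. Every
emitted molecule is rule-compliant by construction, and the generator is a
deterministic function of its seed.

What this emulates: small, drug-like-ish aliphatic/heteroaliphatic
molecules with realistic token statistics for sequence learning. What it
does not emulate: aromatic ring systems (exercised separately with
hand-picked aromatics in the tests), stereochemistry, charged species,
fused polycycles, and the heavy-tailed size distribution of real
databases. A green end-to-end test therefore establishes that the
pipeline's plumbing and learning dynamics work -- not that the model
generalizes to real chemical diversity.

Splits are molecule-level disjoint (the stricter reading of train/test
separation), with a 10% test fraction mirroring the roughly 10:1 ratios of
full-scale practice. The vocabulary is built from the train split only;
unseen test tokens map to `<unk>`.

## Evaluation

Predictions are decoded from their representation to SMILES (decode
failure means invalid), parsed, and compared to references by Tanimoto
similarity `|A & B| / |A | B|` of 881-bit substructure-key fingerprints.
The key layout is the package's own (element counts at thresholds, ring
features, bond-order counts, hashed linear paths of 2--6 atoms with
direction-canonicalized labels); the published 881-key definition lives
outside the method being modelled, and any fixed low-degeneracy
substructure scheme is equivalent for these indicators as long as both
sides of every comparison use the same one.

Reporting conventions: `avg_tanimoto` averages over valid predictions
only; `tanimoto1_pct` is a percentage of all predictions (the stricter
denominator); when nothing is valid the average is NA rather than 0, so
"all wrong" and "all invalid" stay distinguishable. The histogram uses
eleven bins -- [0,0.1) ... [0.9,1.0) and exactly 1.0 -- over valid
outcomes and sums to 100. Descriptor deltas (mean |dlogP| with a coarse
atom-contribution logP, mean |dring| with the cyclomatic ring count) track
whether near-miss predictions are chemically close. The data-size
extrapolation is ordinary least squares of accuracy on training size with
the required size read off the line; a non-positive slope is refused, and
the linear form is an order-of-magnitude indicator only -- the true curve
saturates.

## Numerical and degenerate-input choices

Softmax and log-sum-exp are max-shifted; attention weights are checked to
sum to 1 within 1e-6; argmax ties resolve to the lowest index on every
platform; the empty curation stream yields a zeroed report; a blank
rendering or an empty molecule raises a classed render error carrying the
molecule id; both-empty fingerprints make Tanimoto an explicit
undefined-similarity signal rather than 0/0. All randomness (rotation
seeds, shuffles, parameter init, fixture assembly) flows from explicit
integer seeds through RNG-state-preserving helpers, so library calls never
perturb user RNG state.

## Known limitations

The chemistry core targets the curated subset (neutral, common-element
organic molecules); exotic valences, stereo descriptors and reaction
SMILES are out of scope. The canonicalizer is heuristic (see above). The
default featurizer is untrained, so absolute model quality is far below a
pretrained backbone; the package's accuracy claims are confined to the
sanity oracles its tests compute. The CLI runs single-threaded;
distributed training is a non-goal.
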