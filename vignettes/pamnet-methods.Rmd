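---
title: "Physics-aware multiplex message passing for 3D molecules: models and methods"
author: "pamnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physics-aware multiplex message passing for 3D molecules: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamnet)
```

## The model

Molecular mechanics separates the energy of a molecule into local, covalent
terms (bonds, bond angles, dihedrals — functions of short-range distances
and angles) and non-local, non-covalent terms (van der Waals,
electrostatics — functions of pairwise distances alone). `pamnet`
implements a graph neural network that mirrors this split. Every 3D
structure becomes a **two-layer multiplex graph** over one shared set of
atoms:

* the **local layer** holds covalent or short-range contacts — either the
  chemical bonds of the input, or a radius graph with a small cutoff
  `d_l`;
* the **global layer** holds all pairs within a large cutoff `d_g`
  (it deliberately contains the local pairs too, since non-local physics
  does not switch off at a bond).

Each hidden layer `t = 1..T` runs two message-passing branches over the
same node embeddings `h` (width `F`):

* **Global message passing** uses distances only. Messages on directed
  edges are `m_ji = MLP([h_j | h_i | e_ji])`, where `e_ji` is the radial
  basis expansion of the distance, and the node update is
  `h_i <- h_i + sum_j m_ji * phi_d(e_ji)` with a bias-free linear filter
  `phi_d(e) = W_e e`.
* **Local message passing** additionally folds in angular information.
  Before aggregation, each directed-edge message is augmented with two
  sums: over the *one-hop* angles at the receiving atom (every other
  incoming edge `j' -> i`, angle at vertex `i`) and over the *two-hop*
  angles at the sending atom (every edge `k -> j` with `k != i`, angle at
  vertex `j`). Each term multiplies the partner message by its distance
  filter and an angular filter `phi_theta(a)` (a two-layer MLP of the
  angular basis). The `"s"` variant drops the two-hop sum and keeps only
  one-hop geometry.

After each branch's message block, an **update block** — three residual
blocks (two-layer Swish MLPs with skips) plus a skip connection from the
message-block input to the output of the first residual block — produces
the next `h` and a per-layer branch output `z_g` or `z_l` (width `F`,
through a three-layer MLP).

The **fusion module** pools the two branches per node with attention: the
logit of plex `p` is `LeakyReLU(W_p z_p,i)` and the weights
`alpha_{g,i} + alpha_{l,i} = 1` come from a two-way softmax. The fused
per-layer output is `z_i^t = sum_p alpha_{p,i} (W'_p z_{p,i})` (width
`D`), node outputs are the sum over layers, and graph outputs the sum (or
mean) over nodes. All inputs to this pipeline — distances, angles, atomic
numbers — are E(3)-invariant, so every scalar prediction is invariant to
rotations, translations and reflections by construction; the test suite
verifies this to 1e-5 relative (observed: ~1e-14).

### Equivariant dipole head

Vectorial outputs need equivariance instead. Each node carries a geometric
vector rebuilt after every message-passing module,

    v_i = sum_{j in N(i)} (r_i - r_j) * ||m_ij||,

a sum of position *differences* weighted by invariant message norms: `v`
ignores translations and co-rotates (and reflects) with the molecule. The
fusion steps are re-used with scalar per-node coefficients (`W'_p` is
`1 x F`), and the final dipole is `u = sum_i sum_t u_i^t`; its magnitude
is the scalar dipole prediction. The classical point-charge approximation
`mu = sum_i r_{c,i} q_i` (centroid-relative positions, per-atom charges)
is available as `point_charge_dipole()`; it is the planted ground truth of
the parameter-recovery study and the conceptual baseline the learned head
refines. A centrosymmetric structure must predict `||u|| = 0`, which the
tests check.

### Message-count accounting

Per hidden layer, the global pass computes one message per directed global
edge, `O(N k_g)` in the average global degree `k_g`. The local pass
evaluates one angular term per one-hop and per two-hop angle — for a
directed edge `j -> i` that is `(deg(i) - 1) + (deg(j) - 1)` terms, i.e.
`O(2 N k_l^2)` in total. A single-layer model that needs angles for
*every* pair would instead evaluate `O(N k_g^2)` triplet messages.
`count_messages()` implements both conventions, and the test suite checks
the multiplex tally against an instrumented forward pass (one count per
executed angular-filter evaluation) and against the closed form above. On
the synthetic small-molecule ensemble the multiplex count is about an
order of magnitude below the triplet count — the package's accounting of
why the split into two layers pays off.

## Input featurization

* **Radial basis** (`radial_basis()`): zeroth-order spherical Bessel
  functions, component `m = envelope(d/c) * sqrt(2/c) * sin(m pi d/c)/d`,
  with a degree-`p` polynomial envelope (`p = 5` by default) that reaches
  zero with zero slope at the cutoff. Edges lying exactly at the cutoff
  therefore exist in the graph but contribute nothing — cutoff ties are
  included (`<=`) yet numerically silent. Default `n_rbf = 16`.
* **Angular basis** (`angular_basis()`): cosine expansion
  `cos(l * theta)`, `l = 0..n_abf - 1`, applied identically to one-hop and
  two-hop angles. Default `n_abf = 7`.
* **Atom identity**: trainable per-element embeddings of width `F`,
  initialized uniform in `(-sqrt(3), sqrt(3))` (unit variance). In the
  protein–ligand setting atoms instead carry 18 chemical features
  (element and degree one-hots, electronegativity, covalent radius, and
  related descriptors; `atom_chemical_features()` documents the exact
  set), mapped into `F` dimensions by a learned linear layer.

## Tasks and training recipe

Four task presets bundle the graph construction the corresponding
molecular system uses:

| task | local layer | `d_g` (Å) | atom input |
|---|---|---|---|
| `qm9_scalar` | chemical bonds | 5 (10 for long-range properties) | Z embeddings |
| `qm9_dipole` | chemical bonds | 5–10 | Z embeddings |
| `rna_score` | cutoff `d_l` = 2.6 Å | 20 | Z embeddings (C/N/O atoms) |
| `pdbbind_affinity` | cutoff `d_l` = 2 Å | 6 | 18 chemical features |

Scalar regression trains with mean absolute error; structural-model
scoring (predicted RMSD) with the smooth L1 loss (quadratic below residual
1, linear above). Binding affinity uses three **weight-sharing replica
networks** — the same parameters applied to the pocket complex, the
pocket alone, and the ligand alone — combined as
`dG = G_complex - G_pocket - G_ligand` and trained against log Ki; a
uniform shift `G -> G + c` of the network output therefore shifts `dG` by
`-c`, which is a property test, and an empty pocket falls back to
`G_complex - G_ligand` with a warning.

Optimization is Adam with a linear warm-up over one epoch, then
exponential decay of ratio 0.1 every 600 epochs (the protein–ligand recipe
steps by 0.2 every 50 epochs instead). The decay is applied continuously
(`ratio^((epoch - warmup)/interval)`); a stepwise mode is available
(`decay_mode = "stepwise"`). The decay clock starts at the end of warm-up,
so the rate is `base_lr` exactly when warm-up ends and `0.1 * base_lr`
exactly 600 decay epochs later. An exponential moving average of the
parameters (decay 0.999 in the reference recipe) is what validation and
testing evaluate; early stopping watches the validation loss with a
default patience of 50 epochs. One master seed drives everything —
parameter init, the validation split, and batch order are derived from it
through a small LCG expansion (`derive_seeds()`), so fits are exactly
reproducible.

## Design choices where the architecture was open

* **Branch coupling.** Both branches read the same `h` stream, and the
  next layer's `h` is the sum of the two branches' update-block outputs.
  Both message blocks write to the same node state in the defining
  equations, and a single shared stream is the minimal reading; the code
  keeps the two update paths separate up to that sum so a per-branch
  variant would be a local change.
* **Update-block wiring.** The extra skip runs from the message-block
  input (the previous layer's `h`) to the output of the first residual
  block. With all MLPs zeroed the block is the identity, which is the
  probe test's fixture.
* **Two-way softmax.** The per-node attention softmax over the two plexes
  is computed as `sigmoid(logit_g - logit_l)` — algebraically identical to
  the max-subtracted softmax and unconditionally stable. LeakyReLU slope
  0.01; Swish is `x * sigmoid(x)`.
* **Branch output width.** The update block's output MLP keeps width `F`;
  the fusion projection maps `F -> D`. For scalar regression `D = 1`, so
  the layer-and-node sum *is* the prediction, with no extra head.
* **Basis definitions.** The radial/angular bases above follow the
  spherical-Bessel lineage of directional message-passing models; sizes
  are configurable and the local block consumes exactly (distance, angle)
  pairs.
* **Dipole message direction.** The geometric-vector update contracts the
  message on the *outgoing* edge `i -> j` with `r_i - r_j`; the diatomic
  antisymmetry test (`v_1 = -v_2`) pins the convention.
* **Hydrogens.** Structures keep their hydrogens unless a reader filter
  removes them (`drop_hydrogens`, element whitelists, pocket extraction);
  bond-mode local layers therefore include X–H edges. Heavy-atom-only
  modelling is a preprocessing decision, not a model switch.
* **Initialization.** Linear layers use the standard fan-in uniform
  scheme; the only exception is the input embedding table
  (uniform `(-sqrt(3), sqrt(3))`).

## Numerical choices

* Cutoff ties are *included* in edge sets (closed interval) but carry
  zero features through the envelope; coincident atoms (separation below
  1e-9 Å) never form an edge.
* Radius graphs are built from a Gram-matrix distance computation for
  speed, but selected distances are recomputed by direct differencing —
  the Gram form suffers catastrophic cancellation after large
  translations, which would otherwise create spurious self-edges and
  break E(3) invariance of the edge set.
* Angle cosines are clamped to `[-1, 1]` before `acos`; angles are
  accepted within 1e-9 of `[0, pi]`.
* In bond mode the local layer has no prescribed cutoff; the radial
  features use the longest bond padded by 5% as the effective cutoff so
  the envelope never zeroes a real bond.
* The gradient engine is a plain reverse-mode tape over dense matrices;
  every operator is validated against central finite differences in the
  test suite, and whole-model gradients agree to ~1e-6 relative.

## The synthetic-data generator and what passing means

`synthetic_molecule()` produces self-avoiding random chains (consecutive
bonds 1.2–1.6 Å, the typical single-bond range, minimum non-bonded
separation 0.8 Å) and bond-free blobs (minimum separation 0.8 Å) over H,
C, N, O. `synthetic_decoy_set()` emulates a structural-model scoring
fixture: perturbed copies of a native chain whose coordinate noise is
rescaled so the realized RMSD spans 0.5–12 Å log-uniformly, bracketing
the 2 Å near-native threshold. `synthetic_complex()` surrounds a ligand
blob with small residue clusters at log-uniform distances spanning the
6 Å pocket radius, recording each residue's true minimum distance.

These fixtures reproduce the *geometric regime* of the real tasks (bond
lengths, cutoff scales, decoy RMSD ranges, pocket radii) but none of
their chemistry: no valence rules, no conformational energetics, no
sequence structure, no experimental noise. Passing the symmetry,
counting, capacity and recovery tests therefore certifies the
architecture and its implementation — not benchmark accuracy on QM9,
RNA-Puzzles or PDBbind, which would require training the full-size model
on the real datasets.

## Desk-scale study conditions

The bundled studies run at sizes chosen once for a laptop-class CPU:

* capacity: 50 chain molecules of 8–16 atoms, smooth target = sum of
  pairwise Gaussians of distances, `F = 32`, `T = 2`, 400 full-batch Adam
  steps; the training MAE must fall below 5% of the target's standard
  deviation (observed: ~2%).
* dipole recovery: planted per-element point charges
  {H: +0.10, C: −0.20, N: −0.35, O: +0.40}, 40 training / 12 held-out
  chains, 400 steps; held-out vector cosine similarity must exceed 0.95
  (observed: > 0.99).
* symmetry suite: 20 molecules × 100 random rigid transforms (rotations,
  translations, reflections), tolerance 1e-5 relative.
* ranking study: a scorer trained on 3 × 24 synthetic decoys, evaluated
  on two unseen 30-decoy sets by the rank of the best-scoring near-native
  model and the geometric mean of ranks.

## Known limitations

* No periodic boundary conditions, k-nearest-neighbour graphs, or cell
  lists beyond a uniform pairwise search; graphs above a few thousand
  atoms are out of intended scope.
* Training is CPU-bound R; it is meant for desk-scale studies and method
  verification, not for full benchmark training runs.
* The SDF reader performs no sanitization or valence perception beyond
  what the file states; mmCIF is unsupported.
* Batches are formed once per fit (no per-epoch reshuffling); with
  full-batch defaults this is irrelevant, with mini-batches it trades a
  little stochasticity for exact reproducibility.
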