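# pamnet

Physics-aware multiplex graph neural networks for 3D molecules, in R.

`pamnet` is for computational chemists and structural bioinformaticians who
want one representation-learning architecture that works across molecular
systems — small organic molecules, RNA structural models, and
protein–ligand complexes — and who want to study, test and extend that
architecture at desk scale, on a CPU, with fully reproducible fits.

## The model

Following molecular mechanics, which splits the molecular energy into
local covalent terms (needing distances *and* angles) and non-local terms
(needing distances only), every structure becomes a two-layer **multiplex
graph** `G = {G_global, G_local}` over one shared atom set: a local layer
of chemical bonds or short-range contacts (cutoff `d_l`), and a global
layer of all pairs within a large cutoff `d_g`. Each hidden layer
`t = 1..T` runs two message-passing branches over shared node embeddings
`h` (width `F`):

* **global** (distances only):
  `m_ji = MLP([h_j | h_i | e_ji])`,
  `h_i ← h_i + Σ_j m_ji ⊙ φ_d(e_ji)`, with `φ_d(e) = W_e e` and `e` a
  spherical-Bessel radial basis with a smooth cutoff envelope;
* **local** (distances + one-hop and two-hop angles):
  `m'_ji = m_ji + Σ_{j'∈N(i)\{j}} m_j'i ⊙ φ_d(e_j'i) ⊙ φ_θ(a_j'i,ji)
  + Σ_{k∈N(j)\{i}} m_kj ⊙ φ_d(e_kj) ⊙ φ_θ(a_kj,ji)`, then the same
  aggregation with `m'`.

Per node, an attention softmax fuses the branch outputs
(`z^t_i = Σ_p α_{p,i} W'_p z_{p,i}`, `α_g + α_l = 1`), and outputs sum
over layers and nodes. Everything the scalar path sees is E(3)-invariant;
for dipole moments an equivariant head carries per-node geometric vectors
`v_i = Σ_j (r_i − r_j)·‖m_ij‖` so the predicted vector `μ̂` co-rotates and
reflects with the molecule, and `‖μ̂‖` is the scalar prediction. The
per-layer cost is `O(N k_g + 2 N k_l²)` messages instead of the
`O(N k_g²)` a fully angular model needs — `count_messages()` implements
both tallies.

Training follows the reference recipe: Adam, linear warm-up over one
epoch, exponential decay (ratio 0.1 every 600 epochs; stepwise 0.2 / 50
epochs for the affinity task), an exponential moving average of the
parameters for evaluation, early stopping on the validation loss, MAE or
smooth-L1 losses, and a replica-network `ΔG = G_complex − G_pocket −
G_ligand` head for binding affinity. The whole model — including graph
building, basis featurization, and a small reverse-mode autodiff engine —
is implemented in base R; gradients are validated against finite
differences in the test suite.

## Worked example

```r
library(pamnet)

mol <- synthetic_molecule(9, seed = 4, mode = "chain")
mol
#> <molecule3d 'synthetic_chain_9_seed4': 9 atoms, 8 bonds>

g <- multiplex_graph(mol, d_g = 5, local_mode = "bonds")
g
#> <multiplex_graph: 9 nodes, 54 global edges, 16 local edges,
#>  14 one-hop + 14 two-hop angles>
unlist(count_messages(g))
#> global_messages  local_messages           total
#>              54              28              82

# fit a scalar regressor on 30 labelled chains
mols <- lapply(1:30, function(i) {
  m <- synthetic_molecule(8 + i %% 5, 100 + i, "chain")
  d <- as.matrix(dist(m$pos))
  m$target <- sum(exp(-(d[upper.tri(d)]^2) / 4))  # smooth geometric target
  m
})
cfg <- pamnet_config("qm9_scalar", n_layers = 2, hidden_dim = 32)
fit <- pamnet_fit(mols, config = cfg,
                  train = pamnet_train_config(base_lr = 2e-3,
                                              max_epochs = 200,
                                              early_stop_patience = Inf,
                                              ema_decay = 0.9, seed = 1))
summary(fit)
#> <pamnet_config: task=qm9_scalar, T=2, F=32, D=1, d_g=5, local=bonds, full>
#> epochs run      : 200 (best at 191)
#> final train loss: 0.0823536
#> training MAE    : 0.0534614

round(predict(fit, mols[1:5]), 3)
#> [1]  6.866 13.772 16.697 13.133  9.511
round(sapply(mols[1:5], `[[`, "target"), 3)
#> [1]  6.725 13.776 16.674 13.136  9.533

round(attention_summary(fit, mols[1:5]), 3)
#> alpha_g alpha_l
#>   0.524   0.476
```

The fitted model tracks the smooth geometric target to a few percent, and
the averaged attention weights report how much the local (bonded) versus
global (through-space) branch contributed — the package's built-in
interpretation tool.

Other entry points: `read_sdf()` / `read_qm9_xyz()` / `read_pdb_atoms()`
for standard formats, `extract_pocket()` for 6 Å binding-site extraction,
`predict_dipole()` for equivariant dipole vectors, `predict_affinity()`
for the replica-network ΔG head, `rank_models()` /
`geometric_mean_rank()` for structural-model scoring metrics, and
`save_pamnet()` / `load_pamnet()` for JSON checkpoints.

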