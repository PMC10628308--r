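# Shared fixtures built in code. All generators are deterministic in their
# seeds, so tests never depend on files or ambient RNG state.

# A small desk-scale configuration used wherever the architecture itself is
# under test (not its capacity).
tiny_config <- function(task = "qm9_scalar", n_layers = 2,
                        hidden_dim = 16, ...) {
  pamnet_config(task, n_layers = n_layers, hidden_dim = hidden_dim, ...)
}

# Mixed ensemble of chain and blob molecules.
fixture_molecules <- function(n, seed, n_atoms = 6:10) {
  sizes <- derive_seeds(seed, n) %% length(n_atoms) + 1L
  lapply(seq_len(n), function(i) {
    synthetic_molecule(n_atoms[sizes[i]], seed * 1000 + i,
                       mode = if (i %% 2 == 0) "blob" else "chain")
  })
}

# A methane-like V2000 SDF block (5 atoms, 4 bonds) as text.
methane_sdf_text <- function(name = "methane") {
  c(name,
    "  fixture",
    "",
    "  5  4  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.6291    0.6291    0.6291 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.6291   -0.6291    0.6291 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.6291    0.6291   -0.6291 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.6291   -0.6291   -0.6291 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0",
    "  1  3  1  0  0  0  0",
    "  1  4  1  0  0  0  0",
    "  1  5  1  0  0  0  0",
    "M  END",
    "$$$$")
}

# A QM9-dialect XYZ record for CH4 with a chosen raw value in one property
# column (defaults: U0 = -40).
ch4_qm9_record <- function(u0 = -40, mu = 1.5, homo = -0.4, lumo = 0.1) {
  props <- c(0, 0, 0, mu, 0, homo, lumo, lumo - homo, 0, 0, u0, 0, 0, 0, 0)
  c("5",
    paste("gdb 1", paste(sprintf("%.6f", props), collapse = " ")),
    "C 0.0 0.0 0.0",
    "H 0.6291 0.6291 0.6291",
    "H -0.6291 -0.6291 0.6291",
    "H -0.6291 0.6291 -0.6291",
    "H 0.6291 -0.6291 -0.6291")
}

# Star molecule: one centre with `k` arms at unit-ish distances, bonds from
# the centre to every arm. Used for the k(k-1)/2 angle-count law.
star_molecule <- function(k, seed = 1) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  dirs <- matrix(stats::rnorm(3 * k), k, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pos <- rbind(c(0, 0, 0), dirs * stats::runif(k, 1.2, 1.5))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  molecule3d(rep(6L, k + 1L), pos,
             bonds = cbind(1L, seq_len(k) + 1L), name = "star")
}

# Independent brute-force angle enumeration over all node triples, used as
# the oracle for enumerate_angles. Returns sorted key strings.
brute_force_angles <- function(edges, n) {
  adj <- matrix(FALSE, n, n)
  adj[cbind(edges$src, edges$dst)] <- TRUE
  one <- character(0)
  two <- character(0)
  for (i in seq_len(n)) {
    nb <- which(adj[, i])
    for (j in nb) {
      for (jp in nb) if (jp != j)
        one <- c(one, paste(jp, i, j))          # (j', i, j) per directed edge
      for (k in which(adj[, j])) if (k != i)
        two <- c(two, paste(k, j, i))           # (k, j, i)
    }
  }
  list(one = sort(one), two = sort(two))
}

# Smooth synthetic scalar target: sum of pairwise Gaussians of distances.
smooth_pair_target <- function(mol, width = 2) {
  d <- as.matrix(stats::dist(mol$pos))
  sum(exp(-(d[upper.tri(d)]^2) / width^2))
}

# Planted per-element point charges for dipole-recovery studies.
planted_charges <- c("1" = 0.10, "6" = -0.20, "7" = -0.35, "8" = 0.40)
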