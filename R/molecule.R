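# Element symbol <-> atomic number lookup for the elements that occur in
# small-molecule, RNA and protein-ligand structures.
.ELEMENTS <- c(
  H = 1L, He = 2L, Li = 3L, Be = 4L, B = 5L, C = 6L, N = 7L, O = 8L,
  F = 9L, Ne = 10L, Na = 11L, Mg = 12L, Al = 13L, Si = 14L, P = 15L,
  S = 16L, Cl = 17L, Ar = 18L, K = 19L, Ca = 20L, Mn = 25L, Fe = 26L,
  Co = 27L, Ni = 28L, Cu = 29L, Zn = 30L, Se = 34L, Br = 35L, I = 53L
)

#' Convert element symbols to atomic numbers
#'
#' @param symbol character vector of element symbols (case-sensitive,
#'   e.g. `"C"`, `"Cl"`).
#' @return integer vector of atomic numbers Z.
#' @export
element_number <- function(symbol) {
  z <- .ELEMENTS[as.character(symbol)]
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(z)]), collapse = ", "))
  }
  unname(z)
}

#' Convert atomic numbers to element symbols
#'
#' @param z integer vector of atomic numbers.
#' @return character vector of element symbols.
#' @export
element_symbol <- function(z) {
  idx <- match(as.integer(z), .ELEMENTS)
  if (anyNA(idx)) {
    stop("no symbol known for Z = ",
         paste(unique(z[is.na(idx)]), collapse = ", "))
  }
  names(.ELEMENTS)[idx]
}

#' Construct a 3D molecule
#'
#' The basic container used throughout the package: atomic numbers, Cartesian
#' positions in Angstrom, optional covalent bonds, optional per-atom chemical
#' feature rows (used for protein-ligand work instead of bare atomic numbers),
#' an optional scalar or 3-vector target, and optional per-atom residue labels
#' (chain, residue number, insertion code) carried through from PDB input.
#'
#' @param Z integer vector of atomic numbers (all >= 1).
#' @param pos numeric matrix, one row per atom, three columns (x, y, z), in
#'   Angstrom. All entries must be finite.
#' @param bonds optional integer matrix with two columns of 1-based atom
#'   indices; unordered, no duplicates, no self-bonds.
#' @param atom_features optional numeric matrix with one row per atom
#'   (fixed-width chemical features).
#' @param target optional numeric scalar or length-3 vector label.
#' @param name identifier string.
#' @param residue optional data.frame with one row per atom and columns
#'   `chain`, `resno`, `insert`, `resid`.
#' @return an object of class `molecule3d`.
#' @export
molecule3d <- function(Z, pos, bonds = NULL, atom_features = NULL,
                       target = NULL, name = "mol", residue = NULL) {
  Z <- as.integer(Z)
  pos <- as.matrix(pos)
  storage.mode(pos) <- "double"
  n <- length(Z)
  if (n < 1L) stop("molecule must contain at least one atom")
  if (any(Z < 1L)) stop("atomic numbers must be >= 1")
  if (!is.matrix(pos) || nrow(pos) != n || ncol(pos) != 3L)
    stop("pos must be an n x 3 matrix matching length(Z)")
  if (!all(is.finite(pos))) stop("positions must be finite")
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2L)
    if (nrow(bonds) > 0L) {
      if (any(bonds < 1L) || any(bonds > n))
        stop("bond indices out of range")
      if (any(bonds[, 1L] == bonds[, 2L]))
        stop("self-bonds are not allowed")
      key <- paste(pmin(bonds[, 1L], bonds[, 2L]),
                   pmax(bonds[, 1L], bonds[, 2L]))
      if (anyDuplicated(key)) stop("duplicate bonds")
    }
  }
  if (!is.null(atom_features)) {
    atom_features <- as.matrix(atom_features)
    storage.mode(atom_features) <- "double"
    if (nrow(atom_features) != n)
      stop("atom_features must have one row per atom")
  }
  if (!is.null(target)) {
    target <- as.numeric(target)
    if (!length(target) %in% c(1L, 3L))
      stop("target must be a scalar or a 3-vector")
  }
  if (!is.null(residue)) {
    residue <- as.data.frame(residue)
    if (nrow(residue) != n)
      stop("residue labels must have one row per atom")
  }
  structure(
    list(Z = Z, pos = pos, bonds = bonds, atom_features = atom_features,
         target = target, name = as.character(name), residue = residue),
    class = "molecule3d")
}

#' @export
print.molecule3d <- function(x, ...) {
  nb <- if (is.null(x$bonds)) 0L else nrow(x$bonds)
  cat(sprintf("<molecule3d '%s': %d atoms, %d bonds%s%s>\n",
              x$name, length(x$Z), nb,
              if (!is.null(x$atom_features))
                sprintf(", %d features/atom", ncol(x$atom_features)) else "",
              if (!is.null(x$target)) ", labelled" else ""))
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol a `molecule3d`.
#' @return integer atom count.
#' @export
n_atoms <- function(mol) length(mol$Z)

# Deterministic seed derivation: one master seed expands into a stream of
# independent sub-seeds (data shuffling, parameter init, fixtures) via a
# 31-bit LCG whose products stay exactly representable in doubles.
#' Derive a stream of sub-seeds from one master seed
#'
#' @param master integer master seed.
#' @param n how many sub-seeds to derive.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(master, n) {
  m <- 2^31 - 1
  s <- (abs(as.numeric(master)) %% m)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- (69069 * s + 12345) %% m
    out[i] <- s
  }
  as.integer(out %% (m - 2) + 1)
}

#' Generate a random synthetic 3D molecule
#'
#' Fixture generator used for testing and desk-scale studies. `chain` mode
#' grows a self-avoiding random walk with consecutive covalent bonds of
#' length 1.2-1.6 Angstrom (typical single-bond range); `blob` mode samples a
#' bond-free point cloud with minimum pairwise separation 0.8 Angstrom.
#' Atomic numbers are drawn from \{1, 6, 7, 8\} (H, C, N, O).
#'
#' @param n_atoms number of atoms (>= 1).
#' @param seed integer seed; the result is deterministic for a fixed seed.
#' @param mode `"chain"` or `"blob"`.
#' @return a `molecule3d`.
#' @export
synthetic_molecule <- function(n_atoms, seed, mode = c("chain", "blob")) {
  mode <- match.arg(mode)
  if (n_atoms < 1L) stop("n_atoms must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  Z <- sample(c(1L, 6L, 7L, 8L), n_atoms, replace = TRUE)
  if (mode == "chain") {
    pos <- matrix(0, n_atoms, 3L)
    for (i in seq_len(n_atoms)[-1]) {
      repeat {
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        step <- stats::runif(1, 1.2, 1.6)
        cand <- pos[i - 1L, ] + u * step
        d2 <- rowSums((pos[seq_len(i - 1L), , drop = FALSE] -
                         matrix(cand, i - 1L, 3L, byrow = TRUE))^2)
        # keep non-bonded atoms at least 0.8 A apart
        if (i == 2L || all(d2[seq_len(i - 2L)] >= 0.64)) break
      }
      pos[i, ] <- cand
    }
    bonds <- cbind(seq_len(n_atoms - 1L), seq_len(n_atoms)[-1])
    if (n_atoms == 1L) bonds <- NULL
  } else {
    side <- max(2, 1.7 * n_atoms^(1 / 3))
    pos <- matrix(NA_real_, n_atoms, 3L)
    pos[1L, ] <- stats::runif(3, 0, side)
    for (i in seq_len(n_atoms)[-1]) {
      repeat {
        cand <- stats::runif(3, 0, side)
        d2 <- rowSums((pos[seq_len(i - 1L), , drop = FALSE] -
                         matrix(cand, i - 1L, 3L, byrow = TRUE))^2)
        if (all(d2 >= 0.64)) break
      }
      pos[i, ] <- cand
    }
    bonds <- NULL
  }
  molecule3d(Z, pos, bonds = bonds,
             name = sprintf("synthetic_%s_%d_seed%d", mode, n_atoms,
                            as.integer(seed)))
}

# Save/restore the global RNG state so generators do not disturb user code.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Apply a rigid-body (or improper) transform to a molecule
#'
#' @param mol a `molecule3d`.
#' @param rotation 3 x 3 orthogonal matrix (determinant +1 for a proper
#'   rotation, -1 for a reflection).
#' @param translation length-3 numeric vector.
#' @return the transformed `molecule3d`.
#' @export
transform_molecule <- function(mol, rotation = diag(3),
                               translation = c(0, 0, 0)) {
  pos <- mol$pos %*% t(rotation) +
    matrix(translation, n_atoms(mol), 3L, byrow = TRUE)
  out <- mol
  out$pos <- pos
  out
}

#' Draw a random orthogonal transform
#'
#' @param seed integer seed.
#' @param reflect if `TRUE`, allow improper (reflection) components with
#'   probability 1/2; if `FALSE` always return a proper rotation.
#' @return list with `rotation` (3 x 3) and `translation` (length 3).
#' @export
random_rigid_transform <- function(seed, reflect = TRUE) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  # fix the sign ambiguity of QR, then optionally flip to a reflection
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  if (reflect && stats::runif(1) < 0.5) q[, 1] <- -q[, 1]
  list(rotation = q, translation = stats::rnorm(3, sd = 5))
}

#' Root-mean-square deviation between two conformations
#'
#' Direct (non-superposed) RMSD over corresponding atoms; the synthetic decoy
#' generator produces decoys in the native frame, so no fitting is applied.
#'
#' @param a,b `molecule3d` objects with identical atom ordering.
#' @return RMSD in Angstrom.
#' @export
coord_rmsd <- function(a, b) {
  if (n_atoms(a) != n_atoms(b)) stop("atom counts differ")
  sqrt(mean(rowSums((a$pos - b$pos)^2)))
}

#' Generate a synthetic RNA-like decoy set
#'
#' Emulates a structural-model scoring fixture: one native chain plus
#' perturbed decoys whose coordinate noise spans a controlled RMSD range,
#' so that a configurable fraction lies within the near-native threshold.
#'
#' @param n_models number of structural models.
#' @param seed integer seed.
#' @param n_atoms atoms in the native chain.
#' @param rmsd_range range of target perturbation RMSDs (Angstrom) the decoys
#'   span (log-uniformly).
#' @return list with `native` (`molecule3d`), `models` (list of
#'   `molecule3d`), and `rmsd` (numeric vector of true RMSDs to the native).
#' @export
synthetic_decoy_set <- function(n_models, seed, n_atoms = 20,
                                rmsd_range = c(0.5, 12)) {
  seeds <- derive_seeds(seed, n_models + 2L)
  native <- synthetic_molecule(n_atoms, seeds[1L], mode = "chain")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seeds[2L])
  target_rmsd <- exp(stats::runif(n_models, log(rmsd_range[1]),
                                  log(rmsd_range[2])))
  models <- vector("list", n_models)
  rmsd <- numeric(n_models)
  for (m in seq_len(n_models)) {
    noise <- matrix(stats::rnorm(3 * n_atoms), n_atoms, 3)
    noise <- noise - matrix(colMeans(noise), n_atoms, 3, byrow = TRUE)
    # scale the noise so the realized RMSD equals the drawn target exactly
    noise <- noise * target_rmsd[m] / sqrt(mean(rowSums(noise^2)))
    dec <- native
    dec$pos <- native$pos + noise
    dec$name <- sprintf("decoy_%03d", m)
    models[[m]] <- dec
    rmsd[m] <- coord_rmsd(native, dec)
  }
  list(native = native, models = models, rmsd = rmsd)
}
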