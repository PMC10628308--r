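#' Smooth polynomial cutoff envelope
#'
#' Polynomial envelope with exponent `p` that equals 1 at the origin and
#' goes to zero with zero first derivative at `x = 1` (the cutoff), so
#' features of edges exactly at the cutoff contribute nothing:
#' `u(x) = 1 - (p+1)(p+2)/2 x^p + p(p+2) x^(p+1) - p(p+1)/2 x^(p+2)`.
#'
#' @param x numeric vector of scaled distances `d / cutoff`.
#' @param p envelope exponent (default 5).
#' @return numeric vector; exactly 0 for `x >= 1`.
#' @export
envelope <- function(x, p = 5) {
  out <- 1 - (p + 1) * (p + 2) / 2 * x^p + p * (p + 2) * x^(p + 1) -
    p * (p + 1) / 2 * x^(p + 2)
  out[x >= 1] <- 0
  out
}

#' Radial basis expansion of a pairwise distance
#'
#' Zeroth-order spherical Bessel expansion with a smooth polynomial cutoff
#' envelope: component `m` is
#' `envelope(d/c) * sqrt(2/c) * sin(m pi d / c) / d`, for `m = 1..n_rbf`,
#' cutoff `c`. The un-enveloped components are orthonormal on `(0, c]`
#' under the radial measure; the envelope forces every component to vanish
#' smoothly at the cutoff.
#'
#' @param d numeric vector of distances (> 0), Angstrom.
#' @param cutoff layer cutoff, Angstrom.
#' @param n_rbf number of basis components (default 16).
#' @param envelope_exponent polynomial envelope exponent (default 5).
#' @return matrix `length(d) x n_rbf`.
#' @export
radial_basis <- function(d, cutoff, n_rbf = 16, envelope_exponent = 5) {
  if (any(d <= 0)) stop("distances must be > 0")
  x <- d / cutoff
  env <- envelope(x, envelope_exponent)
  m <- seq_len(n_rbf)
  # outer product: rows = distances, cols = frequencies
  arg <- outer(x, m * pi)
  sweep(sin(arg) / d, 1L, env * sqrt(2 / cutoff), "*")
}

#' Angular basis expansion of an angle
#'
#' Cosine (Chebyshev) expansion: component `l` is `cos(l * theta)` for
#' `l = 0 .. n_abf - 1`. Applied identically to one-hop and two-hop angles.
#'
#' @param theta numeric vector of angles in radians, within `[0, pi]`
#'   (a clamping tolerance of 1e-9 is allowed).
#' @param n_abf number of components (default 7).
#' @return matrix `length(theta) x n_abf`.
#' @export
angular_basis <- function(theta, n_abf = 7) {
  if (any(theta < -1e-9 | theta > pi + 1e-9))
    stop("angles must lie in [0, pi]")
  theta <- pmin(pi, pmax(0, theta))
  outer(theta, seq_len(n_abf) - 1, function(t, l) cos(l * t))
}

#' Initialize a trainable per-element embedding table
#'
#' One embedding row per atomic number, each entry drawn uniformly from
#' `(-sqrt(3), sqrt(3))` (unit variance).
#'
#' @param elements integer vector of atomic numbers to cover.
#' @param width embedding width F.
#' @param seed integer seed.
#' @return numeric matrix with `length(elements)` rows (rownames = Z) and
#'   `width` columns.
#' @export
atom_embedding_table <- function(elements, width, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  tab <- matrix(stats::runif(length(elements) * width, -sqrt(3), sqrt(3)),
                length(elements), width)
  rownames(tab) <- as.character(as.integer(elements))
  tab
}

#' Look up initial node embeddings from an embedding table
#'
#' @param Z integer vector of atomic numbers.
#' @param table embedding table from [atom_embedding_table()].
#' @return matrix `length(Z) x width`; identical rows for identical Z.
#' @export
embed_atoms <- function(Z, table) {
  idx <- match(as.character(as.integer(Z)), rownames(table))
  if (anyNA(idx))
    stop("embedding table has no row for Z = ",
         paste(unique(Z[is.na(idx)]), collapse = ", "))
  table[idx, , drop = FALSE]
}

# Pauling electronegativities and covalent radii (Angstrom) for the
# supported elements; used only by the 18-feature chemical featurizer.
.ELECTRONEG <- c(`1` = 2.20, `6` = 2.55, `7` = 3.04, `8` = 3.44,
                 `9` = 3.98, `15` = 2.19, `16` = 2.58, `17` = 3.16,
                 `35` = 2.96, `53` = 2.66)
.COV_RADIUS <- c(`1` = 0.31, `6` = 0.76, `7` = 0.71, `8` = 0.66,
                 `9` = 0.57, `15` = 1.07, `16` = 1.05, `17` = 1.02,
                 `35` = 1.20, `53` = 1.39)

#' Compute an 18-wide chemical feature row per atom
#'
#' Feature set used for protein-ligand work in place of bare atomic
#' numbers: element one-hot over \{H, C, N, O, S, P, halogen, other\} (8),
#' covalent-degree one-hot over \{0, 1, 2, 3, >=4\} (5, from the bond list
#' when present, else all in the 0 bin), numeric degree, Pauling
#' electronegativity / 4, covalent radius, Z / 10, and a heavy-atom flag —
#' 18 features in total.
#'
#' @param mol a `molecule3d`.
#' @return numeric matrix `n_atoms x 18`.
#' @export
atom_chemical_features <- function(mol) {
  n <- n_atoms(mol)
  Z <- mol$Z
  groups <- c("1" = 1L, "6" = 2L, "7" = 3L, "8" = 4L, "16" = 5L, "15" = 6L,
              "9" = 7L, "17" = 7L, "35" = 7L, "53" = 7L)
  gi <- groups[as.character(Z)]
  gi[is.na(gi)] <- 8L
  onehot_el <- matrix(0, n, 8L)
  onehot_el[cbind(seq_len(n), gi)] <- 1
  deg <- rep(0L, n)
  if (!is.null(mol$bonds) && nrow(mol$bonds) > 0L)
    deg <- tabulate(c(mol$bonds[, 1L], mol$bonds[, 2L]), nbins = n)
  db <- pmin(deg, 4L) + 1L
  onehot_deg <- matrix(0, n, 5L)
  onehot_deg[cbind(seq_len(n), db)] <- 1
  en <- .ELECTRONEG[as.character(Z)]
  en[is.na(en)] <- 2.0
  rad <- .COV_RADIUS[as.character(Z)]
  rad[is.na(rad)] <- 1.2
  cbind(onehot_el, onehot_deg, deg, unname(en) / 4, unname(rad), Z / 10,
        as.numeric(Z != 1L))
}

#' Featurize a multiplex graph
#'
#' Expands every stored distance and angle into basis features: global
#' edges with the global cutoff, local edges with the local cutoff (bond
#' mode uses the longest local edge, padded 5%, as the effective cutoff so
#' the envelope never truncates a bond), and both angle tables with the
#' angular basis. Also reports the initial-embedding source: the atomic
#' numbers, or the 18-wide chemical feature rows in chemical-features mode.
#'
#' @param g a `multiplex_graph` built from `mol`.
#' @param mol the `molecule3d` the graph was built from.
#' @param config a [pamnet_config()].
#' @return list with `e_global`, `e_local` (edge-feature matrices),
#'   `a_one_hop`, `a_two_hop` (angle-feature matrices), and `h0_input`
#'   (`Z` vector or feature matrix).
#' @export
featurize_graph <- function(g, mol, config) {
  if (g$n != n_atoms(mol)) stop("graph and molecule disagree on atom count")
  rb <- function(d, cutoff) {
    if (length(d) == 0L)
      return(matrix(0, 0L, config$n_rbf))
    radial_basis(d, cutoff, config$n_rbf, config$envelope_exponent)
  }
  ab <- function(theta) {
    if (length(theta) == 0L)
      return(matrix(0, 0L, config$n_abf))
    angular_basis(theta, config$n_abf)
  }
  d_l_eff <- g$d_l
  if (is.null(d_l_eff)) {
    d_l_eff <- if (length(g$local$dist)) 1.05 * max(g$local$dist) else 1
  }
  h0_input <- if (config$feature_mode == "chemical_features") {
    if (!is.null(mol$atom_features)) mol$atom_features
    else atom_chemical_features(mol)
  } else mol$Z
  list(e_global = rb(g$global$dist, g$d_g),
       e_local = rb(g$local$dist, d_l_eff),
       a_one_hop = ab(g$one_hop$theta),
       a_two_hop = ab(g$two_hop$theta),
       h0_input = h0_input)
}
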