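#' Read atoms from a PDB file
#'
#' Reads ATOM/HETATM records (via bio3d), optionally keeping only a whitelist
#' of elements (e.g. `c("C", "N", "O")` for RNA scoring work) and optionally
#' dropping hydrogens. Residue labels (chain, residue number, insertion code,
#' residue name) are retained per atom.
#'
#' @param path path to a PDB file.
#' @param element_whitelist optional character vector of element symbols to
#'   keep; `NULL` keeps all elements.
#' @param drop_hydrogens if `TRUE`, remove hydrogen (and deuterium) atoms.
#' @return a `molecule3d` with a `residue` data.frame.
#' @export
read_pdb_atoms <- function(path, element_whitelist = NULL,
                           drop_hydrogens = FALSE) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  sym <- .pdb_elements(at)
  keep <- rep(TRUE, nrow(at))
  if (!is.null(element_whitelist))
    keep <- keep & sym %in% element_whitelist
  if (drop_hydrogens) keep <- keep & !(sym %in% c("H", "D"))
  if (!any(keep))
    stop("no atoms survive the element filter in ", path)
  at <- at[keep, , drop = FALSE]
  sym <- sym[keep]
  molecule3d(
    element_number(sym),
    cbind(at$x, at$y, at$z),
    name = basename(path),
    residue = data.frame(chain = as.character(at$chain),
                         resno = at$resno,
                         insert = ifelse(is.na(at$insert), "", at$insert),
                         resid = as.character(at$resid),
                         stringsAsFactors = FALSE))
}

# Element symbols from a bio3d atom table: prefer the element column, fall
# back to the leading letters of the atom name.
.pdb_elements <- function(at) {
  sym <- trimws(at$elesy)
  bad <- is.na(sym) | !nzchar(sym)
  if (any(bad)) {
    guess <- sub("^[0-9']*", "", trimws(at$elety[bad]))
    guess <- substr(guess, 1L, 1L)
    sym[bad] <- guess
  }
  # normalize case: "CL" -> "Cl"
  long <- nchar(sym) > 1L
  sym[long] <- paste0(substr(sym[long], 1, 1),
                      tolower(substr(sym[long], 2, 2)))
  sym
}

#' Write a molecule to a PDB file
#'
#' Fixture writer (via bio3d). Residue labels are taken from the molecule's
#' `residue` table when present; otherwise every atom is placed in residue 1
#' of chain A with residue name `UNK`.
#'
#' @param mol a `molecule3d`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb_molecule <- function(mol, path) {
  n <- n_atoms(mol)
  res <- mol$residue
  if (is.null(res))
    res <- data.frame(chain = "A", resno = 1L, insert = "", resid = "UNK")
  sym <- element_symbol(mol$Z)
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(mol$pos)),
                   resno = rep_len(res$resno, n),
                   chain = rep_len(res$chain, n),
                   resid = rep_len(res$resid, n),
                   elety = paste0(sym, seq_len(n) %% 10),
                   elesy = sym)
  invisible(path)
}

#' Construct a protein-ligand complex structure
#'
#' @param ligand `molecule3d` for the ligand.
#' @param protein `molecule3d` for the protein, with per-atom residue labels.
#' @return object of class `complex3d` with fields `ligand`, `protein`, and
#'   `complex` (the merged structure).
#' @export
complex_structure <- function(ligand, protein) {
  if (!inherits(ligand, "molecule3d")) stop("ligand must be a molecule3d")
  if (n_atoms(ligand) < 1L) stop("ligand must be non-empty")
  structure(list(ligand = ligand, protein = protein,
                 complex = .merge_molecules(ligand, protein)),
            class = "complex3d")
}

#' @export
print.complex3d <- function(x, ...) {
  np <- if (is.null(x$protein)) 0L else n_atoms(x$protein)
  cat(sprintf("<complex3d: ligand %d atoms, protein %d atoms>\n",
              n_atoms(x$ligand), np))
  invisible(x)
}

.merge_molecules <- function(a, b) {
  if (is.null(b) || n_atoms(b) == 0L) return(a)
  res_a <- a$residue
  res_b <- b$residue
  res <- NULL
  if (!is.null(res_a) || !is.null(res_b)) {
    blank <- function(m) data.frame(chain = "L", resno = 0L, insert = "",
                                    resid = "LIG")[rep(1L, n_atoms(m)), ]
    if (is.null(res_a)) res_a <- blank(a)
    if (is.null(res_b)) res_b <- blank(b)
    res <- rbind(res_a, res_b)
  }
  molecule3d(c(a$Z, b$Z), rbind(a$pos, b$pos),
             name = paste0(a$name, "+", b$name), residue = res)
}

#' Extract the binding pocket of a protein-ligand complex
#'
#' Keeps exactly the protein residues that have at least one heavy atom
#' within `radius` of any ligand heavy atom, and removes all hydrogen atoms
#' from every component. Residue membership uses the PDB identifiers
#' (chain, residue number, insertion code). The merged `complex` field is
#' rebuilt as ligand plus retained residues.
#'
#' @param cplx a `complex3d`.
#' @param radius pocket radius in Angstrom (default 6).
#' @return a `complex3d` whose protein contains only the pocket residues.
#' @export
extract_pocket <- function(cplx, radius = 6) {
  if (!inherits(cplx, "complex3d")) stop("cplx must be a complex3d")
  lig <- .drop_h(cplx$ligand)
  if (is.null(lig) || n_atoms(lig) < 1L) stop("ligand is empty")
  prot <- .drop_h(cplx$protein)
  if (is.null(prot)) {
    out <- complex_structure(lig, NULL)
    return(out)
  }
  if (is.null(prot$residue))
    stop("protein must carry residue labels for pocket extraction")
  rid <- with(prot$residue, paste(chain, resno, insert, sep = "|"))
  keep_res <- vapply(split(seq_len(n_atoms(prot)), rid), function(idx) {
    sub <- prot$pos[idx, , drop = FALSE]
    # min distance between this residue's atoms and any ligand atom
    d2 <- outer(rowSums(sub^2), rowSums(lig$pos^2), "+") -
      2 * sub %*% t(lig$pos)
    min(d2) <= radius^2 + 1e-12
  }, logical(1))
  keep <- rid %in% names(keep_res)[keep_res]
  if (!any(keep)) {
    out <- complex_structure(lig, NULL)
    return(out)
  }
  prot_kept <- .subset_atoms(prot, which(keep))
  complex_structure(lig, prot_kept)
}

.drop_h <- function(mol) {
  if (is.null(mol)) return(NULL)
  keep <- mol$Z != 1L
  if (!any(keep)) return(NULL)
  .subset_atoms(mol, which(keep))
}

.subset_atoms <- function(mol, idx) {
  molecule3d(mol$Z[idx], mol$pos[idx, , drop = FALSE],
             atom_features = if (!is.null(mol$atom_features))
               mol$atom_features[idx, , drop = FALSE],
             name = mol$name,
             residue = if (!is.null(mol$residue))
               mol$residue[idx, , drop = FALSE])
}

#' Generate a synthetic protein-ligand complex
#'
#' Fixture generator: a ligand point cloud at the origin surrounded by small
#' residue clusters placed at log-uniform distances, some inside and some
#' outside a nominal pocket radius. The true minimum heavy-atom distance of
#' every residue to the ligand is recorded so pocket extraction can be
#' checked against ground truth.
#'
#' @param seed integer seed.
#' @param n_ligand ligand atom count.
#' @param n_residues number of protein residues.
#' @param distance_range range (Angstrom) of residue centroid distances.
#' @return a `complex3d`; attribute `"residue_min_dist"` holds the named
#'   vector of true residue-ligand minimum distances.
#' @export
synthetic_complex <- function(seed, n_ligand = 8, n_residues = 6,
                              distance_range = c(2, 14)) {
  seeds <- derive_seeds(seed, 2L)
  lig <- synthetic_molecule(n_ligand, seeds[1L], mode = "blob")
  lig$pos <- lig$pos -
    matrix(colMeans(lig$pos), n_ligand, 3L, byrow = TRUE)
  lig$name <- "ligand"
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seeds[2L])
  pos <- NULL; Z <- integer(0); res <- NULL
  for (r in seq_len(n_residues)) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    centre <- u * exp(stats::runif(1, log(distance_range[1]),
                                   log(distance_range[2])))
    n_at <- sample(3:5, 1L)
    cluster <- matrix(stats::rnorm(3 * n_at, sd = 0.7), n_at, 3L) +
      matrix(centre, n_at, 3L, byrow = TRUE)
    pos <- rbind(pos, cluster)
    Z <- c(Z, sample(c(6L, 7L, 8L, 1L), n_at, replace = TRUE,
                     prob = c(0.4, 0.2, 0.2, 0.2)))
    res <- rbind(res, data.frame(chain = "A", resno = r, insert = "",
                                 resid = "GLY")[rep(1L, n_at), ])
  }
  prot <- molecule3d(Z, pos, name = "protein", residue = res)
  cplx <- complex_structure(lig, prot)
  lig_h <- .drop_h(lig)
  rid <- paste(res$chain, res$resno, res$insert, sep = "|")
  dmin <- vapply(split(seq_len(nrow(pos)), rid), function(idx) {
    heavy <- idx[Z[idx] != 1L]
    if (!length(heavy)) return(Inf)
    sub <- pos[heavy, , drop = FALSE]
    d2 <- outer(rowSums(sub^2), rowSums(lig_h$pos^2), "+") -
      2 * sub %*% t(lig_h$pos)
    sqrt(max(0, min(d2)))
  }, numeric(1))
  attr(cplx, "residue_min_dist") <- dmin
  cplx
}
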