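#' Read molecules from an SDF file
#'
#' Parses a V2000 SDF file (via ChemmineR) into a list of [molecule3d()]
#' objects with bonds taken from the bond block. Hydrogens are retained.
#' Records that fail validation (non-finite or missing coordinates, atom
#' counts disagreeing with the counts line) raise an error naming the
#' offending record index.
#'
#' @param path path to an SDF file.
#' @return list of `molecule3d`, one per record; empty list for a file with
#'   no records.
#' @export
read_sdf <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("read_sdf requires the ChemmineR package")
  if (!file.exists(path)) stop("no such file: ", path)
  if (length(readLines(path, warn = FALSE)) == 0L) return(list())
  set <- suppressWarnings(ChemmineR::read.SDFset(path))
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    sdf <- set[[i]]
    hd <- ChemmineR::header(sdf)
    ab <- ChemmineR::atomblock(sdf)
    counts <- suppressWarnings(
      as.integer(substring(hd[["Counts_Line"]], c(1, 4), c(3, 6))))
    if (is.null(ab) || nrow(ab) == 0L)
      stop(sprintf("SDF record %d ('%s'): no atoms parsed", i,
                   hd[["Molecule_Name"]]))
    pos <- ab[, 1:3, drop = FALSE]
    if (!all(is.finite(pos)))
      stop(sprintf("SDF record %d ('%s'): missing or non-numeric coordinates",
                   i, hd[["Molecule_Name"]]))
    if (!is.na(counts[1L]) && counts[1L] != nrow(ab))
      stop(sprintf(
        "SDF record %d ('%s'): counts line declares %d atoms, found %d",
        i, hd[["Molecule_Name"]], counts[1L], nrow(ab)))
    sym <- sub("_.*$", "", rownames(ab))
    bb <- ChemmineR::bondblock(sdf)
    bonds <- NULL
    if (!is.null(bb) && nrow(bb) > 0L) {
      bonds <- cbind(as.integer(bb[, 1L]), as.integer(bb[, 2L]))
      # zero-bond records parse as a single all-zero placeholder row
      bonds <- bonds[bonds[, 1L] >= 1L & bonds[, 2L] >= 1L, , drop = FALSE]
      if (nrow(bonds) == 0L) bonds <- NULL
    }
    out[[i]] <- molecule3d(element_number(sym), pos, bonds = bonds,
                           name = unname(hd[["Molecule_Name"]]))
  }
  out
}

#' Write molecules to an SDF file
#'
#' Serializes a list of [molecule3d()] objects as V2000 SDF records (via
#' ChemmineR). Coordinates are written at the format's customary 1e-4
#' Angstrom precision; bond orders are written as single bonds (the
#' `molecule3d` container does not carry orders).
#'
#' @param mols a `molecule3d` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("write_sdf requires the ChemmineR package")
  if (inherits(mols, "molecule3d")) mols <- list(mols)
  sdfs <- lapply(mols, function(mol) {
    n <- n_atoms(mol)
    nb <- if (is.null(mol$bonds)) 0L else nrow(mol$bonds)
    ab <- cbind(round(mol$pos, 4),
                matrix(0, n, 12L))
    colnames(ab) <- paste0("C", c(1:3, 5:16))
    rownames(ab) <- paste(element_symbol(mol$Z), seq_len(n), sep = "_")
    bb <- matrix(0, nb, 7L)
    colnames(bb) <- paste0("C", 1:7)
    if (nb > 0L) {
      bb[, 1L] <- mol$bonds[, 1L]
      bb[, 2L] <- mol$bonds[, 2L]
      bb[, 3L] <- 1
      rownames(bb) <- seq_len(nb)
    }
    hd <- c(Molecule_Name = mol$name, Source = "  pamnet", Comment = "",
            Counts_Line = sprintf(
              "%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
    methods::new("SDF", header = hd, atomblock = ab, bondblock = bb,
                 datablock = character(0))
  })
  set <- methods::new("SDFset", SDF = sdfs,
                      ID = vapply(mols, `[[`, "", "name"))
  suppressWarnings(ChemmineR::write.SDF(set, path))
  invisible(path)
}
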