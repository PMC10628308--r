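# The twelve scalar targets carried on the comment line of a QM9-style XYZ
# record, in their conventional order (after the three rotational constants).
.QM9_PROPERTIES <- c("mu", "alpha", "homo", "lumo", "gap", "r2", "zpve",
                     "u0", "u", "h", "g", "cv")

#' Parse one QM9-dialect XYZ record
#'
#' The dialect is the XYZ flavour used for quantum-chemistry property sets:
#' line 1 holds the atom count, line 2 (the comment line) holds an identifier
#' followed by three rotational constants and the twelve scalar targets
#' (mu, alpha, homo, lumo, gap, r2, zpve, U0, U, H, G, Cv), and each atom
#' line holds an element symbol, x, y, z and optionally a partial charge.
#' Fortran-style `*^` exponents are accepted.
#'
#' For the thermochemical targets U0, U, H and G, only atomization energies
#' are meaningful as regression targets, so per-element reference energies
#' are subtracted: `target = raw - sum_i reference[Z_i]`. The HOMO-LUMO gap
#' follows the convention `gap = lumo - homo`: when `property = "gap"` the
#' value stored is recomputed from the homo and lumo entries rather than
#' read from its own column.
#'
#' @param lines character vector holding one record.
#' @param property which target to attach: one of `"mu"`, `"alpha"`,
#'   `"homo"`, `"lumo"`, `"gap"`, `"r2"`, `"zpve"`, `"u0"`, `"u"`, `"h"`,
#'   `"g"`, `"cv"`.
#' @param reference_energies named numeric vector of per-element reference
#'   energies keyed by element symbol (e.g. `c(C = -37.8, H = -0.5)`).
#'   Required for U0/U/H/G; ignored otherwise.
#' @return a `molecule3d` with `target` set.
#' @export
read_qm9_record <- function(lines, property = "u0",
                            reference_energies = NULL) {
  property <- match.arg(tolower(property), .QM9_PROPERTIES)
  lines <- lines[nzchar(trimws(lines))]
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n)) stop("malformed XYZ record: first line is not an atom count")
  if (length(lines) < n + 2L)
    stop("malformed XYZ record: fewer atom lines than declared")
  toks <- strsplit(trimws(lines[2L]), "[[:space:]]+")[[1L]]
  vals <- suppressWarnings(as.numeric(gsub("\\*\\^", "e", toks)))
  num <- which(!is.na(vals))
  if (sum(!is.na(vals)) < 15L)
    stop("comment line must carry 15 numeric values ",
         "(3 rotational constants + 12 targets)")
  tail_idx <- utils::tail(which(!is.na(vals)), 15L)
  props <- vals[tail_idx][-(1:3)]
  names(props) <- .QM9_PROPERTIES
  name <- paste(toks[seq_len(min(tail_idx) - 1L)], collapse = " ")
  if (!nzchar(name)) name <- "qm9"
  atl <- lapply(lines[3:(n + 2L)], function(l)
    strsplit(trimws(l), "[[:space:]]+")[[1L]])
  sym <- vapply(atl, `[`, "", 1L)
  xyz <- t(vapply(atl, function(f)
    as.numeric(gsub("\\*\\^", "e", f[2:4])), numeric(3)))
  if (!all(is.finite(xyz))) stop("malformed XYZ record: bad coordinates")
  Z <- element_number(sym)
  raw <- if (property == "gap") props[["lumo"]] - props[["homo"]]
         else props[[property]]
  target <- raw
  if (property %in% c("u0", "u", "h", "g")) {
    if (is.null(reference_energies))
      stop("reference_energies required for property '", property, "'")
    miss <- setdiff(unique(sym), names(reference_energies))
    if (length(miss))
      stop("missing reference energy for element(s): ",
           paste(miss, collapse = ", "))
    target <- raw - sum(reference_energies[sym])
  }
  molecule3d(Z, xyz, target = unname(target), name = name)
}

#' Read a file of QM9-dialect XYZ records
#'
#' @param path path to a file of one or more concatenated records.
#' @inheritParams read_qm9_record
#' @return list of `molecule3d`.
#' @export
read_qm9_xyz <- function(path, property = "u0", reference_energies = NULL) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ stream at line ", i)
    rec <- lines[i:(i + n + 1L)]
    out[[length(out) + 1L]] <-
      read_qm9_record(rec, property, reference_energies)
    i <- i + n + 2L
  }
  out
}

#' Write QM9-dialect XYZ records
#'
#' Counterpart of [read_qm9_xyz()] used to build fixtures: writes each
#' molecule with a comment line carrying an identifier, three zero
#' rotational constants, and the twelve targets (all zero except the one
#' named in `property`, which takes the molecule's raw value).
#'
#' @param mols list of `molecule3d` (targets used as the raw property value).
#' @param path output path.
#' @param property which target column the molecules' `target` values fill.
#' @return `path`, invisibly.
#' @export
write_qm9_xyz <- function(mols, path, property = "u0") {
  property <- match.arg(tolower(property), .QM9_PROPERTIES)
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in mols) {
    props <- stats::setNames(numeric(12), .QM9_PROPERTIES)
    if (!is.null(mol$target)) props[property] <- mol$target[1L]
    writeLines(as.character(n_atoms(mol)), con)
    writeLines(paste(gsub("[[:space:]]+", "_", mol$name), "0 0 0",
                     paste(sprintf("%.8f", props), collapse = " ")), con)
    sym <- element_symbol(mol$Z)
    for (i in seq_len(n_atoms(mol)))
      writeLines(sprintf("%s %.6f %.6f %.6f", sym[i], mol$pos[i, 1L],
                         mol$pos[i, 2L], mol$pos[i, 3L]), con)
  }
  invisible(path)
}
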