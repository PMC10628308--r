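#' Build directed global-layer edges
#'
#' The global layer connects every pair of atoms within a relatively large
#' cutoff; it contains both local and non-local interactions. A directed
#' edge j -> i is included iff `0 < ||r_i - r_j|| <= d_g`, so both
#' directions of every pair are present and coincident atoms never create
#' an edge. Ties exactly at the cutoff are included.
#'
#' @param mol a `molecule3d`.
#' @param d_g cutoff distance in Angstrom (> 0).
#' @return list with integer vectors `src` (j), `dst` (i) and numeric
#'   `dist`, one entry per directed edge.
#' @export
build_global_edges <- function(mol, d_g) {
  if (d_g <= 0) stop("d_g must be > 0")
  .radius_edges(mol$pos, d_g)
}

.radius_edges <- function(pos, cutoff) {
  n <- nrow(pos)
  if (n < 2L) return(list(src = integer(0), dst = integer(0),
                          dist = numeric(0)))
  g2 <- rowSums(pos^2)
  d2 <- outer(g2, g2, "+") - 2 * pos %*% t(pos)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  # the Gram-matrix form suffers cancellation near zero: kill the diagonal
  # exactly and treat sub-1e-9 separations as coincident (no edge)
  diag(d) <- 0
  sel <- which(d > 1e-9 & d <= cutoff * (1 + 1e-9), arr.ind = TRUE)
  if (nrow(sel)) {
    # recompute the selected distances by direct differencing (full
    # precision, exactly invariant under rigid motions of the coordinates)
    d[sel] <- sqrt(rowSums((pos[sel[, 1L], , drop = FALSE] -
                              pos[sel[, 2L], , drop = FALSE])^2))
    sel <- sel[d[sel] <= cutoff, , drop = FALSE]
  }
  list(src = as.integer(sel[, 1L]), dst = as.integer(sel[, 2L]),
       dist = d[sel])
}

#' Build directed local-layer edges
#'
#' The local layer holds covalent/short-range interactions: either the
#' chemical bonds of the molecule (both directions of every bond, with the
#' geometric distance attached) or a small-cutoff radius graph.
#'
#' @param mol a `molecule3d`.
#' @param mode `"bonds"` (requires `mol$bonds`) or `"cutoff"`.
#' @param d_l cutoff distance in Angstrom, required for `mode = "cutoff"`.
#' @return list with `src`, `dst`, `dist` as in [build_global_edges()].
#' @export
build_local_edges <- function(mol, mode = c("bonds", "cutoff"), d_l = NULL) {
  mode <- match.arg(mode)
  if (mode == "cutoff") {
    if (is.null(d_l) || d_l <= 0) stop("d_l must be supplied and > 0")
    return(.radius_edges(mol$pos, d_l))
  }
  if (is.null(mol$bonds))
    stop("local mode 'bonds' requires bond data on the molecule")
  b <- mol$bonds
  if (nrow(b) == 0L)
    return(list(src = integer(0), dst = integer(0), dist = numeric(0)))
  src <- c(b[, 1L], b[, 2L])
  dst <- c(b[, 2L], b[, 1L])
  d <- sqrt(rowSums((mol$pos[src, , drop = FALSE] -
                       mol$pos[dst, , drop = FALSE])^2))
  if (any(d == 0)) stop("bonded atoms with coincident positions")
  list(src = src, dst = dst, dist = d)
}

#' Angle between two arms at a vertex
#'
#' Computes the angle between `(a - vertex)` and `(b - vertex)` with the
#' cosine clamped to `[-1, 1]` before `acos`. Vectorized over rows when the
#' arguments are matrices.
#'
#' @param a,vertex,b numeric 3-vectors or n x 3 matrices of positions.
#' @return angle(s) in radians, in `[0, pi]`.
#' @export
angle_between <- function(a, vertex, b) {
  to_m <- function(x) if (is.matrix(x)) x else matrix(x, 1L, 3L)
  a <- to_m(a); v <- to_m(vertex); b <- to_m(b)
  u1 <- a - v
  u2 <- b - v
  n1 <- sqrt(rowSums(u1^2))
  n2 <- sqrt(rowSums(u2^2))
  if (any(n1 == 0) || any(n2 == 0))
    stop("zero-length arm: point coincides with the vertex")
  cosv <- rowSums(u1 * u2) / (n1 * n2)
  acos(pmin(1, pmax(-1, cosv)))
}

#' Enumerate one-hop and two-hop angles of the local layer
#'
#' For every directed local edge j -> i, the one-hop terms pair it with each
#' other incoming edge j' -> i (angle at vertex i between the two arms), and
#' the two-hop terms pair it with each edge k -> j, k != i (angle at vertex
#' j). The `"one_hop_only"` variant (the simplified one-hop model) returns
#' an empty two-hop table.
#'
#' @param edges directed local edge list (`src`, `dst`, `dist`).
#' @param pos n x 3 position matrix.
#' @param variant `"full"` or `"one_hop_only"`.
#' @return list of two data.frames. `one_hop` has columns `edge` (index of
#'   j -> i), `partner` (index of j' -> i), `jp`, `i`, `j`, `theta`;
#'   `two_hop` has `edge` (j -> i), `partner` (k -> j), `k`, `j`, `i`,
#'   `theta`. Angles in radians.
#' @export
enumerate_angles <- function(edges, pos, variant = c("full", "one_hop_only")) {
  variant <- match.arg(variant)
  ne <- length(edges$src)
  empty1 <- data.frame(edge = integer(0), partner = integer(0),
                       jp = integer(0), i = integer(0), j = integer(0),
                       theta = numeric(0))
  empty2 <- data.frame(edge = integer(0), partner = integer(0),
                       k = integer(0), j = integer(0), i = integer(0),
                       theta = numeric(0))
  if (ne == 0L) return(list(one_hop = empty1, two_hop = empty2))
  in_by_node <- split(seq_len(ne), edges$dst)

  # one-hop: ordered pairs of distinct incoming edges at each vertex i
  oh_e <- integer(0); oh_p <- integer(0)
  for (ids in in_by_node) {
    k <- length(ids)
    if (k < 2L) next
    grid <- expand.grid(e = ids, p = ids)
    grid <- grid[grid$e != grid$p, , drop = FALSE]
    oh_e <- c(oh_e, grid$e)
    oh_p <- c(oh_p, grid$p)
  }
  if (length(oh_e)) {
    i_v <- edges$dst[oh_e]
    one_hop <- data.frame(
      edge = oh_e, partner = oh_p,
      jp = edges$src[oh_p], i = i_v, j = edges$src[oh_e],
      theta = angle_between(pos[edges$src[oh_p], , drop = FALSE],
                            pos[i_v, , drop = FALSE],
                            pos[edges$src[oh_e], , drop = FALSE]))
  } else one_hop <- empty1

  if (variant == "one_hop_only")
    return(list(one_hop = one_hop, two_hop = empty2))

  # two-hop: for edge j -> i, every edge k -> j with k != i
  th_e <- integer(0); th_p <- integer(0)
  for (e in seq_len(ne)) {
    j <- edges$src[e]; i <- edges$dst[e]
    cand <- in_by_node[[as.character(j)]]
    if (is.null(cand)) next
    cand <- cand[edges$src[cand] != i]
    if (length(cand)) {
      th_e <- c(th_e, rep.int(e, length(cand)))
      th_p <- c(th_p, cand)
    }
  }
  if (length(th_e)) {
    j_v <- edges$src[th_e]
    two_hop <- data.frame(
      edge = th_e, partner = th_p,
      k = edges$src[th_p], j = j_v, i = edges$dst[th_e],
      theta = angle_between(pos[edges$src[th_p], , drop = FALSE],
                            pos[j_v, , drop = FALSE],
                            pos[edges$dst[th_e], , drop = FALSE]))
  } else two_hop <- empty2
  list(one_hop = one_hop, two_hop = two_hop)
}

#' Build the two-layer multiplex graph of a molecule
#'
#' Constructs the global layer (large-cutoff radius graph), the local layer
#' (chemical bonds or small-cutoff radius graph), and the one-hop/two-hop
#' angle tables of the local layer.
#'
#' @param mol a `molecule3d`.
#' @param d_g global-layer cutoff (Angstrom).
#' @param local_mode `"bonds"` or `"cutoff"`.
#' @param d_l local-layer cutoff, required when `local_mode = "cutoff"`.
#' @param variant `"full"` (one-hop and two-hop angles) or `"one_hop_only"`.
#' @return object of class `multiplex_graph`.
#' @export
multiplex_graph <- function(mol, d_g, local_mode = c("bonds", "cutoff"),
                            d_l = NULL,
                            variant = c("full", "one_hop_only")) {
  local_mode <- match.arg(local_mode)
  variant <- match.arg(variant)
  gl <- build_global_edges(mol, d_g)
  lo <- build_local_edges(mol, local_mode, d_l)
  ang <- enumerate_angles(lo, mol$pos, variant)
  structure(list(n = n_atoms(mol), global = gl, local = lo,
                 one_hop = ang$one_hop, two_hop = ang$two_hop,
                 d_g = d_g, d_l = d_l, local_mode = local_mode,
                 variant = variant),
            class = "multiplex_graph")
}

#' @export
print.multiplex_graph <- function(x, ...) {
  cat(sprintf(paste0("<multiplex_graph: %d nodes, %d global edges, ",
                     "%d local edges, %d one-hop + %d two-hop angles>\n"),
              x$n, length(x$global$src), length(x$local$src),
              nrow(x$one_hop), nrow(x$two_hop)))
  invisible(x)
}

#' Count messages per hidden layer
#'
#' Tally of the messages a hidden layer computes on a multiplex graph.
#' Under the default `"pamnet"` convention, the global pass computes one
#' message per directed global edge, and the local pass evaluates one
#' angular term per one-hop and per two-hop angle entry — for a directed
#' local edge j -> i that is `(deg(i) - 1) + (deg(j) - 1)` terms, i.e.
#' O(N k_g + 2 N k_l^2) in total. The `"triplet"` convention counts what a
#' single-layer directional (triplet-based) model would evaluate on the
#' global graph: one message per two-hop triplet, `sum_(j->i) (deg_g(j) -
#' 1)`, i.e. O(N k_g^2).
#'
#' @param g a `multiplex_graph`.
#' @param convention `"pamnet"` or `"triplet"`.
#' @return list with `global_messages`, `local_messages`, `total`.
#' @export
count_messages <- function(g, convention = c("pamnet", "triplet")) {
  convention <- match.arg(convention)
  if (convention == "triplet") {
    deg <- tabulate(g$global$dst, nbins = g$n)
    loc <- sum(pmax(deg[g$global$src] - 1L, 0L))
    return(list(global_messages = 0L, local_messages = loc, total = loc))
  }
  glob <- length(g$global$src)
  loc <- nrow(g$one_hop) + nrow(g$two_hop)
  if (g$variant == "full") {
    # closed form: sum over directed local edges of (deg(i)-1) + (deg(j)-1)
    deg <- tabulate(g$local$dst, nbins = g$n)
    stopifnot(loc == sum(deg[g$local$dst] - 1L) +
                sum(pmax(deg[g$local$src] - 1L, 0L)))
  }
  list(global_messages = glob, local_messages = loc, total = glob + loc)
}

#' Serialize a multiplex graph to JSON
#'
#' Schema: an object with `n`, `d_g`, `d_l`, `local_mode`, `variant`;
#' `global` and `local` as objects of arrays `src`, `dst`, `dist`
#' (1-based indices); `one_hop` and `two_hop` as objects of arrays matching
#' the angle-table columns.
#'
#' @param g a `multiplex_graph`.
#' @param path optional output file; when `NULL` the JSON string is
#'   returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
graph_to_json <- function(g, path = NULL) {
  obj <- list(n = g$n, d_g = g$d_g, d_l = g$d_l, local_mode = g$local_mode,
              variant = g$variant, global = g$global, local = g$local,
              one_hop = as.list(g$one_hop), two_hop = as.list(g$two_hop))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Deserialize a multiplex graph from JSON
#'
#' @param path file path or JSON string produced by [graph_to_json()].
#' @return a `multiplex_graph`.
#' @export
graph_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  fix_edges <- function(e) list(src = as.integer(e$src),
                                dst = as.integer(e$dst),
                                dist = as.numeric(e$dist))
  fix_ang <- function(a, cols) {
    if (length(a$edge) == 0L)
      return(stats::setNames(
        data.frame(matrix(integer(0), 0, length(cols))), cols))
    as.data.frame(a)[, cols]
  }
  structure(list(n = as.integer(obj$n), global = fix_edges(obj$global),
                 local = fix_edges(obj$local),
                 one_hop = fix_ang(obj$one_hop,
                                   c("edge", "partner", "jp", "i", "j",
                                     "theta")),
                 two_hop = fix_ang(obj$two_hop,
                                   c("edge", "partner", "k", "j", "i",
                                     "theta")),
                 d_g = obj$d_g, d_l = obj$d_l,
                 local_mode = obj$local_mode, variant = obj$variant),
            class = "multiplex_graph")
}
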