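#' Model configuration
#'
#' Collects the architecture and graph-construction choices of a multiplex
#' message-passing model. Task presets fill in the cutoffs and input mode
#' used for each molecular system: small-molecule property regression
#' (bond-mode local layer, global cutoff 5 Angstrom), dipole-moment
#' prediction (same, with the equivariant vector head), RNA structural-model
#' scoring (cutoff-mode local layer at 2.6 Angstrom, global 20 Angstrom),
#' and protein-ligand affinity (local 2, global 6 Angstrom, 18 chemical
#' features per atom).
#'
#' @param task one of `"qm9_scalar"`, `"qm9_dipole"`, `"rna_score"`,
#'   `"pdbbind_affinity"`.
#' @param n_layers number of hidden layers T (>= 1).
#' @param hidden_dim embedding width F.
#' @param fused_dim width D of the fused per-layer output; 1 for scalar
#'   regression.
#' @param n_rbf,n_abf radial / angular basis sizes.
#' @param envelope_exponent polynomial cutoff envelope exponent.
#' @param d_g global-layer cutoff, Angstrom.
#' @param d_l local-layer cutoff, Angstrom (`NULL` in bond mode).
#' @param local_mode `"bonds"` or `"cutoff"`.
#' @param variant `"full"` (one-hop + two-hop angles) or `"s"` (the
#'   simplified one-hop-only model).
#' @param readout `"sum"`, `"mean"`, or `"node"` (no graph pooling).
#' @param feature_mode `"atomic_number"` (trainable per-element embeddings)
#'   or `"chemical_features"` (learned linear map of 18 features).
#' @param elements atomic numbers the embedding table must cover (extended
#'   automatically by [pamnet_fit()] from the training data).
#' @param n_features width of the chemical feature rows (default 18).
#' @return object of class `pamnet_config`.
#' @export
pamnet_config <- function(task = c("qm9_scalar", "qm9_dipole", "rna_score",
                                   "pdbbind_affinity"),
                          n_layers = 3, hidden_dim = 128, fused_dim = 1,
                          n_rbf = 16, n_abf = 7, envelope_exponent = 5,
                          d_g = NULL, d_l = NULL, local_mode = NULL,
                          variant = c("full", "s"),
                          readout = c("sum", "mean", "node"),
                          feature_mode = NULL,
                          elements = c(1L, 6L, 7L, 8L), n_features = 18L) {
  task <- match.arg(task)
  variant <- match.arg(variant)
  readout <- match.arg(readout)
  defaults <- switch(task,
    qm9_scalar = ,
    qm9_dipole = list(d_g = 5, d_l = NULL, local_mode = "bonds",
                      feature_mode = "atomic_number"),
    rna_score = list(d_g = 20, d_l = 2.6, local_mode = "cutoff",
                     feature_mode = "atomic_number"),
    pdbbind_affinity = list(d_g = 6, d_l = 2, local_mode = "cutoff",
                            feature_mode = "chemical_features"))
  if (is.null(d_g)) d_g <- defaults$d_g
  if (is.null(local_mode)) local_mode <- defaults$local_mode
  if (is.null(d_l)) d_l <- defaults$d_l
  if (is.null(feature_mode)) feature_mode <- defaults$feature_mode
  if (n_layers < 1) stop("n_layers must be >= 1")
  if (hidden_dim < 1 || fused_dim < 1) stop("dimensions must be >= 1")
  structure(list(task = task, n_layers = as.integer(n_layers),
                 hidden_dim = as.integer(hidden_dim),
                 fused_dim = as.integer(fused_dim),
                 n_rbf = as.integer(n_rbf), n_abf = as.integer(n_abf),
                 envelope_exponent = envelope_exponent, d_g = d_g,
                 d_l = d_l, local_mode = local_mode, variant = variant,
                 readout = readout, feature_mode = feature_mode,
                 elements = sort(unique(as.integer(elements))),
                 n_features = as.integer(n_features)),
            class = "pamnet_config")
}

#' @export
print.pamnet_config <- function(x, ...) {
  cat(sprintf(
    "<pamnet_config: task=%s, T=%d, F=%d, D=%d, d_g=%g, local=%s%s, %s>\n",
    x$task, x$n_layers, x$hidden_dim, x$fused_dim, x$d_g, x$local_mode,
    if (!is.null(x$d_l)) sprintf(" (d_l=%g)", x$d_l) else "",
    if (x$variant == "s") "one-hop only" else "full"))
  invisible(x)
}

.angle_variant <- function(config) {
  if (config$variant == "s") "one_hop_only" else "full"
}

# Fan-in uniform initialization (the standard linear-layer default):
# U(-1/sqrt(fan_in), 1/sqrt(fan_in)) for weights and biases.
.init_mat <- function(nr, nc, fan_in = nr) {
  b <- 1 / sqrt(max(1, fan_in))
  matrix(stats::runif(nr * nc, -b, b), nr, nc)
}

.lin_init <- function(params, name, nin, nout) {
  params[[paste0(name, ".W")]] <- .init_mat(nin, nout)
  params
}

.mlp2_init <- function(params, prefix, nin, nh, nout) {
  params[[paste0(prefix, ".W1")]] <- .init_mat(nin, nh)
  params[[paste0(prefix, ".b1")]] <- .init_mat(1, nh, nin)
  params[[paste0(prefix, ".W2")]] <- .init_mat(nh, nout)
  params[[paste0(prefix, ".b2")]] <- .init_mat(1, nout, nh)
  params
}

#' Initialize model parameters
#'
#' Flat named list of weight matrices. Linear layers use the standard
#' fan-in uniform scheme; the per-element input embedding table uses
#' uniform(-sqrt(3), sqrt(3)).
#'
#' @param config a [pamnet_config()].
#' @param seed integer seed.
#' @return named list of numeric matrices.
#' @export
pamnet_params <- function(config, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  Fd <- config$hidden_dim
  D <- config$fused_dim
  p <- list()
  if (config$feature_mode == "atomic_number") {
    p[["embed"]] <- atom_embedding_table(config$elements, Fd,
                                         derive_seeds(seed, 1L))
  } else {
    p[["feat.W"]] <- .init_mat(config$n_features, Fd)
    p[["feat.b"]] <- .init_mat(1, Fd, config$n_features)
  }
  for (t in seq_len(config$n_layers)) {
    for (br in c("g", "l")) {
      pre <- sprintf("L%d.%s", t, br)
      p <- .mlp2_init(p, paste0(pre, ".msg"), 2 * Fd + config$n_rbf, Fd, Fd)
      p[[paste0(pre, ".phid.W")]] <- .init_mat(config$n_rbf, Fd)
      if (br == "l")
        p <- .mlp2_init(p, paste0(pre, ".phith"), config$n_abf, Fd, Fd)
      for (r in 1:3)
        p <- .mlp2_init(p, sprintf("%s.rb%d", pre, r), Fd, Fd, Fd)
      p[[paste0(pre, ".z.W1")]] <- .init_mat(Fd, Fd)
      p[[paste0(pre, ".z.b1")]] <- .init_mat(1, Fd, Fd)
      p[[paste0(pre, ".z.W2")]] <- .init_mat(Fd, Fd)
      p[[paste0(pre, ".z.b2")]] <- .init_mat(1, Fd, Fd)
      p[[paste0(pre, ".z.W3")]] <- .init_mat(Fd, Fd)
      p[[paste0(pre, ".z.b3")]] <- .init_mat(1, Fd, Fd)
      p[[sprintf("L%d.att.%s.W", t, br)]] <- .init_mat(Fd, 1)
      p[[sprintf("L%d.out.%s.W", t, br)]] <- .init_mat(Fd, D)
    }
  }
  p
}

#' Construct an untrained model
#'
#' Bundles a configuration with freshly initialized parameters. Fit it
#' with [pamnet_fit()] or evaluate it directly with [predict.pamnet()].
#'
#' @param config a [pamnet_config()].
#' @param seed integer seed for the parameter initialization.
#' @return object of class `pamnet` with fields `config` and `params`.
#' @export
pamnet <- function(config = pamnet_config(), seed = 1L) {
  structure(list(config = config, params = pamnet_params(config, seed)),
            class = "pamnet")
}

#' @export
print.pamnet <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<pamnet model: %d parameters>\n", np))
  print(x$config)
  invisible(x)
}

#' Assemble the batched model inputs for a set of molecules
#'
#' Builds the multiplex graph and basis features of every molecule and
#' concatenates them into one disjoint-union batch with offset indices,
#' ready for the forward pass.
#'
#' @param mols list of `molecule3d`.
#' @param config a [pamnet_config()].
#' @return a `pamnet_batch` list (nodes, edges, angle tables, features,
#'   graph ids, position differences per edge).
#' @export
prepare_batch <- function(mols, config) {
  if (inherits(mols, "molecule3d")) mols <- list(mols)
  n_graph <- length(mols)
  parts <- lapply(mols, function(mol) {
    g <- multiplex_graph(mol, d_g = config$d_g,
                         local_mode = config$local_mode, d_l = config$d_l,
                         variant = .angle_variant(config))
    list(g = g, f = featurize_graph(g, mol, config), mol = mol)
  })
  node_off <- cumsum(c(0L, vapply(parts, function(p) p$g$n, integer(1))))
  ledge_off <- cumsum(c(0L, vapply(parts, function(p)
    length(p$g$local$src), integer(1))))
  acc <- function(fun) do.call(rbind, lapply(parts, fun))
  accv <- function(fun) do.call(c, lapply(seq_along(parts), fun))
  Z <- accv(function(i) parts[[i]]$mol$Z)
  graph_id <- accv(function(i) rep.int(i, parts[[i]]$g$n))
  src_g <- accv(function(i) parts[[i]]$g$global$src + node_off[i])
  dst_g <- accv(function(i) parts[[i]]$g$global$dst + node_off[i])
  src_l <- accv(function(i) parts[[i]]$g$local$src + node_off[i])
  dst_l <- accv(function(i) parts[[i]]$g$local$dst + node_off[i])
  one_edge <- accv(function(i) parts[[i]]$g$one_hop$edge + ledge_off[i])
  one_partner <- accv(function(i)
    parts[[i]]$g$one_hop$partner + ledge_off[i])
  two_edge <- accv(function(i) parts[[i]]$g$two_hop$edge + ledge_off[i])
  two_partner <- accv(function(i)
    parts[[i]]$g$two_hop$partner + ledge_off[i])
  pos <- acc(function(p) p$mol$pos)
  h0_input <- if (config$feature_mode == "chemical_features")
    acc(function(p) as.matrix(p$f$h0_input)) else NULL
  structure(list(
    n_nodes = node_off[length(node_off)], n_graph = n_graph,
    Z = Z, graph_id = graph_id, h0_features = h0_input,
    src_g = src_g, dst_g = dst_g, src_l = src_l, dst_l = dst_l,
    e_global = acc(function(p) p$f$e_global),
    e_local = acc(function(p) p$f$e_local),
    a_one = acc(function(p) p$f$a_one_hop),
    a_two = acc(function(p) p$f$a_two_hop),
    one_edge = one_edge, one_partner = one_partner,
    two_edge = two_edge, two_partner = two_partner,
    diff_g = pos[src_g, , drop = FALSE] - pos[dst_g, , drop = FALSE],
    diff_l = pos[src_l, , drop = FALSE] - pos[dst_l, , drop = FALSE],
    node_counts = tabulate(graph_id, nbins = n_graph)),
    class = "pamnet_batch")
}

# Wrap every parameter matrix in a tape node.
.params_to_nodes <- function(tape, params) {
  lapply(params, function(v) ad_param(tape, v))
}

# Message embedding m_ji = MLP([h_j | h_i | e_ji]) over a directed edge set.
.ad_message <- function(h, e_nd, src, dst, pn, pre) {
  x <- ad_cbind(ad_gather(h, src), ad_gather(h, dst), e_nd)
  ad_mlp2(x, list(W1 = pn[[paste0(pre, ".msg.W1")]],
                  b1 = pn[[paste0(pre, ".msg.b1")]],
                  W2 = pn[[paste0(pre, ".msg.W2")]],
                  b2 = pn[[paste0(pre, ".msg.b2")]]))
}

# Update block: three residual blocks plus a skip from the message-block
# input (h_prev) to the output of the first residual block, then a
# three-layer MLP for the per-layer output z (width F).
.ad_update <- function(h_mp, h_prev, pn, pre) {
  mlp2 <- function(x, r) ad_mlp2(x, list(
    W1 = pn[[sprintf("%s.rb%d.W1", pre, r)]],
    b1 = pn[[sprintf("%s.rb%d.b1", pre, r)]],
    W2 = pn[[sprintf("%s.rb%d.W2", pre, r)]],
    b2 = pn[[sprintf("%s.rb%d.b2", pre, r)]]))
  u <- ad_add(h_mp, mlp2(h_mp, 1L))
  if (!is.null(h_prev)) u <- ad_add(u, h_prev)
  u <- ad_add(u, mlp2(u, 2L))
  u <- ad_add(u, mlp2(u, 3L))
  z1 <- ad_swish(ad_add_bias(ad_matmul(u, pn[[paste0(pre, ".z.W1")]]),
                             pn[[paste0(pre, ".z.b1")]]))
  z2 <- ad_swish(ad_add_bias(ad_matmul(z1, pn[[paste0(pre, ".z.W2")]]),
                             pn[[paste0(pre, ".z.b2")]]))
  z <- ad_add_bias(ad_matmul(z2, pn[[paste0(pre, ".z.W3")]]),
                   pn[[paste0(pre, ".z.b3")]])
  list(h_next = u, z = z)
}

#' Forward pass of the multiplex message-passing model
#'
#' Runs the full composition — initial embeddings, then per hidden layer
#' the global message passing (distances only), the local message passing
#' (distances plus one-hop/two-hop angular terms), both update blocks, and
#' the attention-pooling fusion — followed by the layer-sum readout. For
#' the dipole task it additionally maintains per-node geometric vectors and
#' returns the predicted vector per graph.
#'
#' @param params parameter list from [pamnet_params()].
#' @param batch a `pamnet_batch` from [prepare_batch()].
#' @param config the matching [pamnet_config()].
#' @param tape optionally, an existing [ad_tape()]; when supplied the
#'   returned list carries differentiable nodes (`y_node_ad`, `u_ad`) for
#'   training.
#' @return list with `y` (graph-level output, `n_graph x D`, or node-level
#'   matrix when `readout = "node"`), `y_node` (N x D), `alpha` (list per
#'   layer of N x 2 matrices, columns global/local), `u` (n_graph x 3
#'   dipole vectors, dipole task only), `mu_norm` (their magnitudes),
#'   `message_counts` (per-layer evaluated global and angular message
#'   terms), and when a tape was supplied the nodes `y_ad`, `u_ad`.
#' @export
pamnet_forward <- function(params, batch, config, tape = NULL) {
  own_tape <- is.null(tape)
  if (own_tape) tape <- ad_tape()
  pn <- .params_to_nodes(tape, params)
  N <- batch$n_nodes
  Fd <- config$hidden_dim
  dipole <- config$task == "qm9_dipole"

  if (config$feature_mode == "chemical_features") {
    x <- ad_const(tape, batch$h0_features)
    h <- ad_add_bias(ad_matmul(x, pn[["feat.W"]]), pn[["feat.b"]])
  } else {
    ridx <- match(as.character(batch$Z), rownames(params[["embed"]]))
    if (anyNA(ridx))
      stop("embedding table has no row for Z = ",
           paste(unique(batch$Z[is.na(ridx)]), collapse = ", "))
    h <- ad_gather(pn[["embed"]], ridx)
  }

  e_g <- ad_const(tape, batch$e_global)
  e_l <- ad_const(tape, batch$e_local)
  a_one <- ad_const(tape, batch$a_one)
  a_two <- ad_const(tape, batch$a_two)
  n_Eg <- length(batch$src_g)
  n_El <- length(batch$src_l)

  y_node <- NULL
  u_node <- NULL
  alphas <- vector("list", config$n_layers)
  msg_counts <- data.frame(layer = seq_len(config$n_layers),
                           global = 0, local = 0)

  for (t in seq_len(config$n_layers)) {
    pre_g <- sprintf("L%d.g", t)
    pre_l <- sprintf("L%d.l", t)

    # -- global branch ----------------------------------------------------
    if (n_Eg > 0L) {
      m_g <- .ad_message(h, e_g, batch$src_g, batch$dst_g, pn, pre_g)
      phid_g <- ad_matmul(e_g, pn[[paste0(pre_g, ".phid.W")]])
      h_g_mp <- ad_add(h, ad_scatter_add(ad_mul(m_g, phid_g),
                                         batch$dst_g, N))
      msg_counts$global[t] <- n_Eg
    } else {
      m_g <- NULL
      h_g_mp <- h
    }
    ub_g <- .ad_update(h_g_mp, h, pn, pre_g)

    # -- local branch -----------------------------------------------------
    if (n_El > 0L) {
      m_l <- .ad_message(h, e_l, batch$src_l, batch$dst_l, pn, pre_l)
      phid_l <- ad_matmul(e_l, pn[[paste0(pre_l, ".phid.W")]])
      phith <- function(a_nd) ad_mlp2(a_nd, list(
        W1 = pn[[paste0(pre_l, ".phith.W1")]],
        b1 = pn[[paste0(pre_l, ".phith.b1")]],
        W2 = pn[[paste0(pre_l, ".phith.W2")]],
        b2 = pn[[paste0(pre_l, ".phith.b2")]]))
      m_prime <- m_l
      if (length(batch$one_edge)) {
        t1 <- ad_mul(ad_mul(ad_gather(m_l, batch$one_partner),
                            ad_gather(phid_l, batch$one_partner)),
                     phith(a_one))
        m_prime <- ad_add(m_prime, ad_scatter_add(t1, batch$one_edge, n_El))
        msg_counts$local[t] <- msg_counts$local[t] + length(batch$one_edge)
      }
      if (length(batch$two_edge)) {
        t2 <- ad_mul(ad_mul(ad_gather(m_l, batch$two_partner),
                            ad_gather(phid_l, batch$two_partner)),
                     phith(a_two))
        m_prime <- ad_add(m_prime, ad_scatter_add(t2, batch$two_edge, n_El))
        msg_counts$local[t] <- msg_counts$local[t] + length(batch$two_edge)
      }
      h_l_mp <- ad_add(h, ad_scatter_add(ad_mul(m_prime, phid_l),
                                         batch$dst_l, N))
    } else {
      m_l <- NULL
      h_l_mp <- h
    }
    ub_l <- .ad_update(h_l_mp, h, pn, pre_l)

    # -- attention-pooling fusion ----------------------------------------
    logit_g <- ad_leakyrelu(ad_matmul(ub_g$z, pn[[sprintf("L%d.att.g.W", t)]]))
    logit_l <- ad_leakyrelu(ad_matmul(ub_l$z, pn[[sprintf("L%d.att.l.W", t)]]))
    # two-way softmax in its stable sigmoid form
    alpha_g <- ad_sigmoid(ad_sub(logit_g, logit_l))
    alpha_l <- ad_sub(ad_const(tape, matrix(1, N, 1L)), alpha_g)
    fused <- ad_add(
      ad_scale_rows(ad_matmul(ub_g$z, pn[[sprintf("L%d.out.g.W", t)]]),
                    alpha_g),
      ad_scale_rows(ad_matmul(ub_l$z, pn[[sprintf("L%d.out.l.W", t)]]),
                    alpha_l))
    y_node <- if (is.null(y_node)) fused else ad_add(y_node, fused)
    alphas[[t]] <- cbind(g = as.vector(alpha_g$val),
                         l = as.vector(alpha_l$val))

    # -- geometric vectors (equivariant head) -----------------------------
    if (dipole) {
      zero_v <- function() ad_const(tape, matrix(0, N, 3L))
      v_g <- if (!is.null(m_g))
        ad_scatter_add(ad_scale_rows(ad_const(tape, batch$diff_g),
                                     ad_rownorm(m_g)), batch$src_g, N)
      else zero_v()
      v_l <- if (!is.null(m_l))
        ad_scatter_add(ad_scale_rows(ad_const(tape, batch$diff_l),
                                     ad_rownorm(m_l)), batch$src_l, N)
      else zero_v()
      coef_g <- ad_mul(alpha_g,
                       ad_matmul(ub_g$z, pn[[sprintf("L%d.out.g.W", t)]]))
      coef_l <- ad_mul(alpha_l,
                       ad_matmul(ub_l$z, pn[[sprintf("L%d.out.l.W", t)]]))
      u_t <- ad_add(ad_scale_rows(v_g, coef_g), ad_scale_rows(v_l, coef_l))
      u_node <- if (is.null(u_node)) u_t else ad_add(u_node, u_t)
    }

    h <- ad_add(ub_g$h_next, ub_l$h_next)
  }

  y_graph <- ad_scatter_add(y_node, batch$graph_id, batch$n_graph)
  if (config$readout == "mean") {
    inv <- ad_const(tape, matrix(1 / batch$node_counts, ncol = 1L))
    y_graph <- ad_scale_rows(y_graph, inv)
  }
  out <- list(
    y = if (config$readout == "node") y_node$val else y_graph$val,
    y_node = y_node$val,
    alpha = alphas,
    message_counts = msg_counts)
  if (dipole) {
    u_graph <- ad_scatter_add(u_node, batch$graph_id, batch$n_graph)
    out$u <- u_graph$val
    out$mu_norm <- sqrt(rowSums(u_graph$val^2))
    out$u_ad <- u_graph
  }
  out$y_ad <- if (config$readout == "node") y_node else y_graph
  out$param_nodes <- pn
  out$tape <- tape
  out
}

#' Evaluate a model on molecules
#'
#' @param object a `pamnet` (untrained) or `pamnet_fit` (trained) model.
#' @param newdata a `molecule3d` or list of them.
#' @param type `"response"` for the task's scalar prediction (dipole task:
#'   the vector magnitude), `"vector"` for the dipole vector, `"node"` for
#'   per-node outputs, `"detail"` for the full forward result.
#' @param ... unused.
#' @return numeric vector, matrix, or the detailed list.
#' @export
predict.pamnet <- function(object, newdata, type = c("response", "vector",
                                                     "node", "detail"),
                           ...) {
  type <- match.arg(type)
  batch <- if (inherits(newdata, "pamnet_batch")) newdata
           else prepare_batch(newdata, object$config)
  fw <- pamnet_forward(object$params, batch, object$config)
  switch(type,
         response = if (object$config$task == "qm9_dipole") fw$mu_norm
                    else as.vector(fw$y),
         vector = fw$u,
         node = fw$y_node,
         detail = fw)
}

# ---------------------------------------------------------------------------
# Thin single-operation surfaces over the tape machinery. These exist so the
# individual blocks can be probed with fixed weights, independently of the
# full model.

#' Message embeddings for a directed edge set
#'
#' `m_ji = MLP([h_j | h_i | e_ji])` with a two-layer Swish MLP.
#'
#' @param h node-embedding matrix (N x F).
#' @param e edge-feature matrix (E x n_rbf).
#' @param src,dst integer vectors: edge j -> i has source j, target i.
#' @param weights list with `W1`, `b1`, `W2`, `b2`.
#' @return message matrix (E x F).
#' @export
message_embed <- function(h, e, src, dst, weights) {
  if (length(src) == 0L) return(matrix(0, 0L, ncol(weights$W2)))
  tape <- ad_tape()
  hn <- ad_const(tape, h)
  x <- ad_cbind(ad_gather(hn, src), ad_gather(hn, dst), ad_const(tape, e))
  ad_mlp2(x, lapply(weights, function(w) ad_const(tape, w)))$val
}

#' One global message-passing step
#'
#' `h_i <- h_i + sum_j m_ji * phi_d(e_ji)` with the bias-free linear
#' distance filter `phi_d(e) = e W_e`. Nodes with no neighbours are
#' unchanged.
#'
#' @param h node-embedding matrix (N x F).
#' @param m message matrix (E x F).
#' @param e edge-feature matrix (E x n_rbf).
#' @param src,dst directed edge indices.
#' @param W_e distance-filter weight (n_rbf x F).
#' @return updated embedding matrix (N x F).
#' @export
global_message_pass <- function(h, m, e, src, dst, W_e) {
  if (length(src) == 0L) return(h)
  h + .scatter_rows(m * (e %*% W_e), dst, nrow(h))
}

.scatter_rows <- function(x, idx, n) {
  out <- matrix(0, n, ncol(x))
  if (length(idx)) {
    acc <- rowsum(x, group = idx)
    out[as.integer(rownames(acc)), ] <- acc
  }
  out
}

#' One local message-passing step with angular terms
#'
#' Augments each directed-edge message with its one-hop and two-hop angular
#' terms and then aggregates:
#' `m'_ji = m_ji + sum_(j') m_j'i * phi_d(e_j'i) * phi_th(a_j'i,ji)
#'                + sum_(k) m_kj * phi_d(e_kj) * phi_th(a_kj,ji)`,
#' `h_i <- h_i + sum_j m'_ji * phi_d(e_ji)`. The one-hop-only variant drops
#' the second sum (pass empty `two_hop` tables).
#'
#' @param h node-embedding matrix (N x F).
#' @param m message matrix (E x F).
#' @param e local edge-feature matrix (E x n_rbf).
#' @param angles list as from [enumerate_angles()] (`one_hop`, `two_hop`).
#' @param a_one,a_two angle-feature matrices for the two tables.
#' @param dst directed-edge targets.
#' @param W_e distance-filter weight.
#' @param phith_weights list `W1`, `b1`, `W2`, `b2` of the angular MLP.
#' @return list with `h` (updated embeddings), `m_prime` (augmented
#'   messages), and `n_angular_terms` (count of angular filter
#'   evaluations).
#' @export
local_message_pass <- function(h, m, e, angles, a_one, a_two, dst, W_e,
                               phith_weights) {
  E <- nrow(m)
  if (E == 0L) return(list(h = h, m_prime = m, n_angular_terms = 0L))
  if (nrow(angles$one_hop) != nrow(a_one) ||
      nrow(angles$two_hop) != nrow(a_two))
    stop("angle tables and angle features disagree")
  tape <- ad_tape()
  cw <- lapply(phith_weights, function(w) ad_const(tape, w))
  phith <- function(a) ad_mlp2(ad_const(tape, a), cw)$val
  phid <- e %*% W_e
  m_prime <- m
  n_terms <- 0L
  oh <- angles$one_hop
  if (nrow(oh)) {
    t1 <- m[oh$partner, , drop = FALSE] *
      phid[oh$partner, , drop = FALSE] * phith(a_one)
    m_prime <- m_prime + .scatter_rows(t1, oh$edge, E)
    n_terms <- n_terms + nrow(oh)
  }
  th <- angles$two_hop
  if (nrow(th)) {
    t2 <- m[th$partner, , drop = FALSE] *
      phid[th$partner, , drop = FALSE] * phith(a_two)
    m_prime <- m_prime + .scatter_rows(t2, th$edge, E)
    n_terms <- n_terms + nrow(th)
  }
  list(h = h + .scatter_rows(m_prime * phid, dst, nrow(h)),
       m_prime = m_prime, n_angular_terms = n_terms)
}

#' One update block
#'
#' Three residual blocks (two-layer Swish MLP plus a skip across each) with
#' an additional skip from the message-block input to the output of the
#' first residual block, followed by a three-layer MLP producing the
#' per-layer output z.
#'
#' @param h_in message-passing output (N x F).
#' @param weights list with `rb1`, `rb2`, `rb3` (each `W1`, `b1`, `W2`,
#'   `b2`) and `z` (`W1`, `b1`, `W2`, `b2`, `W3`, `b3`).
#' @param h_prev optional message-block input for the extra skip; `NULL`
#'   omits it.
#' @return list with `h_next` (N x F) and `z` (N x F).
#' @export
update_block <- function(h_in, weights, h_prev = NULL) {
  tape <- ad_tape()
  pn <- list()
  for (r in 1:3)
    for (w in names(weights[[paste0("rb", r)]]))
      pn[[sprintf("u.rb%d.%s", r, w)]] <-
        ad_const(tape, weights[[paste0("rb", r)]][[w]])
  for (w in names(weights$z))
    pn[[paste0("u.z.", w)]] <- ad_const(tape, weights$z[[w]])
  res <- .ad_update(ad_const(tape, h_in),
                    if (is.null(h_prev)) NULL else ad_const(tape, h_prev),
                    pn, "u")
  list(h_next = res$h_next$val, z = res$z$val)
}

#' Attention pooling of the two plex outputs
#'
#' Per node, a two-way softmax over `LeakyReLU(W_p z_p)` logits gives the
#' plex weights, and the fused output is the weighted sum of the projected
#' branch outputs: `z^t_i = sum_p alpha_p,i (W'_p z_p,i)`.
#'
#' @param z_g,z_l branch output matrices (N x F).
#' @param W_att_g,W_att_l logit weights (F x 1).
#' @param W_out_g,W_out_l projection weights (F x D).
#' @return list with `alpha` (N x 2 matrix, columns `g`, `l`, rows summing
#'   to 1) and `fused` (N x D).
#' @export
attention_pool <- function(z_g, z_l, W_att_g, W_att_l, W_out_g, W_out_l) {
  lg <- .leaky(z_g %*% W_att_g)
  ll <- .leaky(z_l %*% W_att_l)
  ag <- 1 / (1 + exp(-(lg - ll)))
  alpha <- cbind(g = as.vector(ag), l = as.vector(1 - ag))
  fused <- (z_g %*% W_out_g) * alpha[, 1L] + (z_l %*% W_out_l) * alpha[, 2L]
  list(alpha = alpha, fused = fused)
}

.leaky <- function(x, slope = 0.01) ifelse(x > 0, x, slope * x)

#' Aggregate fused per-layer outputs into the model output
#'
#' Node-level output is the sum over hidden layers; graph-level output is
#' the sum (or mean) of the node-level outputs.
#'
#' @param z_layers list of fused per-layer matrices (N x D).
#' @param readout `"sum"`, `"mean"`, or `"node"`.
#' @param graph_id optional integer vector assigning nodes to graphs
#'   (default: all one graph).
#' @return graph-level matrix (n_graph x D) or node-level matrix.
#' @export
aggregate_layers <- function(z_layers, readout = c("sum", "mean", "node"),
                             graph_id = NULL) {
  readout <- match.arg(readout)
  y_node <- Reduce(`+`, z_layers)
  if (readout == "node") return(y_node)
  if (is.null(graph_id)) graph_id <- rep(1L, nrow(y_node))
  y <- .scatter_rows(y_node, graph_id, max(graph_id))
  if (readout == "mean")
    y <- y / tabulate(graph_id, nbins = max(graph_id))
  y
}
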