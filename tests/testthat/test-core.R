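# fixed probe weights of the right shapes, filled deterministically
probe_mlp2 <- function(nin, nh, nout, scale = 0.3, seed = 1) {
  set.seed(seed)
  list(W1 = matrix(rnorm(nin * nh, sd = scale), nin, nh),
       b1 = matrix(rnorm(nh, sd = scale), 1, nh),
       W2 = matrix(rnorm(nh * nout, sd = scale), nh, nout),
       b2 = matrix(rnorm(nout, sd = scale), 1, nout))
}

swish_ref <- function(x) x / (1 + exp(-x))
mlp2_ref <- function(x, w) {
  h <- swish_ref(sweep(x %*% w$W1, 2, as.vector(w$b1), "+"))
  swish_ref(sweep(h %*% w$W2, 2, as.vector(w$b2), "+"))
}

test_that("message embeddings follow MLP([h_j | h_i | e]) and are directional", {
  set.seed(4)
  h <- matrix(rnorm(4 * 3), 4, 3)
  e <- matrix(rnorm(2 * 2), 2, 2)
  w <- probe_mlp2(8, 5, 5)
  src <- c(1L, 2L); dst <- c(2L, 1L)
  m <- message_embed(h, e, src, dst, w)
  oracle <- mlp2_ref(cbind(h[src, ], h[dst, ], e), w)
  expect_equal(m, oracle, tolerance = 1e-12)
  # ordered concatenation: m_ji != m_ij when h_i != h_j
  expect_gt(max(abs(m[1, ] - m[2, ])), 1e-6)
  # zero edges -> empty message set
  expect_equal(nrow(message_embed(h, matrix(0, 0, 2), integer(0),
                                  integer(0), w)), 0L)
})

test_that("global message passing adds filtered messages to the target node", {
  h <- matrix(1:6 / 10, 3, 2)
  # one directed edge 1 -> 2 with phi_d output forced to all-ones
  e <- matrix(2, 1, 1)
  W_e <- matrix(0.5, 1, 2)      # e %*% W_e = (1, 1)
  m <- matrix(c(0.7, -0.2), 1, 2)
  out <- global_message_pass(h, m, e, src = 1L, dst = 2L, W_e = W_e)
  expect_equal(out[2, ], h[2, ] + m[1, ])   # increment is exactly m_ji
  expect_equal(out[c(1, 3), ], h[c(1, 3), ]) # isolated nodes unchanged
  # permutation of the edge list leaves the result unchanged
  set.seed(5)
  mol <- synthetic_molecule(8, 44, "blob")
  edges <- build_global_edges(mol, 4)
  hh <- matrix(rnorm(8 * 3), 8, 3)
  ee <- radial_basis(edges$dist, 4, 4)
  We <- matrix(rnorm(4 * 3), 4, 3)
  mm <- matrix(rnorm(length(edges$src) * 3), ncol = 3)
  perm <- sample(length(edges$src))
  out1 <- global_message_pass(hh, mm, ee, edges$src, edges$dst, We)
  out2 <- global_message_pass(hh, mm[perm, ], ee[perm, ],
                              edges$src[perm], edges$dst[perm], We)
  expect_equal(out1, out2, tolerance = 1e-12)
})

test_that("local message passing reduces to the plain update on a 2-node path", {
  two <- molecule3d(c(6L, 8L), rbind(c(0, 0, 0), c(1.3, 0, 0)),
                    bonds = cbind(1L, 2L))
  e <- build_local_edges(two, "bonds")
  ang <- enumerate_angles(e, two$pos)
  ef <- radial_basis(e$dist, 2, 4)
  W_e <- matrix(0.3, 4, 3)
  phw <- probe_mlp2(5, 4, 3)
  h <- matrix(1:6 / 7, 2, 3)
  m <- matrix(seq(-0.3, 0.8, length.out = 6), 2, 3)
  res <- local_message_pass(h, m, ef, ang,
                            matrix(0, 0, 5), matrix(0, 0, 5),
                            e$dst, W_e, phw)
  expect_equal(res$m_prime, m)              # both angular sums empty
  expect_equal(res$n_angular_terms, 0L)
  expect_equal(res$h, global_message_pass(h, m, ef, e$src, e$dst, W_e))
})

test_that("local message passing matches a hand expansion on a 3-node path", {
  path3 <- molecule3d(rep(6L, 3),
                      rbind(c(0, 0, 0), c(1.4, 0, 0), c(2.5, 0.8, 0)),
                      bonds = rbind(c(1L, 2L), c(2L, 3L)))
  e <- build_local_edges(path3, "bonds")
  ang <- enumerate_angles(e, path3$pos)
  n_abf <- 3
  ef <- radial_basis(e$dist, 2.5, 4)
  a1 <- angular_basis(ang$one_hop$theta, n_abf)
  a2 <- angular_basis(ang$two_hop$theta, n_abf)
  W_e <- matrix(seq(-0.2, 0.4, length.out = 8), 4, 2)
  phw <- probe_mlp2(n_abf, 4, 2, seed = 6)
  set.seed(7)
  h <- matrix(rnorm(6), 3, 2)
  m <- matrix(rnorm(length(e$src) * 2), ncol = 2)
  res <- local_message_pass(h, m, ef, ang, a1, a2, e$dst, W_e, phw)

  # independent hand expansion of the two angular sums, edge by edge
  phid <- ef %*% W_e
  phith1 <- mlp2_ref(a1, phw)
  phith2 <- mlp2_ref(a2, phw)
  m_prime <- m
  for (r in seq_len(nrow(ang$one_hop)))
    m_prime[ang$one_hop$edge[r], ] <- m_prime[ang$one_hop$edge[r], ] +
      m[ang$one_hop$partner[r], ] * phid[ang$one_hop$partner[r], ] *
      phith1[r, ]
  for (r in seq_len(nrow(ang$two_hop)))
    m_prime[ang$two_hop$edge[r], ] <- m_prime[ang$two_hop$edge[r], ] +
      m[ang$two_hop$partner[r], ] * phid[ang$two_hop$partner[r], ] *
      phith2[r, ]
  h_expect <- h
  for (ed in seq_along(e$src))
    h_expect[e$dst[ed], ] <- h_expect[e$dst[ed], ] +
      m_prime[ed, ] * phid[ed, ]
  expect_equal(res$m_prime, m_prime, tolerance = 1e-12)
  expect_equal(res$h, h_expect, tolerance = 1e-12)
  # one angular-filter evaluation per angle table row: (deg(i)-1)+(deg(j)-1)
  # summed over the 4 directed edges = 4
  expect_equal(res$n_angular_terms, 4L)
})

test_that("update block is the identity under zero weights and keeps shapes", {
  Fd <- 5
  zero <- function() list(W1 = matrix(0, Fd, Fd), b1 = matrix(0, 1, Fd),
                          W2 = matrix(0, Fd, Fd), b2 = matrix(0, 1, Fd))
  w <- list(rb1 = zero(), rb2 = zero(), rb3 = zero(),
            z = list(W1 = matrix(0, Fd, Fd), b1 = matrix(0, 1, Fd),
                     W2 = matrix(0, Fd, Fd), b2 = matrix(0, 1, Fd),
                     W3 = matrix(0, Fd, Fd), b3 = matrix(1.5, 1, Fd)))
  h <- matrix(rnorm(4 * Fd), 4, Fd)
  res <- update_block(h, w)
  expect_equal(res$h_next, h)               # skips preserve the input
  expect_equal(res$z, matrix(1.5, 4, Fd))   # bias-path output
  # with the extra skip the message-block input is added once
  res2 <- update_block(h, w, h_prev = h)
  expect_equal(res2$h_next, 2 * h)
  # shape contract with random weights
  wr <- list(rb1 = probe_mlp2(Fd, Fd, Fd), rb2 = probe_mlp2(Fd, Fd, Fd),
             rb3 = probe_mlp2(Fd, Fd, Fd),
             z = c(probe_mlp2(Fd, Fd, Fd),
                   list(W3 = matrix(0.1, Fd, Fd), b3 = matrix(0, 1, Fd))))
  names(wr$z) <- c("W1", "b1", "W2", "b2", "W3", "b3")
  rr <- update_block(h, wr)
  expect_equal(dim(rr$h_next), c(4L, Fd))
  expect_equal(dim(rr$z), c(4L, Fd))
})

test_that("attention pooling is a normalized two-way softmax", {
  set.seed(8)
  z <- matrix(rnorm(6 * 4), 6, 4)
  W <- matrix(rnorm(4), 4, 1)
  Wo <- matrix(rnorm(8), 4, 2)
  # symmetric inputs: exactly 0.5 / 0.5
  sym <- attention_pool(z, z, W, W, Wo, Wo)
  expect_equal(sym$alpha[, 1], rep(0.5, 6))
  # engineered logits (2, 0): alpha = softmax(2, 0)
  z1 <- matrix(1, 1, 1); z2 <- matrix(0, 1, 1)
  res <- attention_pool(z1, z2, matrix(2), matrix(1), matrix(1), matrix(1))
  expect_equal(unname(res$alpha[1, 1]), exp(2) / (exp(2) + 1),
               tolerance = 1e-12)
  expect_equal(unname(res$alpha[1, 2]), 1 / (exp(2) + 1),
               tolerance = 1e-12)
  # rows always sum to one
  r <- attention_pool(z, matrix(rnorm(24), 6, 4), W,
                      matrix(rnorm(4), 4, 1), Wo, Wo)
  expect_equal(rowSums(r$alpha), rep(1, 6), tolerance = 1e-12)
  # softmax shift invariance: adding a constant to both logits through the
  # positive part of LeakyReLU leaves alpha unchanged
  zc1 <- matrix(3, 1, 1); zc2 <- matrix(2, 1, 1)
  shift <- function(c0)
    attention_pool(zc1 + c0, zc2 + c0, matrix(1), matrix(1),
                   matrix(1), matrix(1))$alpha
  expect_equal(shift(0), shift(5), tolerance = 1e-12)
})

test_that("layer aggregation is linear and respects the readout mode", {
  z1 <- matrix(1:6, 3, 2)
  z2 <- matrix(0.5, 3, 2)
  expect_equal(aggregate_layers(list(z1), "sum"),
               matrix(colSums(z1), 1, 2))
  y <- aggregate_layers(list(z1, z2), "sum")
  expect_equal(y, matrix(colSums(z1 + z2), 1, 2))
  # duplicating atoms doubles the sum readout, leaves the mean unchanged
  dup <- list(rbind(z1, z1), rbind(z2, z2))
  expect_equal(aggregate_layers(dup, "sum"), 2 * y)
  expect_equal(aggregate_layers(dup, "mean"),
               aggregate_layers(list(z1, z2), "mean"))
  # node-level output and permutation invariance of the graph sum
  perm <- c(3, 1, 2)
  expect_equal(aggregate_layers(list(z1[perm, ], z2[perm, ]), "sum"), y)
  expect_equal(aggregate_layers(list(z1, z2), "node"), z1 + z2)
})

test_that("forward pass is invariant to atom relabelling and deterministic", {
  mol <- synthetic_molecule(9, 21, "chain")
  cfg <- tiny_config()
  model <- pamnet(cfg, seed = 31)
  fw1 <- pamnet_forward(model$params, prepare_batch(list(mol), cfg), cfg)
  fw2 <- pamnet_forward(model$params, prepare_batch(list(mol), cfg), cfg)
  expect_identical(fw1$y, fw2$y)            # determinism
  # relabel atoms: graph output unchanged, node outputs permute
  perm <- c(5L, 3L, 9L, 1L, 2L, 8L, 7L, 4L, 6L)
  inv <- order(perm)
  bonds_new <- cbind(perm[mol$bonds[, 1]], perm[mol$bonds[, 2]])
  molp <- molecule3d(mol$Z[inv], mol$pos[inv, ], bonds = bonds_new[
    order(pmin(bonds_new[, 1], bonds_new[, 2])), ])
  fwp <- pamnet_forward(model$params, prepare_batch(list(molp), cfg), cfg)
  expect_equal(fwp$y, fw1$y, tolerance = 1e-9)
  expect_equal(fwp$y_node[perm, , drop = FALSE], fw1$y_node,
               tolerance = 1e-9)
})

test_that("attention weights stay normalized, even with an empty local layer", {
  mols <- fixture_molecules(4, seed = 15)
  cfg <- tiny_config(local_mode = "cutoff", d_l = 2, d_g = 4)
  model <- pamnet(cfg, seed = 2)
  fw <- pamnet_forward(model$params, prepare_batch(mols, cfg), cfg)
  for (a in fw$alpha)
    expect_true(all(abs(rowSums(a) - 1) < 1e-7))
  # local layer empty (d_l below any pairwise distance): model still runs
  # and the softmax over the two logits stays normalized
  cfg0 <- tiny_config(local_mode = "cutoff", d_l = 0.1, d_g = 4)
  model0 <- pamnet(cfg0, seed = 2)
  b0 <- prepare_batch(mols, cfg0)
  expect_equal(length(b0$src_l), 0L)
  fw0 <- pamnet_forward(model0$params, b0, cfg0)
  for (a in fw0$alpha)
    expect_true(all(abs(rowSums(a) - 1) < 1e-7))
  expect_true(all(is.finite(fw0$y)))
})

test_that("one-hop variant evaluates no two-hop terms", {
  mol <- synthetic_molecule(8, 5, "chain")
  cfg_s <- tiny_config(variant = "s")
  model <- pamnet(cfg_s, seed = 3)
  b <- prepare_batch(list(mol), cfg_s)
  expect_equal(length(b$two_edge), 0L)
  fw <- pamnet_forward(model$params, b, cfg_s)
  g <- multiplex_graph(mol, cfg_s$d_g, "bonds", variant = "one_hop_only")
  expect_equal(fw$message_counts$local[1], nrow(g$one_hop))
})

test_that("checkpoints round-trip through JSON", {
  cfg <- tiny_config()
  model <- pamnet(cfg, seed = 77)
  path <- withr::local_tempfile(fileext = ".json")
  save_pamnet(model, path)
  back <- load_pamnet(path)
  expect_equal(back$config$hidden_dim, cfg$hidden_dim)
  mol <- synthetic_molecule(6, 2, "chain")
  expect_equal(predict(back, list(mol)), predict(model, list(mol)),
               tolerance = 1e-12)
})
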