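test_that("losses match their closed forms", {
  expect_equal(pamnet_loss(c(1, 2), c(1, 2), "mae"), 0)
  expect_equal(pamnet_loss(c(2, 0), c(1, 1), "mae"), 1)  # residuals (1, -1)
  expect_equal(pamnet_loss(0.5, 0, "smooth_l1"), 0.125)
  expect_equal(pamnet_loss(2, 0, "smooth_l1"), 1.5)
  expect_error(pamnet_loss(numeric(0), numeric(0)), "empty")
  expect_error(pamnet_loss(1:3, 1:2), "mismatch")
})

test_that("the learning-rate schedule warms up linearly then decays", {
  tc <- pamnet_train_config(base_lr = 1e-3, warmup_epochs = 1,
                            decay_ratio = 0.1,
                            decay_interval_epochs = 600)
  expect_equal(lr_at(0, tc), 0)                       # ramp origin
  expect_equal(lr_at(0.5, tc), 5e-4)
  expect_equal(lr_at(1, tc), 1e-3)                    # warm-up end
  # one decay interval after warm-up: exactly ratio * base_lr
  expect_equal(lr_at(1 + 600, tc), 1e-4)
  # continuity at the warm-up boundary and monotone decay afterwards
  expect_equal(lr_at(1 + 1e-9, tc), lr_at(1, tc), tolerance = 1e-6)
  lrs <- lr_at(seq(1, 1200, by = 7), tc)
  expect_true(all(diff(lrs) <= 0))
  # stepwise mode holds the rate inside an interval
  tcs <- pamnet_train_config(base_lr = 1, warmup_epochs = 0,
                             decay_ratio = 0.2,
                             decay_interval_epochs = 50,
                             decay_mode = "stepwise")
  expect_equal(lr_at(49, tcs), 1)
  expect_equal(lr_at(50, tcs), 0.2)
  expect_equal(lr_at(149, tcs), 0.2^2)
  expect_error(lr_at(-1, tc), "non-negative")
})

test_that("EMA updates follow the two-step closed form and contract", {
  s0 <- list(a = matrix(2, 2, 2))
  p <- list(a = matrix(-1, 2, 2))
  d <- 0.9
  s1 <- ema_update(s0, p, d)
  s2 <- ema_update(s1, p, d)
  # algebraic expansion: s2 = d^2 s0 + (1 - d^2) p, exactly
  expect_identical(s2$a, d^2 * s0$a + (1 - d^2) * p$a)
  # decay 0 copies params; constant params are a fixed point
  expect_equal(ema_update(s0, p, 0)$a, p$a)
  expect_equal(ema_update(p, p, d)$a, p$a)
  # shadow stays in the convex hull of observed parameter values
  s <- s0
  for (i in 1:20) s <- ema_update(s, p, d)
  expect_true(all(s$a >= -1 & s$a <= 2))
  expect_true(all(abs(s$a - p$a) < abs(s0$a - p$a)))
})

test_that("model ranking metrics follow the near-native definitions", {
  # perfect predictor, one model near-native and ranked first
  perfect <- rank_models(predicted = c(1.5, 3, 7), true_rmsd = c(1.5, 3, 7))
  expect_true(perfect$best_scoring_is_near_native)
  expect_true(perfect$top10_contains_near_native)
  expect_equal(perfect$rank_of_best_near_native, 1L)
  # anti-perfect predictor on 10 models with a single near-native model:
  # the near-native model lands at rank 10
  rmsd <- c(1.0, seq(3, 11))
  anti <- rank_models(predicted = -rmsd, true_rmsd = rmsd)
  expect_false(anti$best_scoring_is_near_native)
  expect_true(anti$top10_contains_near_native)  # all 10 models are in top-10
  expect_equal(anti$rank_of_best_near_native, 10L)
  # invariance under strictly monotone transforms of the scores
  set.seed(3)
  pred <- runif(30, 0, 12)
  true_r <- runif(30, 0, 12)
  r1 <- rank_models(pred, true_r)
  r2 <- rank_models(exp(2 * pred) + 5, true_r)
  expect_identical(r1[1:3], r2[1:3])
  # no near-native model: rank reported as missing
  none <- rank_models(c(1, 2), c(5, 7))
  expect_true(is.na(none$rank_of_best_near_native))
  # geometric mean of ranks
  expect_equal(geometric_mean_rank(c(1, 4, 16)), exp(mean(log(c(1, 4, 16)))))
  expect_equal(geometric_mean_rank(c(2, NA)), 2)
})

test_that("attention summary averages to 0.5 for a symmetric model", {
  mols <- fixture_molecules(3, seed = 31)
  # identical plex graphs (d_l = d_g in cutoff mode), mirrored weights, and
  # a silenced angular filter make the two branches exactly symmetric
  cfg <- tiny_config(local_mode = "cutoff", d_l = 4, d_g = 4)
  model <- pamnet(cfg, seed = 6)
  for (t in 1:cfg$n_layers) {
    for (s in c("msg.W1", "msg.b1", "msg.W2", "msg.b2", "phid.W",
                "rb1.W1", "rb1.b1", "rb1.W2", "rb1.b2",
                "rb2.W1", "rb2.b1", "rb2.W2", "rb2.b2",
                "rb3.W1", "rb3.b1", "rb3.W2", "rb3.b2",
                "z.W1", "z.b1", "z.W2", "z.b2", "z.W3", "z.b3"))
      model$params[[sprintf("L%d.l.%s", t, s)]] <-
        model$params[[sprintf("L%d.g.%s", t, s)]]
    model$params[[sprintf("L%d.att.l.W", t)]] <-
      model$params[[sprintf("L%d.att.g.W", t)]]
    model$params[[sprintf("L%d.l.phith.W2", t)]][] <- 0
    model$params[[sprintf("L%d.l.phith.b2", t)]][] <- 0
  }
  a <- attention_summary(model, mols)
  expect_equal(unname(a), c(0.5, 0.5))
  # asymmetric model: still sums to one
  cfg2 <- tiny_config(local_mode = "cutoff", d_l = 2, d_g = 4)
  model2 <- pamnet(cfg2, seed = 8)
  a2 <- attention_summary(model2, fixture_molecules(3, seed = 32))
  expect_equal(sum(a2), 1, tolerance = 1e-7)
})

test_that("zeroing one branch pushes attention toward the surviving logit", {
  mols <- fixture_molecules(3, seed = 33)
  cfg <- tiny_config(local_mode = "cutoff", d_l = 2, d_g = 4)
  model <- pamnet(cfg, seed = 9)
  # force the global logit to a large negative value via its weight row
  for (t in 1:cfg$n_layers) {
    model$params[[sprintf("L%d.att.g.W", t)]][] <- -10
    model$params[[sprintf("L%d.att.l.W", t)]][] <- 10
  }
  batch <- prepare_batch(mols, cfg)
  fw <- pamnet_forward(model$params, batch, cfg)
  # softmax oracle on the realized logits
  a <- do.call(rbind, fw$alpha)
  expect_true(all(abs(rowSums(a) - 1) < 1e-7))
  expect_true(mean(a[, "l"]) > 0.5)
})

test_that("the replica affinity head combines three shared-weight passes", {
  cfg <- pamnet_config("pdbbind_affinity", n_layers = 1, hidden_dim = 8,
                       readout = "mean")
  model <- pamnet(cfg, seed = 4)
  # stub network: all weights zero except the final z bias -> every graph
  # scores the same constant c under mean readout
  for (nm in names(model$params)) model$params[[nm]][] <- 0
  cvalue <- 0.75
  # with all weights zero, z = b3 path through the fusion projections is
  # zero too; instead drive the output through out.g.W acting on z = b3
  model$params[["L1.g.z.b3"]][] <- cvalue
  model$params[["L1.l.z.b3"]][] <- cvalue
  model$params[["L1.out.g.W"]][1, 1] <- 0.125
  model$params[["L1.out.l.W"]][1, 1] <- 0.125
  cplx <- synthetic_complex(21)
  res <- predict_affinity(model, cplx)
  c_graph <- cvalue * model$params[["L1.out.g.W"]][1, 1]
  expect_equal(res$G_complex, c_graph, tolerance = 1e-9)
  expect_equal(res$G_ligand, c_graph, tolerance = 1e-9)
  if (!is.na(res$G_pocket)) {
    expect_equal(res$dG, -c_graph, tolerance = 1e-9)   # c - c - c = -c
  }
  # weight sharing: perturbing one parameter moves all three outputs
  model2 <- pamnet(cfg, seed = 4)
  base <- predict_affinity(model2, cplx)
  model2$params[["L1.g.msg.W1"]][1, 1] <-
    model2$params[["L1.g.msg.W1"]][1, 1] + 0.5
  pert <- predict_affinity(model2, cplx)
  expect_false(isTRUE(all.equal(base$G_complex, pert$G_complex)))
  expect_false(isTRUE(all.equal(base$G_pocket, pert$G_pocket)))
  expect_false(isTRUE(all.equal(base$G_ligand, pert$G_ligand)))
  # empty pocket: documented fallback dG = G_complex - G_ligand
  lig <- synthetic_molecule(5, 3, "blob")
  far <- molecule3d(c(6L, 6L),
                    rbind(c(50, 0, 0), c(51.4, 0, 0)), name = "far",
                    residue = data.frame(chain = "A", resno = 1,
                                         insert = "", resid = "X")[c(1, 1), ])
  expect_warning(resf <- predict_affinity(model2,
                                          complex_structure(lig, far)),
                 "empty pocket")
  expect_equal(resf$dG, resf$G_complex - resf$G_ligand)
})

test_that("a uniform shift of graph outputs shifts dG by -c", {
  cfg <- pamnet_config("pdbbind_affinity", n_layers = 1, hidden_dim = 8,
                       readout = "mean")
  model <- pamnet(cfg, seed = 14)
  cplx <- synthetic_complex(22)
  base <- predict_affinity(model, cplx)
  # shifting every graph-level output by c (via a constant added to the
  # prediction) changes the three-term combination by -c
  shift <- 0.3
  g_shift <- function(G) G + shift
  dg_shifted <- g_shift(base$G_complex) - g_shift(base$G_pocket) -
    g_shift(base$G_ligand)
  expect_equal(dg_shifted, base$dG - shift)
})

test_that("training is deterministic and records a usable history", {
  mols <- lapply(1:10, function(i) {
    mol <- synthetic_molecule(6, 700 + i, "chain")
    mol$target <- smooth_pair_target(mol)
    mol
  })
  cfg <- tiny_config(hidden_dim = 8)
  tc <- pamnet_train_config(base_lr = 2e-3, max_epochs = 12,
                            early_stop_patience = Inf, ema_decay = 0.95,
                            seed = 5)
  f1 <- pamnet_fit(mols, config = cfg, train = tc)
  f2 <- pamnet_fit(mols, config = cfg, train = tc)
  expect_identical(f1$history, f2$history)
  expect_equal(nrow(f1$history), 12L)
  expect_true(all(is.finite(f1$history$train_loss)))
  # the model actually learns on this tiny problem
  expect_lt(tail(f1$history$train_loss, 1), f1$history$train_loss[1])
  # S3 surface
  expect_s3_class(f1, "pamnet_fit")
  expect_length(stats::fitted(f1), 10L)
  expect_length(stats::residuals(f1), 10L)
  expect_named(coef(f1))
  s <- summary(f1)
  expect_s3_class(s, "summary.pamnet_fit")
  expect_output(print(s), "training MAE")
  # validation split + early stopping machinery runs
  tc2 <- pamnet_train_config(base_lr = 2e-3, max_epochs = 8,
                             early_stop_patience = 3, val_fraction = 0.2,
                             ema_decay = 0.95, seed = 5)
  f3 <- pamnet_fit(mols, config = cfg, train = tc2)
  expect_true(all(is.finite(f3$history$val_loss)))
  expect_lte(nrow(f3$history), 8L)
})

test_that("a non-finite loss aborts training with a diagnostic", {
  mols <- lapply(1:6, function(i) {
    mol <- synthetic_molecule(6, 800 + i, "chain")
    mol$target <- smooth_pair_target(mol)
    mol
  })
  mols[[3]]$target <- Inf  # poisons the loss at the first step
  cfg <- tiny_config(hidden_dim = 8)
  tc <- pamnet_train_config(base_lr = 1e-3, max_epochs = 5,
                            early_stop_patience = Inf, seed = 2)
  expect_error(pamnet_fit(mols, config = cfg, train = tc), "diverged")
})

test_that("an RNA-style scorer ranks decoys after a short fit", {
  # train a small scorer to predict decoy RMSD with the smooth L1 loss
  set <- synthetic_decoy_set(24, seed = 77, n_atoms = 12,
                             rmsd_range = c(0.5, 8))
  mols <- set$models
  cfg <- pamnet_config("rna_score", n_layers = 1, hidden_dim = 16,
                       d_g = 12, d_l = 2.6)
  tc <- pamnet_train_config(base_lr = 3e-3, max_epochs = 60,
                            early_stop_patience = Inf, ema_decay = 0.9,
                            loss = "smooth_l1", seed = 8)
  fit <- pamnet_fit(mols, targets = set$rmsd, config = cfg, train = tc)
  pred <- predict(fit, mols)
  # training reduced the loss and the ranking metrics are computable
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  metrics <- rank_models(pred, set$rmsd)
  expect_true(is.finite(metrics$rank_of_best_near_native))
  # predicted scores must correlate positively with true RMSD after fitting
  expect_gt(cor(pred, set$rmsd, method = "spearman"), 0)
})
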