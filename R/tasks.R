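#' Rank structural models by predicted score
#'
#' Scoring-function evaluation for structural-model sets: models are ranked
#' ascending by predicted score (a predicted RMSD, so lower = better); ties
#' are broken by stable input order. A model is near-native when its true
#' RMSD to the experimental structure is within the threshold (2 Angstrom
#' by convention).
#'
#' @param predicted numeric vector of predicted scores (lower is better).
#' @param true_rmsd numeric vector of true RMSDs (Angstrom, >= 0).
#' @param near_native_threshold near-native cutoff (default 2 Angstrom).
#' @return list with `best_scoring_is_near_native`,
#'   `top10_contains_near_native`, `rank_of_best_near_native` (1-based;
#'   `NA` when no model is near-native), and `order` (the ranking
#'   permutation).
#' @export
rank_models <- function(predicted, true_rmsd, near_native_threshold = 2) {
  if (length(predicted) < 1L) stop("need at least one model")
  if (length(predicted) != length(true_rmsd)) stop("length mismatch")
  if (any(true_rmsd < 0)) stop("RMSDs must be >= 0")
  ord <- order(predicted)  # stable for ties
  nn <- true_rmsd[ord] <= near_native_threshold
  rank_nn <- if (any(nn)) which(nn)[1L] else NA_integer_
  list(best_scoring_is_near_native = isTRUE(nn[1L]),
       top10_contains_near_native = any(nn[seq_len(min(10L, length(nn)))]),
       rank_of_best_near_native = rank_nn,
       order = ord)
}

#' Geometric mean of per-target ranks
#'
#' `exp(mean(log(rank)))` across targets (e.g. the rank of the best-scoring
#' near-native model per RNA); missing ranks are dropped.
#'
#' @param ranks numeric vector of 1-based ranks.
#' @return the geometric mean.
#' @export
geometric_mean_rank <- function(ranks) {
  r <- ranks[!is.na(ranks)]
  if (!length(r)) return(NA_real_)
  exp(mean(log(r)))
}

#' Average attention weights over a dataset
#'
#' Runs the model on every molecule and averages the per-node plex
#' attention weights over all nodes, hidden layers and molecules — the
#' overall importance of local vs global interactions for the task. The
#' two means sum to 1.
#'
#' @param model a `pamnet` or `pamnet_fit`.
#' @param mols list of `molecule3d`.
#' @return named numeric vector `c(alpha_g, alpha_l)`.
#' @export
attention_summary <- function(model, mols) {
  if (inherits(mols, "molecule3d")) mols <- list(mols)
  batch <- prepare_batch(mols, model$config)
  fw <- pamnet_forward(model$params, batch, model$config)
  all_a <- do.call(rbind, fw$alpha)
  c(alpha_g = mean(all_a[, "g"]), alpha_l = mean(all_a[, "l"]))
}

#' Binding free-energy prediction with weight-sharing replica networks
#'
#' Applies the same network (one shared parameter set) to three graphs —
#' the pocket complex, the pocket alone, and the ligand alone — and
#' combines the three graph-level outputs as
#' `dG = G_complex - G_pocket - G_ligand`. When the extracted pocket is
#' empty the documented fallback `dG = G_complex - G_ligand` is used with a
#' warning.
#'
#' @param model a `pamnet` or `pamnet_fit` (task `"pdbbind_affinity"`).
#' @param cplx a `complex3d`; pocket extraction is applied at `radius`.
#' @param radius pocket radius, Angstrom (default 6).
#' @return list with `dG`, `G_complex`, `G_pocket` (`NA` when empty),
#'   `G_ligand`, and the extracted `pocket`.
#' @export
predict_affinity <- function(model, cplx, radius = 6) {
  pocket <- extract_pocket(cplx, radius = radius)
  g_of <- function(mol) as.vector(predict(model, list(mol)))[1L]
  G_complex <- g_of(pocket$complex)
  G_ligand <- g_of(pocket$ligand)
  if (is.null(pocket$protein) || n_atoms(pocket$protein) == 0L) {
    warning("empty pocket: falling back to dG = G_complex - G_ligand")
    return(list(dG = G_complex - G_ligand, G_complex = G_complex,
                G_pocket = NA_real_, G_ligand = G_ligand, pocket = pocket))
  }
  G_pocket <- g_of(pocket$protein)
  list(dG = G_complex - G_pocket - G_ligand, G_complex = G_complex,
       G_pocket = G_pocket, G_ligand = G_ligand, pocket = pocket)
}

#' Save a model checkpoint
#'
#' Flat named-parameter archive plus the configuration, serialized as one
#' JSON file (full double precision).
#'
#' @param model a `pamnet` or `pamnet_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_pamnet <- function(model, path) {
  obj <- list(
    config = unclass(model$config),
    params = lapply(model$params, function(m)
      list(dim = dim(m), dimnames = dimnames(m), data = as.vector(m))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path a file written by [save_pamnet()].
#' @return a `pamnet` model.
#' @export
load_pamnet <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- obj$config
  config <- do.call(pamnet_config, cfg[c(
    "task", "n_layers", "hidden_dim", "fused_dim", "n_rbf", "n_abf",
    "envelope_exponent", "d_g", "d_l", "local_mode", "variant", "readout",
    "feature_mode", "elements", "n_features")])
  params <- lapply(obj$params, function(p) {
    m <- matrix(as.numeric(p$data), p$dim[1L], p$dim[2L])
    if (!is.null(p$dimnames) && length(p$dimnames) &&
        !is.null(p$dimnames[[1L]]))
      rownames(m) <- p$dimnames[[1L]]
    m
  })
  structure(list(config = config, params = params), class = "pamnet")
}
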