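#' Training configuration
#'
#' @param base_lr peak learning rate reached at the end of warm-up.
#' @param warmup_epochs length of the linear warm-up (default 1 epoch).
#' @param decay_ratio multiplicative decay factor (default 0.1).
#' @param decay_interval_epochs epochs per decay interval (default 600).
#' @param decay_mode `"continuous"` (ratio^(epoch/interval)) or
#'   `"stepwise"` (ratio^floor(epoch/interval)); the protein-ligand recipe
#'   uses stepwise 0.2 every 50 epochs.
#' @param ema_decay decay rate of the exponential moving average of the
#'   parameters used for validation/testing (default 0.999).
#' @param batch_size molecules per optimization step; `Inf` = full batch.
#' @param max_epochs maximum training epochs.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping; `Inf` disables early stopping.
#' @param seed master seed; data shuffling, parameter initialization and
#'   any fixture generation derive their own sub-seeds from it.
#' @param loss `"mae"` or `"smooth_l1"`.
#' @param val_fraction fraction of the data held out for validation when no
#'   explicit validation set is given (0 disables).
#' @return object of class `pamnet_train_config`.
#' @export
pamnet_train_config <- function(base_lr = 1e-3, warmup_epochs = 1,
                                decay_ratio = 0.1,
                                decay_interval_epochs = 600,
                                decay_mode = c("continuous", "stepwise"),
                                ema_decay = 0.999, batch_size = Inf,
                                max_epochs = 300,
                                early_stop_patience = 50, seed = 1L,
                                loss = c("mae", "smooth_l1"),
                                val_fraction = 0) {
  decay_mode <- match.arg(decay_mode)
  loss <- match.arg(loss)
  if (ema_decay <= 0 || ema_decay >= 1) stop("ema_decay must be in (0, 1)")
  if (decay_ratio <= 0 || decay_ratio > 1)
    stop("decay_ratio must be in (0, 1]")
  structure(list(base_lr = base_lr, warmup_epochs = warmup_epochs,
                 decay_ratio = decay_ratio,
                 decay_interval_epochs = decay_interval_epochs,
                 decay_mode = decay_mode, ema_decay = ema_decay,
                 batch_size = batch_size, max_epochs = max_epochs,
                 early_stop_patience = early_stop_patience,
                 seed = as.integer(seed), loss = loss,
                 val_fraction = val_fraction),
            class = "pamnet_train_config")
}

#' Training loss
#'
#' @param pred,target numeric vectors/matrices of matching shape.
#' @param kind `"mae"` (mean absolute error) or `"smooth_l1"` (Huber-type,
#'   quadratic below residual 1, linear above).
#' @return scalar loss.
#' @export
pamnet_loss <- function(pred, target, kind = c("mae", "smooth_l1")) {
  kind <- match.arg(kind)
  if (length(pred) == 0L) stop("empty batch")
  if (length(pred) != length(target)) stop("shape mismatch")
  r <- as.numeric(pred) - as.numeric(target)
  if (kind == "mae") mean(abs(r))
  else mean(ifelse(abs(r) < 1, 0.5 * r^2, abs(r) - 0.5))
}

#' Learning rate at a given epoch
#'
#' Linear warm-up from 0 to `base_lr` across `warmup_epochs`, then
#' exponential decay: continuously as `base_lr * ratio^((epoch - warmup) /
#' interval)` or stepwise at interval boundaries. Continuous at the warm-up
#' boundary and non-increasing afterwards.
#'
#' @param epoch epoch number (non-negative; fractions allowed).
#' @param config a [pamnet_train_config()].
#' @return learning rate.
#' @export
lr_at <- function(epoch, config) {
  if (any(epoch < 0)) stop("epoch must be non-negative")
  w <- config$warmup_epochs
  ramp <- if (w > 0) pmin(1, epoch / w) else 1
  past <- pmax(0, epoch - w)
  expo <- if (config$decay_mode == "continuous")
    past / config$decay_interval_epochs
  else floor(past / config$decay_interval_epochs)
  config$base_lr * ramp * config$decay_ratio^expo
}

#' Exponential-moving-average update of a parameter set
#'
#' `shadow' = decay * shadow + (1 - decay) * params`, applied element-wise
#' to every parameter matrix. The shadow copy is what validation and
#' testing evaluate.
#'
#' @param shadow named list of matrices (running average).
#' @param params named list of matrices (current values).
#' @param decay decay rate in `[0, 1)`.
#' @return updated shadow list.
#' @export
ema_update <- function(shadow, params, decay) {
  if (!identical(names(shadow), names(params)))
    stop("shadow and params must have identical structure")
  Map(function(s, p) decay * s + (1 - decay) * p, shadow, params)
}

# One Adam step over flat parameter lists. state holds first/second moment
# estimates and the step counter.
.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(state))
    state <- list(m = lapply(params, function(p) p * 0),
                  v = lapply(params, function(p) p * 0), t = 0L)
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Targets for a list of molecules: from the molecules unless given.
.resolve_targets <- function(mols, targets) {
  if (!is.null(targets)) return(targets)
  tl <- lapply(mols, `[[`, "target")
  if (any(vapply(tl, is.null, logical(1))))
    stop("molecules carry no targets; supply `targets`")
  if (all(lengths(tl) == 3L)) do.call(rbind, tl) else unlist(tl)
}

# Loss node for a forward result given the task and target block.
.loss_node <- function(fw, targets, config, kind) {
  lossfn <- if (kind == "mae") ad_mae else ad_smooth_l1
  if (config$task == "qm9_dipole") {
    if (is.matrix(targets)) return(lossfn(fw$u_ad, targets))
    # scalar dipole targets: fit the magnitude
    return(lossfn(ad_rownorm(fw$u_ad), targets))
  }
  lossfn(fw$y_ad, targets)
}

.eval_loss <- function(params, batches, config, kind) {
  tot <- 0; n <- 0
  for (b in batches) {
    fw <- pamnet_forward(params, b$batch, config)
    pred <- if (config$task == "qm9_dipole") {
      if (is.matrix(b$targets)) fw$u else fw$mu_norm
    } else as.vector(fw$y)
    tot <- tot + pamnet_loss(pred, b$targets, kind) * length(b$targets)
    n <- n + length(b$targets)
  }
  tot / n
}

#' Fit a multiplex message-passing model
#'
#' Trains the model with Adam under the package's standard recipe: linear
#' learning-rate warm-up followed by exponential decay, an exponential
#' moving average (EMA) of the parameters for evaluation, and early
#' stopping on the validation loss. Training is deterministic for a fixed
#' master seed.
#'
#' @param mols list of `molecule3d` training structures.
#' @param targets numeric vector (scalar tasks) or n x 3 matrix (dipole
#'   vectors); taken from the molecules' `target` fields when `NULL`.
#' @param config a [pamnet_config()].
#' @param train a [pamnet_train_config()].
#' @param val_mols,val_targets optional explicit validation set.
#' @param init_params optional parameter list to start from (resume /
#'   probe); defaults to a fresh [pamnet_params()] initialization.
#' @param verbose print a progress line every `verbose` epochs (0 = quiet).
#' @return object of class `pamnet_fit` (also `pamnet`): fields `config`,
#'   `params` (EMA weights of the best epoch), `final_params` (last raw
#'   weights), `history` (per-epoch data.frame: epoch, lr, train and
#'   validation loss), `best_epoch`, `fitted_values`, `train_targets`.
#' @export
pamnet_fit <- function(mols, targets = NULL, config = pamnet_config(),
                       train = pamnet_train_config(), val_mols = NULL,
                       val_targets = NULL, init_params = NULL,
                       verbose = 0) {
  targets <- .resolve_targets(mols, targets)
  n <- length(mols)
  tmat <- is.matrix(targets)
  if ((if (tmat) nrow(targets) else length(targets)) != n)
    stop("targets must match the number of molecules")
  # cover every element present in the data
  config$elements <- sort(unique(c(config$elements,
                                   unlist(lapply(mols, `[[`, "Z")))))
  seeds <- derive_seeds(train$seed, 3L)
  params <- if (is.null(init_params)) pamnet_params(config, seeds[1L])
            else init_params

  # held-out validation split (deterministic in the master seed)
  take <- function(idx) list(
    mols = mols[idx],
    targets = if (tmat) targets[idx, , drop = FALSE] else targets[idx])
  if (is.null(val_mols) && train$val_fraction > 0 && n >= 5) {
    old <- .Random.seed_save(); set.seed(seeds[2L])
    vidx <- sample(n, max(1L, floor(train$val_fraction * n)))
    .Random.seed_restore(old)
    val <- take(vidx)
    tr <- take(setdiff(seq_len(n), vidx))
  } else if (!is.null(val_mols)) {
    val <- list(mols = val_mols,
                targets = .resolve_targets(val_mols, val_targets))
    tr <- take(seq_len(n))
  } else {
    val <- NULL
    tr <- take(seq_len(n))
  }

  # fixed batch partition, shuffled once from the master seed
  old <- .Random.seed_save(); set.seed(seeds[3L])
  ord <- sample(length(tr$mols))
  .Random.seed_restore(old)
  bs <- min(train$batch_size, length(tr$mols))
  groups <- split(ord, ceiling(seq_along(ord) / bs))
  batches <- lapply(groups, function(idx) {
    part <- list(
      mols = tr$mols[idx],
      targets = if (tmat) tr$targets[idx, , drop = FALSE]
                else tr$targets[idx])
    list(batch = prepare_batch(part$mols, config), targets = part$targets)
  })
  val_batches <- if (!is.null(val))
    list(list(batch = prepare_batch(val$mols, config),
              targets = val$targets))
  else NULL

  shadow <- params
  state <- NULL
  best <- list(loss = Inf, epoch = 0L, shadow = shadow)
  hist <- data.frame(epoch = integer(0), lr = numeric(0),
                     train_loss = numeric(0), val_loss = numeric(0))
  patience_left <- train$early_stop_patience

  for (epoch in seq_len(train$max_epochs)) {
    lr <- lr_at(epoch, train)
    ep_loss <- 0; ep_n <- 0
    for (b in batches) {
      tape <- ad_tape()
      fw <- pamnet_forward(params, b$batch, config, tape = tape)
      loss_nd <- .loss_node(fw, b$targets, config, train$loss)
      if (!is.finite(loss_nd$val))
        stop(sprintf("training diverged at epoch %d (loss = %g)",
                     epoch, loss_nd$val))
      ad_backward(loss_nd)
      grads <- lapply(fw$param_nodes, function(nd)
        if (is.null(nd$grad)) NULL else nd$grad)
      st <- .adam_step(params, grads, state, lr)
      params <- st$params
      state <- st$state
      shadow <- ema_update(shadow, params, train$ema_decay)
      ep_loss <- ep_loss + loss_nd$val * length(b$targets)
      ep_n <- ep_n + length(b$targets)
    }
    train_loss <- ep_loss / ep_n
    val_loss <- if (!is.null(val_batches))
      .eval_loss(shadow, val_batches, config, train$loss) else NA_real_
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                   train_loss = train_loss,
                                   val_loss = val_loss))
    if (verbose > 0 && epoch %% verbose == 0)
      message(sprintf("epoch %4d  lr %.2e  train %.5g  val %s", epoch, lr,
                      train_loss,
                      if (is.na(val_loss)) "-" else sprintf("%.5g",
                                                            val_loss)))
    monitor <- if (is.na(val_loss)) train_loss else val_loss
    if (monitor < best$loss - 1e-12) {
      best <- list(loss = monitor, epoch = epoch, shadow = shadow)
      patience_left <- train$early_stop_patience
    } else {
      patience_left <- patience_left - 1
      if (patience_left <= 0) break
    }
  }

  fit <- structure(list(config = config, params = best$shadow,
                        final_params = params, history = hist,
                        best_epoch = best$epoch, train = train,
                        train_targets = tr$targets),
                   class = c("pamnet_fit", "pamnet"))
  fit$fitted_values <- predict(
    fit, tr$mols,
    type = if (config$task == "qm9_dipole" && tmat) "vector" else "response")
  fit
}

#' @export
print.pamnet_fit <- function(x, ...) {
  cat(sprintf(
    "<pamnet_fit: task=%s, %d epochs (best %d), final train loss %.5g>\n",
    x$config$task, nrow(x$history), x$best_epoch,
    utils::tail(x$history$train_loss, 1)))
  invisible(x)
}

#' @export
summary.pamnet_fit <- function(object, ...) {
  h <- object$history
  res <- stats::residuals(object)
  out <- list(
    config = object$config,
    n_epochs = nrow(h),
    best_epoch = object$best_epoch,
    final_train_loss = utils::tail(h$train_loss, 1),
    best_val_loss = if (all(is.na(h$val_loss))) NA_real_
                    else min(h$val_loss, na.rm = TRUE),
    train_mae = mean(abs(res)))
  class(out) <- "summary.pamnet_fit"
  out
}

#' @export
print.summary.pamnet_fit <- function(x, ...) {
  print(x$config)
  cat(sprintf("epochs run      : %d (best at %d)\n", x$n_epochs,
              x$best_epoch))
  cat(sprintf("final train loss: %.6g\n", x$final_train_loss))
  if (!is.na(x$best_val_loss))
    cat(sprintf("best val loss   : %.6g\n", x$best_val_loss))
  cat(sprintf("training MAE    : %.6g\n", x$train_mae))
  invisible(x)
}

#' @export
coef.pamnet_fit <- function(object, ...) object$params

#' @export
residuals.pamnet_fit <- function(object, ...) {
  fv <- object$fitted_values
  tg <- object$train_targets
  if (is.matrix(tg)) as.vector(fv) - as.vector(tg)
  else as.vector(fv) - tg
}

#' @export
fitted.pamnet_fit <- function(object, ...) object$fitted_values

#' @export
plot.pamnet_fit <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "l", log = "y",
                 xlab = "epoch", ylab = "loss", ...)
  if (!all(is.na(h$val_loss)))
    graphics::lines(h$epoch, h$val_loss, lty = 2)
  graphics::abline(v = x$best_epoch, col = "grey", lty = 3)
  invisible(x)
}

#' @export
predict.pamnet_fit <- function(object, newdata, ...) {
  NextMethod()
}
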