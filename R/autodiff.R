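# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Every differentiable quantity is a "node": an environment holding the
# forward value (`val`, always a numeric matrix), the accumulated gradient
# (`grad`, filled during the backward sweep), and a backward closure that
# pushes the node's gradient into its parents. Nodes are registered on a
# tape in creation order; backpropagation walks the tape in reverse. This
# is all the machinery the message-passing model needs: matrix products,
# elementwise algebra, row gather/scatter (the graph operations), a few
# activations, row norms, and the two training losses.

#' Create a fresh autodiff tape
#'
#' @return a tape object to pass to [ad_node()] and [ad_backward()].
#' @export
ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$k <- 0L
  class(t) <- "ad_tape"
  t
}

#' Register a value on an autodiff tape
#'
#' Low-level constructor used by all operators. `ad_const()` and
#' `ad_param()` are the user-facing leaf constructors.
#'
#' @param tape an [ad_tape()].
#' @param val numeric matrix (vectors are promoted to one-column matrices).
#' @param backfn backward closure `function(grad)` pushing into parents, or
#'   `NULL` for leaves.
#' @return a node (environment with `val`, `grad`, `backfn`, `tape`).
#' @export
ad_node <- function(tape, val, backfn = NULL) {
  if (!is.matrix(val)) val <- matrix(val, ncol = 1L)
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$backfn <- backfn
  nd$tape <- tape
  tape$k <- tape$k + 1L
  if (tape$k > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$k]] <- nd
  class(nd) <- "ad_nd"
  nd
}

#' @rdname ad_node
#' @export
ad_const <- function(tape, val) ad_node(tape, val)

#' @rdname ad_node
#' @export
ad_param <- function(tape, val) ad_node(tape, val)

.acc <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
}

#' Run the backward sweep from a scalar node
#'
#' Seeds the gradient of `root` with 1 and accumulates gradients into every
#' node on the tape that `root` depends on.
#'
#' @param root a scalar (1 x 1) node.
#' @export
ad_backward <- function(root) {
  if (length(root$val) != 1L)
    stop("backward pass must start from a scalar node")
  root$grad <- matrix(1, 1L, 1L)
  tape <- root$tape
  for (k in rev(seq_len(tape$k))) {
    nd <- tape$nodes[[k]]
    if (!is.null(nd$grad) && !is.null(nd$backfn)) nd$backfn(nd$grad)
  }
  invisible(NULL)
}

#' Matrix product of two nodes
#' @param a,b nodes with conformable values.
#' @return node with value `a$val %*% b$val`.
#' @export
ad_matmul <- function(a, b) {
  ad_node(a$tape, a$val %*% b$val, function(g) {
    .acc(a, g %*% t(b$val))
    .acc(b, t(a$val) %*% g)
  })
}

#' Elementwise sum of two same-shape nodes
#' @param a,b nodes.
#' @return node.
#' @export
ad_add <- function(a, b) {
  ad_node(a$tape, a$val + b$val, function(g) {
    .acc(a, g)
    .acc(b, g)
  })
}

#' Elementwise difference of two same-shape nodes
#' @param a,b nodes.
#' @return node.
#' @export
ad_sub <- function(a, b) {
  ad_node(a$tape, a$val - b$val, function(g) {
    .acc(a, g)
    .acc(b, -g)
  })
}

#' Elementwise (Hadamard) product of two same-shape nodes
#' @param a,b nodes.
#' @return node.
#' @export
ad_mul <- function(a, b) {
  ad_node(a$tape, a$val * b$val, function(g) {
    .acc(a, g * b$val)
    .acc(b, g * a$val)
  })
}

#' Scale each row of a node by a per-row scalar
#' @param x node (n x k).
#' @param s node (n x 1).
#' @return node (n x k) with row i equal to `x[i, ] * s[i]`.
#' @export
ad_scale_rows <- function(x, s) {
  sv <- as.vector(s$val)
  ad_node(x$tape, x$val * sv, function(g) {
    .acc(x, g * sv)
    .acc(s, matrix(rowSums(g * x$val), ncol = 1L))
  })
}

#' Add a bias row to every row of a node
#' @param x node (n x k).
#' @param b node (1 x k).
#' @return node (n x k).
#' @export
ad_add_bias <- function(x, b) {
  ad_node(x$tape, sweep(x$val, 2L, as.vector(b$val), "+"), function(g) {
    .acc(x, g)
    .acc(b, matrix(colSums(g), 1L))
  })
}

#' Gather rows of a node by index
#' @param x node (n x k).
#' @param idx integer vector of row indices (repeats allowed).
#' @return node (`length(idx)` x k).
#' @export
ad_gather <- function(x, idx) {
  ad_node(x$tape, x$val[idx, , drop = FALSE], function(g) {
    acc <- rowsum(g, group = idx)
    full <- matrix(0, nrow(x$val), ncol(x$val))
    full[as.integer(rownames(acc)), ] <- acc
    .acc(x, full)
  })
}

#' Scatter-add rows of a node into `n` output slots
#'
#' Output row i is the sum of the rows of `x` whose `idx` equals i; rows
#' receiving no contribution are zero.
#'
#' @param x node (m x k).
#' @param idx integer vector of length m of destination rows.
#' @param n number of output rows.
#' @return node (n x k).
#' @export
ad_scatter_add <- function(x, idx, n) {
  k <- ncol(x$val)
  out <- matrix(0, n, k)
  if (length(idx)) {
    acc <- rowsum(x$val, group = idx)
    out[as.integer(rownames(acc)), ] <- acc
  }
  ad_node(x$tape, out, function(g) {
    if (length(idx)) .acc(x, g[idx, , drop = FALSE])
  })
}

#' Column-concatenate nodes
#' @param ... nodes with equal row counts.
#' @return node.
#' @export
ad_cbind <- function(...) {
  parts <- list(...)
  widths <- vapply(parts, function(p) ncol(p$val), integer(1))
  stops <- cumsum(widths)
  starts <- c(1L, utils::head(stops, -1L) + 1L)
  ad_node(parts[[1L]]$tape, do.call(cbind, lapply(parts, `[[`, "val")),
          function(g) {
            for (i in seq_along(parts))
              .acc(parts[[i]], g[, starts[i]:stops[i], drop = FALSE])
          })
}

#' Swish (self-gated) activation, `x * sigmoid(x)`
#' @param x node.
#' @return node.
#' @export
ad_swish <- function(x) {
  s <- 1 / (1 + exp(-x$val))
  ad_node(x$tape, x$val * s, function(g) {
    .acc(x, g * (s * (1 + x$val * (1 - s))))
  })
}

#' Logistic sigmoid activation
#' @param x node.
#' @return node.
#' @export
ad_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$val))
  ad_node(x$tape, s, function(g) .acc(x, g * s * (1 - s)))
}

#' Leaky rectified linear activation
#' @param x node.
#' @param slope negative-side slope (default 0.01).
#' @return node.
#' @export
ad_leakyrelu <- function(x, slope = 0.01) {
  d <- ifelse(x$val > 0, 1, slope)
  ad_node(x$tape, x$val * d, function(g) .acc(x, g * d))
}

#' Euclidean norm of each row
#' @param x node (n x k).
#' @return node (n x 1); the subgradient at a zero row is taken as 0.
#' @export
ad_rownorm <- function(x) {
  nr <- sqrt(rowSums(x$val^2))
  ad_node(x$tape, matrix(nr, ncol = 1L), function(g) {
    safe <- ifelse(nr > 0, nr, 1)
    .acc(x, (as.vector(g) / safe) * x$val * (nr > 0))
  })
}

#' Sum of all entries
#' @param x node.
#' @return scalar node (1 x 1).
#' @export
ad_sum <- function(x) {
  dims <- dim(x$val)
  ad_node(x$tape, matrix(sum(x$val), 1L, 1L), function(g) {
    .acc(x, matrix(as.vector(g), dims[1L], dims[2L]))
  })
}

#' Multiply a node by a fixed scalar
#' @param x node.
#' @param c numeric scalar.
#' @return node.
#' @export
ad_scale <- function(x, c) {
  ad_node(x$tape, x$val * c, function(g) .acc(x, g * c))
}

#' Mean absolute error against a fixed target
#' @param pred node.
#' @param target numeric matrix/vector of the same shape.
#' @return scalar node.
#' @export
ad_mae <- function(pred, target) {
  if (!is.matrix(target)) target <- matrix(target, ncol = 1L)
  if (length(target) == 0L) stop("empty batch")
  r <- pred$val - target
  m <- length(r)
  ad_node(pred$tape, matrix(mean(abs(r)), 1L, 1L), function(g) {
    .acc(pred, as.vector(g) * sign(r) / m)
  })
}

#' Smooth L1 (Huber-type) loss against a fixed target
#'
#' Per element: `0.5 r^2` for `|r| < 1`, `|r| - 0.5` otherwise; averaged.
#'
#' @param pred node.
#' @param target numeric matrix/vector of the same shape.
#' @return scalar node.
#' @export
ad_smooth_l1 <- function(pred, target) {
  if (!is.matrix(target)) target <- matrix(target, ncol = 1L)
  if (length(target) == 0L) stop("empty batch")
  r <- pred$val - target
  m <- length(r)
  vals <- ifelse(abs(r) < 1, 0.5 * r^2, abs(r) - 0.5)
  ad_node(pred$tape, matrix(mean(vals), 1L, 1L), function(g) {
    .acc(pred, as.vector(g) * ifelse(abs(r) < 1, r, sign(r)) / m)
  })
}

#' Two-layer perceptron with Swish activations
#'
#' Applies `swish(swish(x W1 + b1) W2 + b2)`; the building block used for
#' message embeddings and the angular filter.
#'
#' @param x input node (n x k).
#' @param p named list of parameter nodes `W1`, `b1`, `W2`, `b2`.
#' @return node.
#' @export
ad_mlp2 <- function(x, p) {
  h <- ad_swish(ad_add_bias(ad_matmul(x, p$W1), p$b1))
  ad_swish(ad_add_bias(ad_matmul(h, p$W2), p$b2))
}
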