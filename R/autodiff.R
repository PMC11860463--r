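# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every node is an environment holding a numeric matrix `value`, an
# accumulated `grad` (NULL until touched by the backward pass), and a
# `backfn` closure that scatters the node's gradient to its parents.
# Nodes are registered on a tape in creation order; ad_backward() walks
# the tape in reverse. Scalars are 1x1 matrices throughout.
#
# This is deliberately small: only the operations the training graph
# needs exist, and each op's adjoint is verified against central finite
# differences in the test suite.

new_tape <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 64L)
  tape$n <- 0L
  tape
}

ad_register <- function(tape, value, backfn = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$backfn <- backfn
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- node
  node
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

# Leaf wrapping a constant (no gradient is read back).
ad_const <- function(tape, x) ad_register(tape, as_mat(x))

# Leaf wrapping a trainable parameter; grad is read after ad_backward().
ad_param <- function(tape, x) ad_register(tape, as_mat(x))

acc_grad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

ad_backward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- matrix(1, 1L, 1L)
  for (i in seq.int(tape$n, 1L)) {
    node <- tape$nodes[[i]]
    if (!is.null(node$grad) && !is.null(node$backfn)) node$backfn(node$grad)
  }
  invisible(NULL)
}

ad_matmul <- function(tape, a, b) {
  ad_register(tape, a$value %*% b$value, function(g) {
    acc_grad(a, g %*% t(b$value))
    acc_grad(b, t(a$value) %*% g)
  })
}

ad_transpose <- function(tape, a) {
  ad_register(tape, t(a$value), function(g) acc_grad(a, t(g)))
}

ad_add <- function(tape, a, b) {
  ad_register(tape, a$value + b$value, function(g) {
    acc_grad(a, g)
    acc_grad(b, g)
  })
}

ad_sub <- function(tape, a, b) {
  ad_register(tape, a$value - b$value, function(g) {
    acc_grad(a, g)
    acc_grad(b, -g)
  })
}

# a (n x k) + v (1 x k) broadcast over rows; the bias-add of a dense layer.
ad_add_rowvec <- function(tape, a, v) {
  ad_register(tape, sweep(a$value, 2L, drop(v$value), "+"), function(g) {
    acc_grad(a, g)
    acc_grad(v, matrix(colSums(g), 1L))
  })
}

# a (n x k) + u (n x 1) broadcast over columns.
ad_add_colvec <- function(tape, a, u) {
  ad_register(tape, a$value + drop(u$value), function(g) {
    acc_grad(a, g)
    acc_grad(u, matrix(rowSums(g), ncol = 1L))
  })
}

ad_mul <- function(tape, a, b) {
  ad_register(tape, a$value * b$value, function(g) {
    acc_grad(a, g * b$value)
    acc_grad(b, g * a$value)
  })
}

# Elementwise product with a constant matrix/scalar (masking, weighting).
ad_mul_const <- function(tape, a, k) {
  ad_register(tape, a$value * k, function(g) acc_grad(a, g * k))
}

ad_add_const <- function(tape, a, k) {
  ad_register(tape, a$value + k, function(g) acc_grad(a, g))
}

ad_neg <- function(tape, a) ad_mul_const(tape, a, -1)

ad_tanh <- function(tape, a) {
  val <- tanh(a$value)
  ad_register(tape, val, function(g) acc_grad(a, g * (1 - val^2)))
}

ad_softmax_rows <- function(tape, a) {
  z <- a$value - apply(a$value, 1L, max)
  e <- exp(z)
  val <- e / rowSums(e)
  ad_register(tape, val, function(g) {
    acc_grad(a, val * (g - rowSums(g * val)))
  })
}

# x^p for constant p; caller guarantees x > 0 when p is non-integral.
ad_pow_const <- function(tape, a, p) {
  val <- a$value^p
  ad_register(tape, val, function(g) acc_grad(a, g * p * a$value^(p - 1)))
}

ad_log <- function(tape, a) {
  ad_register(tape, log(a$value), function(g) acc_grad(a, g / a$value))
}

ad_sum <- function(tape, a) {
  dims <- dim(a$value)
  ad_register(tape, matrix(sum(a$value), 1L, 1L), function(g) {
    acc_grad(a, matrix(g[1L], dims[1L], dims[2L]))
  })
}

ad_mean <- function(tape, a) {
  dims <- dim(a$value)
  n <- length(a$value)
  ad_register(tape, matrix(mean(a$value), 1L, 1L), function(g) {
    acc_grad(a, matrix(g[1L] / n, dims[1L], dims[2L]))
  })
}

ad_rowsums <- function(tape, a) {
  k <- ncol(a$value)
  ad_register(tape, matrix(rowSums(a$value), ncol = 1L), function(g) {
    acc_grad(a, matrix(g, nrow(a$value), k))
  })
}

ad_colsums <- function(tape, a) {
  n <- nrow(a$value)
  ad_register(tape, matrix(colSums(a$value), 1L), function(g) {
    acc_grad(a, matrix(g, n, ncol(a$value), byrow = TRUE))
  })
}

# Row gather; indices must be unique (subsetting a batch, never oversampling).
ad_rows <- function(tape, a, idx) {
  stopifnot(!anyDuplicated(idx))
  ad_register(tape, a$value[idx, , drop = FALSE], function(g) {
    gfull <- matrix(0, nrow(a$value), ncol(a$value))
    gfull[idx, ] <- g
    acc_grad(a, gfull)
  })
}

# Assemble an n-row matrix from disjoint row blocks, each a node.
# parts: list of list(idx = integer rows, node = source of those rows).
ad_stack_rows <- function(tape, n, parts) {
  k <- ncol(parts[[1L]]$node$value)
  val <- matrix(NA_real_, n, k)
  for (p in parts) val[p$idx, ] <- p$node$value
  stopifnot(!anyNA(val))
  ad_register(tape, val, function(g) {
    for (p in parts) acc_grad(p$node, g[p$idx, , drop = FALSE])
  })
}

# Rows renormalised to sum 1: v_ij = a_ij / sum_k a_ik.
ad_row_normalize <- function(tape, a) {
  rs <- rowSums(a$value)
  val <- a$value / rs
  ad_register(tape, val, function(g) {
    acc_grad(a, (g - rowSums(g * val)) / rs)
  })
}

# a / s where s is a scalar (1x1) node: normalisation by a computed total.
ad_div_scalar <- function(tape, a, s) {
  sv <- s$value[1L]
  val <- a$value / sv
  ad_register(tape, val, function(g) {
    acc_grad(a, g / sv)
    acc_grad(s, matrix(-sum(g * val) / sv, 1L, 1L))
  })
}

# All pairwise squared Euclidean distances between rows of a (n x n output).
ad_pairwise_sqdist <- function(tape, a) {
  L <- a$value
  r <- rowSums(L^2)
  val <- outer(r, r, "+") - 2 * (L %*% t(L))
  val[val < 0] <- 0
  diag(val) <- 0
  ad_register(tape, val, function(g) {
    gs <- rowSums(g) + colSums(g)
    acc_grad(a, 2 * (gs * L - (g + t(g)) %*% L))
  })
}
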