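#' @name networks
#' @title Per-view autoencoders and cross-view generators
#'
#' @description
#' Each view gets a fully connected autoencoder: the encoder maps the
#' view's feature space to a shared latent dimension with a softmax on
#' the final layer (latent rows are probability vectors, the substrate
#' of the information-theoretic fusion loss), and a mirrored decoder
#' maps back. Two cross-view generators, one per direction, are
#' fully connected maps on the latent space used to predict the latent
#' of a missing view from the latent of the available one.
#'
#' Networks are plain lists of weight matrices and bias row-vectors
#' with tanh between hidden layers; the same parameter lists are wrapped
#' into autodiff nodes during training, so evaluation here and the
#' training graph share one definition.
NULL

# Glorot-uniform layer init.
init_layer <- function(fan_in, fan_out) {
  b <- sqrt(6 / (fan_in + fan_out))
  list(W = matrix(stats::runif(fan_in * fan_out, -b, b), fan_in, fan_out),
       b = matrix(0, 1L, fan_out))
}

init_mlp <- function(widths) {
  lapply(seq_len(length(widths) - 1L), function(i) {
    init_layer(widths[i], widths[i + 1L])
  })
}

#' Initialise a view autoencoder
#'
#' @param input_dim feature dimension of the view.
#' @param latent_dim shared latent dimension L.
#' @param hidden integer vector of encoder hidden widths; the decoder
#'   mirrors them.
#' @return list with `encoder` and `decoder` layer lists and the dims.
#' @rdname networks
#' @export
init_autoencoder <- function(input_dim, latent_dim, hidden = c(512L, 256L)) {
  structure(
    list(encoder = init_mlp(c(input_dim, hidden, latent_dim)),
         decoder = init_mlp(c(latent_dim, rev(hidden), input_dim)),
         input_dim = input_dim, latent_dim = latent_dim),
    class = "view_autoencoder"
  )
}

#' Initialise a cross-view generator (latent -> latent map)
#'
#' @param hidden integer vector of generator hidden widths.
#' @rdname networks
#' @export
init_generator <- function(latent_dim, hidden = 256L) {
  structure(
    list(layers = init_mlp(c(latent_dim, hidden, latent_dim)),
         latent_dim = latent_dim),
    class = "crossview_generator"
  )
}

# Numeric forward pass; final = "softmax" | "linear".
mlp_forward <- function(layers, X, final = "linear") {
  h <- as.matrix(X)
  nl <- length(layers)
  for (i in seq_len(nl)) {
    h <- sweep(h %*% layers[[i]]$W, 2L, drop(layers[[i]]$b), "+")
    if (i < nl) h <- tanh(h)
  }
  if (final == "softmax") {
    h <- h - apply(h, 1L, max)
    e <- exp(h)
    h <- e / rowSums(e)
  }
  h
}

#' Encode available rows of a view
#'
#' Callers pass only rows whose mask is 1 for this view; masked rows
#' are never encoded. Output rows are softmax-normalised (entries in
#' (0, 1), each row sums to 1).
#'
#' @param ae a `view_autoencoder`.
#' @param X matrix of available rows (n x input_dim).
#' @return n x latent_dim latent matrix `Z`.
#' @rdname networks
#' @export
encode_view <- function(ae, X) {
  X <- as.matrix(X)
  if (ncol(X) != ae$input_dim) {
    stop(sprintf("input has %d columns, encoder expects %d",
                 ncol(X), ae$input_dim), call. = FALSE)
  }
  mlp_forward(ae$encoder, X, final = "softmax")
}

#' @rdname networks
#' @export
decode_view <- function(ae, Z) {
  Z <- as.matrix(Z)
  if (ncol(Z) != ae$latent_dim) {
    stop(sprintf("latent has %d columns, decoder expects %d",
                 ncol(Z), ae$latent_dim), call. = FALSE)
  }
  mlp_forward(ae$decoder, Z, final = "linear")
}

#' @rdname networks
#' @export
generate_latent <- function(gen, L) {
  L <- as.matrix(L)
  if (ncol(L) != gen$latent_dim) {
    stop(sprintf("latent has %d columns, generator expects %d",
                 ncol(L), gen$latent_dim), call. = FALSE)
  }
  mlp_forward(gen$layers, L, final = "linear")
}

#' Within-view reconstruction loss
#'
#' Mean squared reconstruction error per available row, summed over
#' views: `sum_v mean_i ||x_i^v - d_v(e_v(x_i^v))||^2` over rows with
#' mask 1. Averaging over rows (rather than summing) keeps the loss
#' scale independent of batch size so the trade-off weights transfer.
#'
#' @param views list of two view matrices (full N rows each).
#' @param mask N x 2 availability mask.
#' @param aes list of two `view_autoencoder`s.
#' @return nonnegative scalar.
#' @rdname networks
#' @export
reconstruction_loss <- function(views, mask, aes) {
  total <- 0
  for (v in 1:2) {
    idx <- which(mask[, v] == 1)
    if (length(idx) == 0L) next
    X <- views[[v]][idx, , drop = FALSE]
    Xhat <- decode_view(aes[[v]], encode_view(aes[[v]], X))
    total <- total + mean(rowSums((X - Xhat)^2))
  }
  total
}

#' Cross-view prediction loss
#'
#' With paired samples (both views available) the loss is the
#' two-directional squared prediction error
#' `mean ||G12(l1) - l2||^2 + mean ||G21(l2) - l1||^2` over pairs.
#' When no pairs exist (the fully incomplete regime) the paired form is
#' undefined, so the loss falls back to cycle consistency through both
#' generators: `mean ||G21(G12(l1)) - l1||^2` over view-1-only rows
#' plus the symmetric term over view-2-only rows.
#'
#' @param L1,L2 latent matrices of available rows of each view, indexed
#'   by `idx1`/`idx2` (positions in the full sample vector).
#' @param idx1,idx2 integer sample indices the latent rows correspond to.
#' @param gens list with generators `g12` and `g21`.
#' @return list with `value` (nonnegative scalar) and `mode`
#'   (`"paired"` or `"cycle"`).
#' @rdname networks
#' @export
prediction_loss <- function(L1, L2, idx1, idx2, gens) {
  paired <- intersect(idx1, idx2)
  if (length(paired) > 0L) {
    p1 <- L1[match(paired, idx1), , drop = FALSE]
    p2 <- L2[match(paired, idx2), , drop = FALSE]
    val <- mean(rowSums((generate_latent(gens$g12, p1) - p2)^2)) +
      mean(rowSums((generate_latent(gens$g21, p2) - p1)^2))
    return(list(value = val, mode = "paired"))
  }
  only1 <- setdiff(idx1, idx2)
  only2 <- setdiff(idx2, idx1)
  val <- 0
  if (length(only1) > 0L) {
    s1 <- L1[match(only1, idx1), , drop = FALSE]
    cyc <- generate_latent(gens$g21, generate_latent(gens$g12, s1))
    val <- val + mean(rowSums((cyc - s1)^2))
  }
  if (length(only2) > 0L) {
    s2 <- L2[match(only2, idx2), , drop = FALSE]
    cyc <- generate_latent(gens$g12, generate_latent(gens$g21, s2))
    val <- val + mean(rowSums((cyc - s2)^2))
  }
  list(value = val, mode = "cycle")
}

#' Impute missing-view latents with the generators
#'
#' For each sample missing view 2, the view-2 latent is predicted as
#' `G12` of its (reweighted) view-1 latent, and symmetrically for view
#' 1. Available latents are never overwritten.
#'
#' @param latents list of two N x L matrices; rows of missing views may
#'   hold any placeholder (they are replaced, never read).
#' @param mask N x 2 availability mask (every row has at least one 1).
#' @param gens list with `g12` and `g21`.
#' @return list of two complete N x L latent matrices.
#' @rdname networks
#' @export
impute_missing <- function(latents, mask, gens) {
  stopifnot(all(rowSums(mask) >= 1))
  out <- latents
  miss2 <- which(mask[, 2] == 0)
  if (length(miss2) > 0L) {
    out[[2L]][miss2, ] <-
      generate_latent(gens$g12, latents[[1L]][miss2, , drop = FALSE])
  }
  miss1 <- which(mask[, 1] == 0)
  if (length(miss1) > 0L) {
    out[[1L]][miss1, ] <-
      generate_latent(gens$g21, latents[[2L]][miss1, , drop = FALSE])
  }
  out
}

# ---- tape (training) versions -------------------------------------------

# Wrap a layer list as parameter nodes; returns list of list(W=, b=) nodes.
wrap_params <- function(tape, layers) {
  lapply(layers, function(ly) {
    list(W = ad_param(tape, ly$W), b = ad_param(tape, ly$b))
  })
}

ad_mlp <- function(tape, layer_nodes, Xnode, final = "linear") {
  h <- Xnode
  nl <- length(layer_nodes)
  for (i in seq_len(nl)) {
    h <- ad_add_rowvec(tape, ad_matmul(tape, h, layer_nodes[[i]]$W),
                       layer_nodes[[i]]$b)
    if (i < nl) h <- ad_tanh(tape, h)
  }
  if (final == "softmax") h <- ad_softmax_rows(tape, h) else h
}

# mean_i ||a_i - b_i||^2 as a scalar node.
ad_mse_rows <- function(tape, a, b) {
  d <- ad_sub(tape, a, b)
  ad_mul_const(tape, ad_mean(tape, ad_pow_const(tape, d, 2)),
               ncol(a$value))
}
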