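#' @name entropy-weighting
#' @title Entropy-weight feature reconstruction
#'
#' @description
#' The entropy-weighting operator scores each latent feature (column)
#' by how unevenly its values are shared across samples and turns the
#' scores into weights that rescale the latent matrix: features whose
#' share distribution is close to uniform carry little discriminative
#' information and are shrunk, concentrated features are amplified.
#' The pipeline is `distribution_matrix()` -> `entropy_values()` ->
#' `entropy_weights()` -> `reconstruct_latents()`, or the one-call
#' wrapper [entropy_weighting()].
#'
#' Two conventions are provided. The default `"canonical"` mode is the
#' standard entropy-weight method: columns are min-max scaled to
#' \[eps, 1\], shares are column-sum normalised, and the entropy is
#' Shannon entropy normalised by `log(N)` so that `E` lies in \[0, 1\]
#' and the weights form a convex combination. The `"literal"` mode
#' instead normalises by the row mean (distribution matrix) and column
#' mean (shares) and uses the unnormalised, unsigned entropy
#' `E_j = (1/N) sum_i p_ij log p_ij`; it can produce entropies outside
#' \[0, 1\] and hence negative weights (kept, with a warning), and
#' exists so the raw convention can be reproduced and compared.
#'
#' In both modes the weights sum to exactly 1, which follows
#' algebraically from the weight formula
#' `W_j = (1 - E_j) / (m - sum_k E_k)` with `m` the number of features.
#' `0 * log 0` is evaluated as 0 throughout.
NULL

EW_EPS <- 1e-12

#' Distribution matrix of a latent representation
#'
#' @param Z numeric N x L latent matrix (no NaN/Inf).
#' @param mode `"canonical"` (per-column min-max scaling to \[eps, 1\])
#'   or `"literal"` (each entry divided by its row mean, with an eps
#'   guard and a warning when a row mean vanishes).
#' @param eps numerical guard for denominators and lower bounds.
#' @return N x L nonnegative (canonical) or real (literal) matrix `Y`.
#' @rdname entropy-weighting
#' @export
distribution_matrix <- function(Z, mode = c("canonical", "literal"),
                                eps = EW_EPS) {
  mode <- match.arg(mode)
  Z <- as.matrix(Z)
  if (any(!is.finite(Z))) stop("Z contains NaN/Inf", call. = FALSE)
  if (mode == "canonical") {
    lo <- apply(Z, 2L, min)
    hi <- apply(Z, 2L, max)
    span <- hi - lo
    Y <- Z
    for (j in seq_len(ncol(Z))) {
      if (span[j] < eps) {
        Y[, j] <- 1  # constant feature: maximally uniform shares
      } else {
        Y[, j] <- eps + (1 - eps) * (Z[, j] - lo[j]) / span[j]
      }
    }
    Y
  } else {
    rm_ <- rowMeans(Z)
    bad <- abs(rm_) < eps
    if (any(bad)) {
      warning(sprintf("%d row mean(s) ~ 0 in literal distribution matrix; eps guard applied",
                      sum(bad)))
      rm_[bad] <- eps
    }
    Z / rm_
  }
}

#' Per-feature entropy values
#'
#' @param Y distribution matrix from [distribution_matrix()].
#' @inheritParams distribution_matrix
#' @return length-L numeric vector `E`; in canonical mode each entry is
#'   in \[0, 1\] (1 = uniform shares, 0 = one-hot).
#' @rdname entropy-weighting
#' @export
entropy_values <- function(Y, mode = c("canonical", "literal"),
                           eps = EW_EPS) {
  mode <- match.arg(mode)
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (mode == "canonical") {
    if (any(Y < 0)) {
      stop("canonical entropy requires a nonnegative distribution matrix",
           call. = FALSE)
    }
    cs <- colSums(Y)
    cs[cs < eps] <- eps
    p <- sweep(Y, 2L, cs, "/")
    plogp <- ifelse(p > 0, p * log(p), 0)
    if (n == 1L) return(rep(0, ncol(Y)))
    -colSums(plogp) / log(n)
  } else {
    cm <- colMeans(Y)
    bad <- abs(cm) < eps
    if (any(bad)) {
      warning(sprintf("%d column mean(s) ~ 0 in literal shares; eps guard applied",
                      sum(bad)))
      cm[bad] <- eps
    }
    p <- sweep(Y, 2L, cm, "/")
    plogp <- ifelse(p > 0, p * log(p), 0)  # p <= 0 contributes 0
    colSums(plogp) / n
  }
}

#' Entropy weights from per-feature entropies
#'
#' @param E length-L vector of entropies.
#' @param tol degeneracy tolerance for the denominator `m - sum(E)`.
#' @return length-L weight vector summing to 1. Negative weights (only
#'   possible in literal mode, where `E_j > 1` can occur) are kept with
#'   a warning. When every feature is equally (and maximally) entropic
#'   the denominator vanishes but the continuous limit is uniform, so
#'   `W = 1/L` is returned (the constant-matrix case); a vanishing
#'   denominator with unequal entropies is a genuine degeneracy and
#'   errors.
#' @rdname entropy-weighting
#' @export
entropy_weights <- function(E, tol = 1e-10) {
  if (any(!is.finite(E))) stop("E contains non-finite values", call. = FALSE)
  m <- length(E)
  denom <- m - sum(E)
  if (abs(denom) < tol) {
    if (max(abs(E - mean(E))) < tol) {
      return(rep(1 / m, m))  # uniform limit of (1 - E_j)/(m - sum E)
    }
    stop("degenerate entropy profile: features maximally entropic (m - sum(E) = 0)",
         call. = FALSE)
  }
  W <- (1 - E) / denom
  if (any(W < 0)) {
    warning("negative entropy weights produced (literal-mode entropies > 1); values kept")
  }
  W
}

#' Reweight latents by entropy weights
#'
#' Column-scales the latent matrix: `L_ij = W_j * Z_ij`. The output has
#' the same shape as the input (the weighting rescales the feature
#' axis, it does not collapse it).
#'
#' @param Z N x L latent matrix.
#' @param W length-L weight vector.
#' @return N x L reweighted matrix.
#' @rdname entropy-weighting
#' @export
reconstruct_latents <- function(Z, W) {
  Z <- as.matrix(Z)
  if (length(W) != ncol(Z)) {
    stop(sprintf("length(W) = %d does not match ncol(Z) = %d",
                 length(W), ncol(Z)), call. = FALSE)
  }
  sweep(Z, 2L, W, "*")
}

#' One-call entropy weighting
#'
#' @inheritParams distribution_matrix
#' @return list with `Y`, `E`, `W` and the reweighted latents `L`.
#' @rdname entropy-weighting
#' @export
entropy_weighting <- function(Z, mode = c("canonical", "literal"),
                              eps = EW_EPS) {
  mode <- match.arg(mode)
  Y <- distribution_matrix(Z, mode, eps)
  E <- entropy_values(Y, mode, eps)
  W <- entropy_weights(E)
  list(Y = Y, E = E, W = W, L = reconstruct_latents(Z, W), mode = mode)
}
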