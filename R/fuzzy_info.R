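#' @name fuzzy-info
#' @title Fuzzy-membership similarity and information-theoretic fusion
#'
#' @description
#' The clustering signal is carried by sample-by-sample soft
#' memberships. Every sample in a batch acts as a cluster centre, so
#' the membership matrix `U` is N x N and row-stochastic: `U_ij` is the
#' degree to which sample `i` belongs to the fuzzy cluster centred at
#' sample `j`, larger meaning more similar. From `U` and the pairwise
#' squared distances each view yields a similarity matrix `S^v` (the
#' summand of the fuzzy c-means objective) and a row-stochastic
#' probability matrix `P^v = row-softmax(-S^v)`. The two views' P
#' matrices are coupled into a joint distribution `J = P1 P2' / sum`,
#' and the training loss is a mutual-information functional of `J`
#' whose marginals are raised to the power `alpha + 1`: minimising it
#' concentrates the cross-view coupling (high mutual information) while
#' the alpha term balances the marginal entropies.
#'
#' Canonical/literal modes: the canonical membership is the standard
#' inverse-distance fuzzy c-means form `U_ij ~ (d^2_ij + eps)^(-1/(m-1))`
#' (closer = more similar); the literal mode uses the increasing form
#' `((1/m) d^2_ij)^(1/(m-1))` row-normalised. The canonical fusion loss
#' is `-sum J log(J / (Sl^(a+1) Sl'^(a+1)))`; the literal one drops the
#' log: `-sum J / (Sl^(a+1) Sl'^(a+1))`. Canonical is the default in
#' both cases (it is the self-consistent reading: membership decreasing
#' in distance, loss an actual mutual information at `alpha = 0`);
#' literal reproduces the raw formulas for comparison.
NULL

FI_EPS <- 1e-12

#' Pairwise squared Euclidean distances
#'
#' @param L n x d matrix of latent rows.
#' @return symmetric n x n matrix with zero diagonal.
#' @rdname fuzzy-info
#' @export
pairwise_sqdist <- function(L) {
  L <- as.matrix(L)
  r <- rowSums(L^2)
  d2 <- outer(r, r, "+") - 2 * (L %*% t(L))
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  d2
}

#' Fuzzy membership matrix over batch samples
#'
#' @param L n x d latent matrix (n >= 2); all samples act as centres.
#' @param m fuzziness exponent (> 1, default 2).
#' @param mode `"canonical"` (inverse-distance FCM) or `"literal"`
#'   (increasing in distance).
#' @param eps guard added to distances before the negative power.
#' @return n x n row-stochastic membership matrix `U` with zero
#'   diagonal (a sample is not a candidate centre for itself).
#' @rdname fuzzy-info
#' @export
fcm_membership <- function(L, m = 2, mode = c("canonical", "literal"),
                           eps = FI_EPS) {
  mode <- match.arg(mode)
  L <- as.matrix(L)
  if (nrow(L) < 2L) {
    stop("membership needs at least 2 samples", call. = FALSE)
  }
  if (m <= 1) stop("fuzziness m must be > 1", call. = FALSE)
  d2 <- pairwise_sqdist(L)
  expo <- 1 / (m - 1)
  U <- if (mode == "canonical") {
    (d2 + eps)^(-expo)
  } else {
    (d2 / m)^(expo)
  }
  diag(U) <- 0
  rs <- rowSums(U)
  rs[rs < eps] <- eps
  U / rs
}

#' Per-view similarity matrix and fuzzy objective
#'
#' Computes the elementwise summand of the fuzzy c-means objective,
#' `S_ij = (1/V) U_ij^2 d^2_ij` (with `V` the number of views), its sum
#' (the scalar objective), and the probability form
#' `P = row-softmax(-S)` used for cross-view fusion: rows of `P` put
#' the most mass on the centres a sample is fuzzily closest to.
#'
#' @param U n x n membership matrix.
#' @param d2 n x n squared distance matrix.
#' @param n_views the number of views `V` (the 1/V factor).
#' @return list with `S`, `objective` and `P`.
#' @rdname fuzzy-info
#' @export
view_similarity <- function(U, d2, n_views = 2L) {
  U <- as.matrix(U)
  d2 <- as.matrix(d2)
  stopifnot(all(dim(U) == dim(d2)))
  S <- U^2 * d2 / n_views
  negS <- -S
  negS <- negS - apply(negS, 1L, max)
  e <- exp(negS)
  list(S = S, objective = sum(S), P = e / rowSums(e))
}

#' Fuse two per-view probability matrices into a joint distribution
#'
#' @param P1,P2 nonnegative matrices with matching row counts (row-
#'   stochastic in normal use).
#' @return list with `joint` (nonnegative, sums to 1), `row_marginal`
#'   and `col_marginal` (each summing to 1).
#' @rdname fuzzy-info
#' @export
fuse_joint <- function(P1, P2) {
  P1 <- as.matrix(P1)
  P2 <- as.matrix(P2)
  if (any(P1 < 0) || any(P2 < 0)) {
    stop("probability matrices must be nonnegative", call. = FALSE)
  }
  A <- P1 %*% t(P2)
  tot <- sum(A)
  if (tot <= 0) stop("degenerate fusion: coupling matrix sums to 0",
                     call. = FALSE)
  J <- A / tot
  list(joint = J, row_marginal = rowSums(J), col_marginal = colSums(J))
}

#' Information-theoretic fusion loss
#'
#' Canonical mode evaluates
#' `-sum_ij J_ij log( J_ij / (r_i^(a+1) c_j^(a+1)) )` with `r`, `c` the
#' marginals of the joint `J` — at `alpha = 0` this is minus the mutual
#' information of the coupling, so it is 0 for an independent joint and
#' `-(2 alpha + 1) log n` for the perfectly aligned uniform-diagonal
#' joint `I/n`. Literal mode evaluates
#' `-sum_ij J_ij / (r_i^(a+1) c_j^(a+1))` (no log). `0 log 0` is 0 and
#' marginals are guarded by `eps` inside logs/denominators.
#'
#' @param joint output of [fuse_joint()], or a bare joint matrix.
#' @param alpha entropy-balancing exponent (>= 0, default 9).
#' @param mode `"canonical"` or `"literal"`.
#' @param eps numerical guard.
#' @return scalar loss (negative when the coupling is informative).
#' @rdname fuzzy-info
#' @export
info_fusion_loss <- function(joint, alpha = 9,
                             mode = c("canonical", "literal"),
                             eps = FI_EPS) {
  mode <- match.arg(mode)
  if (is.matrix(joint)) {
    joint <- list(joint = joint, row_marginal = rowSums(joint),
                  col_marginal = colSums(joint))
  }
  J <- joint$joint
  r <- pmax(joint$row_marginal, eps)
  cc <- pmax(joint$col_marginal, eps)
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  a1 <- alpha + 1
  if (mode == "canonical") {
    logden <- a1 * (log(r)[row(J)] + log(cc)[col(J)])
    dim(logden) <- dim(J)
    terms <- ifelse(J > 0, J * (log(pmax(J, eps)) - logden), 0)
    -sum(terms)
  } else {
    den <- (r^a1)[row(J)] * (cc^a1)[col(J)]
    dim(den) <- dim(J)
    -sum(J / pmax(den, eps))
  }
}

# ---- tape (training) versions -------------------------------------------

# Membership node from a latent node; returns list(U=, d2=).
ad_fcm_membership <- function(tape, Lnode, m = 2,
                              mode = "canonical", eps = FI_EPS) {
  n <- nrow(Lnode$value)
  d2 <- ad_pairwise_sqdist(tape, Lnode)
  expo <- 1 / (m - 1)
  raw <- if (mode == "canonical") {
    ad_pow_const(tape, ad_add_const(tape, d2, eps), -expo)
  } else {
    # literal form has zero diagonal already; eps keeps the power finite
    ad_pow_const(tape, ad_add_const(tape, ad_mul_const(tape, d2, 1 / m), eps),
                 expo)
  }
  offdiag <- 1 - diag(n)
  U <- ad_row_normalize(tape, ad_mul_const(tape, raw, offdiag))
  list(U = U, d2 = d2)
}

# S^v summand and its softmax probability node.
ad_view_similarity <- function(tape, U, d2, n_views = 2L) {
  S <- ad_mul_const(tape, ad_mul(tape, ad_pow_const(tape, U, 2), d2),
                    1 / n_views)
  P <- ad_softmax_rows(tape, ad_neg(tape, S))
  list(S = S, P = P)
}

# Joint distribution node and the fusion loss node.
ad_info_fusion_loss <- function(tape, P1, P2, alpha = 9,
                                mode = "canonical", eps = FI_EPS) {
  A <- ad_matmul(tape, P1, ad_transpose(tape, P2))
  tot <- ad_add_const(tape, ad_sum(tape, A), eps)
  J <- ad_div_scalar(tape, A, tot)
  r <- ad_rowsums(tape, J)       # n x 1
  cc <- ad_colsums(tape, J)      # 1 x n
  a1 <- alpha + 1
  zero <- ad_mul_const(tape, J, 0)
  if (mode == "canonical") {
    logJ <- ad_log(tape, ad_add_const(tape, J, eps))
    logr <- ad_log(tape, ad_add_const(tape, r, eps))
    logc <- ad_log(tape, ad_add_const(tape, cc, eps))
    # matrix of log r_i + log c_j by broadcasting both marginals
    logden <- ad_add_colvec(tape, ad_add_rowvec(tape, zero, logc), logr)
    inner <- ad_sub(tape, logJ, ad_mul_const(tape, logden, a1))
    ad_neg(tape, ad_sum(tape, ad_mul(tape, J, inner)))
  } else {
    den_r <- ad_pow_const(tape, ad_add_const(tape, r, eps), -a1)
    den_c <- ad_pow_const(tape, ad_add_const(tape, cc, eps), -a1)
    den <- ad_mul(tape,
                  ad_add_colvec(tape, zero, den_r),
                  ad_add_rowvec(tape, zero, den_c))
    ad_neg(tape, ad_sum(tape, ad_mul(tape, J, den)))
  }
}
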