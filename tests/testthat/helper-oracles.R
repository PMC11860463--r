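# Independent brute-force oracles, written as plain double loops so they
# share no code path with the implementation they check.

# Entropy weighting, canonical convention.
oracle_entropy_canonical <- function(Z, eps = 1e-12) {
  n <- nrow(Z)
  L <- ncol(Z)
  Y <- matrix(0, n, L)
  for (j in seq_len(L)) {
    lo <- min(Z[, j])
    hi <- max(Z[, j])
    for (i in seq_len(n)) {
      Y[i, j] <- if (hi - lo < eps) 1 else eps + (1 - eps) * (Z[i, j] - lo) / (hi - lo)
    }
  }
  E <- numeric(L)
  for (j in seq_len(L)) {
    s <- sum(Y[, j])
    acc <- 0
    for (i in seq_len(n)) {
      p <- Y[i, j] / s
      if (p > 0) acc <- acc + p * log(p)
    }
    E[j] <- -acc / log(n)
  }
  W <- (1 - E) / (L - sum(E))
  list(Y = Y, E = E, W = W)
}

# Entropy weighting, literal convention (row-mean shares, unsigned entropy).
oracle_entropy_literal <- function(Z, eps = 1e-12) {
  n <- nrow(Z)
  L <- ncol(Z)
  Y <- matrix(0, n, L)
  for (i in seq_len(n)) {
    rm_ <- mean(Z[i, ])
    if (abs(rm_) < eps) rm_ <- eps
    Y[i, ] <- Z[i, ] / rm_
  }
  E <- numeric(L)
  for (j in seq_len(L)) {
    cm <- mean(Y[, j])
    if (abs(cm) < eps) cm <- eps
    acc <- 0
    for (i in seq_len(n)) {
      p <- Y[i, j] / cm
      if (p > 0) acc <- acc + p * log(p)
    }
    E[j] <- acc / n
  }
  W <- (1 - E) / (L - sum(E))
  list(Y = Y, E = E, W = W)
}

# Canonical inverse-distance membership, row by row.
oracle_membership_canonical <- function(L, m = 2, eps = 1e-12) {
  n <- nrow(L)
  U <- matrix(0, n, n)
  for (i in seq_len(n)) {
    w <- numeric(n)
    for (j in seq_len(n)) {
      if (i == j) next
      d2 <- sum((L[i, ] - L[j, ])^2)
      w[j] <- (d2 + eps)^(-1 / (m - 1))
    }
    U[i, ] <- w / sum(w)
  }
  U
}

oracle_membership_literal <- function(L, m = 2, eps = 1e-12) {
  n <- nrow(L)
  U <- matrix(0, n, n)
  for (i in seq_len(n)) {
    w <- numeric(n)
    for (j in seq_len(n)) {
      if (i == j) next
      d2 <- sum((L[i, ] - L[j, ])^2)
      w[j] <- (d2 / m + eps)^(1 / (m - 1))
    }
    U[i, ] <- w / max(sum(w), eps)
  }
  U
}

# Joint distribution by explicit triple loop.
oracle_joint <- function(P1, P2) {
  n <- nrow(P1)
  k <- nrow(P2)
  A <- matrix(0, n, k)
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      A[i, j] <- sum(P1[i, ] * P2[j, ])
    }
  }
  A / sum(A)
}

# Both fusion-loss conventions by explicit double loop.
oracle_fusion_loss <- function(J, alpha, mode, eps = 1e-12) {
  r <- rowSums(J)
  cc <- colSums(J)
  a1 <- alpha + 1
  acc <- 0
  for (i in seq_len(nrow(J))) {
    for (j in seq_len(ncol(J))) {
      ri <- max(r[i], eps)
      cj <- max(cc[j], eps)
      if (mode == "canonical") {
        if (J[i, j] > 0) {
          acc <- acc + J[i, j] * (log(J[i, j]) - a1 * (log(ri) + log(cj)))
        }
      } else {
        acc <- acc + J[i, j] / max(ri^a1 * cj^a1, eps)
      }
    }
  }
  -acc
}

# Accuracy by exhaustive search over one-to-one matchings.
oracle_accuracy <- function(pred, truth) {
  pl <- sort(unique(pred))
  tl <- sort(unique(truth))
  k <- max(length(pl), length(tl))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  best <- 0
  for (pm in perms(seq_len(k))) {
    hits <- 0
    for (s in seq_along(pred)) {
      pi <- match(pred[s], pl)
      ti <- match(truth[s], tl)
      if (!is.na(pi) && !is.na(ti) && pm[pi] == ti) hits <- hits + 1
    }
    best <- max(best, hits)
  }
  best / length(pred)
}

# NMI by explicit probability loops (arithmetic-mean normalisation).
oracle_nmi <- function(pred, truth) {
  n <- length(pred)
  pl <- unique(pred)
  tl <- unique(truth)
  mi <- 0
  for (a in pl) {
    for (b in tl) {
      pab <- sum(pred == a & truth == b) / n
      pa <- sum(pred == a) / n
      pb <- sum(truth == b) / n
      if (pab > 0) mi <- mi + pab * log(pab / (pa * pb))
    }
  }
  h <- function(x) {
    acc <- 0
    for (a in unique(x)) {
      p <- sum(x == a) / length(x)
      acc <- acc - p * log(p)
    }
    acc
  }
  norm <- (h(pred) + h(truth)) / 2
  if (norm == 0) 0 else mi / norm
}

# ARI by explicit enumeration of all sample pairs.
oracle_ari <- function(pred, truth) {
  n <- length(pred)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      same_p <- pred[i] == pred[j]
      same_t <- truth[i] == truth[j]
      if (same_p && same_t) n11 <- n11 + 1
      else if (!same_p && !same_t) n00 <- n00 + 1
      else if (same_p) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  total <- n11 + n00 + n10 + n01
  expected <- (n11 + n10) * (n11 + n01) / total
  maximum <- ((n11 + n10) + (n11 + n01)) / 2
  if (maximum == expected) return(0)
  (n11 - expected) / (maximum - expected)
}

# Tiny complete two-view dataset with known values.
tiny_dataset <- function(n = 4L, d1 = 3L, d2 = 2L, seed = 11L) {
  set.seed(seed)
  imvc_dataset(list(matrix(rnorm(n * d1), n), matrix(rnorm(n * d2), n)),
               labels = rep_len(1:2, n))
}

# Single linear layer autoencoder whose decoder exactly inverts the
# encoder on the given batch (least-norm exact fit through [Z, 1]).
exact_inverse_autoencoder <- function(X, latent_dim) {
  stopifnot(latent_dim + 1L >= nrow(X))
  ae <- init_autoencoder(ncol(X), latent_dim, hidden = integer(0))
  Z <- encode_view(ae, X)
  Zaug <- cbind(Z, 1)
  # min-norm solution of Zaug %*% B = X (underdetermined, exact fit)
  B <- t(Zaug) %*% solve(Zaug %*% t(Zaug), X)
  ae$decoder[[1L]]$W <- B[seq_len(latent_dim), , drop = FALSE]
  ae$decoder[[1L]]$b <- B[latent_dim + 1L, , drop = FALSE]
  ae
}

# Single linear layer generator computing x -> x %*% W + b.
linear_generator <- function(W, b = NULL) {
  g <- init_generator(nrow(W), hidden = integer(0))
  g$layers[[1L]]$W <- W
  g$layers[[1L]]$b <- if (is.null(b)) matrix(0, 1L, ncol(W)) else b
  g
}

fast_config <- function(epochs = 3L, ...) {
  imvc_config(latent_dim = 8L, encoder_hidden = c(16L), generator_hidden = 8L,
              epochs = epochs, ...)
}
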