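test_that("equilateral points share membership equally", {
  # equilateral triangle in the plane
  L <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  U <- fcm_membership(L)
  expect_equal(diag(U), rep(0, 3))
  off <- U[row(U) != col(U)]
  expect_equal(off, rep(0.5, 6), tolerance = 1e-9)
  expect_equal(rowSums(U), rep(1, 3))
})

test_that("membership follows the inverse-square distance law at m = 2", {
  # point 1 is twice as far from point 3 as from point 2
  L <- rbind(c(0, 0), c(1, 0), c(2, 0))
  U <- fcm_membership(L, m = 2, mode = "canonical")
  expect_equal(U[1, 2] / U[1, 3], 4, tolerance = 1e-6)
})

test_that("membership matches the brute-force oracle in both modes", {
  set.seed(701)
  for (rep in 1:10) {
    L <- matrix(rnorm(5 * 3), 5, 3)
    expect_equal(fcm_membership(L, 2, "canonical"),
                 oracle_membership_canonical(L, 2), tolerance = 1e-8)
    expect_equal(fcm_membership(L, 2, "literal"),
                 oracle_membership_literal(L, 2), tolerance = 1e-8)
    m <- runif(1, 1.5, 3)
    expect_equal(fcm_membership(L, m, "canonical"),
                 oracle_membership_canonical(L, m), tolerance = 1e-8)
  }
})

test_that("membership is invariant to rigid motions and validates input", {
  set.seed(702)
  L <- matrix(rnorm(12), 6, 2)
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta)), c(sin(theta), cos(theta)))
  moved <- sweep(L %*% R, 2, c(5, -3), "+")
  expect_equal(fcm_membership(moved), fcm_membership(L), tolerance = 1e-9)
  expect_error(fcm_membership(L[1, , drop = FALSE]), "at least 2")
  expect_error(fcm_membership(L, m = 1), "> 1")
  # duplicate points are handled by the epsilon guard
  expect_true(all(is.finite(fcm_membership(rbind(L, L[1, ])))))
})

test_that("view similarity reproduces printed arithmetic and scaling", {
  # two points at squared distance 2, off-diagonal membership 1, V = 2
  L <- rbind(c(0, 0), c(1, 1))
  d2 <- pairwise_sqdist(L)
  expect_equal(d2[1, 2], 2)
  U <- matrix(c(0, 1, 1, 0), 2, 2)
  vs <- view_similarity(U, d2, n_views = 2L)
  expect_equal(vs$S[1, 2], 1)
  expect_equal(vs$objective, 2)  # both off-diagonal entries

  # identical points: zero similarity and objective
  z <- view_similarity(matrix(0.5, 3, 3), matrix(0, 3, 3))
  expect_equal(z$S, matrix(0, 3, 3))
  expect_equal(z$objective, 0)
  # P of a zero S matrix is uniform rows
  expect_equal(z$P, matrix(1 / 3, 3, 3))

  # frozen U: doubling coordinates multiplies d2 (and the objective) by 4
  set.seed(703)
  Lr <- matrix(rnorm(8), 4, 2)
  Ur <- fcm_membership(Lr)
  o1 <- view_similarity(Ur, pairwise_sqdist(Lr))$objective
  o2 <- view_similarity(Ur, pairwise_sqdist(2 * Lr))$objective
  expect_equal(o2 / o1, 4, tolerance = 1e-9)
})

test_that("fused joint is a normalized coupling with consistent marginals", {
  # identity rows: each sample its own cluster -> uniform diagonal joint
  P <- diag(4)
  j <- fuse_joint(P, P)
  expect_equal(j$joint, diag(4) / 4)
  expect_equal(j$row_marginal, rep(1 / 4, 4))
  expect_equal(j$col_marginal, rep(1 / 4, 4))

  set.seed(704)
  for (rep in 1:10) {
    P1 <- matrix(runif(20), 5, 4); P1 <- P1 / rowSums(P1)
    P2 <- matrix(runif(20), 5, 4); P2 <- P2 / rowSums(P2)
    j <- fuse_joint(P1, P2)
    expect_equal(sum(j$joint), 1, tolerance = 1e-12)
    expect_true(all(j$joint >= 0))
    expect_equal(sum(j$row_marginal), 1, tolerance = 1e-12)
    expect_equal(j$joint, oracle_joint(P1, P2), tolerance = 1e-10)
  }
  expect_error(fuse_joint(matrix(0, 2, 2), matrix(0, 2, 2)), "degenerate")
  expect_error(fuse_joint(matrix(-1, 2, 2), matrix(1, 2, 2)), "nonnegative")
})

test_that("fusion loss hits its closed forms", {
  for (n in c(4L, 16L)) {
    for (alpha in c(0, 9)) {
      loss <- info_fusion_loss(diag(n) / n, alpha, "canonical")
      expect_equal(loss, -(2 * alpha + 1) * log(n), tolerance = 1e-9)
    }
  }
  # independent joint at alpha = 0: mutual information is 0
  p <- c(0.1, 0.2, 0.3, 0.4)
  q <- c(0.25, 0.25, 0.4, 0.1)
  expect_equal(info_fusion_loss(outer(p, q), 0, "canonical"), 0,
               tolerance = 1e-12)
})

test_that("both fusion-loss modes match the brute-force oracle", {
  set.seed(705)
  for (rep in 1:10) {
    J <- matrix(runif(16), 4, 4)
    J <- J / sum(J)
    for (alpha in c(0, 2, 9)) {
      expect_equal(info_fusion_loss(J, alpha, "canonical"),
                   oracle_fusion_loss(J, alpha, "canonical"),
                   tolerance = 1e-8)
      expect_equal(info_fusion_loss(J, alpha, "literal"),
                   oracle_fusion_loss(J, alpha, "literal"),
                   tolerance = 1e-8)
    }
  }
})

test_that("a concentrated coupling scores below a uniform one", {
  n <- 8L
  alpha <- 9
  diag_loss <- info_fusion_loss(diag(n) / n, alpha)
  unif_loss <- info_fusion_loss(matrix(1 / n^2, n, n), alpha)
  expect_lt(diag_loss, unif_loss)
})

test_that("zero entries follow the 0 log 0 = 0 convention", {
  J <- rbind(c(0.5, 0), c(0, 0.5))
  expect_true(is.finite(info_fusion_loss(J, 9, "canonical")))
  expect_equal(info_fusion_loss(J, 0, "canonical"),
               -sum(0.5 * log(0.5 / 0.25) * 2), tolerance = 1e-12)
})
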