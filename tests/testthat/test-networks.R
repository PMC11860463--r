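test_that("encoder output satisfies the softmax contract", {
  set.seed(601)
  ae <- init_autoencoder(5L, 4L, hidden = c(8L))
  X <- matrix(rnorm(30), 6, 5)
  Z <- encode_view(ae, X)
  expect_equal(dim(Z), c(6L, 4L))
  expect_equal(rowSums(Z), rep(1, 6))
  expect_true(all(Z > 0 & Z < 1))
  # identical inputs give identical latents; a singleton batch matches
  # its row in a larger batch
  expect_identical(encode_view(ae, X[c(2, 2), ])[1, ],
                   encode_view(ae, X[c(2, 2), ])[2, ])
  expect_equal(encode_view(ae, X[3, , drop = FALSE])[1, ], Z[3, ],
               tolerance = 1e-12)
  expect_error(encode_view(ae, matrix(0, 2, 4)), "expects 5")
})

test_that("decode preserves shapes and validates dimensions", {
  set.seed(602)
  ae <- init_autoencoder(5L, 3L, hidden = c(6L))
  Z <- encode_view(ae, matrix(rnorm(20), 4, 5))
  expect_equal(dim(decode_view(ae, Z)), c(4L, 5L))
  expect_error(decode_view(ae, matrix(0, 2, 4)), "expects 3")
})

test_that("reconstruction loss vanishes for an exact-inverse autoencoder", {
  set.seed(603)
  X <- matrix(rnorm(8), 2, 4)
  ae <- exact_inverse_autoencoder(X, latent_dim = 3L)
  expect_equal(max(abs(decode_view(ae, encode_view(ae, X)) - X)), 0,
               tolerance = 1e-10)
  d <- imvc_dataset(list(X, X))
  loss <- reconstruction_loss(d$views, d$mask, list(ae, ae))
  expect_equal(loss, 0, tolerance = 1e-18)
})

test_that("reconstruction loss matches hand arithmetic and ignores masked rows", {
  set.seed(604)
  # single linear layers, hand-computable
  ae1 <- init_autoencoder(2L, 2L, hidden = integer(0))
  ae2 <- init_autoencoder(2L, 2L, hidden = integer(0))
  X1 <- rbind(c(1, 2), c(3, 4))
  X2 <- rbind(c(0, 1), c(1, 0))
  mask <- rbind(c(1, 1), c(1, 0))
  hand <- function(ae, X) {
    Z <- encode_view(ae, X)
    Xh <- Z %*% ae$decoder[[1]]$W + matrix(ae$decoder[[1]]$b, nrow(X), 2,
                                           byrow = TRUE)
    mean(rowSums((X - Xh)^2))
  }
  expected <- hand(ae1, X1) + hand(ae2, X2[1, , drop = FALSE])
  expect_equal(reconstruction_loss(list(X1, X2), mask, list(ae1, ae2)),
               expected, tolerance = 1e-12)
  # permutation of sample order leaves the loss unchanged
  expect_equal(
    reconstruction_loss(list(X1[2:1, ], X2[2:1, ]), mask[2:1, ],
                        list(ae1, ae2)),
    reconstruction_loss(list(X1, X2), mask, list(ae1, ae2)),
    tolerance = 1e-12)
})

test_that("prediction loss is zero for identity generators on identical latents", {
  L <- matrix(runif(12), 4, 3)
  gens <- list(g12 = linear_generator(diag(3)), g21 = linear_generator(diag(3)))
  res <- prediction_loss(L, L, 1:4, 1:4, gens)
  expect_equal(res$value, 0)
  expect_equal(res$mode, "paired")
})

test_that("cycle mode engages without pairs and vanishes for exact inverses", {
  set.seed(605)
  W <- matrix(rnorm(9), 3, 3) + diag(3)  # invertible
  gens <- list(g12 = linear_generator(W), g21 = linear_generator(solve(W)))
  L1 <- matrix(runif(9), 3, 3)
  L2 <- matrix(runif(6), 2, 3)
  res <- prediction_loss(L1, L2, idx1 = 1:3, idx2 = 4:5, gens)
  expect_equal(res$mode, "cycle")
  expect_equal(res$value, 0, tolerance = 1e-12)
})

test_that("paired prediction loss matches hand-computed arithmetic", {
  g12 <- linear_generator(rbind(c(1, 0), c(0, 2)))
  g21 <- linear_generator(rbind(c(0.5, 0), c(0, 0.5)))
  L1 <- rbind(c(1, 1), c(2, 0))
  L2 <- rbind(c(1, 2), c(2, 1))
  # row 1: G12(l1)=(1,2) -> err 0;     G21(l2)=(.5,1)  -> ||(-.5,0)||^2=.25
  # row 2: G12(l1)=(2,0) -> ||0,-1||^2=1; G21(l2)=(1,.5) -> ||(-1,.5)||^2=1.25
  expected <- mean(c(0, 1)) + mean(c(0.25, 1.25))
  res <- prediction_loss(L1, L2, 1:2, 1:2, list(g12 = g12, g21 = g21))
  expect_equal(res$value, expected, tolerance = 1e-12)
})

test_that("imputation fills exactly the missing latents and touches nothing else", {
  set.seed(606)
  gens <- list(g12 = init_generator(3L, hidden = 4L),
               g21 = init_generator(3L, hidden = 4L))
  L1 <- matrix(runif(15), 5, 3)
  L2 <- matrix(runif(15), 5, 3)
  complete <- impute_missing(list(L1, L2), matrix(1, 5, 2), gens)
  expect_identical(complete, list(L1, L2))

  mask <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, 0), c(0, 1))
  out <- impute_missing(list(L1, L2), mask, gens)
  expect_identical(out[[1]][c(1, 3, 4), ], L1[c(1, 3, 4), ])
  expect_identical(out[[2]][c(2, 3, 5), ], L2[c(2, 3, 5), ])
  # generated rows equal direct generator application, row by row
  expect_equal(out[[2]][1, ],
               drop(generate_latent(gens$g12, L1[1, , drop = FALSE])),
               tolerance = 1e-14)
  expect_equal(out[[1]][2, ],
               drop(generate_latent(gens$g21, L2[2, , drop = FALSE])),
               tolerance = 1e-14)

  # fully incomplete: every sample gains exactly one generated latent
  mask100 <- cbind(rep(c(1, 0), length.out = 5), rep(c(0, 1), length.out = 5))
  out100 <- impute_missing(list(L1, L2), mask100, gens)
  expect_true(all(is.finite(out100[[1]])) && all(is.finite(out100[[2]])))
})
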