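test_that("total loss combines components with the trade-off weights", {
  cfg <- imvc_config(lambda1 = 0.1, lambda2 = 0.01)
  expect_equal(total_loss(1, 2, 3, cfg), 1.23)
  cfg_fcit <- imvc_config(use_rec = FALSE, use_pre = FALSE)
  expect_equal(total_loss(1, 2, 3, cfg_fcit), 1)
  cfg0 <- imvc_config(lambda1 = 0, lambda2 = 0)
  expect_equal(total_loss(5, 100, 100, cfg0), 5)
})

test_that("config validation rejects impossible settings", {
  expect_error(imvc_config(lambda1 = -1), ">= 0")
  expect_error(imvc_config(use_fcit = FALSE, use_rec = FALSE,
                           use_pre = FALSE), "at least one")
  expect_error(imvc_config(fuzziness = 1), "> 1")
})

test_that("loss report is additive and training is seed-reproducible", {
  d <- apply_missing(
    simulate_multiview(synthetic_spec(n_samples = 30L, dims = c(6L, 7L),
                                      seed = 4L)),
    missing_spec(0.3, 5L))
  cfg <- fast_config(epochs = 4L, seed = 9L)
  m1 <- imvc_train(d, cfg)
  m2 <- imvc_train(d, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(fimvc:::flatten_params(m1), fimvc:::flatten_params(m2))
  with(m1$history, expect_equal(total, fcit + cfg$lambda1 * rec +
                                  cfg$lambda2 * pre, tolerance = 1e-10))
  # different seed, different trajectory
  m3 <- imvc_train(d, fast_config(epochs = 4L, seed = 10L))
  expect_false(identical(m1$history, m3$history))
})

test_that("optimisation reduces the total loss on the synthetic benchmark", {
  d <- apply_missing(
    simulate_multiview(synthetic_spec(n_samples = 60L, dims = c(8L, 9L),
                                      separation = 6, seed = 6L)),
    missing_spec(0.3, 7L))
  cfg <- imvc_config(latent_dim = 8L, encoder_hidden = c(24L),
                     generator_hidden = 12L, epochs = 30L, lr = 1e-3,
                     seed = 1L)
  m <- imvc_train(d, cfg)
  expect_lt(m$history$total[30], m$history$total[1])
  expect_true(all(is.finite(as.matrix(m$history[, -1]))))
})

test_that("disabling a loss freezes the parameters only it would train", {
  d <- simulate_multiview(synthetic_spec(n_samples = 20L, dims = c(5L, 6L),
                                         seed = 8L))
  # replay the seeded initialisation to recover the starting parameters
  cfg <- fast_config(epochs = 2L, use_rec = FALSE, seed = 3L)
  rng <- fimvc:::local_rng(cfg$seed)
  init_aes <- list(
    init_autoencoder(5L, cfg$latent_dim, cfg$encoder_hidden),
    init_autoencoder(6L, cfg$latent_dim, cfg$encoder_hidden))
  init_gens <- list(g12 = init_generator(cfg$latent_dim, cfg$generator_hidden),
                    g21 = init_generator(cfg$latent_dim, cfg$generator_hidden))
  rng()

  # without the reconstruction loss, decoders receive no gradient
  m <- imvc_train(d, cfg)
  expect_identical(m$aes[[1]]$decoder, init_aes[[1]]$decoder)
  expect_identical(m$aes[[2]]$decoder, init_aes[[2]]$decoder)
  # encoders did move (fusion loss reaches them)
  expect_false(identical(m$aes[[1]]$encoder, init_aes[[1]]$encoder))

  # reconstruction loss alone reaches neither generator
  cfg2 <- fast_config(epochs = 2L, use_pre = FALSE, use_fcit = FALSE,
                      seed = 3L)
  m2 <- imvc_train(d, cfg2)
  expect_identical(m2$gens, init_gens)
})

test_that("training aborts with a named term on divergence", {
  d <- simulate_multiview(synthetic_spec(n_samples = 20L, dims = c(5L, 6L),
                                         seed = 1L))
  # absurd learning rate overflows the squared errors within a few steps
  cfg <- fast_config(epochs = 10L, seed = 2L)
  cfg$lr <- 1e160
  expect_error(imvc_train(d, cfg), "non-finite")
})

test_that("fused rows of complete samples average the two weighted latents", {
  d <- apply_missing(
    simulate_multiview(synthetic_spec(n_samples = 24L, dims = c(5L, 6L),
                                      seed = 2L)),
    missing_spec(0.25, 3L))
  cfg <- fast_config(epochs = 2L, seed = 4L)
  m <- imvc_train(d, cfg)
  fused <- fused_latents(m, d)
  W <- lapply(1:2, function(v) {
    idx <- which(d$mask[, v] == 1)
    Z <- encode_view(m$aes[[v]], d$views[[v]][idx, , drop = FALSE])
    entropy_weighting(Z, cfg$recon_mode)$W
  })
  for (i in fimvc:::paired_indices(d)[1:3]) {
    l1 <- reconstruct_latents(
      encode_view(m$aes[[1]], d$views[[1]][i, , drop = FALSE]), W[[1]])
    l2 <- reconstruct_latents(
      encode_view(m$aes[[2]], d$views[[2]][i, , drop = FALSE]), W[[2]])
    expect_equal(fused[i, ], drop(l1 + l2) / 2, tolerance = 1e-9)
  }
})

test_that("well-separated complete data cluster perfectly", {
  d <- simulate_multiview(synthetic_spec(n_samples = 60L, dims = c(10L, 12L),
                                         separation = 8, seed = 11L))
  cfg <- imvc_config(latent_dim = 64L, encoder_hidden = c(128L, 64L),
                     generator_hidden = 12L, epochs = 10L, seed = 11L)
  m <- imvc_train(d, cfg)
  res <- assign_clusters(m, d)
  expect_equal(res$metrics$acc, 1)
  # assignment is deterministic given the k-means seed
  res2 <- assign_clusters(m, d)
  expect_identical(res$cluster, res2$cluster)
  expect_error(assign_clusters(m, d, k = 100L), "exceeds")
})

test_that("argmax assignment applies when the latent dimension equals K", {
  d <- simulate_multiview(synthetic_spec(n_samples = 30L, dims = c(6L, 7L),
                                         separation = 8, seed = 12L))
  cfg <- imvc_config(latent_dim = 2L, encoder_hidden = c(12L),
                     generator_hidden = 6L, epochs = 5L, assign = "argmax",
                     seed = 12L)
  m <- imvc_train(d, cfg)
  res <- assign_clusters(m, d)
  expect_setequal(unique(res$cluster), 1:2)
  cfg_bad <- imvc_config(latent_dim = 5L, encoder_hidden = c(12L),
                         generator_hidden = 6L, epochs = 1L,
                         assign = "argmax", seed = 12L)
  m_bad <- imvc_train(d, cfg_bad)
  expect_error(assign_clusters(m_bad, d), "latent_dim == n_clusters")
})
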