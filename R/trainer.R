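#' Training configuration
#'
#' All tunables of the joint objective
#' `L = L_fusion + lambda1 * L_rec + lambda2 * L_pre` and its Adam
#' optimisation schedule. Defaults follow the recommended operating
#' point: trade-offs `lambda1 = 0.1`, `lambda2 = 0.01`, learning rate
#' `1e-4`, batch size 256 (clipped to N), 500 epochs, 2 clusters,
#' fuzziness `m = 2`, entropy-balancing `alpha = 9`. Each loss can be
#' toggled off for ablation; at least one must stay enabled.
#'
#' @param lambda1 weight of the within-view reconstruction loss (>= 0).
#' @param lambda2 weight of the cross-view prediction loss (>= 0).
#' @param lr Adam learning rate.
#' @param batch_size mini-batch size (clipped to the sample count).
#' @param epochs number of passes over the data.
#' @param n_clusters number of clusters K extracted at assignment.
#' @param latent_dim shared latent dimension L of the encoders.
#' @param encoder_hidden encoder hidden widths (decoder mirrors them).
#' @param generator_hidden generator hidden widths.
#' @param fuzziness FCM fuzziness exponent m (> 1).
#' @param alpha entropy-balancing exponent of the fusion loss.
#' @param recon_mode entropy-weighting convention,
#'   `"canonical"`/`"literal"`.
#' @param membership_mode membership convention.
#' @param fcit_mode fusion-loss convention.
#' @param use_fcit,use_rec,use_pre loss toggles.
#' @param assign `"kmeans"` (k-means on fused latents, default) or
#'   `"argmax"` (argmax over the softmax latent; requires
#'   `latent_dim == n_clusters`).
#' @param seed master seed; fans out to parameter init, shuffling and
#'   k-means so one integer reproduces a whole run.
#' @return object of class `imvc_config`.
#' @export
imvc_config <- function(lambda1 = 0.1, lambda2 = 0.01, lr = 1e-4,
                        batch_size = 256L, epochs = 500L, n_clusters = 2L,
                        latent_dim = 128L, encoder_hidden = c(512L, 256L),
                        generator_hidden = 256L, fuzziness = 2, alpha = 9,
                        recon_mode = c("canonical", "literal"),
                        membership_mode = c("canonical", "literal"),
                        fcit_mode = c("canonical", "literal"),
                        use_fcit = TRUE, use_rec = TRUE, use_pre = TRUE,
                        assign = c("kmeans", "argmax"), seed = 1L) {
  if (lambda1 < 0 || lambda2 < 0) {
    stop("lambda1 and lambda2 must be >= 0", call. = FALSE)
  }
  if (!any(use_fcit, use_rec, use_pre)) {
    stop("at least one loss must be enabled", call. = FALSE)
  }
  if (fuzziness <= 1) stop("fuzziness must be > 1", call. = FALSE)
  structure(
    list(lambda1 = lambda1, lambda2 = lambda2, lr = lr,
         batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         n_clusters = as.integer(n_clusters),
         latent_dim = as.integer(latent_dim),
         encoder_hidden = as.integer(encoder_hidden),
         generator_hidden = as.integer(generator_hidden),
         fuzziness = fuzziness, alpha = alpha,
         recon_mode = match.arg(recon_mode),
         membership_mode = match.arg(membership_mode),
         fcit_mode = match.arg(fcit_mode),
         use_fcit = use_fcit, use_rec = use_rec, use_pre = use_pre,
         assign = match.arg(assign), seed = as.integer(seed)),
    class = "imvc_config"
  )
}

#' Combine loss components into the total objective
#'
#' `total = L_fusion + lambda1 * L_rec + lambda2 * L_pre`, with
#' disabled components contributing 0.
#'
#' @param fcit,rec,pre the three loss components.
#' @param config an [imvc_config()].
#' @return scalar total loss.
#' @export
total_loss <- function(fcit, rec, pre, config) {
  (if (config$use_fcit) fcit else 0) +
    config$lambda1 * (if (config$use_rec) rec else 0) +
    config$lambda2 * (if (config$use_pre) pre else 0)
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(state, params, grads, lr) {
  state$t <- state$t + 1L
  b1 <- state$beta1
  b2 <- state$beta2
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  for (i in seq_along(params)) {
    g <- grads[[i]]
    if (is.null(g)) next
    state$m[[i]] <- b1 * state$m[[i]] + (1 - b1) * g
    state$v[[i]] <- b2 * state$v[[i]] + (1 - b2) * g^2
    params[[i]] <- params[[i]] -
      lr * (state$m[[i]] / corr1) / (sqrt(state$v[[i]] / corr2) + state$eps)
  }
  list(state = state, params = params)
}

# Flatten model parameter matrices to one list; `set` writes them back.
flatten_params <- function(model) {
  out <- list()
  push <- function(layers, tag) {
    for (i in seq_along(layers)) {
      out[[sprintf("%s.%d.W", tag, i)]] <<- layers[[i]]$W
      out[[sprintf("%s.%d.b", tag, i)]] <<- layers[[i]]$b
    }
  }
  push(model$aes[[1]]$encoder, "e1")
  push(model$aes[[1]]$decoder, "d1")
  push(model$aes[[2]]$encoder, "e2")
  push(model$aes[[2]]$decoder, "d2")
  push(model$gens$g12$layers, "g12")
  push(model$gens$g21$layers, "g21")
  out
}

unflatten_params <- function(model, flat) {
  pull <- function(layers, tag) {
    for (i in seq_along(layers)) {
      layers[[i]]$W <- flat[[sprintf("%s.%d.W", tag, i)]]
      layers[[i]]$b <- flat[[sprintf("%s.%d.b", tag, i)]]
    }
    layers
  }
  model$aes[[1]]$encoder <- pull(model$aes[[1]]$encoder, "e1")
  model$aes[[1]]$decoder <- pull(model$aes[[1]]$decoder, "d1")
  model$aes[[2]]$encoder <- pull(model$aes[[2]]$encoder, "e2")
  model$aes[[2]]$decoder <- pull(model$aes[[2]]$decoder, "d2")
  model$gens$g12$layers <- pull(model$gens$g12$layers, "g12")
  model$gens$g21$layers <- pull(model$gens$g21$layers, "g21")
  model
}

wrap_flat <- function(tape, flat) lapply(flat, function(p) ad_param(tape, p))

# Build the full training graph for one batch; returns loss nodes.
batch_graph <- function(tape, pnodes, views, mask, batch_idx, config, nlay) {
  n_b <- length(batch_idx)
  avail <- lapply(1:2, function(v) which(mask[batch_idx, v] == 1))
  enc <- list(
    pnodes[seq_len(nlay$e1)],
    pnodes[nlay$e1 + nlay$d1 + seq_len(nlay$e2)]
  )
  dec <- list(
    pnodes[nlay$e1 + seq_len(nlay$d1)],
    pnodes[nlay$e1 + nlay$d1 + nlay$e2 + seq_len(nlay$d2)]
  )
  off <- nlay$e1 + nlay$d1 + nlay$e2 + nlay$d2
  g12 <- pnodes[off + seq_len(nlay$g12)]
  g21 <- pnodes[off + nlay$g12 + seq_len(nlay$g21)]
  # regroup flat nodes back into (W, b) layers
  relayer <- function(nodes) {
    lapply(seq_len(length(nodes) / 2L), function(i) {
      list(W = nodes[[2L * i - 1L]], b = nodes[[2L * i]])
    })
  }
  enc <- lapply(enc, relayer)
  dec <- lapply(dec, relayer)
  g12 <- relayer(g12)
  g21 <- relayer(g21)

  Z <- Xn <- vector("list", 2L)
  rec_terms <- list()
  for (v in 1:2) {
    if (length(avail[[v]]) == 0L) next
    Xv <- views[[v]][batch_idx[avail[[v]]], , drop = FALSE]
    Xn[[v]] <- ad_const(tape, Xv)
    Z[[v]] <- ad_mlp(tape, enc[[v]], Xn[[v]], final = "softmax")
    if (config$use_rec) {
      Xhat <- ad_mlp(tape, dec[[v]], Z[[v]], final = "linear")
      rec_terms[[length(rec_terms) + 1L]] <- ad_mse_rows(tape, Xn[[v]], Xhat)
    }
  }

  # entropy weights: per view, per batch, from available latents (no
  # gradient through the weights themselves)
  Lw <- vector("list", 2L)
  for (v in 1:2) {
    if (is.null(Z[[v]])) next
    W <- entropy_weighting(Z[[v]]$value, config$recon_mode)$W
    Lw[[v]] <- ad_mul_const(tape, Z[[v]],
                            matrix(W, nrow(Z[[v]]$value), length(W),
                                   byrow = TRUE))
  }

  # cross-view prediction loss on paired rows, cycle fallback otherwise
  pre_node <- NULL
  if (config$use_pre) {
    paired <- which(mask[batch_idx, 1] == 1 & mask[batch_idx, 2] == 1)
    if (length(paired) > 0L) {
      p1 <- ad_rows(tape, Lw[[1]], match(paired, avail[[1]]))
      p2 <- ad_rows(tape, Lw[[2]], match(paired, avail[[2]]))
      pre_node <- ad_add(
        tape,
        ad_mse_rows(tape, ad_mlp(tape, g12, p1), p2),
        ad_mse_rows(tape, ad_mlp(tape, g21, p2), p1))
    } else {
      terms <- list()
      only1 <- which(mask[batch_idx, 1] == 1 & mask[batch_idx, 2] == 0)
      only2 <- which(mask[batch_idx, 2] == 1 & mask[batch_idx, 1] == 0)
      if (length(only1) > 0L) {
        s1 <- ad_rows(tape, Lw[[1]], match(only1, avail[[1]]))
        cyc <- ad_mlp(tape, g21, ad_mlp(tape, g12, s1))
        terms[[length(terms) + 1L]] <- ad_mse_rows(tape, cyc, s1)
      }
      if (length(only2) > 0L) {
        s2 <- ad_rows(tape, Lw[[2]], match(only2, avail[[2]]))
        cyc <- ad_mlp(tape, g12, ad_mlp(tape, g21, s2))
        terms[[length(terms) + 1L]] <- ad_mse_rows(tape, cyc, s2)
      }
      if (length(terms) == 2L) pre_node <- ad_add(tape, terms[[1]], terms[[2]])
      else if (length(terms) == 1L) pre_node <- terms[[1]]
    }
  }

  # fusion loss on the completed (imputed) weighted latents
  fcit_node <- NULL
  if (config$use_fcit && n_b >= 2L) {
    Lfull <- vector("list", 2L)
    for (v in 1:2) {
      other <- 3L - v
      gen <- if (v == 2L) g12 else g21
      parts <- list()
      if (length(avail[[v]]) > 0L) {
        parts[[length(parts) + 1L]] <- list(idx = avail[[v]], node = Lw[[v]])
      }
      missing_v <- setdiff(seq_len(n_b), avail[[v]])
      if (length(missing_v) > 0L) {
        src <- ad_rows(tape, Lw[[other]], match(missing_v, avail[[other]]))
        parts[[length(parts) + 1L]] <-
          list(idx = missing_v, node = ad_mlp(tape, gen, src))
      }
      Lfull[[v]] <- if (length(parts) == 1L && length(parts[[1]]$idx) == n_b &&
                        all(parts[[1]]$idx == seq_len(n_b))) {
        parts[[1]]$node
      } else {
        ad_stack_rows(tape, n_b, parts)
      }
    }
    Pv <- vector("list", 2L)
    for (v in 1:2) {
      memb <- ad_fcm_membership(tape, Lfull[[v]], config$fuzziness,
                                config$membership_mode)
      Pv[[v]] <- ad_view_similarity(tape, memb$U, memb$d2, 2L)$P
    }
    fcit_node <- ad_info_fusion_loss(tape, Pv[[1]], Pv[[2]],
                                     config$alpha, config$fcit_mode)
  }

  rec_node <- if (length(rec_terms) == 2L) {
    ad_add(tape, rec_terms[[1]], rec_terms[[2]])
  } else if (length(rec_terms) == 1L) rec_terms[[1]]

  total <- NULL
  add_term <- function(tot, node, w) {
    if (is.null(node) || w == 0) return(tot)
    term <- if (w == 1) node else ad_mul_const(tape, node, w)
    if (is.null(tot)) term else ad_add(tape, tot, term)
  }
  total <- add_term(total, fcit_node, if (config$use_fcit) 1 else 0)
  total <- add_term(total, rec_node, if (config$use_rec) config$lambda1 else 0)
  total <- add_term(total, pre_node, if (config$use_pre) config$lambda2 else 0)
  list(total = total, fcit = fcit_node, rec = rec_node, pre = pre_node)
}

#' Train the incomplete multi-view clustering model
#'
#' Runs the joint optimisation: per epoch the samples are shuffled into
#' mini-batches, and for each batch the available views are encoded,
#' latents are entropy-reweighted, missing latents are imputed with the
#' cross-view generators, and the enabled losses (reconstruction,
#' cross-view prediction with paired/cycle selection, information
#' fusion) are combined into the total objective and stepped with Adam.
#' Deterministic given `config$seed`.
#'
#' @param dataset an [imvc_dataset()].
#' @param config an [imvc_config()].
#' @return object of class `imvc_model`: the trained networks, the
#'   config, and `history`, a data.frame of per-epoch mean loss
#'   components (`fcit`, `rec`, `pre`, `total`).
#' @examples
#' \donttest{
#' d <- simulate_multiview(synthetic_spec(n_samples = 60, seed = 2))
#' m <- imvc_train(d, imvc_config(epochs = 5, latent_dim = 8,
#'                                encoder_hidden = c(32, 16)))
#' tail(m$history, 1)
#' }
#' @export
imvc_train <- function(dataset, config = imvc_config()) {
  stopifnot(inherits(dataset, "imvc_dataset"))
  stopifnot(inherits(config, "imvc_config"))
  rng <- local_rng(config$seed)
  on.exit(rng(), add = TRUE)

  n <- dataset$n_samples
  batch <- min(config$batch_size, n)
  aes <- list(
    init_autoencoder(ncol(dataset$views[[1]]), config$latent_dim,
                     config$encoder_hidden),
    init_autoencoder(ncol(dataset$views[[2]]), config$latent_dim,
                     config$encoder_hidden)
  )
  gens <- list(g12 = init_generator(config$latent_dim, config$generator_hidden),
               g21 = init_generator(config$latent_dim, config$generator_hidden))
  model <- list(aes = aes, gens = gens, config = config)
  flat <- flatten_params(model)
  nlay <- list(e1 = 2L * length(aes[[1]]$encoder),
               d1 = 2L * length(aes[[1]]$decoder),
               e2 = 2L * length(aes[[2]]$encoder),
               d2 = 2L * length(aes[[2]]$decoder),
               g12 = 2L * length(gens$g12$layers),
               g21 = 2L * length(gens$g21$layers))
  opt <- adam_init(flat)

  history <- data.frame(epoch = seq_len(config$epochs),
                        fcit = NA_real_, rec = NA_real_, pre = NA_real_,
                        total = NA_real_)
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = batch)
    comp <- c(fcit = 0, rec = 0, pre = 0, total = 0)
    nb <- 0L
    for (s in starts) {
      batch_idx <- perm[s:min(s + batch - 1L, n)]
      if (length(batch_idx) < 2L) next
      tape <- new_tape()
      pnodes <- wrap_flat(tape, flat)
      losses <- batch_graph(tape, pnodes, dataset$views, dataset$mask,
                            batch_idx, config, nlay)
      if (is.null(losses$total)) next
      val <- function(x) if (is.null(x)) 0 else x$value[1L]
      for (nm in c("fcit", "rec", "pre", "total")) {
        if (!is.finite(val(losses[[nm]]))) {
          stop(sprintf("training diverged at epoch %d: non-finite %s loss",
                       epoch, nm), call. = FALSE)
        }
      }
      ad_backward(tape, losses$total)
      grads <- lapply(pnodes, function(p) p$grad)
      step <- adam_step(opt, flat, grads, config$lr)
      opt <- step$state
      flat <- step$params
      comp <- comp + c(val(losses$fcit), val(losses$rec), val(losses$pre),
                       val(losses$total))
      nb <- nb + 1L
    }
    history[epoch, c("fcit", "rec", "pre", "total")] <- comp / max(nb, 1L)
  }
  model <- unflatten_params(model, flat)
  model$history <- history
  class(model) <- "imvc_model"
  model
}

#' @export
print.imvc_model <- function(x, ...) {
  cat(sprintf("imvc_model: latent dim %d, %d epochs trained\n",
              x$config$latent_dim, nrow(x$history)))
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  final losses: fusion %.4g, recon %.4g, pred %.4g, total %.4g\n",
              last$fcit, last$rec, last$pre, last$total))
  invisible(x)
}

#' Fused latent representation of a dataset
#'
#' Encodes every available view, entropy-reweights the latents (weights
#' computed per view over all available rows), imputes missing latents
#' with the generators, and averages the two completed weighted latent
#' matrices row-wise.
#'
#' @param model an `imvc_model`.
#' @param dataset an [imvc_dataset()] with matching feature dims.
#' @return N x latent_dim fused matrix.
#' @export
fused_latents <- function(model, dataset) {
  stopifnot(inherits(model, "imvc_model"), inherits(dataset, "imvc_dataset"))
  n <- dataset$n_samples
  latents <- vector("list", 2L)
  for (v in 1:2) {
    idx <- which(dataset$mask[, v] == 1)
    Z <- matrix(0, n, model$config$latent_dim)
    if (length(idx) > 0L) {
      Zv <- encode_view(model$aes[[v]],
                        dataset$views[[v]][idx, , drop = FALSE])
      W <- entropy_weighting(Zv, model$config$recon_mode)$W
      Z[idx, ] <- reconstruct_latents(Zv, W)
    }
    latents[[v]] <- Z
  }
  completed <- impute_missing(latents, dataset$mask, model$gens)
  (completed[[1]] + completed[[2]]) / 2
}

#' Extract hard cluster assignments
#'
#' Computes the fused latent matrix and assigns clusters, by default
#' with seeded k-means (10 restarts); `assign = "argmax"` instead takes
#' the argmax latent coordinate (requires
#' `latent_dim == n_clusters`). If the dataset carries labels, ACC, NMI
#' and ARI are attached.
#'
#' @param model an `imvc_model`.
#' @param dataset an [imvc_dataset()].
#' @param k number of clusters (default from the config).
#' @param seed k-means seed (default derived from the config seed).
#' @return object of class `imvc_clustering`: `cluster` (integer
#'   labels), `fused` (the fused latents), and `metrics` (list of acc,
#'   nmi, ari, or NULL without labels).
#' @export
assign_clusters <- function(model, dataset, k = NULL, seed = NULL) {
  stopifnot(inherits(model, "imvc_model"))
  if (is.null(k)) k <- model$config$n_clusters
  if (is.null(seed)) seed <- model$config$seed + 1L
  if (k > dataset$n_samples) {
    stop(sprintf("k = %d exceeds the %d samples", k, dataset$n_samples),
         call. = FALSE)
  }
  fused <- fused_latents(model, dataset)
  if (model$config$assign == "argmax") {
    if (ncol(fused) != k) {
      stop("argmax assignment requires latent_dim == n_clusters",
           call. = FALSE)
    }
    cl <- max.col(fused, ties.method = "first")
  } else {
    rng <- local_rng(seed)
    on.exit(rng(), add = TRUE)
    cl <- stats::kmeans(fused, centers = k, nstart = 10L,
                        iter.max = 100L)$cluster
  }
  metrics <- if (!is.null(dataset$labels)) {
    clustering_metrics(cl, dataset$labels)
  }
  structure(list(cluster = cl, fused = fused, metrics = metrics, k = k),
            class = "imvc_clustering")
}

#' @export
print.imvc_clustering <- function(x, ...) {
  cat(sprintf("imvc_clustering: %d samples in %d clusters\n",
              length(x$cluster), x$k))
  if (!is.null(x$metrics)) {
    cat(sprintf("  ACC %.3f | NMI %.3f | ARI %.3f\n",
                x$metrics$acc, x$metrics$nmi, x$metrics$ari))
  }
  invisible(x)
}
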