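#' @name clustering-metrics
#' @title Clustering evaluation metrics
#'
#' @description
#' Three external validity indices against reference labels, all
#' invariant to relabelling of either partition: clustering accuracy
#' (fraction of agreements under the optimal one-to-one cluster/class
#' matching, solved as an assignment problem), normalised mutual
#' information (normalised by the arithmetic mean of the two partition
#' entropies), and the adjusted Rand index (pair-counting, chance
#' corrected).
NULL

# Hungarian algorithm (shortest augmenting path with potentials) for a
# square cost matrix; returns the column assigned to each row.
# O(n^3); minimises total cost.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)      # p[j]: row matched to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L                # columns are 1-indexed with a virtual col 1
    minv <- rep(INF, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- INF
      j1 <- 0L
      for (j in 2L:(n + 1L)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0 + 0L] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in 1L:(n + 1L)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  match_of_row <- integer(n)
  for (j in 2L:(n + 1L)) if (p[j] > 0L) match_of_row[p[j]] <- j - 1L
  match_of_row
}

# Contingency table on the union of observed labels, padded square.
contingency_square <- function(pred, truth) {
  pl <- sort(unique(pred))
  tl <- sort(unique(truth))
  k <- max(length(pl), length(tl))
  tab <- matrix(0, k, k)
  tab[seq_along(pl), seq_along(tl)] <-
    as.matrix(table(factor(pred, pl), factor(truth, tl)))
  tab
}

#' Clustering accuracy under optimal label matching
#'
#' @param pred integer vector of predicted cluster labels.
#' @param truth integer vector of reference class labels (same length).
#' @return fraction of samples on the optimally matched diagonal, in
#'   \[0, 1\].
#' @rdname clustering-metrics
#' @export
clustering_accuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop(sprintf("label lengths differ: %d vs %d", length(pred),
                 length(truth)), call. = FALSE)
  }
  tab <- contingency_square(pred, truth)
  # maximise agreements = minimise negated counts; ties resolve to the
  # lowest-index matching by the algorithm's scan order
  assign_cols <- solve_assignment(-tab)
  sum(tab[cbind(seq_len(nrow(tab)), assign_cols)]) / length(pred)
}

partition_entropy <- function(x) {
  p <- as.numeric(table(x)) / length(x)
  -sum(ifelse(p > 0, p * log(p), 0))
}

#' Normalised mutual information of two partitions
#'
#' Mutual information normalised by the arithmetic mean of the two
#' partition entropies. When both partitions are single-cluster the
#' normaliser is 0; NMI is then defined as 0 with a warning.
#'
#' @rdname clustering-metrics
#' @export
clustering_nmi <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop(sprintf("label lengths differ: %d vs %d", length(pred),
                 length(truth)), call. = FALSE)
  }
  n <- length(pred)
  tab <- table(pred, truth)
  pj <- rowSums(tab) / n
  qk <- colSums(tab) / n
  pjk <- tab / n
  mi <- 0
  for (j in seq_along(pj)) {
    for (k in seq_along(qk)) {
      if (pjk[j, k] > 0) {
        mi <- mi + pjk[j, k] * log(pjk[j, k] / (pj[j] * qk[k]))
      }
    }
  }
  hp <- partition_entropy(pred)
  ht <- partition_entropy(truth)
  norm <- (hp + ht) / 2
  if (norm == 0) {
    warning("both partitions are single-cluster; NMI defined as 0")
    return(0)
  }
  max(0, min(1, mi / norm))
}

#' Adjusted Rand index
#'
#' Pair-counting Rand index corrected for chance:
#' `(Index - Expected) / (Max - Expected)`. 1 for identical partitions,
#' about 0 for independent ones, negative for worse-than-chance.
#'
#' @rdname clustering-metrics
#' @export
clustering_ari <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop(sprintf("label lengths differ: %d vs %d", length(pred),
                 length(truth)), call. = FALSE)
  }
  n <- length(pred)
  tab <- table(pred, truth)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  a <- sum(choose2(rowSums(tab)))
  b <- sum(choose2(colSums(tab)))
  total <- choose2(n)
  expected <- a * b / total
  maximum <- (a + b) / 2
  if (maximum == expected) {
    warning("degenerate partitions (ARI denominator 0); ARI defined as 0")
    return(0)
  }
  (sum_ij - expected) / (maximum - expected)
}

#' All three metrics at once
#'
#' @return named list `acc`, `nmi`, `ari`.
#' @rdname clustering-metrics
#' @export
clustering_metrics <- function(pred, truth) {
  list(acc = clustering_accuracy(pred, truth),
       nmi = clustering_nmi(pred, truth),
       ari = clustering_ari(pred, truth))
}

#' Missing-rate sweep on a synthetic benchmark
#'
#' Draws one complete dataset per seed, masks it at each requested
#' missing rate, trains the full model, and evaluates ACC/NMI/ARI
#' against the generator's labels. Returns per-run rows and a per-rate
#' mean/sd summary.
#'
#' @param spec a [synthetic_spec()]; the seed field is overridden per
#'   run by `seeds`.
#' @param rates numeric vector of missing rates.
#' @param config an [imvc_config()] (its seed is also overridden).
#' @param seeds integer vector of run seeds.
#' @param verbose print one line per run.
#' @return list with data.frames `runs` (rate, seed, acc, nmi, ari) and
#'   `summary` (rate, mean/sd of each metric, n).
#' @export
sweep_missing_rates <- function(spec, rates, config, seeds = 1:5,
                                verbose = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  runs <- list()
  for (seed in seeds) {
    sp <- spec
    sp$seed <- as.integer(seed)
    datasets <- make_benchmark(sp, rates)
    for (i in seq_along(rates)) {
      cfg <- config
      cfg$seed <- as.integer(seed)
      model <- imvc_train(datasets[[i]], cfg)
      res <- assign_clusters(model, datasets[[i]])
      runs[[length(runs) + 1L]] <- data.frame(
        rate = rates[i], seed = seed,
        acc = res$metrics$acc, nmi = res$metrics$nmi, ari = res$metrics$ari)
      if (verbose) {
        message(sprintf("rate %.2f seed %d: ACC %.3f NMI %.3f ARI %.3f",
                        rates[i], seed, res$metrics$acc, res$metrics$nmi,
                        res$metrics$ari))
      }
    }
  }
  runs <- do.call(rbind, runs)
  summary <- do.call(rbind, lapply(split(runs, runs$rate), function(d) {
    data.frame(rate = d$rate[1L],
               acc_mean = mean(d$acc), acc_sd = stats::sd(d$acc),
               nmi_mean = mean(d$nmi), nmi_sd = stats::sd(d$nmi),
               ari_mean = mean(d$ari), ari_sd = stats::sd(d$ari),
               n = nrow(d))
  }))
  rownames(summary) <- NULL
  list(runs = runs, summary = summary)
}

# The seven non-empty subsets of the three losses, full objective last.
ablation_grid <- function() {
  data.frame(
    use_fcit = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE),
    use_rec  = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE),
    use_pre  = c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE)
  )
}

#' Loss-ablation harness
#'
#' Trains every non-empty subset of the three loss terms (fusion,
#' reconstruction, prediction) on the same masked dataset(s) and
#' reports ACC/NMI/ARI per configuration, averaged over `seeds`. Rows
#' follow the conventional ordering: each loss alone, the three pairs
#' (fusion+reconstruction, fusion+prediction,
#' reconstruction+prediction), then the full objective.
#'
#' @param spec a [synthetic_spec()].
#' @param rate missing rate applied before training.
#' @param config an [imvc_config()]; the loss toggles and seed are
#'   overridden per row/run.
#' @param seeds integer vector of run seeds.
#' @return data.frame with the toggle columns and mean acc/nmi/ari.
#' @export
ablate_losses <- function(spec, rate, config, seeds = 1L, verbose = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  grid <- ablation_grid()
  out <- grid
  out$acc <- out$nmi <- out$ari <- NA_real_
  for (g in seq_len(nrow(grid))) {
    accs <- nmis <- aris <- numeric(length(seeds))
    for (s in seq_along(seeds)) {
      sp <- spec
      sp$seed <- as.integer(seeds[s])
      data <- apply_missing(simulate_multiview(sp),
                            missing_spec(rate, mask_seed(sp$seed, rate)))
      cfg <- config
      cfg$seed <- as.integer(seeds[s])
      cfg$use_fcit <- grid$use_fcit[g]
      cfg$use_rec <- grid$use_rec[g]
      cfg$use_pre <- grid$use_pre[g]
      model <- imvc_train(data, cfg)
      res <- assign_clusters(model, data)
      accs[s] <- res$metrics$acc
      nmis[s] <- res$metrics$nmi
      aris[s] <- res$metrics$ari
    }
    out$acc[g] <- mean(accs)
    out$nmi[g] <- mean(nmis)
    out$ari[g] <- mean(aris)
    if (verbose) {
      message(sprintf("fcit=%d rec=%d pre=%d: ACC %.3f",
                      grid$use_fcit[g], grid$use_rec[g], grid$use_pre[g],
                      out$acc[g]))
    }
  }
  out
}
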