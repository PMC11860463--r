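#' Specification for a synthetic two-view clustered dataset
#'
#' Describes a seeded generative model that emulates the structure of a
#' two-phase imaging cohort: `n_samples` patients fall into `n_clusters`
#' latent classes, and each patient contributes two feature views that
#' are noisy, view-specific linear images of one shared class-dependent
#' signal. The two views therefore carry consistent cluster information
#' (what a multiview method exploits) while remaining conditionally
#' independent given the signal (each view adds its own noise).
#'
#' The class centroids sit at the vertices of a scaled simplex in a
#' `n_clusters`-dimensional signal space; each view's linear map has
#' orthonormal rows, so centroid distances survive into view space
#' unchanged. `separation` is the distance between any two class
#' centroids measured in units of the within-cluster standard deviation
#' (`view_noise`): separation 0 makes the classes exchangeable, and
#' large values make them trivially separable.
#'
#' @param n_samples number of samples N.
#' @param n_clusters number of latent classes K (default 2, a binary
#'   prognostic grouping).
#' @param dims integer pair: feature dimensions of the two views.
#' @param separation centroid distance in units of within-cluster
#'   standard deviation; must be positive (use values near 0 for
#'   chance-level controls).
#' @param view_noise per-view additive Gaussian noise sd.
#' @param seed integer; generation is bit-reproducible given the seed.
#' @param balance if `TRUE` (default) classes are balanced within one
#'   sample; otherwise a vector of K class proportions.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 200L, n_clusters = 2L,
                           dims = c(20L, 24L), separation = 6,
                           view_noise = 1, seed = 1L, balance = TRUE) {
  n_samples <- as.integer(n_samples)
  n_clusters <- as.integer(n_clusters)
  if (n_clusters < 2L) stop("need at least 2 clusters", call. = FALSE)
  if (n_samples < n_clusters) {
    stop(sprintf("n_samples (%d) must be >= n_clusters (%d)",
                 n_samples, n_clusters), call. = FALSE)
  }
  if (!is.numeric(separation) || separation < 0) {
    stop("separation must be >= 0", call. = FALSE)
  }
  if (view_noise <= 0) stop("view_noise must be positive", call. = FALSE)
  stopifnot(length(dims) == 2L, all(dims >= n_clusters))
  structure(
    list(n_samples = n_samples, n_clusters = n_clusters,
         dims = as.integer(dims), separation = separation,
         view_noise = view_noise, seed = as.integer(seed),
         balance = balance),
    class = "synthetic_spec"
  )
}

# Random K x D matrix with orthonormal rows (distance-preserving map).
orthonormal_rows <- function(k, d) {
  q <- qr.Q(qr(matrix(stats::rnorm(d * k), d, k)))
  t(q[, seq_len(k), drop = FALSE])
}

#' Generate a complete two-view dataset from a synthetic specification
#'
#' Draws class labels, places class centroids `separation * view_noise`
#' apart in the shared signal space, maps the per-sample signal into
#' each view through a seeded orthonormal linear map, and adds
#' spherical Gaussian noise of sd `view_noise` per view. The returned
#' dataset is complete (mask all ones) and carries the labels.
#'
#' @param spec a [synthetic_spec()].
#' @return An [imvc_dataset()] with `n_samples` rows per view.
#' @examples
#' d <- simulate_multiview(synthetic_spec(n_samples = 40, seed = 3))
#' table(d$labels)
#' @export
simulate_multiview <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rng <- local_rng(spec$seed)
  on.exit(rng(), add = TRUE)
  n <- spec$n_samples
  k <- spec$n_clusters

  labels <- if (isTRUE(spec$balance)) {
    sample(rep_len(seq_len(k), n))
  } else {
    sample(seq_len(k), n, replace = TRUE, prob = spec$balance)
  }

  # simplex vertices e_k are sqrt(2) apart; rescale to the requested
  # centroid distance in noise units
  centroids <- diag(k) * spec$separation * spec$view_noise / sqrt(2)
  signal <- centroids[labels, , drop = FALSE]

  views <- vector("list", 2L)
  for (v in 1:2) {
    d <- spec$dims[v]
    A <- orthonormal_rows(k, d)
    noise <- matrix(stats::rnorm(n * d, sd = spec$view_noise), n, d)
    views[[v]] <- signal %*% A + noise
  }
  imvc_dataset(views, labels = labels)
}

#' Build a missing-rate benchmark from one synthetic draw
#'
#' Generates a single complete dataset and returns one masked copy per
#' requested missing rate. All copies share identical features and
#' labels and differ only in the availability mask; each mask is seeded
#' deterministically from the spec seed and the rate, so the benchmark
#' is bit-reproducible.
#'
#' @param spec a [synthetic_spec()].
#' @param rates numeric vector of missing rates in \[0, 1\].
#' @return A named list of [imvc_dataset()]s (names like `"rate_0.3"`),
#'   in the order of `rates`.
#' @export
make_benchmark <- function(spec, rates) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (length(rates) == 0L) return(list())
  if (any(rates < 0 | rates > 1)) {
    stop("all rates must be in [0, 1]", call. = FALSE)
  }
  complete <- simulate_multiview(spec)
  out <- lapply(rates, function(r) {
    apply_missing(complete, missing_spec(r, seed = mask_seed(spec$seed, r)))
  })
  names(out) <- sprintf("rate_%g", rates)
  out
}

# Deterministic per-rate mask seed, kept within 32-bit integer range.
mask_seed <- function(seed, rate) {
  (as.integer(seed) %% 1000000L) * 1009L + as.integer(round(rate * 1000))
}
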