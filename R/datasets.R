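#' Incomplete two-view dataset
#'
#' Container for a two-view dataset with a per-sample view-availability
#' mask. Row `i` of every view describes sample `i`; a mask entry of 1
#' means the view was observed for that sample. Masked-out rows are
#' stored as zeros on disk but are semantically undefined: every
#' consumer in this package selects rows by the mask and never reads a
#' masked entry.
#'
#' @param views list of two numeric matrices (samples x features); the
#'   two views may have different feature dimensions but must share the
#'   number of rows.
#' @param mask N x 2 binary matrix (1 = view available). Defaults to all
#'   ones (complete data).
#' @param labels optional length-N integer class vector (ground truth
#'   for evaluation only; never used in training).
#' @return An object of class `imvc_dataset` with elements `views`,
#'   `mask`, `labels`, `n_samples`, `n_views`.
#' @examples
#' d <- imvc_dataset(list(matrix(rnorm(12), 4), matrix(rnorm(8), 4)))
#' d$n_samples
#' @export
imvc_dataset <- function(views, mask = NULL, labels = NULL) {
  if (!is.list(views) || length(views) != 2L) {
    stop("`views` must be a list of exactly two matrices (two-view method)",
         call. = FALSE)
  }
  views <- lapply(views, function(v) {
    v <- as.matrix(v)
    storage.mode(v) <- "double"
    v
  })
  n <- nrow(views[[1L]])
  if (nrow(views[[2L]]) != n) {
    stop(sprintf("view row counts disagree: %d vs %d", n, nrow(views[[2L]])),
         call. = FALSE)
  }
  if (is.null(mask)) mask <- matrix(1, n, 2L)
  mask <- as.matrix(mask)
  storage.mode(mask) <- "double"
  if (nrow(mask) != n || ncol(mask) != 2L) {
    stop(sprintf("mask must be %d x 2, got %d x %d", n, nrow(mask), ncol(mask)),
         call. = FALSE)
  }
  if (!all(mask %in% c(0, 1))) {
    stop("mask entries must be 0 or 1", call. = FALSE)
  }
  empty <- which(rowSums(mask) == 0)
  if (length(empty) > 0L) {
    stop(sprintf("sample %d has no available view (mask row of all zeros)",
                 empty[1L]), call. = FALSE)
  }
  for (v in 1:2) {
    avail <- views[[v]][mask[, v] == 1, , drop = FALSE]
    if (any(!is.finite(avail))) {
      stop(sprintf("view %d contains NaN/Inf in available rows", v),
           call. = FALSE)
    }
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != n) {
      stop(sprintf("labels length %d does not match %d samples",
                   length(labels), n), call. = FALSE)
    }
  }
  structure(
    list(views = views, mask = mask, labels = labels,
         n_samples = n, n_views = 2L),
    class = "imvc_dataset"
  )
}

#' @export
print.imvc_dataset <- function(x, ...) {
  cat(sprintf("imvc_dataset: %d samples, 2 views (%d, %d features)\n",
              x$n_samples, ncol(x$views[[1L]]), ncol(x$views[[2L]])))
  paired <- sum(rowSums(x$mask) == 2)
  cat(sprintf("  paired samples: %d; view-1 only: %d; view-2 only: %d\n",
              paired, sum(x$mask[, 1] == 1) - paired,
              sum(x$mask[, 2] == 1) - paired))
  cat(sprintf("  labels: %s\n",
              if (is.null(x$labels)) "absent" else
                paste0(length(unique(x$labels)), " classes")))
  invisible(x)
}

read_matrix_csv <- function(file) {
  x <- as.matrix(utils::read.csv(file, header = FALSE))
  dimnames(x) <- NULL
  storage.mode(x) <- "double"
  x
}

write_matrix_csv <- function(x, file) {
  # %.17g round-trips IEEE doubles exactly
  lines <- apply(x, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(lines, file)
}

#' Load a two-view dataset from a directory
#'
#' Reads the comma-delimited, headerless layout `view1.csv`,
#' `view2.csv`, `mask.csv` and (if present) `labels.csv` and validates
#' the result: all row counts must agree, mask entries must be 0/1, and
#' every sample must have at least one available view.
#'
#' @param path directory containing the files.
#' @return An [imvc_dataset()].
#' @seealso [save_dataset()]
#' @export
load_dataset <- function(path) {
  need <- file.path(path, c("view1.csv", "view2.csv", "mask.csv"))
  missing_files <- need[!file.exists(need)]
  if (length(missing_files) > 0L) {
    stop("missing dataset file(s): ", paste(missing_files, collapse = ", "),
         call. = FALSE)
  }
  views <- list(read_matrix_csv(need[1L]), read_matrix_csv(need[2L]))
  mask <- read_matrix_csv(need[3L])
  labels_file <- file.path(path, "labels.csv")
  labels <- if (file.exists(labels_file)) {
    drop(read_matrix_csv(labels_file))
  }
  if (nrow(mask) != nrow(views[[1L]])) {
    stop(sprintf("mask has %d rows but views have %d", nrow(mask),
                 nrow(views[[1L]])), call. = FALSE)
  }
  imvc_dataset(views, mask, labels)
}

#' Save a two-view dataset to a directory
#'
#' Writes the layout read by [load_dataset()]. Feature values are
#' written with 17 significant digits so that save/load round-trips
#' bit-exactly. Masked-out rows are written as zeros (placeholders,
#' never read back as data).
#'
#' @param dataset an [imvc_dataset()].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
save_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "imvc_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (v in 1:2) {
    x <- dataset$views[[v]]
    x[dataset$mask[, v] == 0, ] <- 0  # placeholder, semantically undefined
    write_matrix_csv(x, file.path(path, sprintf("view%d.csv", v)))
  }
  write_matrix_csv(dataset$mask, file.path(path, "mask.csv"))
  if (!is.null(dataset$labels)) {
    writeLines(as.character(dataset$labels), file.path(path, "labels.csv"))
  }
  invisible(path)
}

#' Missing-view masking specification
#'
#' Describes how a complete two-view dataset is degraded to an
#' incomplete one: a fraction `rate` of the samples lose exactly one
#' view, the lost view chosen uniformly at random per sample. At
#' `rate = 1` every sample retains exactly one view (the fully
#' incomplete regime); at `rate = 0` the data stay complete.
#'
#' @param rate fraction of samples to degrade, in \[0, 1\].
#' @param seed integer seed; masking is bit-reproducible given the seed.
#' @return An object of class `missing_spec`.
#' @export
missing_spec <- function(rate, seed = 1L) {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) ||
      rate < 0 || rate > 1) {
    stop("missing rate must be a single number in [0, 1]", call. = FALSE)
  }
  structure(list(rate = rate, seed = as.integer(seed),
                 scheme = "one-view-per-missing-sample"),
            class = "missing_spec")
}

#' Mask one view for a fraction of samples
#'
#' Applies a [missing_spec()] to a complete dataset: exactly
#' `round(rate * N)` samples are chosen without replacement and each
#' loses one view, picked uniformly. Deterministic given the spec's
#' seed; the features themselves are untouched.
#'
#' @param dataset a complete [imvc_dataset()] (all mask entries 1).
#' @param spec a [missing_spec()], or a bare rate (seed then defaults
#'   to 1).
#' @return A new `imvc_dataset` with the degraded mask.
#' @export
apply_missing <- function(dataset, spec) {
  stopifnot(inherits(dataset, "imvc_dataset"))
  if (is.numeric(spec)) spec <- missing_spec(spec)
  stopifnot(inherits(spec, "missing_spec"))
  if (!all(dataset$mask == 1)) {
    stop("apply_missing requires a complete dataset (all mask entries 1)",
         call. = FALSE)
  }
  n <- dataset$n_samples
  n_miss <- round(spec$rate * n)
  mask <- matrix(1, n, 2L)
  if (n_miss > 0L) {
    rng <- local_rng(spec$seed)
    on.exit(rng(), add = TRUE)
    hit <- sample.int(n, n_miss)
    lost_view <- sample(1:2, n_miss, replace = TRUE)
    mask[cbind(hit, lost_view)] <- 0
  }
  imvc_dataset(dataset$views, mask, dataset$labels)
}

# Seed the RNG locally; returns a restorer for on.exit().
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

# Rows with both views present.
paired_indices <- function(dataset) {
  which(rowSums(dataset$mask) == 2)
}
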