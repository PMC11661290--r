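#' Fit a methylome atlas embedding
#'
#' Compresses a complete beta-value matrix into `n_dims` coordinates (2 for
#' visualization, 5 for downstream classification) with a pairwise-controlled
#' manifold approximation: matrices wider than 100 probes are first reduced to
#' 100 principal components, near/mid-near/further point pairs are built from
#' locally scaled distances, and coordinates are optimized by Adam through the
#' algorithm's three weighting phases. The fit is deterministic for a given
#' seed.
#'
#' @param beta Samples x probes beta matrix, no missing values (run
#'   [qc_pipeline()] first), at least ~20 samples.
#' @param n_dims Embedding dimensionality (2 or 5 in the atlas workflow).
#' @param seed Integer seed controlling pair sampling.
#' @param n_neighbors Near-pair count per sample.
#' @param mn_ratio,fp_ratio Mid-near and further pair counts as multiples of
#'   `n_neighbors` (algorithm defaults 0.5 and 2).
#' @param n_iters Length-3 integer vector of optimization iterations per phase.
#' @return An object of class `atlas_embedding` with elements `coords`
#'   (samples x n_dims), `probe_ids`, the PCA basis used for preprocessing,
#'   the retained training matrix in that basis, and fitting metadata
#'   (`transform_method = "knn_weighted_average"` records how unseen samples
#'   are projected).
#' @seealso [project_samples()]
#' @examples
#' cohort <- generate_cohort(cohort_config(n_samples = 60, n_probes = 200,
#'                                         missing_rate = 0, seed = 2))
#' atlas <- fit_embedding(cohort$beta, n_dims = 2, seed = 11)
#' dim(atlas$coords)
#' @export
fit_embedding <- function(beta, n_dims = 5, seed = 42, n_neighbors = 10,
                          mn_ratio = 0.5, fp_ratio = 2,
                          n_iters = c(100, 100, 250)) {
  .check_beta(beta, allow_missing = FALSE)
  .assert(n_dims >= 2, "n_dims must be at least 2")
  n <- nrow(beta)
  .assert(n >= n_neighbors + 2,
          "need at least n_neighbors + 2 = %d samples", n_neighbors + 2)
  set.seed(seed)

  center <- colMeans(beta)
  x <- sweep(beta, 2, center)
  rotation <- NULL
  if (ncol(x) > 100) {
    pc <- stats::prcomp(x, center = FALSE, rank. = min(100, n - 1))
    rotation <- pc$rotation
    x <- pc$x
  }

  pairs <- .pacmap_pairs(x, n_neighbors, mn_ratio, fp_ratio)
  init <- stats::prcomp(x, center = FALSE, rank. = n_dims)$x
  if (ncol(init) < n_dims) {   # degenerate rank; pad with tiny noise
    init <- cbind(init, matrix(stats::rnorm(n * (n_dims - ncol(init)), 0, 1e-4),
                               n))
  }
  y <- .pacmap_optimize(init * 0.01, pairs, n_iters = n_iters)
  dimnames(y) <- list(rownames(beta), paste0("dim", seq_len(n_dims)))

  structure(list(coords = y, probe_ids = colnames(beta), center = center,
                 rotation = rotation, train_x = x, n_dims = n_dims,
                 seed = seed,
                 params = list(n_neighbors = n_neighbors, mn_ratio = mn_ratio,
                               fp_ratio = fp_ratio, n_iters = n_iters),
                 transform_method = "knn_weighted_average",
                 transform_k = 10),
            class = "atlas_embedding")
}

#' Project unseen samples into a fitted atlas
#'
#' Maps new beta profiles onto the fixed training embedding without refitting:
#' each new sample is placed at the inverse-distance-weighted average of the
#' coordinates of its `k` nearest training samples in the (PCA-reduced)
#' high-dimensional space — the out-of-sample rule recorded in the model's
#' `transform_method`. A training sample projects exactly onto its own
#' coordinate.
#'
#' Probes must match the training probe set; columns given in a different
#' order are reordered by probe id before projection.
#'
#' @param model An [fit_embedding()] result.
#' @param new_beta Samples x probes beta matrix over the training probe set.
#' @return Matrix of coordinates, `nrow(new_beta)` x `n_dims`.
#' @export
project_samples <- function(model, new_beta) {
  .assert(inherits(model, "atlas_embedding"), "model must be an atlas_embedding")
  if (is.null(dim(new_beta))) {
    new_beta <- matrix(new_beta, 1, dimnames = list("sample", names(new_beta)))
  }
  .assert(!anyNA(new_beta), "new samples contain missing values; impute first")
  missing <- setdiff(model$probe_ids, colnames(new_beta))
  extra <- setdiff(colnames(new_beta), model$probe_ids)
  .assert(length(missing) == 0 && length(extra) == 0,
          "probe set mismatch with atlas (missing: %s%s; extra: %s%s)",
          paste(utils::head(missing, 3), collapse = ","),
          if (length(missing) > 3) ",..." else "",
          paste(utils::head(extra, 3), collapse = ","),
          if (length(extra) > 3) ",..." else "")
  new_beta <- new_beta[, model$probe_ids, drop = FALSE]

  x <- sweep(new_beta, 2, model$center)
  if (!is.null(model$rotation)) x <- x %*% model$rotation
  k <- min(model$transform_k, nrow(model$train_x))
  out <- matrix(0, nrow(x), model$n_dims,
                dimnames = list(rownames(new_beta),
                                colnames(model$coords)))
  for (i in seq_len(nrow(x))) {
    d2 <- colSums((t(model$train_x) - x[i, ])^2)
    nn <- order(d2)[seq_len(k)]
    w <- 1 / (sqrt(d2[nn]) + 1e-12)
    w <- w / sum(w)
    out[i, ] <- as.vector(w %*% model$coords[nn, , drop = FALSE])
  }
  out
}

#' @export
print.atlas_embedding <- function(x, ...) {
  cat("Methylome atlas embedding\n")
  cat(sprintf("  %d training samples, %d probes -> %d dimensions\n",
              nrow(x$coords), length(x$probe_ids), x$n_dims))
  cat(sprintf("  seed %d; out-of-sample projection: %s (k = %d)\n",
              x$seed, x$transform_method, x$transform_k))
  invisible(x)
}
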