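#' Remove flagged probes (sex-linked, non-CpG, masked)
#'
#' Drops probes whose manifest entry carries any of the `sex_linked`,
#' `non_cpg`, or `masked` flags; the order of surviving probes is preserved.
#'
#' @param beta Samples x probes beta matrix.
#' @param manifest Probe manifest with logical flag columns.
#' @return The filtered beta matrix.
#' @export
filter_probes <- function(beta, manifest) {
  .check_beta(beta)
  missing_probes <- setdiff(colnames(beta), manifest$probe_id)
  .assert(length(missing_probes) == 0,
          "probes absent from manifest: %s",
          paste(utils::head(missing_probes, 5), collapse = ", "))
  m <- manifest[match(colnames(beta), manifest$probe_id), ]
  keep <- !(m$sex_linked | m$non_cpg | m$masked)
  beta[, keep, drop = FALSE]
}

#' Remove samples failing detection p-value QC
#'
#' A sample is removed when the fraction of its probes with detection
#' p-value above `p_cut` exceeds `max_fail_frac`.
#'
#' @param beta Samples x probes beta matrix.
#' @param detection Matrix of detection p-values, same shape and dimnames.
#' @param p_cut Per-probe detection failure threshold.
#' @param max_fail_frac Maximum tolerated fraction of failed probes.
#' @return list with `beta` (retained samples) and `removed` (sample ids).
#' @export
filter_failed_samples <- function(beta, detection, p_cut = 0.05,
                                  max_fail_frac = 0.05) {
  .check_beta(beta)
  .assert(is.matrix(detection) && all(dim(detection) == dim(beta)),
          "detection p-value matrix must match beta's shape")
  .assert(all(detection >= 0 & detection <= 1, na.rm = TRUE),
          "detection p-values must lie in [0, 1]")
  if (!is.null(rownames(detection))) {
    .assert(identical(rownames(detection), rownames(beta)) &&
              identical(colnames(detection), colnames(beta)),
            "detection matrix dimnames must match beta")
  }
  fail_frac <- rowMeans(detection > p_cut, na.rm = TRUE)
  removed <- rownames(beta)[fail_frac > max_fail_frac]
  list(beta = beta[!rownames(beta) %in% removed, , drop = FALSE],
       removed = removed)
}

#' Remove probes with excess missingness
#'
#' Drops probes whose missing fraction is strictly greater than
#' `max_missing_frac` (a probe missing exactly the threshold fraction is kept).
#'
#' @param beta Samples x probes beta matrix.
#' @param max_missing_frac Maximum tolerated missing fraction per probe.
#' @return The filtered beta matrix.
#' @export
filter_high_missing_probes <- function(beta, max_missing_frac = 0.05) {
  .check_beta(beta)
  miss <- colMeans(is.na(beta))
  beta[, miss <= max_missing_frac, drop = FALSE]
}

#' Flag outlying samples on leading principal components
#'
#' Missing entries are mean-imputed internally, samples are projected onto the
#' first `n_components` principal axes, and a sample is flagged when its score
#' on any axis lies more than `sd_threshold` robust standard deviations
#' (1.4826 x MAD) from the axis median. Axes with zero MAD (e.g. identical
#' samples) flag nothing.
#'
#' @param beta Samples x probes beta matrix.
#' @param n_components Number of leading principal axes to inspect.
#' @param sd_threshold Robust-SD multiple defining an outlier.
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
pca_outlier_samples <- function(beta, n_components = 2, sd_threshold = 6) {
  .check_beta(beta)
  .assert(nrow(beta) >= max(3, n_components + 1),
          "need more samples than components for PCA outlier detection")
  x <- beta
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2]]
  }
  x <- x[, apply(x, 2, stats::sd) > 0, drop = FALSE]
  if (ncol(x) == 0) return(character(0))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  flagged <- rep(FALSE, nrow(beta))
  for (j in seq_len(ncol(pc$x))) {
    s <- pc$x[, j]
    m <- stats::median(s)
    robust_sd <- stats::mad(s)   # includes the 1.4826 consistency constant
    if (robust_sd < 1e-12) next
    flagged <- flagged | abs(s - m) > sd_threshold * robust_sd
  }
  rownames(beta)[flagged]
}

#' Fill missing beta values with batch means
#'
#' Each missing entry is replaced by the mean of the non-missing values of the
#' same probe within the same batch; probes with no observations in a batch
#' fall back to the global probe mean. A probe missing everywhere is an error
#' (it should have been removed by [filter_high_missing_probes()]).
#'
#' @param beta Samples x probes beta matrix.
#' @param batches Batch label per sample (vector along rows of `beta`).
#' @return Completed beta matrix.
#' @export
impute_batch_mean <- function(beta, batches) {
  .check_beta(beta)
  .assert(length(batches) == nrow(beta), "every sample needs a batch label")
  .assert(!anyNA(batches), "batch labels must not be missing")
  all_missing <- colSums(!is.na(beta)) == 0
  .assert(!any(all_missing), "probe(s) entirely missing: %s",
          paste(utils::head(colnames(beta)[all_missing], 5), collapse = ", "))
  if (!anyNA(beta)) return(beta)
  global_mean <- colMeans(beta, na.rm = TRUE)
  out <- beta
  for (b in unique(batches)) {
    rows <- which(batches == b)
    sub <- beta[rows, , drop = FALSE]
    if (!anyNA(sub)) next
    bm <- colMeans(sub, na.rm = TRUE)
    bm[is.nan(bm)] <- global_mean[is.nan(bm)]
    idx <- which(is.na(sub), arr.ind = TRUE)
    sub[idx] <- bm[idx[, 2]]
    out[rows, ] <- sub
  }
  out
}

#' Empirical-Bayes batch adjustment of beta values
#'
#' Wraps the parametric ComBat location/scale model (via the sva package):
#' probes are standardized, batch effects estimated and shrunk toward
#' batch-level priors, and the data restored. Afterwards each probe is
#' re-centered to its pre-adjustment pooled mean and values are clipped to
#' \[0, 1\]. A single batch returns the input unchanged; probes with zero
#' overall variance are passed through untouched.
#'
#' @param beta Samples x probes beta matrix without missing values.
#' @param batches Batch label per sample; every batch needs >= 2 samples.
#' @param covariates Optional data.frame of biological covariates to protect
#'   during adjustment (off by default; batch-only adjustment).
#' @return Adjusted beta matrix, same shape and dimnames.
#' @export
combat_adjust <- function(beta, batches, covariates = NULL) {
  .check_beta(beta, allow_missing = FALSE)
  .assert(length(batches) == nrow(beta), "every sample needs a batch label")
  batches <- as.factor(batches)
  if (nlevels(droplevels(batches)) < 2) return(beta)
  tab <- table(batches)
  .assert(all(tab >= 2), "each batch needs at least 2 samples (offenders: %s)",
          paste(names(tab)[tab < 2], collapse = ", "))
  sds <- apply(beta, 2, stats::sd)
  varying <- sds > 0
  out <- beta
  if (any(varying)) {
    dat <- t(beta[, varying, drop = FALSE])     # probes x samples for ComBat
    mod <- NULL
    if (!is.null(covariates)) {
      mod <- stats::model.matrix(~., data = as.data.frame(covariates))
    }
    adj <- NULL
    invisible(utils::capture.output(
      adj <- suppressMessages(sva::ComBat(dat = dat, batch = batches,
                                          mod = mod))))
    # restore the per-probe pooled mean exactly, then clip to the beta range
    adj <- adj - (rowMeans(adj) - rowMeans(dat))
    adj <- pmin(pmax(adj, 0), 1)
    out[, varying] <- t(adj)
  }
  out
}

#' Beta to M-value conversion
#'
#' `M = log2(beta / (1 - beta))` after clipping beta to
#' `[epsilon, 1 - epsilon]` so M stays finite at fully (un)methylated probes.
#'
#' @param beta Beta matrix or vector in \[0, 1\].
#' @param epsilon Clipping bound.
#' @return M-values, same shape.
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  log2(b / (1 - b))
}

#' M-value to beta conversion (inverse of [beta_to_m()])
#'
#' @param m M-value matrix or vector.
#' @return Beta values in (0, 1), exactly inverting [beta_to_m()] for beta
#'   strictly inside the clipping bounds.
#' @export
m_to_beta <- function(m) {
  1 / (1 + 2^(-m))
}

#' Run the full array QC and harmonization pipeline
#'
#' Applies, in order: (i) manifest flag filters (sex-linked/non-CpG), (ii)
#' masked-probe removal (part of the same flag filter), (iii) detection-failure
#' sample removal, (iv) high-missingness probe removal, (v) caller-supplied
#' non-target sample removal, (vi) PCA outlier removal; then batch-mean
#' imputation of remaining missing values and empirical-Bayes batch
#' adjustment. Each step's input/output counts are recorded.
#'
#' @param beta Samples x probes beta matrix.
#' @param manifest Probe manifest.
#' @param detection Optional detection p-value matrix (step iii skipped if
#'   `NULL`).
#' @param batches Optional batch label per sample of `beta` (named or in row
#'   order); imputation falls back to global means and batch adjustment is
#'   skipped when `NULL`.
#' @param non_target Sample ids to drop as non-target (e.g. non-hematopoietic).
#' @param p_cut,max_fail_frac,max_missing_frac,pca_components,pca_sd_threshold
#'   Thresholds forwarded to the individual steps.
#' @return list with `beta` (clean matrix), `report` (named list of counts per
#'   step), and `removed_samples`.
#' @export
qc_pipeline <- function(beta, manifest, detection = NULL, batches = NULL,
                        non_target = NULL, p_cut = 0.05, max_fail_frac = 0.05,
                        max_missing_frac = 0.05, pca_components = 2,
                        pca_sd_threshold = 6) {
  .check_beta(beta)
  if (!is.null(batches)) {
    .assert(length(batches) == nrow(beta), "batches must align with beta rows")
    names(batches) <- rownames(beta)
  }
  report <- list(n_samples_in = nrow(beta), n_probes_in = ncol(beta))

  b <- filter_probes(beta, manifest)
  report$probes_removed_flags <- ncol(beta) - ncol(b)

  removed_fail <- character(0)
  if (!is.null(detection)) {
    det <- detection[rownames(b), colnames(b), drop = FALSE]
    ff <- filter_failed_samples(b, det, p_cut, max_fail_frac)
    b <- ff$beta
    removed_fail <- ff$removed
  }
  report$samples_removed_detection <- length(removed_fail)

  p_before <- ncol(b)
  b <- filter_high_missing_probes(b, max_missing_frac)
  report$probes_removed_missing <- p_before - ncol(b)

  removed_nt <- intersect(non_target, rownames(b))
  b <- b[!rownames(b) %in% removed_nt, , drop = FALSE]
  report$samples_removed_non_target <- length(removed_nt)

  removed_pca <- pca_outlier_samples(b, pca_components, pca_sd_threshold)
  b <- b[!rownames(b) %in% removed_pca, , drop = FALSE]
  report$samples_removed_pca <- length(removed_pca)

  bt <- if (is.null(batches)) rep(1L, nrow(b)) else unname(batches[rownames(b)])
  b <- impute_batch_mean(b, bt)
  b <- combat_adjust(b, bt)
  report$n_samples_out <- nrow(b)
  report$n_probes_out <- ncol(b)

  list(beta = b, report = report,
       removed_samples = list(detection = removed_fail,
                              non_target = removed_nt, pca = removed_pca))
}
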