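make_beta <- function(n, p, seed = 1, miss = 0) {
  set.seed(seed)
  b <- matrix(runif(n * p, 0.1, 0.9), n, p,
              dimnames = list(sprintf("S%02d", 1:n), sprintf("cg%03d", 1:p)))
  if (miss > 0) b[sample(length(b), round(miss * length(b)))] <- NA
  b
}

manifest_for <- function(beta, sex = character(0), masked = character(0)) {
  data.frame(probe_id = colnames(beta), chrom = "chr1",
             pos = seq_len(ncol(beta)) * 100L,
             sex_linked = colnames(beta) %in% sex, non_cpg = FALSE,
             masked = colnames(beta) %in% masked)
}

test_that("flag filter removes flagged probes, preserves order, and is idempotent", {
  b <- make_beta(4, 5)
  man <- manifest_for(b, sex = "cg002", masked = "cg004")
  out <- filter_probes(b, man)
  expect_identical(colnames(out), c("cg001", "cg003", "cg005"))
  expect_identical(filter_probes(out, man), out)       # idempotent
  expect_identical(filter_probes(b, manifest_for(b)), b)  # no flags: identity
  all_flagged <- manifest_for(b, masked = colnames(b))
  empty <- filter_probes(b, all_flagged)
  expect_identical(dim(empty), c(4L, 0L))
  expect_identical(rownames(empty), rownames(b))
  expect_error(filter_probes(b, man[-1, ]), "cg001")
})

test_that("detection failure rule removes samples exceeding the failed fraction", {
  b <- make_beta(3, 20)
  det <- matrix(0, 3, 20, dimnames = dimnames(b))
  det[2, 1:2] <- 0.5   # 10% of probes fail at p_cut = 0.05
  res <- filter_failed_samples(b, det, p_cut = 0.05, max_fail_frac = 0.05)
  expect_identical(res$removed, "S02")
  expect_identical(rownames(res$beta), c("S01", "S03"))
  # all-pass sample retained; max_fail_frac = 1 removes nothing
  expect_length(filter_failed_samples(b, det, max_fail_frac = 1)$removed, 0)
  expect_error(filter_failed_samples(b, det[, 1:5]), "shape|match")
})

test_that("probe missingness filter uses a strict threshold", {
  b <- make_beta(20, 3)
  b[1, 1] <- NA            # 5% exactly: kept
  b[1:2, 2] <- NA          # 10%: dropped
  out <- filter_high_missing_probes(b, max_missing_frac = 0.05)
  expect_identical(colnames(out), c("cg001", "cg003"))
  full <- make_beta(20, 3)
  expect_identical(filter_high_missing_probes(full), full)
})

test_that("PCA outlier detection flags a displaced sample and only it", {
  set.seed(5)
  b <- matrix(0.5 + rnorm(100 * 30, 0, 0.02), 100, 30,
              dimnames = list(sprintf("S%03d", 1:100), sprintf("cg%03d", 1:30)))
  b[7, 1:10] <- b[7, 1:10] + 0.4   # ~20 robust SDs along the leading axis
  b <- pmin(pmax(b, 0), 1)
  # independent oracle: eigen-decomposition of the covariance
  xc <- scale(b, scale = FALSE)
  ev <- eigen(stats::cov(xc))$vectors[, 1]
  s1 <- xc %*% ev
  expect_identical(which.max(abs(s1 - stats::median(s1))), 7L)
  expect_identical(pca_outlier_samples(b), "S007")

  same <- matrix(0.4, 10, 5, dimnames = list(paste0("S", 1:10), paste0("cg", 1:5)))
  expect_length(pca_outlier_samples(same), 0)

  set.seed(6)
  cloud <- matrix(plogis(rnorm(200 * 40)), 200, 40,
                  dimnames = list(sprintf("S%03d", 1:200), sprintf("cg%03d", 1:40)))
  expect_length(pca_outlier_samples(cloud, sd_threshold = 6), 0)
})

test_that("batch-mean imputation fills from the batch, then the global mean", {
  b <- matrix(c(0.2, 0.4, NA, 0.6, 0.8, 0.7), 6, 1,
              dimnames = list(paste0("S", 1:6), "cg001"))
  out <- impute_batch_mean(b, c(1, 1, 1, 2, 2, 2))
  expect_equal(out["S3", 1], 0.3)
  # probe fully missing in batch 1 falls back to the global mean
  b2 <- matrix(c(NA, NA, 0.5, 0.5), 4, 1,
               dimnames = list(paste0("S", 1:4), "cg001"))
  out2 <- impute_batch_mean(b2, c(1, 1, 2, 2))
  expect_equal(unname(out2[1:2, 1]), c(0.5, 0.5))
  complete <- make_beta(4, 3)
  expect_identical(impute_batch_mean(complete, rep(1, 4)), complete)
  b3 <- make_beta(4, 2); b3[, 2] <- NA
  expect_error(impute_batch_mean(b3, rep(1, 4)), "entirely missing")
})

test_that("batch adjustment removes a planted shift and leaves single batches alone", {
  set.seed(9)
  n <- 60; p <- 80
  b <- matrix(plogis(rnorm(n * p, 0, 0.5)), n, p,
              dimnames = list(sprintf("S%03d", 1:n), sprintf("cg%03d", 1:p)))
  batch <- rep(1:2, each = n / 2)
  shifted <- pmin(pmax(b + 0.1 * (batch - 1), 0), 1)
  adj <- combat_adjust(shifted, batch)
  diff_pre <- colMeans(shifted[batch == 1, ]) - colMeans(shifted[batch == 2, ])
  diff_post <- colMeans(adj[batch == 1, ]) - colMeans(adj[batch == 2, ])
  expect_lt(mean(abs(diff_post)), mean(abs(diff_pre)) / 4)
  # pooled probe means preserved
  expect_lt(max(abs(colMeans(adj) - colMeans(shifted))), 1e-6)
  # single batch: identity
  expect_lt(max(abs(combat_adjust(b, rep(1, n)) - b)), 1e-10)
  # two identically distributed batches barely move
  adj_null <- combat_adjust(b, batch)
  expect_lt(mean(abs(adj_null - b)), 0.02)
  expect_error(combat_adjust(b, c(rep(1, n - 1), 2)), "at least 2 samples")
})

test_that("beta/M transforms match the log2 logit definition and invert", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  b <- seq(0.01, 0.99, by = 0.01)
  expect_lt(max(abs(m_to_beta(beta_to_m(b)) - b)), 1e-12)
  expect_true(all(is.finite(beta_to_m(c(0, 1)))))
})

test_that("the QC pipeline applies filters in order and reports counts", {
  cohort <- small_cohort(seed = 31)
  res <- qc_pipeline(cohort$beta, cohort$manifest,
                     batches = cohort$clinical$batch)
  expect_false(anyNA(res$beta))
  expect_lt(ncol(res$beta), ncol(cohort$beta))  # flagged probes removed
  rep <- res$report
  expect_identical(rep$n_probes_in, ncol(cohort$beta))
  expect_identical(rep$n_probes_out, ncol(res$beta))
  expect_identical(rep$probes_removed_flags,
                   sum(cohort$manifest$sex_linked | cohort$manifest$masked))
  # re-running QC on its own output changes nothing further structurally
  res2 <- qc_pipeline(res$beta, cohort$manifest,
                      batches = cohort$clinical$batch[
                        match(rownames(res$beta), cohort$clinical$sample_id)])
  expect_identical(dim(res2$beta), dim(res$beta))
})
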