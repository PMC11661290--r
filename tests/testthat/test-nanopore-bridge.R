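bed_manifest <- data.frame(probe_id = c("cgA", "cgB", "cgC"), chrom = "chr1",
                           pos = c(1000L, 2000L, 3000L), sex_linked = FALSE,
                           non_cpg = FALSE, masked = FALSE)

write_lines <- function(lines) {
  f <- tempfile(fileext = ".bed")
  writeLines(lines, f)
  f
}

mk_row <- function(chrom, start, code, strand, cov, nmod) {
  paste(chrom, start, start + 1, code, cov, strand, start, start + 1,
        "255,0,0", cov, round(100 * nmod / max(cov, 1), 2), nmod, cov - nmod,
        0, 0, 0, 0, 0, sep = "\t")
}

test_that("the parser keeps 5mCG rows, counts skipped 5hmC, and validates rows", {
  f <- write_lines(c(
    mk_row("chr1", 999, "m", "+", 10, 8),
    mk_row("chr1", 999, "h", "+", 10, 1),
    mk_row("chr1", 1000, "m", "-", 6, 3)
  ))
  rec <- parse_bedmethyl(f)
  expect_identical(nrow(rec), 2L)
  expect_identical(attr(rec, "n_skipped_h"), 1L)
  expect_equal(rec$n_mod, c(8, 3))

  bad <- write_lines(c(mk_row("chr1", 999, "m", "+", 10, 8), "chr1\t5\tm"))
  expect_error(parse_bedmethyl(bad), "line 2")
  over <- write_lines(mk_row("chr1", 999, "m", "+", 5, 9))
  expect_error(parse_bedmethyl(over), "exceeds valid coverage")
})

test_that("strand collapse pools counts and applies the strict coverage rule", {
  f <- write_lines(c(
    mk_row("chr1", 999, "m", "+", 10, 8),    # cgA + strand
    mk_row("chr1", 1000, "m", "-", 6, 3),    # cgA - strand
    mk_row("chr1", 1999, "m", "+", 3, 1),    # cgB: pooled coverage 5 -> missing
    mk_row("chr1", 2000, "m", "-", 2, 2),
    mk_row("chr1", 500000, "m", "+", 30, 15) # unmatched locus, ignored
  ))
  rec <- parse_bedmethyl(f)
  v <- collapse_and_map(rec, bed_manifest, min_coverage = 5)
  expect_equal(unname(v["cgA"]), 11 / 16)
  expect_true(is.na(v["cgB"]))      # coverage exactly 5 is not "> 5x"
  expect_true(is.na(v["cgC"]))      # no records at all
  expect_identical(attr(v, "n_unmatched_records"), 1L)
  # per-strand filtering mode drops thin strands before pooling
  v2 <- collapse_and_map(rec, bed_manifest, min_coverage = 5,
                         per_strand = TRUE)
  expect_equal(unname(v2["cgA"]), 11 / 16)
})

test_that("reference-mean imputation fills exactly the missing entries", {
  x <- c(cgA = 0.7, cgB = NA, cgC = NA)
  ref <- c(cgA = 0.5, cgB = 0.42, cgC = 0.9)
  out <- impute_reference_means(x, ref)
  expect_equal(unname(out), c(0.7, 0.42, 0.9), ignore_attr = TRUE)
  expect_equal(attr(out, "imputed_fraction"), 2 / 3)
  none <- impute_reference_means(c(cgA = 0.7), ref)
  expect_equal(attr(none, "imputed_fraction"), 0)
  expect_warning(impute_reference_means(c(cgA = NA_real_), ref), "all features")
  expect_error(impute_reference_means(c(cgZ = NA_real_), ref),
               "no reference mean")
})

test_that("write -> parse -> collapse round trip is exact at the counts level", {
  cohort <- small_cohort(seed = 51)
  beta <- cohort$beta[3, ]
  beta[is.na(beta)] <- 0.5
  f <- tempfile(fileext = ".bed")
  set.seed(4)
  rows <- write_bedmethyl(beta, cohort$manifest, f, mean_coverage = 10,
                          dispersion = 0)
  rec <- parse_bedmethyl(f)
  v <- collapse_and_map(rec, cohort$manifest, min_coverage = 5)
  # deterministic coverage 10 per strand: pooled coverage 20 everywhere
  expect_false(anyNA(v))
  # counts-level equality with what the writer drew
  key <- ifelse(rows$strand == "+", rows$start + 1, rows$start)
  probe <- cohort$manifest$probe_id[match(paste0(rows$chrom, ":", key),
                                          paste0(cohort$manifest$chrom, ":",
                                                 cohort$manifest$pos))]
  agg_mod <- tapply(rows$n_mod, probe, sum)
  expect_equal(unname(v[names(agg_mod)]), unname(as.vector(agg_mod)) / 20)
  # binomial sampling keeps fractions near the generative beta
  expect_lt(max(abs(v - beta[names(v)])), 4 * sqrt(0.25 / 20) + 1e-9)
  # extreme betas survive the round trip exactly
  beta2 <- beta
  beta2[] <- rep(c(0, 1), length.out = length(beta2))
  f2 <- tempfile(fileext = ".bed")
  write_bedmethyl(beta2, cohort$manifest, f2, mean_coverage = 10,
                  dispersion = 0)
  v2 <- collapse_and_map(parse_bedmethyl(f2), cohort$manifest)
  expect_equal(unname(v2[names(beta2)]), unname(beta2))
})

test_that("sample reports gate prognostic models on subtype and confidence", {
  cohort <- generate_cohort(cohort_config(n_samples = 90, n_probes = 300,
                                          n_subtypes = 3, missing_rate = 0,
                                          batch_shift = 0,
                                          n_prognostic_cpgs = 4, seed = 53))
  atlas <- fit_embedding(cohort$beta, n_dims = 5, seed = 55)
  grid <- expand.grid(eta = 0.1, max_leaves = 15, alpha = 0, lambda = 0,
                      KEEP.OUT.ATTRS = FALSE)
  subtype <- train_subtype(atlas$coords, cohort$clinical$subtype, seed = 57,
                           grid = grid)
  risk <- train_risk(atlas$coords, cohort$clinical$os_time,
                     cohort$clinical$os_event, seed = 59, grid = grid)
  m <- beta_to_m(cohort$beta)
  sig <- fit_signature(m, cohort$truth$prognostic_probes[1:2],
                       cohort$clinical)
  gate <- c("AML_1", "AML_2")

  aml_idx <- which(cohort$clinical$subtype == "AML_1")[1]
  rep_aml <- report_sample(cohort$beta[aml_idx, ], atlas, subtype, risk, sig,
                           gate_classes = gate, sample_id = "aml")
  expect_true(rep_aml$gated)
  expect_true(!is.na(rep_aml$risk_prob))
  expect_true(rep_aml$signature_group %in% c("low", "high"))

  ctrl_idx <- which(cohort$clinical$subtype == "control")[1]
  rep_ctrl <- report_sample(cohort$beta[ctrl_idx, ], atlas, subtype, risk,
                            sig, gate_classes = gate, sample_id = "ctrl")
  expect_false(rep_ctrl$gated)
  expect_true(is.na(rep_ctrl$risk_prob))
  expect_true(is.na(rep_ctrl$signature_score))

  # determinism of the report
  rep_again <- report_sample(cohort$beta[aml_idx, ], atlas, subtype, risk,
                             sig, gate_classes = gate, sample_id = "aml")
  expect_identical(rep_aml$subtype_probs, rep_again$subtype_probs)
  expect_identical(rep_aml$risk_prob, rep_again$risk_prob)
})

test_that("paired draws from one generative sample agree on the top subtype", {
  cohort <- generate_cohort(cohort_config(n_samples = 90, n_probes = 200,
                                          n_subtypes = 3, missing_rate = 0,
                                          batch_shift = 0, seed = 61))
  atlas <- fit_embedding(cohort$beta, n_dims = 5, seed = 63)
  grid <- expand.grid(eta = 0.1, max_leaves = 15, alpha = 0, lambda = 0,
                      KEEP.OUT.ATTRS = FALSE)
  subtype <- train_subtype(atlas$coords, cohort$clinical$subtype, seed = 65,
                           grid = grid)
  clean <- cohort$truth$beta_clean
  set.seed(67)
  agree <- replicate(100, {
    i <- sample(nrow(clean), 1)
    # two independent 30x binomial readouts of the same underlying methylome
    draw <- function() {
      k <- rbinom(ncol(clean), 30, clean[i, ]) / 30
      names(k) <- colnames(clean)
      k
    }
    p1 <- predict_subtype(subtype, project_samples(atlas, draw()))$label
    p2 <- predict_subtype(subtype, project_samples(atlas, draw()))$label
    p1 == p2
  })
  expect_gte(mean(agree), 0.95)
})
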