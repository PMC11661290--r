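test_that("per-probe Cox scan matches the independent partial-likelihood oracle", {
  fx <- planted_m_fixture(n = 30, p = 8, planted = 2, seed = 5)
  ew <- cox_ewas(fx$m, fx$clinical)
  rg <- stats::model.matrix(~risk_group, fx$clinical)[, -1]
  cens_t <- pmin(fx$clinical$os_time, 60)
  cens_e <- ifelse(fx$clinical$os_time <= 60, fx$clinical$os_event, 0)
  for (probe in ew$probe[1:5]) {
    orc <- oracle_coxph(cbind(fx$m[, probe], rg), cens_t, cens_e)
    row <- ew[ew$probe == probe, ]
    expect_equal(row$coef, orc$coef[1], tolerance = 1e-4)
    expect_equal(row$se, orc$se[1], tolerance = 1e-4)
    expect_equal(row$p, orc$p[1], tolerance = 1e-4)
  }
})

test_that("null probes yield uniform association p-values", {
  set.seed(33)
  n <- 300
  m <- matrix(rnorm(n * 400, 0, 0.7), n, 400,
              dimnames = list(sprintf("S%03d", 1:n), sprintf("cg%04d", 1:400)))
  cfg <- cohort_config(baseline_hazard = 0.012, censoring_rate = 0.1, seed = 2)
  surv <- plant_survival(rep(0, n), cfg)
  clin <- data.frame(os_time = surv$os_time, os_event = surv$os_event,
                     risk_group = factor(sample(c("low", "standard", "high"),
                                                n, TRUE)))
  ew <- cox_ewas(m, clin)
  expect_gt(stats::ks.test(ew$p, "punif")$p.value, 0.01)
})

test_that("degenerate probes are skipped and coordinates attach from the manifest", {
  fx <- planted_m_fixture(n = 40, p = 5, planted = 1, seed = 9)
  fx$m[, 3] <- 1.7   # constant probe
  man <- data.frame(probe_id = colnames(fx$m), chrom = "chr2",
                    pos = seq_len(5) * 10L, sex_linked = FALSE,
                    non_cpg = FALSE, masked = FALSE)
  ew <- cox_ewas(fx$m, fx$clinical, manifest = man)
  expect_false(colnames(fx$m)[3] %in% ew$probe)
  expect_identical(attr(ew, "n_skipped_zero_variance"), 1L)
  expect_true(all(c("chrom", "pos") %in% names(ew)))
})

test_that("the suggestive screen uses a strict threshold and sorts by p", {
  ew <- data.frame(probe = c("a", "b", "c", "d"),
                   p = c(1e-6, 1e-5, 2e-7, NA))
  class(ew) <- c("ewas_result", "data.frame")
  hits <- select_suggestive(ew, p_threshold = 1e-5)
  expect_identical(hits, c("c", "a"))   # exactly-at-threshold excluded
  ew$p <- c(0.5, 0.2, 0.9, 0.4)
  expect_message(none <- select_suggestive(ew), "halts")
  expect_length(none, 0)
})

test_that("stability selection recovers planted effects and controls nulls (reduced scale)", {
  fx <- planted_m_fixture(n = 250, p = 60, planted = 5, b = 0.8, seed = 13)
  st <- stability_select(fx$m, fx$clinical, n_iter = 30, n_folds = 10,
                         seed = 15)
  expect_gte(sum(fx$planted %in% st$selected), 4)
  expect_lte(sum(!st$selected %in% fx$planted), 3)
  expect_length(st$lambda_grid, 50)
  expect_true(all(st$frequency$frequency >= 0 & st$frequency$frequency <= 1))
  # screen/selection consistency: selected within candidates
  expect_true(all(st$selected %in% colnames(fx$m)))
})

test_that("stability selection is reproducible and errors on thin inputs", {
  fx <- planted_m_fixture(n = 120, p = 20, planted = 3, seed = 17)
  a <- stability_select(fx$m, fx$clinical, n_iter = 5, seed = 19)
  b <- stability_select(fx$m, fx$clinical, n_iter = 5, seed = 19)
  expect_identical(a$frequency, b$frequency)
  expect_error(stability_select(fx$m[, 1, drop = FALSE], fx$clinical),
               "at least 2 candidate")
})

test_that("the fitted signature scores linearly and dichotomizes at the median", {
  fx <- planted_m_fixture(n = 200, p = 10, planted = 2, seed = 21)
  sig <- fit_signature(fx$m, fx$planted, fx$clinical)
  sg <- score_and_group(sig, fx$m)
  # median split: half the training cohort on each side (up to ties)
  expect_lte(abs(sum(sg$group == "high") - sum(sg$group == "low")), 1)
  # linearity: shifting one probe's M by +1 moves the score by its coefficient
  m2 <- fx$m
  m2[, sig$probes[1]] <- m2[, sig$probes[1]] + 1
  sg2 <- score_and_group(sig, m2)
  expect_equal(unname(sg2$score - sg$score),
               rep(unname(sig$coefficients[1]), nrow(fx$m)))
  # a sample exactly at the cutoff goes to the low group
  at_cut <- fx$m[1, , drop = FALSE]
  at_cut[1, sig$probes] <- 0
  at_cut[1, sig$probes[1]] <- sig$cutoff / sig$coefficients[1]
  sg3 <- score_and_group(sig, at_cut)
  expect_equal(unname(sg3$score), sig$cutoff)
  expect_identical(as.character(sg3$group), "low")
  expect_error(score_and_group(sig, fx$m[, -match(sig$probes[1],
                                                  colnames(fx$m))]),
               "missing from input")
})

test_that("signature coefficients are consistent for a planted two-probe signal", {
  fx <- planted_m_fixture(n = 800, p = 6, planted = 2, b = 0.6, seed = 23,
                          censoring_rate = 0)
  sig <- fit_signature(fx$m, fx$planted, fx$clinical)
  fit <- survival::coxph(
    survival::Surv(pmin(fx$clinical$os_time, 60),
                   ifelse(fx$clinical$os_time <= 60,
                          fx$clinical$os_event, 0)) ~ fx$m[, fx$planted])
  ses <- sqrt(diag(stats::vcov(fit)))
  for (i in 1:2) {
    expect_lt(abs(sig$coefficients[i] - fx$coefs[i]), 2 * ses[i])
  }
})

test_that("a single-probe signature reduces to a scaled M-value", {
  fx <- planted_m_fixture(n = 150, p = 4, planted = 1, seed = 25)
  sig <- fit_signature(fx$m, fx$planted[1], fx$clinical)
  sg <- score_and_group(sig, fx$m)
  expect_equal(unname(sg$score),
               unname(sig$coefficients[1] * fx$m[, fx$planted[1]]))
})

test_that("collinear probes trigger the ridge fallback with a warning", {
  fx <- planted_m_fixture(n = 100, p = 5, planted = 2, seed = 27)
  m <- cbind(fx$m, dup = fx$m[, fx$planted[1]])
  colnames(m)[ncol(m)] <- "cg_dup"
  expect_warning(sig <- fit_signature(m, c(fx$planted, "cg_dup"),
                                      fx$clinical),
                 "ridge fallback")
  expect_identical(sig$method, "ridge_penalized")
  expect_true(all(is.finite(sig$coefficients)))
})

test_that("the signature chain is seed-stable end to end", {
  fx <- planted_m_fixture(n = 150, p = 30, planted = 3, b = 0.9, seed = 29)
  run_chain <- function() {
    ew <- cox_ewas(fx$m, fx$clinical)
    sug <- select_suggestive(ew, p_threshold = 1e-3)
    st <- stability_select(fx$m, fx$clinical, candidates = sug, n_iter = 10,
                           seed = 31)
    sig <- fit_signature(fx$m, st$selected, fx$clinical)
    list(ew = ew, sug = sug, st = st, sig = sig)
  }
  a <- run_chain()
  b <- run_chain()
  expect_identical(a$sig$coefficients, b$sig$coefficients)
  expect_identical(a$st$frequency, b$st$frequency)
  # screen/selection nesting
  expect_true(all(a$st$selected %in% a$sug))
  expect_true(all(a$sug %in% a$ew$probe))
})
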