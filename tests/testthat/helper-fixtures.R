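# Shared fixtures, built in code at test time.

# A small cohort for fast structural tests.
small_cohort <- function(seed = 7, ...) {
  generate_cohort(cohort_config(n_samples = 60, n_probes = 300,
                                n_subtypes = 3, n_prognostic_cpgs = 4,
                                missing_rate = 0.01, seed = seed, ...))
}

# Random survival fixture for Cox oracle comparisons.
surv_fixture <- function(n = 40, p = 2, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  eta <- as.vector(x %*% rep_len(c(0.5, -0.3), p))
  time <- round(-log(runif(n)) / (0.05 * exp(eta)), 1)  # rounding makes ties
  event <- as.integer(runif(n) < 0.75)
  list(x = x, time = time, event = event)
}

# Well-separated Gaussian clusters in coordinate space (bypasses embedding).
cluster_coords <- function(n_per = 100, k = 6, dims = 5, sep = 8, sd = 1,
                           seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(k * dims), k, dims)
  centers <- centers / sqrt(rowSums(centers^2)) * sep / sqrt(2)
  lab <- rep(seq_len(k), each = n_per)
  coords <- centers[lab, ] + matrix(rnorm(n_per * k * dims, 0, sd),
                                    n_per * k, dims)
  rownames(coords) <- sprintf("S%04d", seq_len(nrow(coords)))
  list(coords = coords, labels = paste0("cl", lab))
}

# M-value matrix with planted survival effects, for signature-stage tests.
planted_m_fixture <- function(n = 200, p = 50, planted = 5, b = 0.7,
                              seed = 1, baseline_hazard = 0.01,
                              censoring_rate = 0.1) {
  set.seed(seed)
  m <- matrix(rnorm(n * p, 0, 0.7), n, p,
              dimnames = list(sprintf("S%04d", seq_len(n)),
                              sprintf("cg%05d", seq_len(p))))
  idx <- seq_len(planted)
  coefs <- rep_len(c(b, -b), planted)
  eta <- as.vector(m[, idx, drop = FALSE] %*% coefs)
  cfg <- cohort_config(baseline_hazard = baseline_hazard,
                       censoring_rate = censoring_rate, seed = seed + 1)
  surv <- plant_survival(eta, cfg)
  risk_group <- factor(sample(c("low", "standard", "high"), n, TRUE),
                       levels = c("low", "standard", "high"))
  list(m = m, planted = colnames(m)[idx], coefs = coefs, eta = eta,
       clinical = data.frame(os_time = surv$os_time, os_event = surv$os_event,
                             risk_group = risk_group))
}

# Cohort with a binary latent risk group (eta = log(hr) * g) carried by a few
# strongly bimodal CpGs: the discovery/validation pair for signature
# generalization experiments. The probe baseline is drawn from a fixed
# sub-seed so independent cohorts share the same population.
latent_group_cohort <- function(n, p = 300, k = 3, delta = 2, hr = 3, seed) {
  set.seed(1000)
  base <- rnorm(p, 0, 1.5)
  set.seed(seed)
  g <- sample(rep(0:1, length.out = n))
  x <- matrix(rnorm(n * p, 0, 0.5), n, p,
              dimnames = list(sprintf("S%04d", seq_len(n)),
                              sprintf("cg%05d", seq_len(p))))
  x <- x + rep(base, each = n)
  x[, 1:k] <- matrix(rnorm(n * k, 0, 0.5), n, k) +
    (c(-1, 1) * delta / 2)[g + 1]
  surv <- plant_survival(log(hr) * g,
                         cohort_config(baseline_hazard = 0.01,
                                       censoring_rate = 0.1,
                                       seed = seed + 1))
  clin <- data.frame(os_time = surv$os_time, os_event = surv$os_event,
                     risk_group = factor(sample(c("low", "standard", "high"),
                                                n, TRUE),
                                         levels = c("low", "standard",
                                                    "high")))
  list(beta = plogis(x), clinical = clin, g = g,
       sig_probes = colnames(x)[1:k])
}
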