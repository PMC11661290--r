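#' Configuration for a synthetic methylome cohort
#'
#' Describes the generative model used by [generate_cohort()]: a logit-normal
#' cluster mixture for beta values (per-subtype centroids in logit space,
#' inverse-logit back to \[0, 1\]), additive batch shifts on the beta scale,
#' completely-at-random missingness, and exponential survival times driven by a
#' planted set of prognostic CpGs through a Cox linear predictor.
#'
#' The defaults emulate a pediatric-AML-like discovery cohort: within-cluster
#' noise of 0.5 on the logit scale (roughly a beta-value SD of 0.1 at
#' intermediate methylation), a baseline hazard of 0.01 events/month (about 45%
#' mortality by 60 months at a null linear predictor), and 10% loss to
#' follow-up before the horizon.
#'
#' @param n_samples,n_probes,n_subtypes Cohort dimensions. `n_subtypes >= 2`;
#'   clusters are labelled `AML_1 ... AML_{K-1}` plus a `control` cluster.
#' @param cluster_separation Euclidean distance between cluster centroids in
#'   logit space (expected value; offsets are Gaussian over the informative
#'   probe subset).
#' @param n_batches,batch_shift Number of batches and the additive beta-scale
#'   offset applied to batch b as `batch_shift * (b - 1)`, then clipped.
#' @param missing_rate Fraction of entries set missing completely at random.
#' @param n_prognostic_cpgs,prognostic_log_hr Planted survival signal: number
#'   of prognostic probes and their log hazard ratio per M-value unit (scalar,
#'   recycled, or a vector of that length; signs alternate if scalar).
#' @param cluster_log_hr SD of per-subtype log-hazard offsets (prognosis is
#'   partly a function of diagnostic subtype; 0 disables the cluster-level
#'   survival component).
#' @param baseline_hazard Exponential baseline hazard, events per month.
#' @param censoring_rate Target fraction of samples lost to follow-up (censored
#'   before the horizon); calibrated by bisection to within 0.02.
#' @param horizon_months Administrative censoring horizon (months); may be `Inf`.
#' @param sigma_logit Within-cluster noise SD on the logit scale.
#' @param frac_sex_linked,frac_masked Fractions of probes flagged sex-linked
#'   (placed on chrX) and masked/unreliable in the manifest.
#' @param seed Integer seed; identical configs give bit-identical cohorts.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()], [plant_survival()], [write_bedmethyl()]
#' @export
cohort_config <- function(n_samples = 600, n_probes = 2000, n_subtypes = 6,
                          cluster_separation = 8, n_batches = 2,
                          batch_shift = 0.05, missing_rate = 0.01,
                          n_prognostic_cpgs = 10, prognostic_log_hr = 0.7,
                          cluster_log_hr = 0.5,
                          baseline_hazard = 0.01, censoring_rate = 0.1,
                          horizon_months = 60, sigma_logit = 0.5,
                          frac_sex_linked = 0.02, frac_masked = 0.05,
                          seed = 1L) {
  cfg <- list(n_samples = n_samples, n_probes = n_probes,
              n_subtypes = n_subtypes, cluster_separation = cluster_separation,
              n_batches = n_batches, batch_shift = batch_shift,
              missing_rate = missing_rate,
              n_prognostic_cpgs = n_prognostic_cpgs,
              prognostic_log_hr = prognostic_log_hr,
              cluster_log_hr = cluster_log_hr,
              baseline_hazard = baseline_hazard,
              censoring_rate = censoring_rate,
              horizon_months = horizon_months, sigma_logit = sigma_logit,
              frac_sex_linked = frac_sex_linked, frac_masked = frac_masked,
              seed = as.integer(seed))
  for (f in c("n_samples", "n_probes", "n_subtypes", "n_batches")) {
    .assert(length(cfg[[f]]) == 1 && cfg[[f]] >= 1, "%s must be a positive count", f)
  }
  .assert(cfg$n_subtypes >= 2, "n_subtypes must be at least 2")
  for (f in c("missing_rate", "censoring_rate", "frac_sex_linked", "frac_masked")) {
    .assert(cfg[[f]] >= 0 && cfg[[f]] <= 1, "%s must be a fraction in [0, 1]", f)
  }
  .assert(cfg$n_prognostic_cpgs <= cfg$n_probes,
          "n_prognostic_cpgs must not exceed n_probes")
  .assert(cfg$baseline_hazard > 0, "baseline_hazard must be positive")
  .assert(cfg$cluster_separation >= 0 && cfg$sigma_logit > 0,
          "cluster_separation must be >= 0 and sigma_logit > 0")
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic methylome cohort with planted structure
#'
#' Draws a samples x probes beta matrix from a logit-normal cluster mixture,
#' adds batch shifts and missingness, builds a probe manifest with hg38-style
#' coordinates and QC flags, and simulates a clinical table whose survival
#' endpoints are driven by the planted prognostic CpGs. The linear predictor
#' eta, cluster and batch assignments, and the planted probe set are returned
#' as ground truth.
#'
#' Cluster-informative, prognostic, and flagged probe subsets are mutually
#' disjoint, so QC filters never remove planted signal and the association scan
#' is run against clean nulls. Batch shifts and missingness are applied after
#' eta is computed: the survival signal lives in the biological layer, batch
#' structure is pure nuisance.
#'
#' @param config A [cohort_config()].
#' @param template Optional result of a previous [generate_cohort()] call:
#'   its generative model (probe roles, baseline means, cluster centroids,
#'   prognostic coefficients, manifest) is reused so the new cohort is an
#'   independent draw from the same population — e.g. a validation cohort for
#'   a signature trained on the template cohort. `n_probes` and `n_subtypes`
#'   must match the template.
#' @return A list with elements:
#' \describe{
#'   \item{beta}{samples x probes matrix in \[0,1\] with `NA` missingness.}
#'   \item{manifest}{data.frame: `probe_id`, `chrom`, `pos` (1-based + strand C
#'     position), logical `sex_linked`, `non_cpg`, `masked`.}
#'   \item{clinical}{data.frame: `sample_id`, `subtype`, `os_time`, `os_event`,
#'     `efs_time`, `efs_event`, `risk_group` (low/standard/high), `mrd1`,
#'     `age_years`, `wbc`, `batch`.}
#'   \item{truth}{list: `cluster`, `batch`, `prognostic_probes`,
#'     `prognostic_coefs`, `eta`, `beta_clean` (pre-batch, pre-missingness).}
#' }
#' @examples
#' cohort <- generate_cohort(cohort_config(n_samples = 60, n_probes = 300, seed = 7))
#' dim(cohort$beta)
#' table(cohort$clinical$subtype)
#' @export
generate_cohort <- function(config, template = NULL) {
  .assert(inherits(config, "cohort_config"), "config must come from cohort_config()")
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_samples
  p <- cfg$n_probes
  K <- cfg$n_subtypes

  sample_ids <- sprintf("S%04d", seq_len(n))

  if (is.null(template)) {
    probe_ids <- sprintf("cg%07d", seq_len(p))
    # disjoint probe roles
    n_flag_sex <- round(cfg$frac_sex_linked * p)
    n_flag_mask <- round(cfg$frac_masked * p)
    n_info <- min(max(50, round(0.1 * p)),
                  p - cfg$n_prognostic_cpgs - n_flag_sex - n_flag_mask)
    .assert(n_info >= 1, "n_probes too small for the requested probe roles")
    roles <- sample.int(p)
    idx_info <- roles[seq_len(n_info)]
    idx_prog <- roles[n_info + seq_len(cfg$n_prognostic_cpgs)]
    idx_sex <- roles[n_info + cfg$n_prognostic_cpgs + seq_len(n_flag_sex)]
    idx_mask <- roles[n_info + cfg$n_prognostic_cpgs + n_flag_sex +
                        seq_len(n_flag_mask)]

    # manifest: probes spread over autosomes, sex-linked probes moved to chrX
    chrom <- paste0("chr", rep_len(1:22, p))
    pos <- 10000L + 1000L * (seq_len(p) - 1L)
    if (n_flag_sex > 0) chrom[idx_sex] <- "chrX"
    manifest <- data.frame(probe_id = probe_ids, chrom = chrom, pos = pos,
                           sex_linked = FALSE, non_cpg = FALSE, masked = FALSE,
                           stringsAsFactors = FALSE)
    manifest$sex_linked[idx_sex] <- TRUE
    manifest$masked[idx_mask] <- TRUE

    # logit-space means: bimodal-ish baseline plus cluster offsets on the
    # informative subset, scaled so E||centroid_k - centroid_l|| = separation
    base_mu <- stats::rnorm(p, 0, 1.5)
    offset_sd <- cfg$cluster_separation / sqrt(2 * n_info)
    centroids <- matrix(0, K, p)
    centroids[, idx_info] <- stats::rnorm(K * n_info, 0, offset_sd)

    coefs <- rep_len(cfg$prognostic_log_hr, cfg$n_prognostic_cpgs)
    if (length(cfg$prognostic_log_hr) == 1 && cfg$n_prognostic_cpgs > 1) {
      coefs <- coefs * rep_len(c(1, -1), cfg$n_prognostic_cpgs)
    }
    # prognosis is partly a function of subtype: per-cluster hazard offsets
    cluster_hr <- stats::rnorm(K, 0, cfg$cluster_log_hr)
    cluster_hr <- cluster_hr - mean(cluster_hr)
    generative <- list(probe_ids = probe_ids, manifest = manifest,
                       base_mu = base_mu, centroids = centroids,
                       idx_info = idx_info, idx_prog = idx_prog,
                       coefs = coefs, cluster_hr = cluster_hr)
  } else {
    generative <- template$truth$generative
    .assert(!is.null(generative), "template lacks a generative model")
    .assert(length(generative$probe_ids) == p && nrow(generative$centroids) == K,
            "template dimensions do not match config (n_probes/n_subtypes)")
    probe_ids <- generative$probe_ids
    manifest <- generative$manifest
    base_mu <- generative$base_mu
    centroids <- generative$centroids
    idx_prog <- generative$idx_prog
    coefs <- generative$coefs
  }

  cluster <- sample(rep_len(seq_len(K), n))
  x <- matrix(stats::rnorm(n * p, 0, cfg$sigma_logit), n, p,
              dimnames = list(sample_ids, probe_ids))
  x <- x + rep(base_mu, each = n) + centroids[cluster, ]
  beta_clean <- stats::plogis(x)

  # planted survival signal on the M-value (log2 logit) scale, centered at
  # the population mean so eta is comparable across template-shared cohorts
  if (length(idx_prog) > 0) {
    m_prog <- x[, idx_prog, drop = FALSE] / log(2)
    m_center <- base_mu[idx_prog] / log(2)
    eta <- as.vector(sweep(m_prog, 2, m_center) %*% coefs)
  } else {
    eta <- rep(0, n)
  }
  eta <- eta + generative$cluster_hr[cluster]

  # nuisance layers
  batch <- sample(rep_len(seq_len(cfg$n_batches), n))
  beta <- beta_clean + cfg$batch_shift * (batch - 1)
  beta <- pmin(pmax(beta, 0), 1)   # argument order keeps the dim attributes
  if (cfg$missing_rate > 0) {
    beta[stats::runif(n * p) < cfg$missing_rate] <- NA_real_
  }

  os <- plant_survival(eta, config)
  # EFS: earlier failures from a proportional cause (relapse/induction failure)
  # sharing the same linear predictor at 1.5x the baseline hazard
  efs_cfg <- cfg
  efs_cfg$baseline_hazard <- 1.5 * cfg$baseline_hazard
  efs <- plant_survival(eta, structure(efs_cfg, class = "cohort_config"))
  efs_time <- pmin(os$os_time, efs$os_time)
  efs_event <- as.integer(efs$os_event == 1 | (os$os_event == 1 & os$os_time <= efs$os_time))

  # risk group from noisy tertiles of eta (an imperfect clinical proxy of the
  # epigenomic signal, as cytogenetic risk is in practice); MRD1 logistic in eta
  eta_sd <- max(stats::sd(eta), 1e-8)
  eta_noisy <- eta + stats::rnorm(n, 0, 1.5 * eta_sd)
  cuts <- stats::quantile(eta_noisy, c(1 / 3, 2 / 3))
  risk_group <- cut(eta_noisy, c(-Inf, cuts, Inf),
                    labels = c("low", "standard", "high"))
  mrd1 <- stats::rbinom(n, 1, stats::plogis(-1 + eta / eta_sd))

  subtype_levels <- c(paste0("AML_", seq_len(K - 1)), "control")
  clinical <- data.frame(
    sample_id = sample_ids,
    subtype = factor(subtype_levels[cluster], levels = subtype_levels),
    os_time = os$os_time, os_event = os$os_event,
    efs_time = efs_time, efs_event = efs_event,
    risk_group = factor(risk_group, levels = c("low", "standard", "high")),
    mrd1 = mrd1,
    age_years = round(stats::runif(n, 0.5, 18), 1),
    wbc = round(stats::rlnorm(n, log(20), 0.9), 1),
    batch = batch,
    stringsAsFactors = FALSE
  )

  truth <- list(cluster = cluster, batch = batch,
                prognostic_probes = probe_ids[idx_prog],
                prognostic_coefs = coefs, eta = eta,
                informative_probes = probe_ids[generative$idx_info],
                beta_clean = beta_clean, generative = generative)
  list(beta = beta, manifest = manifest, clinical = clinical, truth = truth)
}

#' Simulate survival endpoints from a Cox linear predictor
#'
#' Event times follow an exponential proportional-hazards model,
#' `T = -log(U) / (baseline_hazard * exp(eta))`. Loss to follow-up is uniform
#' on `[0, horizon]` and applied to a subject subset whose size is calibrated
#' by bisection so the realized censored-before-horizon fraction matches
#' `config$censoring_rate` to within 0.02 (when attainable); administrative
#' censoring at `horizon_months` is applied on top.
#'
#' @param eta Numeric vector of per-sample log-hazard offsets (finite).
#' @param config A [cohort_config()]; only `baseline_hazard`,
#'   `censoring_rate`, and `horizon_months` are used.
#' @return data.frame with `os_time` (months) and `os_event` (0/1).
#' @examples
#' cfg <- cohort_config(baseline_hazard = 0.02, censoring_rate = 0, seed = 1)
#' set.seed(1)
#' surv <- plant_survival(rep(0, 100), cfg)
#' mean(surv$os_event)
#' @export
plant_survival <- function(eta, config) {
  .assert(inherits(config, "cohort_config"), "config must come from cohort_config()")
  .assert(all(is.finite(eta)), "eta must be finite")
  .assert(config$baseline_hazard > 0, "baseline_hazard must be positive")
  n <- length(eta)
  horizon <- config$horizon_months
  t_event <- -log(stats::runif(n)) / (config$baseline_hazard * exp(eta))

  cap <- if (is.finite(horizon)) horizon else max(t_event) * 1.01
  v <- stats::runif(n, 0, cap)      # candidate loss-to-follow-up times
  u <- stats::runif(n)              # inclusion draws for the censoring layer
  rate_at <- function(q) {
    c_i <- ifelse(u < q, v, Inf)
    mean(c_i < pmin(t_event, horizon))
  }
  q <- 0
  if (config$censoring_rate > 0) {
    lo <- 0; hi <- 1
    if (rate_at(1) <= config$censoring_rate) {
      q <- 1
    } else {
      for (i in 1:40) {
        mid <- (lo + hi) / 2
        if (rate_at(mid) < config$censoring_rate) lo <- mid else hi <- mid
      }
      q <- (lo + hi) / 2
    }
  }
  c_i <- ifelse(u < q, v, Inf)
  os_time <- pmin(t_event, c_i, horizon)
  os_event <- as.integer(t_event <= c_i & t_event <= horizon)
  data.frame(os_time = os_time, os_event = os_event)
}

#' Write a sample's methylome as a modkit-dialect bedMethyl file
#'
#' Emits one 5mCG ("m") row per strand for every manifest probe. The manifest
#' `pos` is the 1-based hg38 position of the CpG cytosine on the + strand, so
#' the + strand row has 0-based `start = pos - 1` and the - strand (the G's
#' paired C) has `start = pos`. Per-strand coverage is drawn from a negative
#' binomial (Poisson-gamma) model — deterministic when `dispersion = 0` — and
#' modified counts are binomial in the sample's beta value.
#'
#' @param sample_beta Named numeric vector, probe id -> beta in \[0,1\].
#' @param manifest Probe manifest covering all names of `sample_beta`.
#' @param path Output file path (tab-separated, 18 columns as written by
#'   modkit `pileup`).
#' @param mean_coverage Mean per-strand read depth.
#' @param dispersion Negative-binomial dispersion; 0 gives constant coverage
#'   `round(mean_coverage)` per strand.
#' @return Invisibly, the data.frame of rows written (sorted by chrom, start).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_samples = 5, n_probes = 50, seed = 3))
#' bv <- ifelse(is.na(cohort$beta[1, ]), 0.5, cohort$beta[1, ])
#' f <- tempfile(fileext = ".bed")
#' write_bedmethyl(bv, cohort$manifest, f, mean_coverage = 10, dispersion = 0)
#' @export
write_bedmethyl <- function(sample_beta, manifest, path, mean_coverage = 30,
                            dispersion = 0) {
  .assert(!is.null(names(sample_beta)), "sample_beta must be named by probe id")
  .assert(all(names(sample_beta) %in% manifest$probe_id),
          "sample_beta has probes absent from the manifest")
  .assert(all(sample_beta >= 0 & sample_beta <= 1, na.rm = TRUE),
          "beta values must lie in [0, 1]")
  m <- manifest[match(names(sample_beta), manifest$probe_id), ]
  n <- length(sample_beta)

  draw_cov <- function(k) {
    if (dispersion <= 0) rep(as.integer(round(mean_coverage)), k)
    else stats::rnbinom(k, mu = mean_coverage, size = 1 / dispersion)
  }
  cov_plus <- draw_cov(n)
  cov_minus <- draw_cov(n)
  nmod_plus <- stats::rbinom(n, cov_plus, sample_beta)
  nmod_minus <- stats::rbinom(n, cov_minus, sample_beta)

  rows <- data.frame(
    chrom = rep(m$chrom, 2),
    start = c(m$pos - 1L, m$pos),
    end = c(m$pos, m$pos + 1L),
    code = "m",
    score = c(cov_plus, cov_minus),
    strand = rep(c("+", "-"), each = n),
    thick_start = c(m$pos - 1L, m$pos),
    thick_end = c(m$pos, m$pos + 1L),
    color = "255,0,0",
    n_valid = c(cov_plus, cov_minus),
    pct_mod = round(100 * c(nmod_plus, nmod_minus) / pmax(1, c(cov_plus, cov_minus)), 2),
    n_mod = c(nmod_plus, nmod_minus),
    n_canonical = c(cov_plus - nmod_plus, cov_minus - nmod_minus),
    n_other = 0L, n_delete = 0L, n_fail = 0L, n_diff = 0L, n_nocall = 0L,
    stringsAsFactors = FALSE
  )
  chrom_order <- unique(manifest$chrom)
  rows <- rows[order(match(rows$chrom, chrom_order), rows$start), ]
  ok <- tryCatch({
    data.table::fwrite(rows, path, sep = "\t", col.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("could not write bedMethyl file '", path, "': ",
                        conditionMessage(ok), call. = FALSE)
  invisible(rows)
}
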