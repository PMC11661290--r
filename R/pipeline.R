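# Discovery-training and specimen-to-result inference workflows wiring the
# stages together with explicit seeds and a written artifact manifest.

#' Configuration for the discovery workflow
#'
#' Collects every stage parameter and derives per-stage seeds from one master
#' seed, so a config plus seed reproduces the whole run bit-for-bit.
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param cohort Optional [cohort_config()]; by default a 600-sample,
#'   2000-probe, 6-subtype cohort with 10 planted prognostic CpGs, seeded from
#'   the master seed.
#' @param embedding_dims Embedding dimensionality used for classification.
#' @param p_threshold Suggestive screen threshold for the association scan.
#' @param stability_iters,stability_folds,min_freq Stability-selection
#'   settings. The default iteration count (100) is the package's
#'   synthetic-scale choice; raise it (the reference workflow uses 1000) for
#'   production cohorts.
#' @param subtype_folds,risk_folds Cross-validation folds for the classifiers.
#' @param horizon_months Administrative censoring horizon.
#' @param boost_grid Hyperparameter grid for the boosted classifiers.
#' @return list of class `discovery_config`.
#' @export
discovery_config <- function(seed = 1L, cohort = NULL, embedding_dims = 5,
                             p_threshold = 1e-5, stability_iters = 100,
                             stability_folds = 10, min_freq = 0.95,
                             subtype_folds = 5, risk_folds = 5,
                             horizon_months = 60,
                             boost_grid = .default_boost_grid()) {
  seed <- as.integer(seed)
  if (is.null(cohort)) cohort <- cohort_config(seed = .derive_seed(seed, 1))
  structure(list(seed = seed, cohort = cohort,
                 embedding_dims = embedding_dims, p_threshold = p_threshold,
                 stability_iters = stability_iters,
                 stability_folds = stability_folds, min_freq = min_freq,
                 subtype_folds = subtype_folds, risk_folds = risk_folds,
                 horizon_months = horizon_months, boost_grid = boost_grid,
                 embedding_seed = .derive_seed(seed, 2),
                 subtype_seed = .derive_seed(seed, 3),
                 risk_seed = .derive_seed(seed, 4),
                 stability_seed = .derive_seed(seed, 5)),
            class = "discovery_config")
}

#' Run the discovery-training workflow
#'
#' Executes the full atlas-building pipeline on a cohort: QC and batch
#' harmonization, 5-D atlas embedding, subtype and mortality classifiers on
#' the coordinates, the epigenome-wide Cox scan, suggestive screen, stability
#' selection, signature fit, and a survival evaluation (Kaplan-Meier, log-rank,
#' Cox hazard ratio, five-year AUCs, score correlation). When the screen or
#' the stability selection comes back empty, the signature stages are skipped
#' and reported as such. If `out_dir` is given, plain-text artifacts plus a
#' manifest of their MD5 hashes are written there.
#'
#' @param config A [discovery_config()].
#' @param data Optional list with `beta`, `manifest`, `clinical` (and
#'   optionally `truth`) to use instead of generating a synthetic cohort.
#' @param out_dir Optional output directory for artifacts.
#' @return list with the cohort, QC output, atlas, models, EWAS table,
#'   stability result, signature, evaluation, reference means, and gating
#'   class set.
#' @export
run_discovery <- function(config = discovery_config(), data = NULL,
                          out_dir = NULL) {
  .assert(inherits(config, "discovery_config"),
          "config must come from discovery_config()")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  cohort <- stage("synthetic_cohort",
                  if (is.null(data)) generate_cohort(config$cohort) else data)
  clinical <- cohort$clinical
  batches <- clinical$batch[match(rownames(cohort$beta), clinical$sample_id)]

  qc <- stage("qc_preprocess",
              qc_pipeline(cohort$beta, cohort$manifest, batches = batches))
  clinical <- clinical[match(rownames(qc$beta), clinical$sample_id), ]

  atlas <- stage("atlas_embedding",
                 fit_embedding(qc$beta, n_dims = config$embedding_dims,
                               seed = config$embedding_seed))
  coords <- atlas$coords

  subtype <- stage("train_subtype",
                   train_subtype(coords, clinical$subtype,
                                 n_folds = config$subtype_folds,
                                 seed = config$subtype_seed,
                                 grid = config$boost_grid))
  risk <- stage("train_risk",
                train_risk(coords, clinical$os_time, clinical$os_event,
                           n_folds = config$risk_folds,
                           seed = config$risk_seed,
                           grid = config$boost_grid,
                           horizon = config$horizon_months))

  m <- beta_to_m(qc$beta)
  ewas <- stage("cox_ewas",
                cox_ewas(m, clinical, adjust = "risk_group",
                         horizon_months = config$horizon_months,
                         manifest = cohort$manifest))
  suggestive <- select_suggestive(ewas, config$p_threshold)

  stability <- NULL
  signature <- NULL
  if (length(suggestive) >= 2) {
    stability <- stage("stability_select",
                       stability_select(m, clinical, candidates = suggestive,
                                        n_iter = config$stability_iters,
                                        n_folds = config$stability_folds,
                                        min_freq = config$min_freq,
                                        seed = config$stability_seed,
                                        horizon_months = config$horizon_months))
    if (length(stability$selected) >= 1) {
      signature <- stage("fit_signature",
                         fit_signature(m, stability$selected, clinical,
                                       horizon_months = config$horizon_months))
    }
  }

  # survival evaluation on the discovery cohort
  cens <- .censor_at(clinical$os_time, clinical$os_event,
                     config$horizon_months)
  risk_prob <- predict_risk(risk, coords)
  evaluation <- list(
    subtype_cv = subtype$cv_metrics[c("accuracy", "macro_f1", "weighted_f1",
                                      "kappa")],
    per_class_concordance = as.list(subtype$per_class_concordance),
    risk_cv_auc = risk$cv_auc,
    risk_auc_5y = as.numeric(auc_5y(risk_prob, clinical$os_time,
                                    clinical$os_event,
                                    config$horizon_months))
  )
  if (!is.null(signature)) {
    sg <- score_and_group(signature, m)
    lr <- logrank_test(cens$time, cens$event, sg$group)
    cx <- cox_fit(data.frame(signature_group = sg$group), cens$time,
                  cens$event)
    evaluation$signature <- list(
      n_probes = length(signature$probes), cutoff = signature$cutoff,
      hr_high_vs_low = cx$hr[1], hr_lower = cx$lower[1],
      hr_upper = cx$upper[1], cox_p = cx$p[1], logrank_p = lr$p,
      auc_5y = as.numeric(auc_5y(sg$score, clinical$os_time,
                                 clinical$os_event, config$horizon_months)),
      cor_with_risk_prob = stats::cor(risk_prob, sg$score)
    )
  } else {
    evaluation$signature <- list(n_probes = 0)
    message("signature stage empty; survival evaluation of the signature skipped")
  }

  gate_classes <- grep("^control$", levels(clinical$subtype), value = TRUE,
                       invert = TRUE)
  result <- list(config = config, cohort = cohort, qc = qc,
                 clinical = clinical, atlas = atlas, subtype = subtype,
                 risk = risk, ewas = ewas, suggestive = suggestive,
                 stability = stability, signature = signature,
                 evaluation = evaluation,
                 reference_means = colMeans(qc$beta),
                 gate_classes = gate_classes)
  if (!is.null(out_dir)) {
    result$artifact_manifest <- .write_artifacts(result, out_dir)
  }
  result
}

# Write plain-text artifacts and an MD5 manifest; all writers are
# deterministic (no timestamps).
#' @keywords internal
#' @noRd
.write_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wj <- function(x, file) {
    jsonlite::write_json(x, file.path(out_dir, file), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  }
  wj(result$qc$report, "qc_report.json")
  coords_df <- data.frame(sample_id = rownames(result$atlas$coords),
                          result$atlas$coords)
  data.table::fwrite(coords_df, file.path(out_dir, "atlas_coords.tsv"),
                     sep = "\t")
  data.table::fwrite(as.data.frame(result$ewas),
                     file.path(out_dir, "ewas.tsv"), sep = "\t")
  if (!is.null(result$stability)) {
    data.table::fwrite(result$stability$frequency,
                       file.path(out_dir, "stability.tsv"), sep = "\t")
  }
  if (!is.null(result$signature)) {
    wj(list(probes = result$signature$probes,
            coefficients = as.list(result$signature$coefficients),
            cutoff = result$signature$cutoff,
            method = result$signature$method,
            horizon_months = result$signature$horizon_months),
       "signature.json")
  }
  wj(result$evaluation, "evaluation.json")
  rm_df <- data.frame(probe_id = names(result$reference_means),
                      mean_beta = unname(result$reference_means))
  data.table::fwrite(rm_df, file.path(out_dir, "reference_means.tsv"),
                     sep = "\t")
  files <- sort(setdiff(list.files(out_dir), "artifact_manifest.json"))
  hashes <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(hashes) <- files
  wj(hashes, "artifact_manifest.json")
  hashes
}

#' Run specimen-to-result inference on bedMethyl files
#'
#' Applies the fitted discovery artifacts to nanopore samples: parse the
#' bedMethyl calls, collapse strands onto the manifest loci with the coverage
#' filter, restrict to the atlas probe set, impute missing features with
#' discovery-cohort means, project, classify, and apply the prognostic models
#' behind the subtype/confidence gate.
#'
#' @param discovery A [run_discovery()] result (or a list providing `atlas`,
#'   `subtype`, `risk`, `signature`, `reference_means`, `gate_classes`, and
#'   `cohort$manifest`).
#' @param bed_paths Named character vector of bedMethyl paths (names become
#'   sample ids).
#' @param min_coverage Pooled-coverage keep threshold (strictly greater-than).
#' @param gate_conf Confidence gate for the prognostic models.
#' @return list with `reports` (one `sample_report` per input) and `summary`
#'   (one row per sample).
#' @export
run_inference <- function(discovery, bed_paths, min_coverage = 5,
                          gate_conf = 0.5) {
  for (part in c("atlas", "subtype", "reference_means", "gate_classes")) {
    .assert(!is.null(discovery[[part]]),
            "missing trained artifact '%s' in discovery input", part)
  }
  manifest <- discovery$cohort$manifest
  .assert(!is.null(manifest), "missing trained artifact 'cohort$manifest'")
  if (is.null(names(bed_paths)) && length(bed_paths) > 0) {
    names(bed_paths) <- tools::file_path_sans_ext(basename(bed_paths))
  }
  reports <- vector("list", length(bed_paths))
  names(reports) <- names(bed_paths)
  for (i in seq_along(bed_paths)) {
    recs <- parse_bedmethyl(bed_paths[i])
    x <- collapse_and_map(recs, manifest, min_coverage = min_coverage)
    x <- x[discovery$atlas$probe_ids]
    x <- impute_reference_means(x, discovery$reference_means)
    reports[[i]] <- report_sample(
      x, discovery$atlas, discovery$subtype, discovery$risk,
      discovery$signature, gate_classes = discovery$gate_classes,
      gate_conf = gate_conf, sample_id = names(bed_paths)[i])
  }
  summary <- data.frame(
    sample_id = names(bed_paths),
    top_subtype = vapply(reports, function(r) r$top_subtype, character(1)),
    confidence = vapply(reports, function(r) r$confidence, numeric(1)),
    gated = vapply(reports, function(r) r$gated, logical(1)),
    risk_prob = vapply(reports, function(r) r$risk_prob, numeric(1)),
    signature_score = vapply(reports, function(r) r$signature_score,
                             numeric(1)),
    signature_group = vapply(reports, function(r)
      as.character(r$signature_group), character(1)),
    imputed_fraction = vapply(reports, function(r) r$imputed_fraction,
                              numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(reports = reports, summary = summary)
}
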