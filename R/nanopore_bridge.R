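# Bridge from nanopore 5mCG calls (modkit-dialect bedMethyl) into the array
# feature space: parse, strand-collapse onto manifest loci, coverage filter,
# reference-mean imputation, and a gated per-sample report.

#' Parse a modkit-dialect bedMethyl file
#'
#' Reads BED9+ rows as written by modkit pileup (tab- or space-separated tail
#' columns). Only 5mCG rows (mod code `"m"`) are returned; `"h"`
#' (hydroxymethylation) rows are skipped and counted in the `n_skipped_h`
#' attribute. Malformed rows and modified counts exceeding coverage raise an
#' error naming the line.
#'
#' @param path Path to a bedMethyl file.
#' @return data.frame with `chrom`, `start` (0-based), `end`, `strand`,
#'   `coverage` (valid calls), `n_mod`; attributes `n_skipped_h` and
#'   `n_skipped_other`.
#' @export
parse_bedmethyl <- function(path) {
  .assert(file.exists(path), "bedMethyl file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n_h <- 0L
  n_other <- 0L
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) < 11) {
      stop(sprintf("malformed bedMethyl row at line %d: expected >= 11 fields, got %d",
                   i, length(f)), call. = FALSE)
    }
    code <- f[4]
    if (code %in% c("h", "h,0", "h,CG,0")) { n_h <- n_h + 1L; next }
    if (!code %in% c("m", "m,0", "m,CG,0")) { n_other <- n_other + 1L; next }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    coverage <- suppressWarnings(as.numeric(f[10]))
    if (anyNA(c(start, end, coverage))) {
      stop(sprintf("malformed bedMethyl row at line %d: non-numeric coordinates or coverage", i),
           call. = FALSE)
    }
    n_mod <- if (length(f) >= 12) suppressWarnings(as.numeric(f[12]))
             else round(suppressWarnings(as.numeric(f[11])) / 100 * coverage)
    if (is.na(n_mod)) {
      stop(sprintf("malformed bedMethyl row at line %d: unreadable modified count", i),
           call. = FALSE)
    }
    if (n_mod > coverage) {
      stop(sprintf("line %d: modified count %g exceeds valid coverage %g",
                   i, n_mod, coverage), call. = FALSE)
    }
    rows[[i]] <- data.frame(chrom = f[1], start = start, end = end,
                            strand = f[6], coverage = coverage, n_mod = n_mod,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), coverage = numeric(),
                      n_mod = numeric(), stringsAsFactors = FALSE)
  }
  attr(out, "n_skipped_h") <- n_h
  attr(out, "n_skipped_other") <- n_other
  out
}

#' Collapse strand-level calls onto manifest CpG loci
#'
#' For each manifest probe (1-based + strand cytosine position `pos`), pools
#' the + strand record at 0-based `start = pos - 1` and the - strand record at
#' `start = pos` by summing counts: `beta = sum(n_mod) / sum(coverage)`
#' (coverage-weighted, exact). A probe is set missing when its pooled coverage
#' is `<= min_coverage` (the "> 5x" keep rule is strict). Records at
#' non-manifest loci are ignored. Strand-combined records (strand `"."`) are
#' accepted at the + strand start.
#'
#' @param records Parsed records from [parse_bedmethyl()].
#' @param manifest Probe manifest.
#' @param min_coverage Pooled-coverage threshold; loci at or below it are
#'   missing.
#' @param per_strand Apply the coverage threshold per strand instead of after
#'   pooling (off by default).
#' @return Named numeric vector probe -> beta with `NA` for missing probes;
#'   attribute `n_unmatched_records`.
#' @export
collapse_and_map <- function(records, manifest, min_coverage = 5,
                             per_strand = FALSE) {
  key_plus <- paste0(manifest$chrom, ":", manifest$pos - 1L)
  key_minus <- paste0(manifest$chrom, ":", manifest$pos)
  rec_key <- paste0(records$chrom, ":", records$start)

  use_plus <- records$strand %in% c("+", ".")
  use_minus <- records$strand == "-"
  i_plus <- match(rec_key, key_plus)
  i_minus <- match(rec_key, key_minus)

  probe_idx <- ifelse(use_plus, i_plus, ifelse(use_minus, i_minus, NA))
  matched <- !is.na(probe_idx)
  n_unmatched <- sum(!matched)

  cov <- stats::setNames(numeric(nrow(manifest)), manifest$probe_id)
  nmod <- cov
  if (any(matched)) {
    r <- records[matched, , drop = FALSE]
    idx <- probe_idx[matched]
    if (per_strand) {
      ok <- r$coverage > min_coverage
      r <- r[ok, , drop = FALSE]
      idx <- idx[ok]
    }
    if (nrow(r) > 0) {
      cov_add <- rowsum(r$coverage, idx)
      nmod_add <- rowsum(r$n_mod, idx)
      ids <- as.integer(rownames(cov_add))
      cov[ids] <- cov[ids] + cov_add[, 1]
      nmod[ids] <- nmod[ids] + nmod_add[, 1]
    }
  }
  beta <- ifelse(cov > min_coverage, nmod / pmax(cov, 1), NA_real_)
  names(beta) <- manifest$probe_id
  attr(beta, "n_unmatched_records") <- n_unmatched
  beta
}

#' Impute missing atlas features with discovery-cohort means
#'
#' @param x Named probe -> beta vector with `NA` for missing loci.
#' @param reference_means Named probe -> mean beta vector covering every probe
#'   of `x`.
#' @return Completed vector with attribute `imputed_fraction`; warns when
#'   every value was imputed.
#' @export
impute_reference_means <- function(x, reference_means) {
  missing_ref <- setdiff(names(x)[is.na(x)], names(reference_means))
  .assert(length(missing_ref) == 0,
          "no reference mean for missing probe(s): %s",
          paste(utils::head(missing_ref, 5), collapse = ", "))
  idx <- is.na(x)
  out <- x
  out[idx] <- reference_means[names(x)[idx]]
  frac <- mean(idx)
  if (frac == 1) warning("all features were imputed from reference means")
  attr(out, "imputed_fraction") <- frac
  attr(out, "n_unmatched_records") <- attr(x, "n_unmatched_records")
  out
}

#' Diagnostic/prognostic report for one nanopore sample
#'
#' Projects a complete atlas feature vector into the fitted embedding,
#' predicts the subtype, and — only when the top subtype belongs to
#' `gate_classes` with confidence strictly above `gate_conf` — applies the
#' mortality classifier and the CpG hazard signature (whose M-values come from
#' the same vector). Otherwise the prognostic fields are marked not
#' applicable.
#'
#' @param x Named probe -> beta vector, complete over the atlas probe set
#'   (typically from [impute_reference_means()]).
#' @param atlas An [fit_embedding()] model.
#' @param subtype_model A [train_subtype()] model.
#' @param risk_model Optional [train_risk()] model.
#' @param signature_model Optional [fit_signature()] model.
#' @param gate_classes Subtype labels (AML/MDS-like) that open the prognostic
#'   gate.
#' @param gate_conf Confidence threshold (strictly greater-than).
#' @param sample_id Identifier recorded in the report.
#' @return Object of class `sample_report`.
#' @export
report_sample <- function(x, atlas, subtype_model, risk_model = NULL,
                          signature_model = NULL, gate_classes,
                          gate_conf = 0.5, sample_id = "sample") {
  .assert(!anyNA(x), "feature vector has missing values; impute first")
  mat <- matrix(x, 1, dimnames = list(sample_id, names(x)))
  coords <- project_samples(atlas, mat)
  pred <- predict_subtype(subtype_model, coords)
  gated <- pred$label[1] %in% gate_classes && pred$confidence[1] > gate_conf

  risk_prob <- NA_real_
  sig_score <- NA_real_
  sig_group <- NA_character_
  if (gated) {
    if (!is.null(risk_model)) risk_prob <- predict_risk(risk_model, coords)
    if (!is.null(signature_model)) {
      mvals <- beta_to_m(x[signature_model$probes])
      sg <- score_and_group(signature_model,
                            matrix(mvals, 1,
                                   dimnames = list(sample_id,
                                                   signature_model$probes)))
      sig_score <- unname(sg$score)
      sig_group <- as.character(sg$group)
    }
  }
  structure(list(sample_id = sample_id, coords = coords,
                 subtype_probs = pred$probs[1, ],
                 top_subtype = pred$label[1],
                 confidence = unname(pred$confidence[1]),
                 gated = gated, gate_classes = gate_classes,
                 gate_conf = gate_conf, risk_prob = unname(risk_prob),
                 signature_score = sig_score, signature_group = sig_group,
                 imputed_fraction = attr(x, "imputed_fraction") %||% 0),
            class = "sample_report")
}

#' @export
print.sample_report <- function(x, ...) {
  cat(sprintf("Sample %s: %s (confidence %.3f)\n", x$sample_id,
              x$top_subtype, x$confidence))
  if (x$gated) {
    if (!is.na(x$risk_prob)) {
      cat(sprintf("  5-year mortality probability: %.3f\n", x$risk_prob))
    }
    if (!is.na(x$signature_score)) {
      cat(sprintf("  signature score %.3f -> %s\n", x$signature_score,
                  x$signature_group))
    }
  } else {
    cat("  prognostic models not applicable (gate not passed)\n")
  }
  cat(sprintf("  imputed feature fraction: %.3f\n", x$imputed_fraction))
  invisible(x)
}
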