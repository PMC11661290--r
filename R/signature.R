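# Stepwise CpG hazard-signature pipeline: per-probe Cox association scan,
# suggestive screen, stability-selected L1 Cox, joint refit, median cutoff.

#' Epigenome-wide Cox proportional-hazards association scan
#'
#' Fits, for every probe, a Cox model of overall survival on the probe's
#' M-value plus risk-group indicator covariates (Efron tie handling), with
#' follow-up administratively censored at `horizon_months`. Reports the Wald
#' statistics on the probe coefficient (log hazard ratio per M-value unit).
#'
#' @param m Samples x probes M-value matrix (no missing values).
#' @param clinical data.frame with `os_time`, `os_event`, and the adjustment
#'   columns, aligned with the rows of `m`.
#' @param adjust Character vector of clinical covariates to adjust for
#'   (default `"risk_group"`, encoded as factor indicators against the first
#'   level).
#' @param horizon_months Administrative censoring horizon.
#' @return data.frame of class `ewas_result`: `probe`, `coef`, `se`, `z`, `p`
#'   (and `chrom`/`pos` if `manifest` is given). Zero-variance probes are
#'   omitted; non-converging probes keep `NA` p with a warning count in the
#'   `n_nonconverged` attribute.
#' @param manifest Optional probe manifest to attach genomic coordinates for
#'   Manhattan-style output.
#' @export
cox_ewas <- function(m, clinical, adjust = "risk_group", horizon_months = 60,
                     manifest = NULL) {
  .assert(is.matrix(m) && is.numeric(m), "m must be a numeric matrix")
  .assert(!anyNA(m), "M-value matrix must be complete")
  .assert(all(c("os_time", "os_event", adjust) %in% names(clinical)),
          "clinical must contain os_time, os_event and adjustment columns")
  .assert(nrow(clinical) == nrow(m), "clinical must align with m rows")
  cens <- .censor_at(clinical$os_time, clinical$os_event, horizon_months)
  y <- survival::Surv(cens$time, cens$event)

  adj_mm <- NULL
  if (length(adjust) > 0) {
    adj_mm <- stats::model.matrix(
      stats::reformulate(adjust), data = clinical)[, -1, drop = FALSE]
  }

  probes <- colnames(m)
  keep <- apply(m, 2, stats::sd) > 0
  n_skipped <- sum(!keep)
  probes <- probes[keep]
  res <- matrix(NA_real_, length(probes), 4,
                dimnames = list(probes, c("coef", "se", "z", "p")))
  n_nonconv <- 0L
  for (j in seq_along(probes)) {
    x <- cbind(m[, probes[j]], adj_mm)
    fit <- tryCatch({
      withCallingHandlers(
        survival::coxph(y ~ x, ties = "efron"),
        warning = function(w) {
          if (grepl("converge|infinite|loglik", conditionMessage(w))) {
            n_nonconv <<- n_nonconv + 1L
            invokeRestart("muffleWarning")
          }
        })
    }, error = function(e) NULL)
    if (is.null(fit)) next
    co <- summary(fit)$coefficients
    if (is.na(co[1, "coef"]) || !is.finite(co[1, "se(coef)"])) next
    res[j, ] <- c(co[1, "coef"], co[1, "se(coef)"], co[1, "z"],
                  co[1, "Pr(>|z|)"])
  }
  out <- data.frame(probe = probes, res, row.names = NULL,
                    stringsAsFactors = FALSE)
  if (!is.null(manifest)) {
    i <- match(out$probe, manifest$probe_id)
    out$chrom <- manifest$chrom[i]
    out$pos <- manifest$pos[i]
  }
  if (n_nonconv > 0) {
    warning(sprintf("%d probe fits flagged as non-converged", n_nonconv))
  }
  attr(out, "n_skipped_zero_variance") <- n_skipped
  attr(out, "n_nonconverged") <- n_nonconv
  class(out) <- c("ewas_result", "data.frame")
  out
}

#' Screen association results at a suggestive p-value threshold
#'
#' @param ewas A [cox_ewas()] result.
#' @param p_threshold Suggestive threshold; probes with `p` strictly below it
#'   are kept (a probe at exactly the threshold is excluded).
#' @return Character vector of probe ids sorted by ascending p (possibly
#'   empty).
#' @export
select_suggestive <- function(ewas, p_threshold = 1e-5) {
  keep <- !is.na(ewas$p) & ewas$p < p_threshold
  hits <- ewas[keep, , drop = FALSE]
  if (nrow(hits) == 0) {
    message("no probes pass the suggestive threshold; signature pipeline halts")
    return(character(0))
  }
  hits$probe[order(hits$p)]
}

#' Stability selection by iterated cross-validated L1 Cox regression
#'
#' Repeats, `n_iter` times: re-randomize an event-stratified `n_folds`-fold
#' assignment, pick the L1 penalty minimizing mean cross-validated partial-
#' likelihood deviance over a fixed 50-point log-spaced grid (from the
#' smallest penalty zeroing all coefficients down four decades), then record
#' which probes carry non-zero coefficients in a penalized Cox fit at that
#' penalty. By default (`resample = "subsample"`) the recorded fit uses a
#' random half of the samples, the Meinshausen-Buehlmann stability-selection
#' element: without it the full-data fit at a given penalty is deterministic,
#' selection frequencies collapse to 0/1, and the `min_freq` threshold loses
#' its false-positive control. `resample = "none"` records the full-data fit
#' (fold randomization is then the only stochastic element);
#' `resample = "bootstrap"` resamples n draws with replacement. Probes with
#' selection frequency at least `min_freq` form the signature candidate set.
#'
#' @param m Samples x probes M-value matrix restricted (or restrictable via
#'   `candidates`) to the screened probes; >= 2 candidates.
#' @param clinical data.frame with `os_time`, `os_event`.
#' @param candidates Probe ids to evaluate (default: all columns of `m`).
#' @param n_iter Number of selection iterations.
#' @param n_folds Cross-validation folds per iteration (requires at least that
#'   many events).
#' @param min_freq Selection-frequency threshold ("at least 95%").
#' @param seed Integer seed.
#' @param horizon_months Administrative censoring horizon.
#' @param resample How the recorded fit resamples rows per iteration
#'   (see Details above).
#' @param subsample_frac Fraction of samples in the recorded fit when
#'   `resample = "subsample"`.
#' @return list with `frequency` (data.frame probe/frequency, descending),
#'   `selected` (probe ids at `min_freq`, possibly empty), `n_iter`,
#'   `resample`, and `lambda_grid`.
#' @export
stability_select <- function(m, clinical, candidates = colnames(m),
                             n_iter = 1000, n_folds = 10, min_freq = 0.95,
                             seed = 42, horizon_months = 60,
                             resample = c("subsample", "none", "bootstrap"),
                             subsample_frac = 0.5) {
  resample <- match.arg(resample)
  .assert(length(candidates) >= 2, "need at least 2 candidate probes")
  .assert(all(candidates %in% colnames(m)), "candidates must be columns of m")
  x <- m[, candidates, drop = FALSE]
  cens <- .censor_at(clinical$os_time, clinical$os_event, horizon_months)
  .assert(sum(cens$event) >= n_folds,
          "need at least n_folds = %d events, got %d", n_folds, sum(cens$event))
  y <- survival::Surv(cens$time, cens$event)

  lmax <- max(glmnet::glmnet(x, y, family = "cox", alpha = 1,
                             nlambda = 3)$lambda)
  lambda_grid <- exp(seq(log(lmax), log(lmax) - 4 * log(10), length.out = 50))

  n <- nrow(x)
  set.seed(seed)
  counts <- stats::setNames(numeric(length(candidates)), candidates)
  for (it in seq_len(n_iter)) {
    foldid <- .stratified_folds(cens$event, n_folds)
    cv <- glmnet::cv.glmnet(x, y, family = "cox", alpha = 1,
                            lambda = lambda_grid, foldid = foldid,
                            type.measure = "deviance")
    if (resample == "none") {
      fit <- cv$glmnet.fit
    } else {
      idx <- if (resample == "subsample") {
        sample.int(n, max(n_folds + 1, floor(subsample_frac * n)))
      } else {
        sample.int(n, n, replace = TRUE)
      }
      # warm-started path truncated at the chosen penalty keeps the
      # saturated small-penalty region out of the fit
      fit <- glmnet::glmnet(x[idx, , drop = FALSE], y[idx, ],
                            family = "cox", alpha = 1,
                            lambda = lambda_grid[lambda_grid >=
                                                   cv$lambda.min * 0.999])
    }
    co <- as.vector(glmnet::coef.glmnet(fit, s = cv$lambda.min))
    counts[co != 0] <- counts[co != 0] + 1
  }
  freq <- counts / n_iter
  selected <- names(freq)[freq >= min_freq]
  if (length(selected) == 0) {
    message("stability selection: no probe reached the frequency threshold")
  }
  list(frequency = data.frame(probe = names(freq), frequency = unname(freq),
                              stringsAsFactors = FALSE)[order(-freq), ],
       selected = selected, n_iter = n_iter, resample = resample,
       lambda_grid = lambda_grid)
}

#' Fit the linear M-value hazard signature
#'
#' Joint (multivariable, unpenalized) Cox fit of overall survival on the
#' selected probes' M-values, with follow-up censored at `horizon_months`.
#' The signature score of a sample is the linear combination
#' `sum_i coef_i * M_i`; the dichotomization cutoff is the median training
#' score. Collinear probe sets fall back to a ridge fit (penalty 1e-3) with a
#' warning; that fallback (or `penalized = TRUE`) stores penalized
#' coefficients instead.
#'
#' @param m Samples x probes M-value matrix containing the selected probes.
#' @param probes Selected probe ids (>= 1).
#' @param clinical data.frame with `os_time`, `os_event`.
#' @param horizon_months Administrative censoring horizon.
#' @param penalized Use ridge-penalized coefficients even when the joint fit
#'   is well-posed.
#' @return Object of class `signature_model`: `probes`, `coefficients`,
#'   `cutoff`, `horizon_months`, `method`.
#' @export
fit_signature <- function(m, probes, clinical, horizon_months = 60,
                          penalized = FALSE) {
  .assert(length(probes) >= 1, "need at least one selected probe")
  .assert(all(probes %in% colnames(m)), "probes missing from M matrix: %s",
          paste(setdiff(probes, colnames(m)), collapse = ", "))
  x <- m[, probes, drop = FALSE]
  cens <- .censor_at(clinical$os_time, clinical$os_event, horizon_months)
  y <- survival::Surv(cens$time, cens$event)

  method <- "joint_cox_refit"
  coefs <- NULL
  if (!penalized) {
    fit <- tryCatch(survival::coxph(y ~ x, ties = "efron"),
                    warning = function(w) w, error = function(e) NULL)
    if (inherits(fit, "coxph") && !anyNA(stats::coef(fit))) {
      coefs <- stats::setNames(as.vector(stats::coef(fit)), probes)
    }
  }
  if (is.null(coefs)) {
    if (!penalized) warning("joint Cox fit ill-posed; using ridge fallback")
    method <- "ridge_penalized"
    if (length(probes) == 1) {
      # glmnet needs >= 2 columns; a 1-probe ridge is just a shrunk slope
      fit <- survival::coxph(y ~ x, ties = "efron")
      coefs <- stats::setNames(as.vector(stats::coef(fit)), probes)
    } else {
      fit <- glmnet::glmnet(x, y, family = "cox", alpha = 0, lambda = 1e-3,
                            standardize = FALSE)
      coefs <- stats::setNames(as.vector(glmnet::coef.glmnet(fit, s = 1e-3)),
                               probes)
    }
  }
  scores <- as.vector(x %*% coefs)
  structure(list(probes = probes, coefficients = coefs,
                 cutoff = stats::median(scores),
                 horizon_months = horizon_months, method = method),
            class = "signature_model")
}

#' Score samples and assign signature risk groups
#'
#' @param model A [fit_signature()] result.
#' @param m Samples x probes M-value matrix covering the signature probes.
#' @return list with `score` (named numeric) and `group` (factor `low`/`high`;
#'   `high` iff score strictly exceeds the cutoff, ties assigned `low`).
#' @export
score_and_group <- function(model, m) {
  .assert(inherits(model, "signature_model"), "model must be a signature_model")
  if (is.null(dim(m))) m <- matrix(m, 1, dimnames = list("sample", names(m)))
  missing <- setdiff(model$probes, colnames(m))
  .assert(length(missing) == 0, "signature probes missing from input: %s",
          paste(missing, collapse = ", "))
  score <- as.vector(m[, model$probes, drop = FALSE] %*% model$coefficients)
  names(score) <- rownames(m)
  group <- factor(ifelse(score > model$cutoff, "high", "low"),
                  levels = c("low", "high"))
  list(score = score, group = group)
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("CpG hazard signature: %d probes (%s), median cutoff %.4f\n",
              length(x$probes), x$method, x$cutoff))
  invisible(x)
}
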