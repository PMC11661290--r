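# Survival evaluation layer: Kaplan-Meier, log-rank, Cox reporting, 5-year ROC.

#' Kaplan-Meier product-limit estimate
#'
#' Product-limit estimator with Greenwood variance on the log scale (the
#' survival package's default confidence construction).
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators (0/1).
#' @param conf_level Confidence level for the Greenwood interval.
#' @return data.frame of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `surv`, `lower`, `upper` at each observed time.
#' @export
km_estimate <- function(times, events, conf_level = 0.95) {
  .assert(length(times) > 0, "empty survival input")
  .assert(all(times >= 0), "times must be non-negative")
  .assert(length(events) == length(times), "times and events must align")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log", conf.int = conf_level)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv,
                    lower = ifelse(is.na(fit$lower), 0, fit$lower),
                    upper = ifelse(is.na(fit$upper), 1, fit$upper))
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Log-rank test for group survival differences
#'
#' Standard (unweighted) log-rank statistic with a chi-square reference on
#' `g - 1` degrees of freedom.
#'
#' @param times,events Survival data.
#' @param groups Group label per sample (>= 2 non-empty groups).
#' @return list with `chi2`, `df`, `p`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.factor(groups)
  .assert(nlevels(droplevels(groups)) >= 2, "need at least 2 non-empty groups")
  .assert(sum(events) >= 1, "need at least one event")
  fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(fit$n) - 1
  list(chi2 = fit$chisq, df = df,
       p = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Multivariable Cox proportional-hazards report
#'
#' Partial-likelihood Newton-Raphson fit (Efron tie handling) via the survival
#' package, reporting hazard ratio, Wald 95% confidence interval, and p-value
#' per covariate — the forest-plot quantities. Rows with missing covariates
#' are dropped and counted. Coefficients with `|coef| > 20` are flagged as
#' likely separation.
#'
#' @param design data.frame of covariates (factors use their first level as
#'   reference).
#' @param times,events Survival data aligned with `design`.
#' @param conf_level Confidence level.
#' @return data.frame of class `cox_fit_result` with `term`, `hr`, `lower`,
#'   `upper`, `p`, `separation`; attributes `n_dropped` and `n_used`.
#' @export
cox_fit <- function(design, times, events, conf_level = 0.95) {
  design <- as.data.frame(design)
  .assert(nrow(design) == length(times) && length(times) == length(events),
          "design, times, and events must align")
  complete <- stats::complete.cases(design)
  n_dropped <- sum(!complete)
  design <- design[complete, , drop = FALSE]
  times <- times[complete]
  events <- events[complete]
  dat <- cbind(design, .time = times, .event = events)
  fit <- survival::coxph(
    stats::as.formula(paste("survival::Surv(.time, .event) ~",
                            paste(names(design), collapse = " + "))),
    data = dat, ties = "efron")
  if (!is.null(fit$info) && grepl("not converge", paste(fit$info, collapse = ""))) {
    stop("Cox fit did not converge", call. = FALSE)
  }
  s <- summary(fit, conf.int = conf_level)
  co <- s$coefficients
  ci <- s$conf.int
  out <- data.frame(term = rownames(co), hr = unname(co[, "exp(coef)"]),
                    lower = unname(ci[, 3]), upper = unname(ci[, 4]),
                    p = unname(co[, "Pr(>|z|)"]),
                    separation = abs(unname(co[, "coef"])) > 20,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- n_dropped
  attr(out, "n_used") <- sum(complete)
  class(out) <- c("cox_fit_result", "data.frame")
  out
}

#' Five-year ROC AUC of a prognostic score
#'
#' AUC of a continuous score against the binary dead-by-horizon outcome,
#' computed rank-based (Mann-Whitney). Only samples with determinate status
#' enter: events before the horizon count as dead, follow-up reaching the
#' horizon as alive; samples censored earlier are excluded.
#'
#' @param score Continuous risk score (higher = worse).
#' @param times,events Survival data.
#' @param horizon Horizon in months (60 for the five-year endpoint).
#' @return Scalar AUC; attribute `n_used` gives the determinate sample count.
#' @export
auc_5y <- function(score, times, events, horizon = 60) {
  .assert(length(score) == length(times) && length(times) == length(events),
          "score, times, and events must align")
  status <- .status_at_horizon(times, events, horizon)
  keep <- !is.na(status)
  .assert(any(status[keep]) && any(!status[keep]),
          "AUC undefined: only one outcome class among determinate samples")
  out <- .rank_auc(score[keep], status[keep])
  attr(out, "n_used") <- sum(keep)
  out
}
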