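# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
.assert <- function(cond, ..., call. = FALSE) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = call.)
}

# Validate a beta matrix: numeric matrix, samples in rows, probes in columns,
# dimnames present, non-missing values inside [0, 1].
#' @keywords internal
#' @noRd
.check_beta <- function(beta, allow_missing = TRUE, what = "beta") {
  .assert(is.matrix(beta) && is.numeric(beta),
          "%s must be a numeric matrix (samples x probes)", what)
  .assert(!is.null(rownames(beta)) && !is.null(colnames(beta)),
          "%s must carry sample ids (rownames) and probe ids (colnames)", what)
  .assert(!anyDuplicated(rownames(beta)), "%s has duplicated sample ids", what)
  .assert(!anyDuplicated(colnames(beta)), "%s has duplicated probe ids", what)
  v <- beta[!is.na(beta)]
  .assert(all(v >= 0 & v <= 1), "%s has values outside [0, 1]", what)
  if (!allow_missing) {
    .assert(!anyNA(beta), "%s contains missing values; run QC imputation first", what)
  }
  invisible(beta)
}

# Rank-based (Mann-Whitney) AUC of a score against a binary label.
# Ties in the score contribute 1/2 through midranks.
#' @keywords internal
#' @noRd
.rank_auc <- function(score, label) {
  label <- as.logical(label)
  n_pos <- sum(label)
  n_neg <- sum(!label)
  .assert(n_pos > 0 && n_neg > 0, "AUC undefined: outcome has a single class")
  r <- rank(score)
  (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Administrative censoring of (time, event) at a horizon.
#' @keywords internal
#' @noRd
.censor_at <- function(times, events, horizon) {
  .assert(is.numeric(times) && all(times >= 0), "times must be non-negative")
  e <- ifelse(times <= horizon, events, 0L)
  list(time = pmin(times, horizon), event = as.integer(e))
}

# Determinate 5-year vital status: TRUE = dead by horizon, FALSE = alive at
# horizon, NA = censored before the horizon (status unknowable).
#' @keywords internal
#' @noRd
.status_at_horizon <- function(times, events, horizon = 60) {
  dead <- events == 1 & times <= horizon
  alive <- times >= horizon & !dead
  out <- rep(NA, length(times))
  out[dead] <- TRUE
  out[alive] <- FALSE
  out
}

# Stratified fold assignment: samples within each stratum are spread across
# folds as evenly as possible, in randomized order.
#' @keywords internal
#' @noRd
.stratified_folds <- function(strata, n_folds) {
  folds <- integer(length(strata))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(sample.int(n_folds), length(idx))
  }
  folds
}

#' @keywords internal
#' @noRd
.derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% 2147483646L + 1L
}
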