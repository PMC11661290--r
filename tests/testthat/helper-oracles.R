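# Independent reference implementations used as oracles. These deliberately
# avoid the code paths (and packages) the implementation uses: the Cox oracle
# maximizes the Efron partial likelihood numerically with optim(), standard
# errors come from the numerical Hessian.

# Negative log partial likelihood with Efron handling of tied event times.
# x: n x p covariate matrix; b: coefficient vector.
efron_neg_loglik <- function(b, x, time, event) {
  lp <- as.vector(x %*% b)
  elp <- exp(lp)
  ll <- 0
  for (t in unique(time[event == 1])) {
    d_set <- which(event == 1 & time == t)
    r_set <- which(time >= t)
    d <- length(d_set)
    sum_r <- sum(elp[r_set])
    sum_d <- sum(elp[d_set])
    ll <- ll + sum(lp[d_set])
    l <- seq_len(d) - 1
    ll <- ll - sum(log(sum_r - (l / d) * sum_d))
  }
  -ll
}

# Numerical Hessian by central differences.
num_hessian <- function(f, b, eps = 1e-5) {
  p <- length(b)
  h <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in i:p) {
      bpp <- b; bpp[i] <- bpp[i] + eps; bpp[j] <- bpp[j] + eps
      bpm <- b; bpm[i] <- bpm[i] + eps; bpm[j] <- bpm[j] - eps
      bmp <- b; bmp[i] <- bmp[i] - eps; bmp[j] <- bmp[j] + eps
      bmm <- b; bmm[i] <- bmm[i] - eps; bmm[j] <- bmm[j] - eps
      h[i, j] <- (f(bpp) - f(bpm) - f(bmp) + f(bmm)) / (4 * eps^2)
      h[j, i] <- h[i, j]
    }
  }
  h
}

# Reference Cox fit: coefficients, standard errors, Wald p-values.
oracle_coxph <- function(x, time, event) {
  x <- as.matrix(x)
  f <- function(b) efron_neg_loglik(b, x, time, event)
  opt <- stats::optim(rep(0, ncol(x)), f, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  h <- num_hessian(f, opt$par)
  se <- sqrt(diag(solve(h)))
  z <- opt$par / se
  list(coef = opt$par, se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
}

# Brute-force O(n^2) concordance AUC (ties in the score count 1/2).
oracle_auc <- function(score, label) {
  pos <- which(label)
  neg <- which(!label)
  tot <- 0
  for (i in pos) {
    tot <- tot + sum(score[i] > score[neg]) + 0.5 * sum(score[i] == score[neg])
  }
  tot / (length(pos) * length(neg))
}

# Hand product-limit estimator (no censoring adjustment shortcuts).
oracle_km <- function(time, event) {
  ts <- sort(unique(time))
  s <- 1
  out <- data.frame(time = ts, surv = NA_real_)
  for (k in seq_along(ts)) {
    at_risk <- sum(time >= ts[k])
    d <- sum(time == ts[k] & event == 1)
    s <- s * (1 - d / at_risk)
    out$surv[k] <- s
  }
  out
}
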