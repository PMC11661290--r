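# Pairwise-controlled manifold approximation: graph construction and
# three-phase Adam optimization, following the published algorithm.
# Three pair sets control the layout: near pairs (scaled-distance nearest
# neighbours) pull, mid-near pairs preserve global structure early, and
# further (random far) pairs push. Loss terms use d~ = 1 + ||yi - yj||^2:
#   near:     w_NB * d~ / (10 + d~)
#   mid-near: w_MN * d~ / (10000 + d~)
#   further:  w_FP * 1 / (1 + d~)

#' @keywords internal
#' @noRd
.pacmap_pairs <- function(x, n_neighbors, mn_ratio, fp_ratio) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf

  # per-point scale: mean distance to the 4th-6th nearest neighbour
  sig <- apply(d, 1, function(r) mean(sort(r)[4:6]))
  sig <- pmax(sig, 1e-10)

  k_cand <- min(n - 1, n_neighbors + 50)
  nb <- matrix(0L, n, n_neighbors)
  for (i in seq_len(n)) {
    cand <- order(d[i, ])[seq_len(k_cand)]
    scaled <- d[i, cand]^2 / (sig[i] * sig[cand])
    nb[i, ] <- cand[order(scaled)[seq_len(n_neighbors)]]
  }
  pair_nb <- cbind(rep(seq_len(n), each = n_neighbors), as.vector(t(nb)))

  n_mn <- round(mn_ratio * n_neighbors)
  pair_mn <- NULL
  if (n_mn > 0 && n > 7) {
    mi <- rep(seq_len(n), each = n_mn)
    mj <- integer(length(mi))
    for (k in seq_along(mi)) {
      i <- mi[k]
      cand <- sample.int(n, 6)
      cand <- cand[cand != i]
      scaled <- d[i, cand]^2 / (sig[i] * sig[cand])
      mj[k] <- cand[order(scaled)[min(2L, length(cand))]]
    }
    pair_mn <- cbind(mi, mj)
  }

  n_fp <- round(fp_ratio * n_neighbors)
  pair_fp <- NULL
  if (n_fp > 0) {
    fi <- rep(seq_len(n), each = n_fp)
    fj <- integer(length(fi))
    for (i in seq_len(n)) {
      excl <- c(i, nb[i, ])
      pool <- seq_len(n)[-excl]
      fj[(i - 1L) * n_fp + seq_len(n_fp)] <- sample(pool, min(n_fp, length(pool)))
    }
    pair_fp <- cbind(fi, fj)
  }
  list(nb = pair_nb, mn = pair_mn, fp = pair_fp)
}

# gradient contribution of one pair set; scatter-added into an n x dims matrix
#' @keywords internal
#' @noRd
.pair_grad <- function(y, pairs, w, kind) {
  diff <- y[pairs[, 1], , drop = FALSE] - y[pairs[, 2], , drop = FALSE]
  dtil <- 1 + rowSums(diff^2)
  coef <- switch(kind,
                 nb = w * 20 / (10 + dtil)^2,
                 mn = w * 20000 / (10000 + dtil)^2,
                 fp = -w * 2 / (1 + dtil)^2)
  g <- diff * coef
  idx <- c(pairs[, 1], pairs[, 2])
  rowsum(rbind(g, -g), group = idx, reorder = TRUE)
}

#' @keywords internal
#' @noRd
.pacmap_optimize <- function(y, pairs, n_iters = c(100, 100, 250), lr = 1.0) {
  n <- nrow(y)
  m1 <- v1 <- matrix(0, n, ncol(y))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-7
  total <- sum(n_iters)
  t_adam <- 0
  for (itr in seq_len(total)) {
    if (itr <= n_iters[1]) {
      w_mn <- 1000 * (1 - (itr - 1) / n_iters[1]) + 3 * (itr - 1) / n_iters[1]
      w_nb <- 2; w_fp <- 1
    } else if (itr <= n_iters[1] + n_iters[2]) {
      w_nb <- 3; w_mn <- 3; w_fp <- 1
    } else {
      w_nb <- 1; w_mn <- 0; w_fp <- 1
    }
    grad <- matrix(0, n, ncol(y))
    add_into <- function(grad, gpart) {
      ids <- as.integer(rownames(gpart))
      grad[ids, ] <- grad[ids, ] + gpart
      grad
    }
    grad <- add_into(grad, .pair_grad(y, pairs$nb, w_nb, "nb"))
    if (!is.null(pairs$mn) && w_mn > 0) {
      grad <- add_into(grad, .pair_grad(y, pairs$mn, w_mn, "mn"))
    }
    if (!is.null(pairs$fp)) {
      grad <- add_into(grad, .pair_grad(y, pairs$fp, w_fp, "fp"))
    }
    t_adam <- t_adam + 1
    m1 <- beta1 * m1 + (1 - beta1) * grad
    v1 <- beta2 * v1 + (1 - beta2) * grad^2
    mhat <- m1 / (1 - beta1^t_adam)
    vhat <- v1 / (1 - beta2^t_adam)
    y <- y - lr * mhat / (sqrt(vhat) + eps)
  }
  y
}
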