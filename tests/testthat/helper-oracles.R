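# Independent straight-line oracles used across the suite. Each one
# re-derives the quantity from its definition (explicit loops, exhaustive
# enumeration) without calling the package's computational path.

# GSVA: explicit kernel-CDF evaluation, explicit ranked walk.
oracle_gsva <- function(expr, genes, tau = 1, kcdf = "gaussian") {
  p <- nrow(expr); n <- ncol(expr)
  z <- matrix(0, p, n)
  for (i in seq_len(p)) {
    if (kcdf == "gaussian") {
      h <- max(sd(expr[i, ]) / 4, 1e-8)
      for (j in seq_len(n)) z[i, j] <- mean(pnorm((expr[i, j] - expr[i, ]) / h))
    } else {
      for (j in seq_len(n)) z[i, j] <- mean(ppois(expr[i, j], expr[i, ] + 0.5))
    }
  }
  inset <- rownames(expr) %in% genes
  out <- numeric(n)
  for (j in seq_len(n)) {
    ord <- order(z[, j], decreasing = TRUE)
    rk <- integer(p); rk[ord] <- seq_len(p)
    r <- abs(p / 2 - rk)
    v <- numeric(p); num <- 0; den <- sum(r[inset]^tau); outc <- 0
    for (l in seq_len(p)) {
      g <- ord[l]
      if (inset[g]) num <- num + r[g]^tau else outc <- outc + 1
      v[l] <- num / den - outc / (p - sum(inset))
    }
    out[j] <- max(c(0, v[v > 0])) + min(c(0, v[v < 0]))
  }
  out
}

# ssGSEA: explicit per-position running sum for one sample and one set.
oracle_ssgsea_one <- function(values, gene_ids, set_genes, alpha = 0.25) {
  p <- length(values)
  ord <- order(values, decreasing = TRUE)
  inset_ord <- gene_ids[ord] %in% set_genes
  wts <- (p - seq_len(p) + 1)^alpha
  w <- ifelse(inset_ord, wts, 0)
  sum(cumsum(w) / sum(w) - cumsum(!inset_ord) / (p - sum(inset_ord)))
}

# Nearest-shrunken-centroid statistics and discriminants, formula by formula.
oracle_nsc <- function(x, labels, delta, newx, priors = NULL) {
  cls <- sort(unique(labels)); n <- length(labels); K <- length(cls)
  nk <- vapply(cls, function(c) sum(labels == c), numeric(1))
  cent <- vapply(cls, function(c) rowMeans(x[, labels == c, drop = FALSE]),
                 numeric(nrow(x)))
  cent <- matrix(cent, nrow = nrow(x))
  ov <- rowMeans(x)
  ss <- rowSums(vapply(cls, function(c) {
    rowSums((x[, labels == c, drop = FALSE] - cent[, which(cls == c)])^2)
  }, numeric(nrow(x))))
  si <- sqrt(ss / (n - K)); s0 <- median(si); mk <- sqrt(1 / nk - 1 / n)
  d <- sweep(sweep(cent - ov, 1, si + s0, "/"), 2, mk, "/")
  ds <- sign(d) * pmax(abs(d) - delta, 0)
  shr <- ov + sweep(sweep(ds, 1, si + s0, "*"), 2, mk, "*")
  if (is.null(priors)) priors <- nk / n
  surv <- apply(abs(ds), 1, max) > 0
  del <- vapply(seq_len(K), function(k) {
    if (any(surv)) {
      colSums(((newx[surv, , drop = FALSE] - shr[surv, k]) / (si + s0)[surv])^2) -
        2 * log(priors[k])
    } else rep(-2 * log(priors[k]), ncol(newx))
  }, numeric(ncol(newx)))
  del <- matrix(del, ncol = K)
  list(d = d, shrunken = shr, surviving = surv,
       label = cls[apply(del, 1, which.min)], delta_scores = del)
}

# Exhaustive k-medoids: minimum cost over all medoid subsets.
oracle_pam_cost <- function(d, k) {
  combos <- combn(nrow(d), k)
  min(apply(combos, 2, function(m) sum(apply(d[, m, drop = FALSE], 1, min))))
}

# Exact rank-sum: full enumeration of group-A index assignments,
# two-sided p as 2 * min(tails), capped at 1.
oracle_rank_sum_p <- function(a, b) {
  pooled <- c(a, b); n <- length(pooled); n_a <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  u_all <- apply(combn(n, n_a), 2, function(idx) sum(r[idx]) - n_a * (n_a + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Pixel-counting coverage oracle: fraction of patch pixel centers inside a
# disc, per patch of the grid covering the disc's bounding box.
oracle_disc_patch_count <- function(cx, cy, radius, patch = 224, min_cov = 0.75) {
  gx_range <- floor((cx - radius) / patch):ceiling((cx + radius) / patch)
  gy_range <- floor((cy - radius) / patch):ceiling((cy + radius) / patch)
  count <- 0
  for (gx in gx_range) for (gy in gy_range) {
    px <- (gx * patch):(gx * patch + patch - 1) + 0.5
    py <- (gy * patch):(gy * patch + patch - 1) + 0.5
    inside <- outer((px - cx)^2, (py - cy)^2, "+") <= radius^2
    if (mean(inside) >= min_cov) count <- count + 1
  }
  count
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

balanced_acc <- function(truth, pred) {
  mean(vapply(unique(truth), function(cl) mean(pred[truth == cl] == cl), numeric(1)))
}

# Random small classification instance for shrunken-centroid checks.
make_nsc_instance <- function(seed) {
  set.seed(seed)
  nf <- sample(2:5, 1)
  n <- sample(12:24, 1)
  k <- sample(2:3, 1)
  labs <- sample(paste0("C", seq_len(k)), n, replace = TRUE)
  while (min(table(labs)) < 3) labs <- sample(paste0("C", seq_len(k)), n, replace = TRUE)
  x <- matrix(rnorm(nf * n), nf, n,
              dimnames = list(paste0("f", seq_len(nf)), paste0("s", seq_len(n))))
  list(x = x, labels = labs)
}

# Small seeded expression fixture.
toy_expr <- function(p = 10, n = 4, seed = 42) {
  set.seed(seed)
  matrix(rnorm(p * n), p, n,
         dimnames = list(paste0("g", seq_len(p)), paste0("s", seq_len(n))))
}
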