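#' Single-sample gene-set variation scores (GSVA)
#'
#' Converts a genes x samples expression matrix into signatures x samples
#' enrichment scores. For each gene a cross-sample kernel CDF is estimated
#' (Gaussian kernel with bandwidth `sd/4`, or a shifted-Poisson kernel for
#' count-like data) and evaluated at each sample's value; within each sample
#' genes are ranked by that statistic and a weighted Kolmogorov-Smirnov
#' random walk over the ranked list yields the enrichment score per set.
#'
#' With `mx_diff = TRUE` (the conventional default) the score is the sum of
#' the largest positive and largest negative deviation of the walk, which
#' confines scores to `[-1, 1]`.
#'
#' @param expr Numeric matrix, genes x samples, log-scale; >= 2 samples
#'   (the cross-sample CDF is undefined for one sample).
#' @param panel A [signature_panel()].
#' @param kcdf Kernel: `"gaussian"` (log-scale data) or `"poisson"` (counts).
#' @param tau Rank-weight exponent of the random walk (default 1).
#' @param mx_diff If `TRUE`, score = max positive deviation + min negative
#'   deviation; if `FALSE`, the single maximum-magnitude deviation.
#' @param min_size Minimum set size after intersection with the gene
#'   universe (default 2); smaller sets raise an error naming the set.
#' @return Signatures x samples numeric matrix with attribute
#'   `method = "gsva"`.
#' @seealso [ssgsea_scores()], [zscore_rows()]
#' @export
gsva_scores <- function(expr, panel, kcdf = c("gaussian", "poisson"),
                        tau = 1, mx_diff = TRUE, min_size = 2L) {
  kcdf <- match.arg(kcdf)
  check_expression_matrix(expr, min_samples = 2L)
  panel <- restrict_panel(check_panel(panel), rownames(expr), min_size = min_size)
  z <- kernel_cdf_matrix(expr, kcdf)
  score_ranked_walk(z, panel, tau = tau, mx_diff = mx_diff, method = "gsva")
}

# Cross-sample kernel CDF estimate evaluated at each observed value.
kernel_cdf_matrix <- function(expr, kcdf) {
  p <- nrow(expr); n <- ncol(expr)
  z <- matrix(0, p, n, dimnames = dimnames(expr))
  if (kcdf == "gaussian") {
    bw <- pmax(matrixStats::rowSds(expr) / 4, 1e-8)  # floor: zero-variance genes
    for (i in seq_len(p)) {
      xi <- expr[i, ]
      z[i, ] <- rowMeans(pnorm(outer(xi, xi, "-") / bw[i]))
    }
  } else {
    for (i in seq_len(p)) {
      xi <- expr[i, ]
      z[i, ] <- rowMeans(outer(xi, xi, function(x, y) ppois(x, y + 0.5)))
    }
  }
  z
}

# Shared ranked-walk scorer: rank genes per sample by `stat` descending
# (ties by first occurrence), apply the symmetric rank statistic
# |p/2 - rank|, and run the weighted KS walk per set.
score_ranked_walk <- function(stat, panel, tau, mx_diff, method) {
  p <- nrow(stat); n <- ncol(stat)
  sets <- lapply(panel$sets, function(g) match(g, rownames(stat)))
  out <- matrix(NA_real_, length(sets), n,
                dimnames = list(names(sets), colnames(stat)))
  for (j in seq_len(n)) {
    ord <- order(stat[, j], decreasing = TRUE)       # stable: ties -> gene order
    rank_of <- integer(p); rank_of[ord] <- seq_len(p)
    r <- abs(p / 2 - rank_of)
    out[, j] <- vapply(sets, function(idx) {
      ks_walk_es(ord, r, idx, tau, mx_diff)
    }, numeric(1))
  }
  attr(out, "method") <- method
  out
}

# Weighted KS random walk over a ranked gene list; returns the enrichment
# score for one gene set.
ks_walk_es <- function(ord, r, set_idx, tau, mx_diff) {
  p <- length(ord); m <- length(set_idx)
  in_set <- logical(p); in_set[set_idx] <- TRUE
  in_ord <- in_set[ord]
  w <- ifelse(in_ord, r[ord]^tau, 0)
  denom_in <- sum(w)
  step_in <- if (denom_in > 0) cumsum(w) / denom_in else cumsum(in_ord) / m
  step_out <- cumsum(!in_ord) / (p - m)
  v <- step_in - step_out
  if (mx_diff) {
    max(c(0, v[v > 0])) + min(c(0, v[v < 0]))
  } else {
    v[which.max(abs(v))]
  }
}

#' Single-sample GSEA scores (ssGSEA)
#'
#' Per sample, genes are ranked by expression (descending; ties broken by
#' gene order) and the enrichment score is the summed difference between the
#' rank-weighted in-set ECDF (weights `rank^alpha`) and the uniform
#' out-of-set ECDF. Scores depend on within-sample ranks only. With
#' `normalize = TRUE` all scores are divided by the global score range.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param panel A [signature_panel()]; each set must be a strict subset of
#'   the gene universe.
#' @param alpha Rank weight exponent (default 0.25).
#' @param normalize Divide by `max(ES) - min(ES)` over the whole matrix.
#' @param min_size Minimum set size after universe intersection.
#' @return Signatures x samples matrix, attribute `method` of
#'   `"ssgsea"` or `"ssgsea_normalized"`.
#' @export
ssgsea_scores <- function(expr, panel, alpha = 0.25, normalize = TRUE,
                          min_size = 2L) {
  check_expression_matrix(expr, min_samples = 1L)
  panel <- restrict_panel(check_panel(panel), rownames(expr), min_size = min_size)
  whole <- vapply(panel$sets, function(g) length(g) >= nrow(expr), logical(1))
  if (any(whole)) {
    stop(sprintf("gene set(s) equal to the whole gene universe (out-of-set ECDF undefined): %s",
                 paste(names(panel$sets)[whole], collapse = ", ")), call. = FALSE)
  }
  p <- nrow(expr); n <- ncol(expr)
  sets <- lapply(panel$sets, function(g) match(g, rownames(expr)))
  out <- matrix(NA_real_, length(sets), n,
                dimnames = list(names(sets), colnames(expr)))
  for (j in seq_len(n)) {
    ord <- order(expr[, j], decreasing = TRUE)
    rank_of <- integer(p); rank_of[ord] <- seq_len(p)
    wts <- (p - seq_len(p) + 1)^alpha        # weight of the gene at walk position l
    for (s in seq_along(sets)) {
      in_ord <- logical(p); in_ord[rank_of[sets[[s]]]] <- TRUE
      w <- ifelse(in_ord, wts, 0)
      step_in <- cumsum(w) / sum(w)
      step_out <- cumsum(!in_ord) / (p - length(sets[[s]]))
      out[s, j] <- sum(step_in - step_out)
    }
  }
  if (normalize) {
    rng <- max(out) - min(out)
    if (rng > 0) out <- out / rng
    attr(out, "method") <- "ssgsea_normalized"
  } else {
    attr(out, "method") <- "ssgsea"
  }
  out
}

#' Row-wise z-scoring of a score matrix
#'
#' Maps each row to `(x - mean) / sd` (sample sd, `n - 1` denominator).
#' Constant rows are mapped to all zeros with a warning.
#'
#' @param scores Numeric matrix with >= 2 columns.
#' @return Matrix of the same shape, attribute `method = "zscored"`.
#' @export
zscore_rows <- function(scores) {
  if (!is.matrix(scores) || !is.numeric(scores)) stop("`scores` must be a numeric matrix", call. = FALSE)
  if (ncol(scores) < 2L) stop("z-scoring needs at least 2 samples", call. = FALSE)
  mu <- rowMeans(scores)
  s <- matrixStats::rowSds(scores)
  const <- s == 0
  if (any(const)) {
    warning(sprintf("%d constant row(s) mapped to zeros", sum(const)), call. = FALSE)
    s[const] <- 1
  }
  out <- (scores - mu) / s
  out[const, ] <- 0
  dimnames(out) <- dimnames(scores)
  attr(out, "method") <- "zscored"
  out
}

#' Select cell-type-rich spots from a spot score matrix
#'
#' Returns the spots (columns) whose score for `cell_type` strictly exceeds
#' the stated quantile (type-7, linear interpolation) of that row.
#'
#' @param scores Signatures x spots score matrix.
#' @param cell_type Row name to threshold on.
#' @param quantile Quantile cut (default 0.75).
#' @return Character vector of spot ids.
#' @export
rich_region_spots <- function(scores, cell_type, quantile = 0.75) {
  if (!is.matrix(scores)) stop("`scores` must be a matrix", call. = FALSE)
  if (!cell_type %in% rownames(scores)) {
    stop(sprintf("unknown cell type '%s'", cell_type), call. = FALSE)
  }
  row <- scores[cell_type, ]
  cut <- stats::quantile(row, probs = quantile, type = 7, names = FALSE)
  colnames(scores)[row > cut]
}
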