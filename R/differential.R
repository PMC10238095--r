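#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration of the rank-sum null (handling ties by full
#' combinatorial enumeration) when `n_a + n_b <= 12` or `mode = "exact"`;
#' otherwise a normal approximation with tie-corrected variance and no
#' continuity correction. The reported statistic is the centered
#' Mann-Whitney `U - n_a n_b / 2`.
#'
#' @param group_a,group_b Numeric vectors (both nonempty).
#' @param mode `"auto"` (default), `"exact"` or `"normal"`.
#' @return List with `statistic` (centered U) and `p`.
#' @export
rank_sum_test <- function(group_a, group_b, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(group_a) == 0 || length(group_b) == 0) stop("both groups must be nonempty", call. = FALSE)
  n_a <- length(group_a); n_b <- length(group_b)
  if (mode == "auto") mode <- if (n_a + n_b <= 12) "exact" else "normal"
  pooled <- c(group_a, group_b)
  if (length(unique(pooled)) == 1L) {
    return(list(statistic = 0, p = 1))
  }
  r <- rank(pooled)
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  centered <- u - n_a * n_b / 2
  if (mode == "exact") {
    p <- exact_rank_sum_p(pooled, n_a, u)
  } else {
    ties <- table(r)
    n <- n_a + n_b
    sigma2 <- n_a * n_b / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- centered / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(statistic = centered, p = p)
}

# Exact two-sided p by enumeration of all group-A index assignments;
# two-sided as 2 * min(tail probabilities), capped at 1.
exact_rank_sum_p <- function(pooled, n_a, u_obs) {
  n <- length(pooled)
  r <- rank(pooled)
  offset <- n_a * (n_a + 1) / 2
  combos <- combn(n, n_a)
  u_all <- colSums(matrix(r[combos], nrow = n_a)) - offset
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, clipped at 1 and monotone with the p-value
#' ranks.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted q-values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvalues, method = "BH")
}

# Vectorised rank-sum over matrix rows; returns centered statistics and
# normal-approximation p-values (used for cohort-scale scans).
rank_sum_rows <- function(mat, in_group) {
  n_a <- sum(in_group); n_b <- sum(!in_group); n <- n_a + n_b
  r <- t(apply(mat, 1, rank))
  u <- rowSums(r[, in_group, drop = FALSE]) - n_a * (n_a + 1) / 2
  centered <- u - n_a * n_b / 2
  tie_term <- apply(r, 1, function(rr) {
    tt <- table(rr)
    sum(tt^3 - tt)
  })
  sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  sigma2 <- pmax(sigma2, .Machine$double.eps)
  z <- centered / sqrt(sigma2)
  p <- pmin(1, 2 * pnorm(-abs(z)))
  p[apply(mat, 1, function(v) length(unique(v)) == 1L)] <- 1
  list(statistic = centered, p = p)
}

# Vectorised Welch t over matrix rows.
welch_t_rows <- function(mat, in_group) {
  a <- mat[, in_group, drop = FALSE]; b <- mat[, !in_group, drop = FALSE]
  n_a <- ncol(a); n_b <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- matrixStats::rowVars(a); vb <- matrixStats::rowVars(b)
  se2 <- va / n_a + vb / n_b
  tstat <- (ma - mb) / sqrt(pmax(se2, .Machine$double.eps))
  df <- se2^2 / pmax(va^2 / (n_a^2 * (n_a - 1)) + vb^2 / (n_b^2 * (n_b - 1)),
                     .Machine$double.eps)
  p <- pmin(1, 2 * stats::pt(-abs(tstat), df))
  p[se2 == 0] <- 1
  list(statistic = tstat, p = p)
}

differential_table <- function(mat, in_group, comparison, test) {
  res <- switch(test,
                rank_sum = rank_sum_rows(mat, in_group),
                welch_t = welch_t_rows(mat, in_group))
  effect <- unname(rowMeans(mat[, in_group, drop = FALSE]) -
                     rowMeans(mat[, !in_group, drop = FALSE]))
  p <- unname(res$p)
  tibble::tibble(feature = rownames(mat), comparison = comparison,
                 effect = effect, statistic = unname(res$statistic), p = p,
                 fdr = bh_fdr(p),
                 direction = ifelse(effect >= 0, "up", "down"))
}

#' One-vs-rest differential analysis
#'
#' For each class, tests every feature between that class and all remaining
#' samples. Effects are mean differences on the (log) input scale;
#' Benjamini-Hochberg correction is applied within each comparison.
#'
#' @param mat Features x samples numeric matrix.
#' @param labels Class label per sample.
#' @param test `"rank_sum"` (default) or `"welch_t"`.
#' @return Tibble of [rank_sum_test()]-style rows: `feature`, `comparison`
#'   (`<class>-vs-rest`), `effect`, `statistic`, `p`, `fdr`, `direction`.
#' @export
one_vs_rest_differential <- function(mat, labels, test = c("rank_sum", "welch_t")) {
  test <- match.arg(test)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need >= 2 classes", call. = FALSE)
  small <- classes[vapply(classes, function(cl) sum(labels == cl) < 2L, logical(1))]
  if (length(small) > 0) stop("class(es) of size < 2: ", paste(small, collapse = ", "), call. = FALSE)
  purrr::map_dfr(classes, function(cl) {
    differential_table(mat, labels == cl, paste0(cl, "-vs-rest"), test)
  })
}

#' Pairwise differential analysis between all class pairs
#'
#' Runs every unordered class pair `(a, b)` (classes in sorted order;
#' effect = mean(b) - mean(a) so the sign points from the earlier to the
#' later class label).
#'
#' @inheritParams one_vs_rest_differential
#' @return Tibble with `comparison` of the form `"a-vs-b"`.
#' @export
pairwise_differential <- function(mat, labels, test = c("rank_sum", "welch_t")) {
  test <- match.arg(test)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need >= 2 classes", call. = FALSE)
  pairs <- combn(classes, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    sub <- labels %in% c(a, b)
    differential_table(mat[, sub, drop = FALSE], labels[sub] == b,
                       paste0(a, "-vs-", b), test)
  })
}

#' Subtype-specific feature selection
#'
#' From per-class one-vs-rest results, keeps each class's significant
#' features (`fdr < fdr_cut`, optional `direction == "up"` filter) and then
#' removes any feature that is also significant in another class's
#' one-vs-rest comparison, so the resulting lists are pairwise disjoint.
#' Optionally ranks by `|effect|` and truncates at `top_n`.
#'
#' @param ovr Tibble from [one_vs_rest_differential()].
#' @param fdr_cut Significance cut on the per-comparison FDR.
#' @param top_n Optional truncation after ranking by `|effect|`.
#' @param direction `"up"` (default: positively associated features only)
#'   or `"any"`.
#' @return Named list of feature vectors, one per class.
#' @export
subtype_specific_features <- function(ovr, fdr_cut = 0.05, top_n = NULL,
                                      direction = c("up", "any")) {
  direction <- match.arg(direction)
  classes <- sub("-vs-rest$", "", unique(ovr$comparison))
  sig_any <- lapply(classes, function(cl) {
    d <- ovr[ovr$comparison == paste0(cl, "-vs-rest") & ovr$fdr < fdr_cut, ]
    d$feature
  })
  names(sig_any) <- classes
  out <- lapply(classes, function(cl) {
    d <- ovr[ovr$comparison == paste0(cl, "-vs-rest") & ovr$fdr < fdr_cut, ]
    if (direction == "up") d <- d[d$direction == "up", ]
    others <- unlist(sig_any[setdiff(classes, cl)], use.names = FALSE)
    d <- d[!d$feature %in% others, ]
    d <- d[order(-abs(d$effect)), ]
    if (!is.null(top_n)) d <- head(d, top_n)
    d$feature
  })
  names(out) <- classes
  out
}

#' Differentially methylated gene filter
#'
#' A gene is a DMG when its mean promoter beta value is `< 0.2` in normal
#' samples, `> 0.5` in tumor samples, and the test FDR is `< 0.05` (all
#' strict).
#'
#' @param beta_normal_means,beta_tumor_means Named numeric vectors of
#'   per-gene mean beta values in `[0, 1]`.
#' @param fdrs Named numeric vector of FDRs (same genes).
#' @param normal_cut,tumor_cut,fdr_cut Thresholds (defaults 0.2, 0.5, 0.05).
#' @return Character vector of DMG gene ids.
#' @export
dmg_filter <- function(beta_normal_means, beta_tumor_means, fdrs,
                       normal_cut = 0.2, tumor_cut = 0.5, fdr_cut = 0.05) {
  if (any(beta_normal_means < 0 | beta_normal_means > 1) ||
      any(beta_tumor_means < 0 | beta_tumor_means > 1)) {
    stop("beta values must lie in [0, 1]", call. = FALSE)
  }
  genes <- names(beta_normal_means)
  keep <- beta_normal_means < normal_cut & beta_tumor_means > tumor_cut &
    fdrs < fdr_cut
  genes[keep]
}

#' Aggregate promoter probes to gene-level beta values
#'
#' Per gene, the median beta value across its mapped promoter probes per
#' sample. Probes with missing values are dropped before taking the
#' median; genes with no remaining probes are absent from the output.
#' Restriction to promoter regions (TSS200, 1stExon, TSS1500, 5'UTR) and
#' autosomes is expected upstream.
#'
#' @param probe_betas Probes x samples beta-value matrix (may contain NA).
#' @param probe_to_gene Named character vector mapping probe id -> gene id.
#' @return Genes x samples matrix of median beta values.
#' @export
aggregate_promoter_probes <- function(probe_betas, probe_to_gene) {
  probes <- intersect(rownames(probe_betas), names(probe_to_gene))
  if (length(probes) == 0L) stop("no probes map to genes", call. = FALSE)
  genes <- split(probes, probe_to_gene[probes])
  rows <- lapply(genes, function(pr) {
    vals <- probe_betas[pr, , drop = FALSE]
    apply(vals, 2, function(col) {
      col <- col[!is.na(col)]
      if (length(col) == 0L) NA_real_ else median(col)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(genes)
  out[rowSums(!is.na(out)) > 0, , drop = FALSE]
}
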