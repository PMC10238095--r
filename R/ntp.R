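#' Cancer-cell-intrinsic marker filter for the pre-clinical model
#'
#' Two cascaded pure filters on per-class subtype marker lists:
#'
#' 1. PDX filter - a gene is cancer-cell-intrinsic when the human-tumor vs
#'    patient-derived-xenograft comparison shows no stromal/immune signal:
#'    FDR > 0.5 and |log2FC| < 1.
#' 2. Cell-line expression filter - the gene's maximum expression across
#'    cell lines must lie within the 10-90 percentile range of all gene
#'    maxima, rank in the top 25% by that maximum, and exceed a
#'    high-expression threshold (the `high_quantile` quantile of all matrix
#'    values) in at least `min_high_lines` lines.
#'
#' Classes whose list empties are dropped with a warning.
#'
#' @param subtype_markers Named list of per-class gene vectors (already
#'   truncated upstream, e.g. top 500 by log2FC).
#' @param pdx_diff Tibble with `feature`, `effect` (log2FC) and `fdr` from
#'   the human-tumor vs PDX comparison; genes absent from it are dropped.
#' @param cell_line_expr Genes x cell-lines log-scale expression matrix.
#' @param pdx_fdr_min,pdx_lfc_max PDX filter cuts (defaults 0.5 and 1).
#' @param range_quantiles Percentile gate on gene maxima (default
#'   `c(0.1, 0.9)`).
#' @param top_fraction Top rank fraction by gene maximum (default 0.25).
#' @param high_quantile Quantile of all matrix values defining "high"
#'   expression (default 0.75).
#' @param min_high_lines Minimum number of high-expressing lines (default 3).
#' @return Named list of filtered per-class gene vectors.
#' @export
intrinsic_gene_filter <- function(subtype_markers, pdx_diff, cell_line_expr,
                                  pdx_fdr_min = 0.5, pdx_lfc_max = 1,
                                  range_quantiles = c(0.1, 0.9),
                                  top_fraction = 0.25,
                                  high_quantile = 0.75, min_high_lines = 3L) {
  intrinsic <- pdx_diff$feature[pdx_diff$fdr > pdx_fdr_min &
                                  abs(pdx_diff$effect) < pdx_lfc_max]
  gene_max <- matrixStats::rowMaxs(cell_line_expr)
  names(gene_max) <- rownames(cell_line_expr)
  rng <- stats::quantile(gene_max, range_quantiles, names = FALSE)
  in_range <- gene_max >= rng[1] & gene_max <= rng[2]
  top_cut <- stats::quantile(gene_max, 1 - top_fraction, names = FALSE)
  in_top <- gene_max >= top_cut
  high_cut <- stats::quantile(cell_line_expr, high_quantile, names = FALSE)
  n_high <- rowSums(cell_line_expr > high_cut)
  expr_pass <- rownames(cell_line_expr)[in_range & in_top & n_high >= min_high_lines]
  out <- lapply(subtype_markers, function(g) intersect(intersect(g, intrinsic), expr_pass))
  empty <- lengths(out) == 0L
  if (any(empty)) {
    warning("class(es) dropped after intrinsic filtering: ",
            paste(names(out)[empty], collapse = ", "), call. = FALSE)
    out <- out[!empty]
  }
  out
}

#' Build a template set from per-class marker lists
#'
#' @param markers Named list of pairwise-disjoint, nonempty per-class gene
#'   vectors.
#' @param min_markers Minimum markers a class must retain in the data
#'   (default 5).
#' @return A `template_set` object.
#' @export
template_set <- function(markers, min_markers = 5L) {
  stopifnot(is.list(markers), !is.null(names(markers)))
  if (any(lengths(markers) == 0L)) stop("every class needs >= 1 marker", call. = FALSE)
  all_genes <- unlist(markers, use.names = FALSE)
  if (anyDuplicated(all_genes)) stop("marker lists must be pairwise disjoint", call. = FALSE)
  structure(list(markers = lapply(markers, as.character),
                 min_markers = as.integer(min_markers)),
            class = "template_set")
}

#' Nearest-template prediction with permutation FDR
#'
#' Rows of `expr` are z-scored over samples; each sample's standardized
#' values over the marker union are compared to each class's binary
#' template by cosine distance (`d_k = 1 - cosine`), and the sample is
#' assigned to the nearest template. Significance: for each of `n_perm`
#' draws, marker positions are resampled from the gene universe (same set
#' sizes) and the null minimum distance over classes is recorded; the
#' sample's p-value is the fraction of draws with null distance <= the
#' observed minimum, and FDR is Benjamini-Hochberg across samples.
#'
#' @param expr Genes x samples matrix (>= 2 samples for row z-scoring).
#' @param templates A [template_set()]; markers absent from the matrix are
#'   dropped with a warning, `min_markers` enforced.
#' @param n_perm Number of null draws (default 1000; < 100 warns).
#' @param seed Seed for the null draws.
#' @return Tibble: `sample_id`, `label`, one `dist_<class>` column per
#'   class, `p`, `fdr`.
#' @export
ntp_classify <- function(expr, templates, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(templates, "template_set"))
  check_expression_matrix(expr, min_samples = 2L)
  if (n_perm < 100) warning("n_perm < 100 gives coarse p-values", call. = FALSE)
  markers <- lapply(templates$markers, intersect, y = rownames(expr))
  dropped <- sum(lengths(templates$markers)) - sum(lengths(markers))
  if (dropped > 0) warning(dropped, " marker gene(s) absent from the matrix dropped", call. = FALSE)
  short <- lengths(markers) < templates$min_markers
  if (any(short)) {
    stop("class(es) below min_markers after matching: ",
         paste(names(markers)[short], collapse = ", "), call. = FALSE)
  }
  if (length(markers) < 2L) stop("need >= 2 classes", call. = FALSE)

  z <- zscore_rows(expr)
  union_genes <- unlist(markers, use.names = FALSE)
  tmpl <- vapply(names(markers), function(cl) {
    as.numeric(union_genes %in% markers[[cl]])
  }, numeric(length(union_genes)))

  obs <- cosine_distances(z[union_genes, , drop = FALSE], tmpl)
  lab <- names(markers)[apply(obs, 1, which.min)]
  d_min <- matrixStats::rowMins(obs)

  n_genes <- nrow(z)
  null_min <- matrix(NA_real_, n_perm, ncol(z))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n_genes, length(union_genes))
      nd <- cosine_distances(z[idx, , drop = FALSE], tmpl)
      null_min[b, ] <- matrixStats::rowMins(nd)
    }
  })
  p <- vapply(seq_len(ncol(z)), function(j) mean(null_min[, j] <= d_min[j]),
              numeric(1))
  out <- tibble::tibble(sample_id = colnames(z), label = lab)
  for (k in seq_along(markers)) out[[paste0("dist_", names(markers)[k])]] <- obs[, k]
  out$p <- p
  out$fdr <- bh_fdr(p)
  out
}

# 1 - cosine similarity between each column of `x` (samples) and each
# template column; returns samples x templates.
cosine_distances <- function(x, templates) {
  num <- t(x) %*% templates
  xn <- sqrt(colSums(x^2))
  tn <- sqrt(colSums(templates^2))
  sim <- num / (pmax(xn, .Machine$double.eps) %o% tn)
  1 - sim
}
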