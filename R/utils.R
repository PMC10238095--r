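#' @importFrom stats pnorm ppois quantile sd median cor hclust cutree as.dist
#'   p.adjust rnorm runif setNames pwilcox complete.cases
#' @importFrom rlang .data
#' @importFrom utils head combn
NULL

# Validate a genes-x-samples numeric matrix with unique dimnames.
check_expression_matrix <- function(expr, min_samples = 1L, arg = "expr") {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop(sprintf("`%s` must be a numeric matrix (genes x samples)", arg), call. = FALSE)
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop(sprintf("`%s` must have gene rownames and sample colnames", arg), call. = FALSE)
  }
  if (anyDuplicated(rownames(expr))) {
    stop(sprintf("`%s` has duplicated gene ids; collapse duplicates first (see collapse_duplicate_genes)", arg),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(expr))) {
    stop(sprintf("`%s` has duplicated sample ids", arg), call. = FALSE)
  }
  if (anyNA(expr)) stop(sprintf("`%s` contains missing values", arg), call. = FALSE)
  if (ncol(expr) < min_samples) {
    stop(sprintf("`%s` needs at least %d sample(s)", arg, min_samples), call. = FALSE)
  }
  invisible(expr)
}

check_panel <- function(panel) {
  if (!inherits(panel, "signature_panel")) {
    stop("`panel` must be a signature_panel (see signature_panel() or read_gmt())", call. = FALSE)
  }
  invisible(panel)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a per-replicate seed from a master seed; keeps results
# order-independent across replicates and within 32-bit range.
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 16807) %% 2147483647)
}

balanced_accuracy <- function(truth, predicted) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  classes <- unique(truth)
  mean(vapply(classes, function(cl) {
    mean(predicted[truth == cl] == cl)
  }, numeric(1)))
}

# Stratified fold assignment: within each class, shuffled samples are
# dealt round-robin into folds.
stratified_folds <- function(labels, n_folds, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}
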