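#' Pearson distance between items (columns)
#'
#' `d(a, b) = 1 - cor(a, b)`; symmetric, zero diagonal, range `[0, 2]`.
#'
#' @param x Numeric matrix, features x items (e.g. signature scores with
#'   samples as columns); >= 2 features per item.
#' @return Items x items distance matrix.
#' @export
pearson_distance <- function(x) {
  if (!is.matrix(x) || nrow(x) < 2L) stop("need a matrix with >= 2 features per item", call. = FALSE)
  s <- matrixStats::colSds(x)
  if (any(s == 0)) {
    bad <- colnames(x)[s == 0]
    if (is.null(bad)) bad <- which(s == 0)
    stop("constant item vector(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  d <- 1 - cor(x)
  d[d < 0] <- 0          # guard numerical -1e-17
  diag(d) <- 0
  d
}

#' k-medoids clustering (PAM, BUILD + SWAP)
#'
#' Partitioning around medoids on a precomputed dissimilarity matrix:
#' greedy BUILD initialisation followed by SWAP passes until no exchange of
#' a medoid with a non-medoid lowers the total within-cluster
#' distance-to-medoid. Deterministic given the input; a local optimum.
#'
#' @param dist Symmetric nonnegative dissimilarity matrix.
#' @param k Number of clusters, `1 <= k <= n`.
#' @param seed Unused (the algorithm is deterministic); kept so callers can
#'   thread a seed uniformly through clustering backends.
#' @return List with `assignments` (integer vector named by item),
#'   `medoids` (item indices) and `cost` (total distance to assigned
#'   medoid).
#' @export
pam_cluster <- function(dist, k, seed = NULL) {
  if (!is.matrix(dist)) dist <- as.matrix(dist)
  n <- nrow(dist)
  if (k > n) stop(sprintf("k = %d exceeds the number of items (%d)", k, n), call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k == n) {
    return(list(assignments = setNames(seq_len(n), rownames(dist)),
                medoids = seq_len(n), cost = 0))
  }
  fit <- cluster::pam(stats::as.dist(dist), k = k, diss = TRUE,
                      do.swap = TRUE, cluster.only = FALSE, keep.diss = FALSE)
  medoids <- as.integer(fit$id.med)
  assignments <- as.integer(fit$clustering)
  cost <- sum(dist[cbind(seq_len(n), medoids[assignments])])
  names(assignments) <- rownames(dist)
  list(assignments = assignments, medoids = medoids, cost = cost)
}

#' Consensus clustering of samples by resampled k-medoids
#'
#' For each candidate `k`, repeatedly subsamples `ceiling(p_item * n)`
#' samples without replacement, clusters them with PAM on Pearson distance
#' of their score profiles, and accumulates co-clustering frequencies given
#' co-sampling. Final assignments per `k` come from average-linkage
#' hierarchical clustering of `1 - M` cut at `k`. Model selection uses the
#' consensus CDF and delta-area curve (see [cdf_and_delta_area()]).
#'
#' @param scores Signatures x samples score matrix (items = columns).
#' @param k_range Candidate cluster numbers (default `2:6`).
#' @param reps Number of resampling iterations (default 1000).
#' @param p_item Subsample fraction in `(0, 1]` (default 0.8).
#' @param seed Master seed; per-rep seeds are derived from it so replicates
#'   are order-independent.
#' @param delta_threshold Relative-gain threshold passed to
#'   [cdf_and_delta_area()].
#' @return A `consensus_result` object: per-k consensus matrices,
#'   assignments, CDF areas, delta areas and `chosen_k`.
#' @export
consensus_cluster <- function(scores, k_range = 2:6, reps = 1000, p_item = 0.8,
                              seed = 1L, delta_threshold = 0.1) {
  if (!is.matrix(scores)) stop("`scores` must be a matrix (signatures x samples)", call. = FALSE)
  if (reps < 1) stop("`reps` must be >= 1", call. = FALSE)
  if (p_item <= 0 || p_item > 1) stop("`p_item` must be in (0, 1]", call. = FALSE)
  n <- ncol(scores)
  ids <- colnames(scores)
  m_sub <- ceiling(p_item * n)

  # Subsamples are shared across k so consensus matrices are comparable.
  subsamples <- lapply(seq_len(reps), function(r) {
    with_seed(derive_seed(seed, r), sort(sample.int(n, m_sub)))
  })

  per_k <- list()
  for (k in k_range) {
    co_cluster <- matrix(0, n, n)
    co_sample <- matrix(0, n, n)
    for (r in seq_len(reps)) {
      idx <- subsamples[[r]]
      d <- pearson_distance(scores[, idx, drop = FALSE])
      cl <- pam_cluster(d, k)$assignments
      co_sample[idx, idx] <- co_sample[idx, idx] + 1
      same <- outer(cl, cl, "==")
      co_cluster[idx, idx] <- co_cluster[idx, idx] + same
    }
    M <- ifelse(co_sample > 0, co_cluster / pmax(co_sample, 1), 0)
    diag(M) <- 1
    M <- (M + t(M)) / 2
    dimnames(M) <- list(ids, ids)
    hc <- hclust(as.dist(1 - M), method = "average")
    assignments <- cutree(hc, k = k)
    names(assignments) <- ids
    per_k[[as.character(k)]] <- list(k = k, M = M, assignments = assignments)
  }

  res <- structure(list(k_range = as.integer(k_range), per_k = per_k,
                        reps = reps, p_item = p_item, seed = seed),
                   class = "consensus_result")
  sel <- cdf_and_delta_area(res, delta_threshold = delta_threshold)
  res$area <- sel$area
  res$delta_area <- sel$delta_area
  res$cdf <- sel$cdf
  res$chosen_k <- sel$chosen_k
  res
}

#' Consensus CDF areas, delta-area curve and cluster-number choice
#'
#' The empirical CDF is taken over the upper-triangle entries of each
#' consensus matrix. The area under the CDF is the step-function integral
#' `A(k) = sum (x_{i+1} - x_i) * CDF(x_i)` over sorted support values.
#' `delta(2) = A(2)` by convention and
#' `delta(k) = (A(k) - A(k-1)) / A(k-1)` for larger `k`; the chosen `k` is
#' the largest one reached before the relative gain falls below
#' `delta_threshold` (user-overridable).
#'
#' @param result A `consensus_result` (or its `per_k` list).
#' @param delta_threshold Relative-gain threshold (default 0.1).
#' @return List with `area`, `delta_area` (named by k), `cdf` (per-k
#'   tibbles of support and CDF values) and `chosen_k`.
#' @export
cdf_and_delta_area <- function(result, delta_threshold = 0.1) {
  per_k <- if (inherits(result, "consensus_result")) result$per_k else result
  if (length(per_k) < 2L) stop("need >= 2 values of k", call. = FALSE)
  ks <- vapply(per_k, function(e) e$k, numeric(1))
  area <- vapply(per_k, function(e) consensus_cdf_area(e$M)$area, numeric(1))
  cdf <- lapply(per_k, function(e) consensus_cdf_area(e$M)$cdf)
  names(area) <- names(cdf) <- names(per_k)
  delta <- numeric(length(ks))
  delta[1] <- area[1]
  if (length(ks) > 1) {
    for (i in 2:length(ks)) delta[i] <- (area[i] - area[i - 1]) / area[i - 1]
  }
  names(delta) <- names(per_k)
  below <- which(delta < delta_threshold)
  below <- below[below > 1]       # delta(first k) = A(first k) by convention
  chosen_idx <- if (length(below) == 0) length(ks) else min(below) - 1L
  list(area = area, delta_area = delta, cdf = cdf,
       chosen_k = as.integer(ks[chosen_idx]))
}

consensus_cdf_area <- function(M) {
  if (length(M) == 0L) stop("empty consensus matrix", call. = FALSE)
  vals <- M[upper.tri(M)]
  if (length(vals) == 0L) stop("consensus matrix has no off-diagonal entries", call. = FALSE)
  support <- sort(unique(vals))
  cdf_vals <- vapply(support, function(x) mean(vals <= x), numeric(1))
  area <- 0
  if (length(support) > 1) {
    area <- sum(diff(support) * cdf_vals[-length(cdf_vals)])
  }
  list(area = area,
       cdf = tibble::tibble(support = support, cdf = cdf_vals))
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> %d items, k in {%s}, %d reps, p_item %.2f\n",
              ncol(x$per_k[[1]]$M), paste(x$k_range, collapse = ", "),
              x$reps, x$p_item))
  cat(sprintf("  chosen_k = %d; delta areas: %s\n", x$chosen_k,
              paste(sprintf("%s=%.3f", names(x$delta_area), x$delta_area),
                    collapse = ", ")))
  invisible(x)
}

#' @rdname tidy-cccrc
#' @export
tidy.consensus_result <- function(x, ...) {
  purrr::map_dfr(x$per_k, function(e) {
    tibble::tibble(k = e$k, sample_id = names(e$assignments),
                   cluster = unname(e$assignments))
  })
}

#' @rdname tidy-cccrc
#' @export
glance.consensus_result <- function(x, ...) {
  tibble::tibble(k = x$k_range, area = unname(x$area),
                 delta_area = unname(x$delta_area),
                 chosen = x$k_range == x$chosen_k)
}

#' Consensus assignments for one k
#'
#' @param result A `consensus_result`.
#' @param k Cluster number (default the chosen one).
#' @param prefix Label prefix, default `"C"` giving labels `C1..Ck`.
#' @return Named character vector of subtype labels.
#' @export
consensus_assignments <- function(result, k = result$chosen_k, prefix = "C") {
  e <- result$per_k[[as.character(k)]]
  if (is.null(e)) stop("k = ", k, " was not evaluated", call. = FALSE)
  setNames(paste0(prefix, e$assignments), names(e$assignments))
}
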